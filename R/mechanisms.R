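.MECHANISMS <- c("compensatory", "compensatory_misregulated", "none",
                 "unevaluable")

#' Classify putative regulatory mechanisms per gene
#'
#' Implements the three-criterion call for compensatory cis-trans divergence:
#' a gene is compensatory when it (1) is \emph{not} differentially expressed
#' between the parental species, (2) shows hybrid ASE, and (3) shows no ASE
#' in any parental sample. If such a gene is additionally misregulated in
#' hybrids it is labelled \code{compensatory_misregulated}. Genes without
#' retained heterozygous sites are \code{unevaluable}; everything else is
#' \code{none}.
#'
#' @param deP1P2 DE table (gene, log2FC, padj) of parent2 vs parent1.
#' @param aseStatus output of [geneASECall()] (gene, hybrid_ase,
#'   parental_ase; NA status means unevaluable).
#' @param misregulated output of [misregulatedPooled()] (gene,
#'   misregulated), or NULL to treat all genes as not misregulated.
#' @param fdr threshold on parental-DE adjusted p.
#' @param cisConsistency also emit an exploratory column comparing the
#'   hybrid allelic direction with the parental fold-change direction
#'   (requires a \code{hybrid_major_allele} column in \code{aseStatus};
#'   off by default).
#' @return data.frame with gene, mechanism and the four evidence booleans.
#' @export
classifyMechanism <- function(deP1P2, aseStatus, misregulated = NULL,
                              fdr = 0.05, cisConsistency = FALSE) {
  deP1P2 <- .checkDEtable(deP1P2, "deP1P2")
  if (anyDuplicated(deP1P2$gene) || anyDuplicated(aseStatus$gene))
    stop("conflicting duplicate gene records")
  genes <- intersect(deP1P2$gene, aseStatus$gene)
  iD <- match(genes, deP1P2$gene)
  iA <- match(genes, aseStatus$gene)
  parentalDE <- !is.na(deP1P2$padj[iD]) & deP1P2$padj[iD] <= fdr
  hybAse <- aseStatus$hybrid_ase[iA]
  parAse <- aseStatus$parental_ase[iA]
  mis <- rep(FALSE, length(genes))
  if (!is.null(misregulated)) {
    iM <- match(genes, misregulated$gene)
    mis <- !is.na(misregulated$misregulated[iM]) & misregulated$misregulated[iM]
  }
  mech <- rep("none", length(genes))
  unev <- is.na(hybAse) | is.na(parAse)
  comp <- !unev & !parentalDE & hybAse & !parAse
  mech[comp] <- ifelse(mis[comp], "compensatory_misregulated", "compensatory")
  mech[unev] <- "unevaluable"
  out <- data.frame(gene = genes,
                    mechanism = factor(mech, levels = .MECHANISMS),
                    parental_de = parentalDE, hybrid_ase = hybAse,
                    parental_ase = parAse, misregulated = mis,
                    stringsAsFactors = FALSE)
  if (cisConsistency) {
    dirP <- sign(deP1P2$log2FC[iD])
    maj <- aseStatus$hybrid_major_allele[iA]
    out$cis_consistent <- ifelse(is.na(maj) | dirP == 0, NA,
                                 (maj == 2) == (dirP > 0))
  }
  out
}

#' Summarize mechanism calls
#'
#' Counts and percentages per mechanism against the eligible denominator
#' (evaluable genes without parental DE, mirroring how compensatory
#' candidates are screened), plus the overlap percentage of compensatory
#' genes that are also misregulated. Numerator and denominator always
#' accompany each percentage.
#'
#' @param calls output of [classifyMechanism()].
#' @return list with \code{counts} (data.frame), \code{eligible} denominator,
#'   and \code{overlap} (a [proportionSummary()] of misregulated compensatory
#'   genes among all compensatory genes, or NULL when there are none).
#' @export
mechanismSummary <- function(calls) {
  eligible <- sum(calls$mechanism != "unevaluable" & !calls$parental_de)
  if (eligible == 0) stop("no eligible genes (zero denominator)")
  tab <- table(calls$mechanism)
  counts <- data.frame(mechanism = names(tab), n = as.integer(tab),
                       eligible = eligible,
                       percent = .pct(as.integer(tab), eligible),
                       stringsAsFactors = FALSE)
  nComp <- sum(tab[c("compensatory", "compensatory_misregulated")])
  overlap <- NULL
  if (nComp > 0)
    overlap <- proportionSummary(as.integer(tab["compensatory_misregulated"]),
                                 nComp, digits = 1)
  list(counts = counts, eligible = eligible, overlap = overlap)
}
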
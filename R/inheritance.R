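.MODES <- c("conserved", "additive", "dominant_p1", "dominant_p2",
            "overdominant", "underdominant", "ambiguous")

.checkDEtable <- function(de, name) {
  need <- c("gene", "log2FC", "padj")
  if (!all(need %in% names(de)))
    stop(name, " must have columns gene, log2FC, padj")
  de
}

#' Classify hybrid gene-expression inheritance
#'
#' Assigns each gene one inheritance mode from the three pairwise comparisons
#' hybrid-vs-parent1, hybrid-vs-parent2 and parent2-vs-parent1. With
#' significance vs neither parent the gene is conserved; vs exactly one
#' parent it is dominant toward the parent it matches; vs both parents it is
#' overdominant (above both), underdominant (below both) or additive
#' (between the parents). When \code{requireParentalDE} is set, additive
#' additionally requires parent1-vs-parent2 significance, otherwise the gene
#' is ambiguous. Fold changes of exactly zero against a significant call are
#' ambiguous (direction undefined).
#'
#' Orientation: \code{deHP1} and \code{deHP2} must report log2FC of the
#' hybrid relative to the parent; \code{deP1P2} reports parent2 vs parent1.
#'
#' @param deHP1,deHP2,deP1P2 DE tables (gene, log2FC, padj), covering the
#'   same gene set.
#' @param alpha significance threshold on adjusted p-values.
#' @param requireParentalDE require P1-vs-P2 significance for additive calls.
#' @return data.frame with gene, mode, and the three (log2FC, padj) pairs.
#' @export
classifyInheritance <- function(deHP1, deHP2, deP1P2, alpha = 0.05,
                                requireParentalDE = FALSE) {
  deHP1 <- .checkDEtable(deHP1, "deHP1")
  deHP2 <- .checkDEtable(deHP2, "deHP2")
  deP1P2 <- .checkDEtable(deP1P2, "deP1P2")
  genes <- deHP1$gene
  for (tb in list(deHP2, deP1P2)) {
    miss <- setdiff(genes, tb$gene)
    miss2 <- setdiff(tb$gene, genes)
    if (length(miss) || length(miss2))
      stop("DE tables cover different gene sets; missing: ",
           paste(unique(c(miss, miss2)), collapse = ", "))
  }
  i2 <- match(genes, deHP2$gene)
  iP <- match(genes, deP1P2$gene)
  l1 <- deHP1$log2FC
  l2 <- deHP2$log2FC[i2]
  s1 <- !is.na(deHP1$padj) & deHP1$padj <= alpha
  s2 <- !is.na(deHP2$padj[i2]) & deHP2$padj[i2] <= alpha
  sP <- !is.na(deP1P2$padj[iP]) & deP1P2$padj[iP] <= alpha

  mode <- rep("conserved", length(genes))
  mode[s1 & !s2] <- "dominant_p2"   # differs from P1, matches P2
  mode[!s1 & s2] <- "dominant_p1"   # differs from P2, matches P1
  both <- s1 & s2
  mode[both & l1 > 0 & l2 > 0] <- "overdominant"
  mode[both & l1 < 0 & l2 < 0] <- "underdominant"
  between <- both & (sign(l1) * sign(l2) < 0)
  mode[between] <- if (requireParentalDE) "ambiguous" else "additive"
  if (requireParentalDE) mode[between & sP] <- "additive"
  mode[both & (l1 == 0 | l2 == 0)] <- "ambiguous"

  data.frame(gene = genes, mode = factor(mode, levels = .MODES),
             lfc_HP1 = l1, lfc_HP2 = l2, lfc_P1P2 = deP1P2$log2FC[iP],
             padj_HP1 = deHP1$padj, padj_HP2 = deHP2$padj[i2],
             padj_P1P2 = deP1P2$padj[iP], stringsAsFactors = FALSE)
}

#' Flag misregulated genes from the hybrid-vs-pooled-parents comparison
#'
#' A gene is misregulated when it is significantly differentially expressed
#' between hybrids and the pooled parental samples; the direction follows the
#' sign of the fold change (hybrid relative to pooled parents).
#'
#' @param dePooled DE table (gene, log2FC, padj) for hybrids vs pooled
#'   parents.
#' @param fdr significance threshold on adjusted p.
#' @return data.frame with gene, misregulated (logical) and direction
#'   (\code{"up"}, \code{"down"} or \code{"none"}).
#' @export
misregulatedPooled <- function(dePooled, fdr = 0.05) {
  dePooled <- .checkDEtable(dePooled, "dePooled")
  sig <- !is.na(dePooled$padj) & dePooled$padj <= fdr
  dir <- rep("none", nrow(dePooled))
  dir[sig & dePooled$log2FC > 0] <- "up"
  dir[sig & dePooled$log2FC < 0] <- "down"
  data.frame(gene = dePooled$gene, misregulated = sig,
             direction = factor(dir, levels = c("up", "down", "none")),
             log2FC = dePooled$log2FC, padj = dePooled$padj,
             stringsAsFactors = FALSE)
}

.pct <- function(n, d) round(100 * n / d, 2)

#' Summarize inheritance calls as counts and percentages
#'
#' Tabulates the modes against an explicit denominator (the number of genes
#' that passed filtering), reporting numerator, denominator and percentage
#' together so every proportion is auditable.
#'
#' @param calls output of [classifyInheritance()].
#' @param totalGenes denominator (> 0).
#' @return data.frame with mode, n, total, percent (two decimals).
#' @export
summarizeInheritance <- function(calls, totalGenes) {
  if (totalGenes <= 0) stop("totalGenes must be positive")
  tab <- table(factor(calls$mode, levels = .MODES))
  data.frame(mode = names(tab), n = as.integer(tab),
             total = totalGenes,
             percent = .pct(as.integer(tab), totalGenes),
             stringsAsFactors = FALSE)
}

#' Numerator / denominator / percentage record
#'
#' Small helper used throughout reports so that percentages are always
#' printed with the counts they come from.
#'
#' @param n numerator count.
#' @param total denominator (> 0).
#' @param digits decimals for the percentage.
#' @return list with n, total and percent.
#' @export
proportionSummary <- function(n, total, digits = 2) {
  if (total <= 0) stop("denominator must be positive")
  list(n = n, total = total, percent = round(100 * n / total, digits))
}

#' Compare misregulation magnitude between transgressive classes
#'
#' Two-sided Wilcoxon rank-sum test on the absolute pooled-comparison log2
#' fold changes of overdominant vs underdominant genes.
#'
#' @param lfcOver,lfcUnder numeric log2 fold changes (absolute values are
#'   taken internally).
#' @return list with statistic, p.value, nOver, nUnder; both sets empty or
#'   either set empty yields an error (an undefined comparison is never
#'   silently reported as zero).
#' @export
magnitudeComparison <- function(lfcOver, lfcUnder) {
  lfcOver <- lfcOver[!is.na(lfcOver)]
  lfcUnder <- lfcUnder[!is.na(lfcUnder)]
  if (length(lfcOver) == 0 || length(lfcUnder) == 0)
    stop("magnitude comparison undefined: one of the classes is empty")
  wt <- wilcox.test(abs(lfcOver), abs(lfcUnder), exact = NULL)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       nOver = length(lfcOver), nUnder = length(lfcUnder))
}
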
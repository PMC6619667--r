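.checkAlleleTable <- function(tab) {
  need <- c("gene", "site_id", "sample", "count1", "count2")
  if (!all(need %in% names(tab)))
    stop("allele-count table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$count1 < 0 | tab$count2 < 0)) stop("allele counts must be >= 0")
  key <- paste(tab$site_id, tab$sample)
  if (anyDuplicated(key))
    stop("duplicate (site, sample) records in allele-count table")
  tab
}

#' Filter shared heterozygous sites on coverage
#'
#' A site is retained only if in \emph{every} listed sample the total allele
#' coverage is at least \code{minTotal} and each allele individually has at
#' least \code{minPerAllele} reads (both boundaries inclusive). This encodes
#' the shared-het-site restriction: the analysis only trusts sites deeply
#' covered in all individuals.
#'
#' @param tab allele-count table (gene, site_id, sample, count1, count2).
#' @param minTotal minimum total coverage per sample (default 20).
#' @param minPerAllele minimum reads per allele per sample (default 0).
#' @param samples samples that must all pass; default all samples in the
#'   table.
#' @return character vector of retained site ids.
#' @export
filterHetSites <- function(tab, minTotal = 20, minPerAllele = 0,
                           samples = NULL) {
  .checkAlleleTable(tab)
  if (minTotal < 0 || minPerAllele < 0) stop("thresholds must be >= 0")
  if (is.null(samples)) samples <- unique(tab$sample)
  sub <- tab[tab$sample %in% samples, , drop = FALSE]
  tot <- sub$count1 + sub$count2
  ok <- tot >= minTotal & sub$count1 >= minPerAllele &
    sub$count2 >= minPerAllele
  nSamp <- length(samples)
  passCount <- tapply(ok, sub$site_id, sum)
  seen <- tapply(rep(1L, nrow(sub)), sub$site_id, sum)
  keep <- names(passCount)[passCount == nSamp & seen == nSamp]
  sort(keep)
}

#' Exact binomial test for allelic imbalance at one site
#'
#' Two-sided exact binomial test of the allele-1 count against an expected
#' fraction of 0.5, using the minimum-likelihood two-sided convention (the
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one).
#'
#' @param count1,count2 reads supporting each allele; the total must be >= 1.
#' @return list with p.value, fraction (= count1/total) and favoredAllele
#'   (1, 2, or NA when the counts tie).
#' @export
binomialSiteTest <- function(count1, count2) {
  tot <- count1 + count2
  if (tot < 1) stop("site has zero total coverage")
  p <- binom.test(count1, tot, p = 0.5)$p.value
  favored <- if (count1 > count2) 1L else if (count2 > count1) 2L else NA_integer_
  list(p.value = p, fraction = count1 / tot, favoredAllele = favored)
}

#' Per-site binomial tests over an allele-count table
#'
#' Applies [binomialSiteTest()] to every (site, sample) record.
#'
#' @param tab allele-count table.
#' @return the table with columns p, fraction, favored appended.
#' @export
siteTests <- function(tab) {
  .checkAlleleTable(tab)
  tot <- tab$count1 + tab$count2
  if (any(tot < 1)) stop("sites with zero total coverage; filter first")
  ## binom.test per distinct (count1, total) pair; dedup for speed
  key <- paste(tab$count1, tot)
  uk <- !duplicated(key)
  pv <- vapply(which(uk), function(i)
    binom.test(tab$count1[i], tot[i], p = 0.5)$p.value, numeric(1))
  p <- pv[match(key, key[uk])]
  favored <- ifelse(tab$count1 > tab$count2, 1L,
                    ifelse(tab$count2 > tab$count1, 2L, NA_integer_))
  out <- tab
  out$p <- p
  out$fraction <- tab$count1 / tot
  out$favored <- favored
  out
}

#' Gene-level ASE status from per-site tests
#'
#' A gene shows hybrid ASE when some retained site is significant
#' (p < alpha) in \emph{every} hybrid sample with the same favored allele
#' across all hybrids; it shows parental ASE when any site is significant in
#' \emph{any} parental sample. Genes without retained sites get \code{NA}
#' status (unevaluable), never \code{FALSE}.
#'
#' @param tests output of [siteTests()], restricted to retained sites.
#' @param hybridSamples,parentalSamples sample id vectors.
#' @param alpha per-site significance threshold (default 0.05).
#' @param genes gene universe to report; defaults to genes present in
#'   \code{tests}.
#' @return data.frame with gene, hybrid_ase, parental_ase, supporting_site
#'   (first site meeting the hybrid criterion, or NA), n_sites.
#' @export
geneASECall <- function(tests, hybridSamples, parentalSamples, alpha = 0.05,
                        genes = NULL) {
  if (!all(c("p", "favored") %in% names(tests)))
    stop("tests must come from siteTests()")
  if (is.null(genes)) genes <- unique(tests$gene)
  hyb <- tests[tests$sample %in% hybridSamples, , drop = FALSE]
  par <- tests[tests$sample %in% parentalSamples, , drop = FALSE]

  hybSig <- logical(length(genes)); parSig <- logical(length(genes))
  support <- rep(NA_character_, length(genes))
  nSites <- integer(length(genes))
  names(hybSig) <- names(parSig) <- names(support) <- names(nSites) <- genes

  bySiteH <- split(hyb, hyb$site_id)
  nHyb <- length(hybridSamples)
  siteHybOK <- vapply(bySiteH, function(d) {
    nrow(d) == nHyb && all(d$p < alpha) &&
      !anyNA(d$favored) && length(unique(d$favored)) == 1
  }, logical(1))
  geneOfSite <- vapply(bySiteH, function(d) d$gene[1], character(1))
  for (g in unique(geneOfSite)) {
    ok <- siteHybOK[geneOfSite == g]
    if (any(ok)) {
      hybSig[g] <- TRUE
      support[g] <- sort(names(ok)[ok])[1]
    }
  }
  sigPar <- par[par$p < alpha, , drop = FALSE]
  parSig[unique(sigPar$gene)] <- TRUE
  cnt <- tapply(tests$site_id, tests$gene, function(x) length(unique(x)))
  nSites[names(cnt)] <- as.integer(cnt)

  res <- data.frame(gene = genes, hybrid_ase = hybSig, parental_ase = parSig,
                    supporting_site = support, n_sites = nSites,
                    stringsAsFactors = FALSE)
  res$hybrid_ase[res$n_sites == 0] <- NA
  res$parental_ase[res$n_sites == 0] <- NA
  rownames(res) <- NULL
  res
}

#' Pseudo-phasing gene-level ASE test for one sample
#'
#' At each SNP of a gene the larger-count allele is assigned to a putative
#' "major" haplotype; the statistic is the summed major count over the summed
#' total. Because picking the maximum inflates the statistic even under
#' balance, the null distribution is obtained by simulation: each SNP is
#' redrawn from a (beta-)binomial(n_i, 0.5, rho) and major assignment is
#' re-applied. The p-value uses the add-one estimator
#' \code{(1 + #(null >= observed)) / (nSim + 1)}.
#'
#' @param count1,count2 per-SNP allele counts of one gene in one sample.
#'   SNPs with zero total are excluded with a warning; if all are excluded,
#'   an error is raised.
#' @param nSim number of null simulations (>= 1000).
#' @param rho beta-binomial intraclass correlation of the null in [0, 1).
#' @param seed optional integer seed.
#' @return list with statistic (major-allele fraction), p.value and nSNP.
#' @export
mbasedGeneTest <- function(count1, count2, nSim = 1e6, rho = 0, seed = NULL) {
  if (nSim < 1000) stop("nSim must be >= 1000")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  tot <- count1 + count2
  drop <- tot == 0
  if (any(drop)) {
    warning(sum(drop), " SNP(s) with zero total coverage excluded")
    count1 <- count1[!drop]; count2 <- count2[!drop]; tot <- tot[!drop]
  }
  if (length(tot) == 0) stop("no SNP with nonzero coverage")
  if (!is.null(seed)) set.seed(seed)
  obs <- sum(pmax(count1, count2)) / sum(tot)
  nSNP <- length(tot)
  exceed <- 0
  chunk <- 100000L
  done <- 0L
  while (done < nSim) {
    b <- min(chunk, nSim - done)
    k <- matrix(.rbetabinom(b * nSNP, rep(tot, each = b), 0.5, rho),
                nrow = b)
    major <- pmax(k, matrix(rep(tot, each = b), nrow = b) - k)
    stat <- rowSums(major) / sum(tot)
    exceed <- exceed + sum(stat >= obs - 1e-12)
    done <- done + b
  }
  list(statistic = obs, p.value = (1 + exceed) / (nSim + 1), nSNP = nSNP)
}

#' Per-sample proportion of genes showing significant ASE
#'
#' Given per-sample, per-gene significance calls, returns for each sample the
#' fraction of eligible genes (those with at least one retained site in that
#' sample) called significant.
#'
#' @param calls data.frame with columns sample, gene, significant (logical).
#' @return named numeric vector of fractions per sample.
#' @export
aseProportion <- function(calls) {
  if (!all(c("sample", "gene", "significant") %in% names(calls)))
    stop("calls must have columns sample, gene, significant")
  if (nrow(calls) == 0) stop("no eligible genes")
  tapply(calls$significant, calls$sample, mean)
}

#' Per-sample gene-level significance from site tests
#'
#' Convenience wrapper: a gene is significant in a sample when any of its
#' retained sites has p < alpha in that sample.
#'
#' @param tests output of [siteTests()] on retained sites.
#' @param alpha per-site threshold.
#' @return data.frame (sample, gene, significant) suitable for
#'   [aseProportion()].
#' @export
sampleGeneASE <- function(tests, alpha = 0.05) {
  agg <- stats::aggregate(tests$p < alpha,
                          by = list(sample = tests$sample, gene = tests$gene),
                          FUN = any)
  names(agg)[3] <- "significant"
  agg
}
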
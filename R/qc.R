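#' Correct a misregulation proportion for library-preparation bias
#'
#' When hybrids and parents were sequenced with different library kits, the
#' misregulated-gene proportion is inflated. A calibration pair of
#' comparisons at a stage where both designs exist quantifies the inflation:
#' \code{nMatched} misregulated genes when hybrid and parental libraries were
#' prepared identically versus \code{nMismatched} when they were not. The
#' corrected proportion scales the raw estimate by the count ratio:
#' \code{corrected = raw * nMatched / nMismatched}.
#'
#' @param rawPct raw misregulation percentage in [0, 100].
#' @param nMatched misregulated-gene count from the matched-kit calibration
#'   comparison.
#' @param nMismatched misregulated-gene count from the mismatched-kit
#'   calibration comparison (> 0).
#' @return corrected percentage (unrounded).
#' @examples
#' round(correctMisregulation(51.6, 370, 997), 1)  # 19.1
#' @export
correctMisregulation <- function(rawPct, nMatched, nMismatched) {
  if (nMismatched <= 0) stop("nMismatched must be > 0")
  if (rawPct < 0 || rawPct > 100) stop("rawPct must be in [0, 100]")
  rawPct * nMatched / nMismatched
}

#' Full bias-correction record
#'
#' Wraps [correctMisregulation()] and also reports the calibration count
#' ratio and the true percent change between the matched and mismatched
#' calibration counts.
#'
#' @inheritParams correctMisregulation
#' @return list with raw_pct, n_matched, n_mismatched, corrected_pct,
#'   count_ratio and percent_change (of mismatched relative to matched).
#' @export
biasCorrectionEstimate <- function(rawPct, nMatched, nMismatched) {
  corrected <- correctMisregulation(rawPct, nMatched, nMismatched)
  list(raw_pct = rawPct, n_matched = nMatched, n_mismatched = nMismatched,
       corrected_pct = corrected,
       count_ratio = nMatched / nMismatched,
       percent_change = 100 * (nMismatched - nMatched) / nMatched)
}

#' Transcript integrity number of a coverage profile
#'
#' Entropy-based score of coverage uniformity: with \code{p_i} the fraction
#' of depth at covered base i, \code{H = -sum p_i log p_i} and
#' \code{TIN = 100 * exp(H) / k} where k is the transcript length. Uniform
#' coverage over all bases scores 100; coverage concentrated on a single
#' base of a k-base transcript scores 100/k. Degraded transcripts, whose
#' coverage piles up near the 3' end, score low.
#'
#' @param depth nonnegative per-base depth vector (length >= 1).
#' @return TIN in [0, 100], or NA (with a warning) for all-zero coverage.
#' @export
tin <- function(depth) {
  if (length(depth) < 1) stop("depth vector must have length >= 1")
  if (any(depth < 0)) stop("depths must be nonnegative")
  tot <- sum(depth)
  if (tot == 0) {
    warning("all-zero coverage: TIN undefined")
    return(NA_real_)
  }
  p <- depth[depth > 0] / tot
  H <- -sum(p * log(p))
  100 * exp(H) / length(depth)
}

#' TIN table and per-sample medians for a set of coverage profiles
#'
#' @param coverage named list (per sample) of transcript-by-base depth
#'   matrices, as stored in a [HybridSimulation-class].
#' @return list with \code{records} (data.frame transcript, sample, tin) and
#'   \code{medTIN} (named per-sample median TIN).
#' @export
tinTable <- function(coverage) {
  rec <- do.call(rbind, lapply(names(coverage), function(s) {
    m <- coverage[[s]]
    data.frame(transcript = rownames(m), sample = s,
               tin = apply(m, 1, tin), stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  med <- tapply(rec$tin, rec$sample, median, na.rm = TRUE)
  list(records = rec, medTIN = med)
}

#' Regress per-sample ASE proportion on median TIN
#'
#' Ordinary least squares of the per-sample fraction of ASE-significant genes
#' on the sample's median transcript integrity number, with the exact t-test
#' on the slope. An exclusion set re-fits on the complementary samples (used
#' to check that a degradation-ASE association is not driven by one group).
#'
#' @param medTIN named per-sample median TIN.
#' @param aseProp named per-sample ASE proportion.
#' @param exclude sample ids to drop before fitting.
#' @return list with slope, intercept, p.value, n.
#' @export
regressAseOnTin <- function(medTIN, aseProp, exclude = character(0)) {
  common <- setdiff(intersect(names(medTIN), names(aseProp)), exclude)
  if (length(common) < 3) stop("need at least 3 samples to fit")
  x <- as.numeric(medTIN[common]); y <- as.numeric(aseProp[common])
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = sm["x", "Estimate"], intercept = sm["(Intercept)", "Estimate"],
       p.value = sm["x", "Pr(>|t|)"], n = length(common))
}

#' Group-difference tests for per-sample QC metrics
#'
#' For each metric, tests whether its per-sample values differ between
#' groups (library kit or sequencing date): a Welch two-sample t-test when
#' exactly two groups have >= 2 samples, classical one-way ANOVA for three
#' or more. Groups with fewer than 2 samples are dropped with a note; a
#' metric left with fewer than 2 usable groups is skipped (flagged).
#'
#' @param metrics data.frame of per-sample scalar metrics (rownames or a
#'   \code{sample} column identify samples).
#' @param grouping named character vector sample -> group label.
#' @return data.frame with metric, method, statistic, p.value, note.
#' @export
batchVarianceChecks <- function(metrics, grouping) {
  if ("sample" %in% names(metrics)) {
    rownames(metrics) <- metrics$sample
    metrics$sample <- NULL
  }
  samples <- rownames(metrics)
  g <- factor(grouping[samples])
  res <- lapply(names(metrics), function(mname) {
    v <- metrics[[mname]]
    tab <- table(g[!is.na(v)])
    usable <- names(tab)[tab >= 2]
    dropped <- setdiff(names(tab), usable)
    note <- if (length(dropped))
      paste("dropped groups with < 2 samples:",
            paste(dropped, collapse = ",")) else ""
    keep <- !is.na(v) & g %in% usable
    gi <- droplevels(g[keep]); vi <- v[keep]
    if (length(usable) < 2)
      return(data.frame(metric = mname, method = "skipped",
                        statistic = NA_real_, p.value = NA_real_,
                        note = paste("fewer than 2 usable groups;", note),
                        stringsAsFactors = FALSE))
    if (length(usable) == 2) {
      tt <- t.test(vi ~ gi)   # Welch by default
      data.frame(metric = mname, method = "welch_t",
                 statistic = unname(tt$statistic), p.value = tt$p.value,
                 note = note, stringsAsFactors = FALSE)
    } else {
      av <- summary(aov(vi ~ gi))[[1]]
      data.frame(metric = mname, method = "anova",
                 statistic = av[1, "F value"], p.value = av[1, "Pr(>F)"],
                 note = note, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
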
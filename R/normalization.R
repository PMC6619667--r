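#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of that sample's count to the gene's geometric mean across samples.
#' Reference genes are those with strictly positive counts in every sample;
#' with an even number of them the median is the midpoint of the two central
#' ratios.
#'
#' @param counts nonnegative genes-by-samples count matrix.
#' @return named positive numeric vector, one size factor per sample.
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(100, 200))
#' medianRatioSizeFactors(m)  # 1/sqrt(2), sqrt(2)
#' @export
medianRatioSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no reference genes: no gene has nonzero counts in every sample; ",
         "size factors are undefined")
  lc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(exp(lc - geo), 2, median)
  setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' Divides each sample's column by its size factor, yielding real-valued
#' normalized counts comparable across libraries.
#'
#' @param counts genes-by-samples count matrix.
#' @param sizeFactors per-sample positive factors; by default computed with
#'   [medianRatioSizeFactors()]. A named vector must cover every column.
#' @return normalized numeric matrix of the same shape.
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
  if (!is.null(names(sizeFactors)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(sizeFactors)))
      stop("sizeFactors do not cover all samples: ",
           paste(setdiff(colnames(counts), names(sizeFactors)), collapse = ", "))
    sizeFactors <- sizeFactors[colnames(counts)]
  }
  if (length(sizeFactors) != ncol(counts))
    stop("one size factor per sample required")
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  sweep(counts, 2, sizeFactors, `/`)
}

#' Filter genes on normalized counts
#'
#' The default \code{"min"} rule keeps a gene only if every sample shows at
#' least \code{threshold} normalized counts (the stricter reading: genes must
#' be expressed everywhere). The \code{"any"} rule keeps a gene if at least
#' one sample reaches the threshold (i.e. discards only genes below the
#' threshold in every sample). Both boundaries are inclusive.
#'
#' @param normalized normalized count matrix.
#' @param threshold positive count threshold (default 10).
#' @param rule \code{"min"} or \code{"any"}.
#' @return logical vector (named by gene) indicating retained genes.
#' @export
filterLowCounts <- function(normalized, threshold = 10,
                            rule = c("min", "any")) {
  rule <- match.arg(rule)
  if (threshold <= 0) stop("threshold must be positive")
  normalized <- as.matrix(normalized)
  keep <- if (rule == "min") {
    apply(normalized, 1, min) >= threshold
  } else {
    apply(normalized, 1, max) >= threshold
  }
  setNames(keep, rownames(normalized))
}

#' Benjamini-Hochberg adjustment with a significance call
#'
#' Step-up FDR adjustment of a p-value vector plus the set significant at the
#' given FDR (adjusted p <= fdr).
#'
#' @param p numeric p-values in [0, 1] (NA allowed, propagated).
#' @param fdr target false discovery rate.
#' @return list with \code{padj} and logical \code{significant}.
#' @export
bhAdjust <- function(p, fdr = 0.05) {
  if (length(p) == 0) return(list(padj = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  padj <- p.adjust(p, method = "BH")
  list(padj = padj, significant = !is.na(padj) & padj <= fdr)
}
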
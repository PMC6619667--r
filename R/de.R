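## ---- negative-binomial two-group engine ----------------------------------
##
## Model: counts y_gj ~ NB(mu_gj, alpha_g), mu_gj = s_j * m_{g,group(j)},
## log link with a group indicator; one dispersion alpha per gene shared by
## both groups. Group log-means are profiled out by Newton iterations (the
## score in b = log m is sum_j (y_j - mu_j)/(1 + alpha mu_j), all vectorised
## across genes); alpha is maximised by a golden-section search on log(alpha).
## The Wald statistic uses the plug-in dispersion: I_k = sum_j mu_j/(1+a mu_j)
## per group and SE(log-ratio) = sqrt(1/I_1 + 1/I_2).

.ALPHA_MIN <- 1e-8
.ALPHA_MAX <- 30

## Newton solve of group log-means for one group block, vectorised over genes.
## Y: genes x n, sf: n, alpha: per-gene. Returns log-mean vector b.
.fitGroupLogMean <- function(Y, sf, alpha, iter = 12L) {
  tot <- as.numeric(Y %*% rep(1, ncol(Y)))
  m0 <- pmax(tot / sum(sf), 1e-10)
  b <- log(m0)
  for (it in seq_len(iter)) {
    mu <- exp(b) %o% sf
    aM <- mu * alpha
    f <- rowSums((Y - mu) / (1 + aM))
    fp <- -rowSums(mu * (1 + alpha * Y) / (1 + aM)^2)
    step <- f / pmin(fp, -1e-12)
    step <- pmin(pmax(step, -5), 5)
    b <- b - step
  }
  b[tot == 0] <- -Inf
  b
}

## per-gene NB log-likelihood at group fits for a given per-gene alpha
.profileLoglik <- function(Ys, sfs, alpha) {
  ll <- 0
  for (k in seq_along(Ys)) {
    b <- .fitGroupLogMean(Ys[[k]], sfs[[k]], alpha)
    mu <- pmax(exp(b) %o% sfs[[k]], 1e-10)
    ll <- ll + rowSums(dnbinom(Ys[[k]], size = 1 / alpha, mu = mu, log = TRUE))
  }
  ll
}

## golden-section ML of per-gene dispersion on log(alpha), vectorised
.mlDispersion <- function(Ys, sfs, iter = 28L) {
  nG <- nrow(Ys[[1]])
  lo <- rep(log(.ALPHA_MIN), nG)
  hi <- rep(log(.ALPHA_MAX), nG)
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- .profileLoglik(Ys, sfs, exp(x1))
  f2 <- .profileLoglik(Ys, sfs, exp(x2))
  for (it in seq_len(iter)) {
    left <- f1 > f2            # maximum lies in [lo, x2]
    hi <- ifelse(left, x2, hi)
    lo <- ifelse(left, lo, x1)
    x2n <- ifelse(left, x1, lo + gr * (hi - lo))
    x1n <- ifelse(left, hi - gr * (hi - lo), x2)
    f2n <- ifelse(left, f1, NA_real_)
    f1n <- ifelse(left, NA_real_, f2)
    need1 <- which(is.na(f1n))
    need2 <- which(is.na(f2n))
    if (length(need1)) {
      f1new <- .profileLoglik(lapply(Ys, function(m) m[need1, , drop = FALSE]),
                              sfs, exp(x1n[need1]))
      f1n[need1] <- f1new
    }
    if (length(need2)) {
      f2new <- .profileLoglik(lapply(Ys, function(m) m[need2, , drop = FALSE]),
                              sfs, exp(x2n[need2]))
      f2n[need2] <- f2new
    }
    x1 <- x1n; x2 <- x2n; f1 <- f1n; f2 <- f2n
  }
  alpha <- exp((lo + hi) / 2)
  alpha[alpha <= .ALPHA_MIN * 2] <- 0
  alpha
}

#' Estimate the negative-binomial dispersion of one gene
#'
#' Maximum-likelihood dispersion under a two-group (or one-group) mean model
#' with fixed size factors, floored at 0; an all-zero gene yields 0 with a
#' warning.
#'
#' @param y integer counts for one gene across samples.
#' @param groups factor/character of group membership (1 or 2 levels).
#' @param sizeFactors per-sample size factors (default all 1).
#' @return scalar dispersion alpha (variance = mu + alpha mu^2).
#' @export
estimateDispersion <- function(y, groups, sizeFactors = NULL) {
  if (is.null(sizeFactors)) sizeFactors <- rep(1, length(y))
  groups <- as.factor(groups)
  if (max(table(groups)) < 2)
    stop("at least one group needs >= 2 samples")
  if (all(y == 0)) {
    warning("all-zero gene: dispersion set to 0")
    return(0)
  }
  Ys <- lapply(levels(groups), function(g)
    matrix(y[groups == g], nrow = 1))
  sfs <- lapply(levels(groups), function(g) sizeFactors[groups == g])
  .mlDispersion(Ys, sfs)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Fits, per gene, a negative-binomial log-link model with a group indicator
#' and size-factor offsets; the reported \code{log2FC} is group2 relative to
#' group1, and the p-value is the two-sided normal tail of the Wald statistic
#' with plug-in ML dispersion. Genes where one group has zero counts get
#' their reported fold change from a 0.5 pseudocount added to the group means
#' (the test itself uses a half-count floor on the fitted mean).
#'
#' @param counts genes-by-samples count matrix with dimnames.
#' @param group1,group2 character vectors of sample (column) names.
#' @param sizeFactors named per-sample factors; by default median-of-ratios
#'   factors computed on the two groups' columns.
#' @param dispersion either NULL (per-gene ML estimate), or a fixed scalar /
#'   per-gene vector (0 gives the Poisson model).
#' @param fdr FDR used for the BH-adjusted column.
#' @param comparison optional label stored as an attribute.
#' @return data.frame with columns gene, baseMean, log2FC, SE, stat, pvalue,
#'   padj, plus a \code{comparison} attribute.
#' @export
nbWaldTest <- function(counts, group1, group2, sizeFactors = NULL,
                       dispersion = NULL, fdr = 0.05, comparison = NULL) {
  counts <- as.matrix(counts)
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be nonempty")
  missing <- setdiff(c(group1, group2), colnames(counts))
  if (length(missing))
    stop("samples not in count matrix: ", paste(missing, collapse = ", "))
  cols <- c(group1, group2)
  Y <- counts[, cols, drop = FALSE]
  if (is.null(sizeFactors)) {
    sizeFactors <- medianRatioSizeFactors(Y)
  } else {
    sizeFactors <- sizeFactors[cols]
  }
  Y1 <- Y[, group1, drop = FALSE]
  Y2 <- Y[, group2, drop = FALSE]
  sf1 <- unname(sizeFactors[group1])
  sf2 <- unname(sizeFactors[group2])
  nG <- nrow(Y)

  alpha <- if (is.null(dispersion)) {
    .mlDispersion(list(Y1, Y2), list(sf1, sf2))
  } else rep_len(dispersion, nG)
  alphaFit <- pmax(alpha, .ALPHA_MIN)

  b1 <- .fitGroupLogMean(Y1, sf1, alphaFit)
  b2 <- .fitGroupLogMean(Y2, sf2, alphaFit)

  ## half-count floor keeps the Wald statistic finite for empty groups
  floor1 <- log(0.5 / sum(sf1))
  floor2 <- log(0.5 / sum(sf2))
  b1f <- pmax(b1, floor1)
  b2f <- pmax(b2, floor2)

  mu1 <- exp(b1f) %o% sf1
  mu2 <- exp(b2f) %o% sf2
  info1 <- rowSums(mu1 / (1 + alphaFit * mu1))
  info2 <- rowSums(mu2 / (1 + alphaFit * mu2))
  seLn <- sqrt(1 / info1 + 1 / info2)
  betaLn <- b2f - b1f
  stat <- betaLn / seLn
  p <- 2 * pnorm(-abs(stat))

  m1 <- exp(b1); m2 <- exp(b2)
  zero <- !is.finite(b1) | !is.finite(b2)
  lfc <- ifelse(zero,
                log2((ifelse(is.finite(b2), m2, 0) + 0.5) /
                     (ifelse(is.finite(b1), m1, 0) + 0.5)),
                (b2 - b1) / log(2))
  norm <- normalizeCounts(Y, sizeFactors)
  res <- data.frame(
    gene = rownames(Y),
    baseMean = rowMeans(norm),
    log2FC = lfc,
    SE = seLn / log(2),
    stat = stat,
    pvalue = p,
    padj = bhAdjust(p, fdr)$padj,
    dispersion = alpha,
    stringsAsFactors = FALSE)
  rownames(res) <- res$gene
  attr(res, "comparison") <- comparison %||%
    paste(deparse(substitute(group2)), "vs", deparse(substitute(group1)))
  attr(res, "fdr") <- fdr
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
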
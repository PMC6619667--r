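#' Build a synthetic-experiment configuration
#'
#' Constructor for [SimConfig-class] with defaults describing the study
#' design this package targets: two parental species (6 libraries each) and
#' their F1 hybrids (4 libraries), negative-binomial counts, a handful of
#' shared heterozygous sites per gene, and no batch or degradation artefacts
#' unless requested.
#'
#' @param nGenes number of genes.
#' @param nPerGroup named vector \code{c(parent1=, parent2=, hybrid=)}.
#' @param architectureMix proportions over conserved/cis/trans/compensatory.
#' @param totalModeMix proportions over additive/dominant_p1/dominant_p2/
#'   overdominant/underdominant for hybrid totals of cis/trans genes.
#' @param effectSizeLog2 absolute log2 fold change of expression divergence.
#' @param muRange log-uniform range of baseline mean expression.
#' @param dispersionRange log-uniform range of NB dispersion alpha.
#' @param snpsPerGene mean shared het sites per gene.
#' @param aseDepth mean per-site total allele coverage.
#' @param aseDepthSize NB size of the depth draw (large = near-fixed depth).
#' @param aseOverdispersionRho beta-binomial intraclass correlation in [0,1).
#' @param compensatoryRatio hybrid parent1-allele fraction of compensatory
#'   genes (in (0,1), != 0.5).
#' @param compensatoryMisregProb probability a compensatory gene is also
#'   transgressive in hybrid totals.
#' @param batchSigma SD of the per-gene log-normal kit factor.
#' @param batchAssignment named character sample -> kit label (empty = one kit).
#' @param degradationLambda named per-sample 3' decay rates (empty = none).
#' @param alleleDegradationBias multiplier (<= 1) on allele-2 counts of
#'   degraded samples.
#' @param transcriptLength,nCoverageTranscripts,coverageDepth coverage-profile
#'   geometry.
#' @param seed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 100, seed = 7)
#' sim <- simulateExperiment(cfg)
#' @export
simConfig <- function(nGenes = 1000,
                      nPerGroup = c(parent1 = 6L, parent2 = 6L, hybrid = 4L),
                      architectureMix = c(conserved = 0.7, cis = 0.1,
                                          trans = 0.1, compensatory = 0.1),
                      totalModeMix = c(additive = 1, dominant_p1 = 0,
                                       dominant_p2 = 0, overdominant = 0,
                                       underdominant = 0),
                      effectSizeLog2 = 2,
                      muRange = c(50, 2000),
                      dispersionRange = c(0.05, 0.4),
                      snpsPerGene = 4,
                      aseDepth = 100,
                      aseDepthSize = 5,
                      aseOverdispersionRho = 0,
                      compensatoryRatio = 0.8,
                      compensatoryMisregProb = 0.5,
                      batchSigma = 0,
                      batchAssignment = character(0),
                      degradationLambda = numeric(0),
                      alleleDegradationBias = 1,
                      transcriptLength = 1000L,
                      nCoverageTranscripts = 50L,
                      coverageDepth = 30,
                      seed = 1L) {
  new("SimConfig",
      nGenes = nGenes,
      nPerGroup = setNames(as.integer(nPerGroup), names(nPerGroup)),
      architectureMix = architectureMix[.ARCHITECTURES],
      totalModeMix = totalModeMix[.TOTAL_MODES],
      effectSizeLog2 = effectSizeLog2,
      muRange = muRange,
      dispersionRange = dispersionRange,
      snpsPerGene = snpsPerGene,
      aseDepth = aseDepth,
      aseDepthSize = aseDepthSize,
      aseOverdispersionRho = aseOverdispersionRho,
      compensatoryRatio = compensatoryRatio,
      compensatoryMisregProb = compensatoryMisregProb,
      batchSigma = batchSigma,
      batchAssignment = batchAssignment,
      degradationLambda = degradationLambda,
      alleleDegradationBias = alleleDegradationBias,
      transcriptLength = as.integer(transcriptLength),
      nCoverageTranscripts = as.integer(nCoverageTranscripts),
      coverageDepth = coverageDepth,
      seed = as.integer(seed))
}

#' Simulate negative-binomial counts for one gene
#'
#' Counts are NB with mean \code{sizeFactors * mu} and dispersion alpha
#' (variance \code{mu + alpha mu^2}); \code{alpha = 0} degenerates to Poisson.
#'
#' @param mu mean expression on the normalized-count scale (> 0), scalar or
#'   one value per sample.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param sizeFactors per-sample scaling constants (default all 1).
#' @param n number of samples when \code{mu} and \code{sizeFactors} are
#'   scalars.
#' @param seed optional integer seed.
#' @return integer vector of counts.
#' @export
simulateGeneCounts <- function(mu, dispersion = 0, sizeFactors = NULL,
                               n = NULL, seed = NULL) {
  if (any(mu <= 0)) stop("mu must be strictly positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- max(length(mu), length(sizeFactors), 1L)
  if (is.null(sizeFactors)) sizeFactors <- rep(1, n)
  m <- sizeFactors * rep_len(mu, n)
  if (dispersion == 0) rpois(n, m) else rnbinom(n, mu = m, size = 1 / dispersion)
}

## beta-binomial draw with intraclass correlation rho; rho = 0 is binomial
.rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate allele counts at heterozygous sites
#'
#' Per-site totals are drawn from a negative binomial around \code{depth}
#' (floored at 1 read) and split between the two alleles by a binomial (or
#' beta-binomial when \code{rho > 0}) with parent1-allele probability
#' \code{ratio}.
#'
#' @param ratio expected allele-1 fraction, strictly inside (0, 1).
#' @param nSites number of sites.
#' @param depth mean total coverage per site, or a vector of fixed totals of
#'   length \code{nSites}.
#' @param rho beta-binomial intraclass correlation in [0, 1).
#' @param seed optional integer seed.
#' @return matrix with columns \code{count1}, \code{count2}.
#' @export
simulateAlleleCounts <- function(ratio, nSites, depth, rho = 0, seed = NULL) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be strictly inside (0, 1)")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  tot <- if (length(depth) == nSites && nSites > 1) as.integer(depth)
         else pmax(1L, rnbinom(nSites, mu = depth, size = 5))
  a1 <- .rbetabinom(nSites, tot, ratio, rho)
  cbind(count1 = a1, count2 = tot - a1)
}

#' Apply a multiplicative library-kit batch effect to a count matrix
#'
#' Each gene receives one log-normal factor per batch
#' (\code{exp(N(0, sigma^2))}, centred per gene across batches so the effect
#' is purely a between-batch contrast); counts are multiplied and re-rounded.
#' With \code{sigma = 0} or a single batch the counts are returned unchanged.
#'
#' @param counts genes-by-samples count matrix with column names.
#' @param batchMap named character vector mapping every sample to a batch/kit
#'   label.
#' @param sigma SD of the log factor.
#' @param seed optional integer seed.
#' @return perturbed count matrix.
#' @export
applyBatchEffect <- function(counts, batchMap, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  missing <- setdiff(colnames(counts), names(batchMap))
  if (length(missing))
    stop("samples missing from batchMap: ", paste(missing, collapse = ", "))
  batches <- unique(batchMap[colnames(counts)])
  if (sigma == 0 || length(batches) < 2) return(counts)
  if (!is.null(seed)) set.seed(seed)
  logf <- matrix(rnorm(nrow(counts) * length(batches), 0, sigma),
                 nrow = nrow(counts),
                 dimnames = list(rownames(counts), batches))
  logf <- logf - rowMeans(logf)
  f <- exp(logf)[, batchMap[colnames(counts)], drop = FALSE]
  out <- round(counts * f)
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}

#' Apply 3'-biased coverage decay and an allelic degradation bias
#'
#' Depth at base \code{i} of an L-base transcript is scaled by
#' \code{exp(-lambda * (L - i)/L)} (the 3' end, base L, is preserved;
#' 5' coverage decays), mimicking in vitro RNA degradation of poly-A selected
#' libraries. Optionally, allele-2 counts of an allele-count table are scaled
#' by \code{alleleBias <= 1}, coupling degradation to apparent allele-specific
#' expression.
#'
#' @param depth per-base depth vector, or a matrix with one transcript per
#'   row and one column per base.
#' @param lambda decay rate (>= 0); 0 is the identity.
#' @param alleleCounts optional data.frame/matrix with columns
#'   \code{count1, count2}.
#' @param alleleBias multiplier in (0, 1] applied to \code{count2}.
#' @return list with elements \code{depth} (scaled profile) and
#'   \code{alleleCounts} (adjusted, rounded; NULL when not supplied).
#' @export
applyDegradation <- function(depth, lambda, alleleCounts = NULL,
                             alleleBias = 1) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (alleleBias <= 0 || alleleBias > 1) stop("alleleBias must be in (0, 1]")
  scale1 <- function(v) {
    L <- length(v)
    v * exp(-lambda * (L - seq_len(L)) / L)
  }
  prof <- if (is.matrix(depth)) {
    L <- ncol(depth)
    sweep(depth, 2, exp(-lambda * (L - seq_len(L)) / L), `*`)
  } else scale1(depth)
  ac <- alleleCounts
  if (!is.null(ac)) {
    ac <- as.data.frame(ac)
    ac$count2 <- round(ac$count2 * alleleBias)
  }
  list(depth = prof, alleleCounts = ac)
}

## hybrid total mean implied by an inheritance mode
.modeMean <- function(mode, mu1, mu2, effect) {
  switch(mode,
         additive = (mu1 + mu2) / 2,
         dominant_p1 = mu1,
         dominant_p2 = mu2,
         overdominant = max(mu1, mu2) * 2^effect,
         underdominant = min(mu1, mu2) / 2^effect,
         none = (mu1 + mu2) / 2)
}

#' Simulate a complete F1-hybrid RNA-seq experiment
#'
#' Draws per-gene regulatory architectures, expression means, dispersions and
#' hybrid allelic ratios according to the configured mixtures, then generates
#' read counts, allele counts at shared heterozygous sites, coverage profiles,
#' and a per-gene truth table. Given the same configuration (including its
#' seed) the output is byte-identical.
#'
#' Architecture contracts: conserved genes have equal parental means and a
#' hybrid allelic ratio of 0.5; cis genes have divergent parental means with
#' ratio \code{mu_p1/(mu_p1 + mu_p2)}; trans genes have divergent means but
#' ratio 0.5 (both hybrid alleles see the same trans environment);
#' compensatory genes have equal parental means but a hybrid ratio away from
#' 0.5, and are transgressive in totals with probability
#' \code{compensatoryMisregProb}.
#'
#' @param config a [SimConfig-class].
#' @return a [HybridSimulation-class].
#' @export
simulateExperiment <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nG <- config@nGenes
  np <- config@nPerGroup
  genes <- sprintf("gene%05d", seq_len(nG))
  samples <- c(sprintf("p1_%d", seq_len(np[["parent1"]])),
               sprintf("p2_%d", seq_len(np[["parent2"]])),
               sprintf("hyb_%d", seq_len(np[["hybrid"]])))
  group <- rep(c("parent1", "parent2", "hybrid"), np[c("parent1", "parent2", "hybrid")])

  arch <- sample(.ARCHITECTURES, nG, replace = TRUE,
                 prob = config@architectureMix)
  muBase <- exp(runif(nG, log(config@muRange[1]), log(config@muRange[2])))
  disp <- if (diff(config@dispersionRange) == 0) {
    rep(config@dispersionRange[1], nG)
  } else {
    lo <- max(config@dispersionRange[1], 1e-6)
    exp(runif(nG, log(lo), log(config@dispersionRange[2])))
  }
  if (config@dispersionRange[2] == 0) disp <- rep(0, nG)
  eff <- config@effectSizeLog2
  sgn <- sample(c(-1, 1), nG, replace = TRUE)

  div <- arch %in% c("cis", "trans")
  mu1 <- ifelse(div, muBase * 2^(sgn * eff / 2), muBase)
  mu2 <- ifelse(div, muBase * 2^(-sgn * eff / 2), muBase)

  ratio <- rep(0.5, nG)
  ratio[arch == "cis"] <- mu1[arch == "cis"] /
    (mu1[arch == "cis"] + mu2[arch == "cis"])
  compSide <- sample(c(TRUE, FALSE), nG, replace = TRUE)
  r <- config@compensatoryRatio
  ratio[arch == "compensatory"] <-
    ifelse(compSide[arch == "compensatory"], r, 1 - r)

  mode <- rep("none", nG)
  mode[div] <- sample(.TOTAL_MODES, sum(div), replace = TRUE,
                      prob = config@totalModeMix)
  isComp <- arch == "compensatory"
  compMis <- isComp & runif(nG) < config@compensatoryMisregProb
  mode[isComp] <- "additive"
  mode[compMis] <- sample(c("overdominant", "underdominant"),
                          sum(compMis), replace = TRUE)
  muH <- vapply(seq_len(nG), function(i)
    .modeMean(mode[i], mu1[i], mu2[i], eff), numeric(1))

  counts <- matrix(0L, nG, length(samples),
                   dimnames = list(genes, samples))
  muMat <- cbind(parent1 = mu1, parent2 = mu2, hybrid = muH)
  for (j in seq_along(samples)) {
    m <- muMat[, group[j]]
    counts[, j] <- as.integer(ifelse(disp == 0, rpois(nG, m),
                                     rnbinom(nG, mu = m, size = 1 / disp)))
  }

  batch <- rep("kitA", length(samples))
  if (length(config@batchAssignment)) {
    batch <- unname(config@batchAssignment[samples])
    if (anyNA(batch))
      stop("batchAssignment must cover every sample")
    counts <- applyBatchEffect(counts, config@batchAssignment,
                               config@batchSigma)
  }

  ## allele counts at shared het sites (het in every sample; parents balanced)
  nSites <- 1L + rpois(nG, max(config@snpsPerGene - 1, 0))
  siteGene <- rep(genes, nSites)
  siteArchRatio <- rep(ratio, nSites)
  siteId <- unlist(lapply(seq_len(nG), function(i)
    sprintf("%s_s%d", genes[i], seq_len(nSites[i]))))
  sitePos <- unlist(lapply(nSites, function(k) sort(sample(1000L, k))))
  alleles <- c("A", "C", "G", "T")
  nTotSites <- length(siteId)
  a1 <- sample(alleles, nTotSites, replace = TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(alleles, x), 1), character(1))
  rows <- vector("list", length(samples))
  rho <- config@aseOverdispersionRho
  for (j in seq_along(samples)) {
    pr <- if (group[j] == "hybrid") siteArchRatio else rep(0.5, nTotSites)
    tot <- pmax(1L, rnbinom(nTotSites, mu = config@aseDepth,
                            size = config@aseDepthSize))
    c1 <- .rbetabinom(nTotSites, tot, pr, rho)
    rows[[j]] <- data.frame(gene = siteGene, site_id = siteId,
                            position = sitePos, allele1 = a1, allele2 = a2,
                            sample = samples[j], count1 = c1,
                            count2 = tot - c1, stringsAsFactors = FALSE)
  }
  alleleTab <- do.call(rbind, rows)
  rownames(alleleTab) <- NULL

  ## coverage profiles + degradation coupling
  L <- config@transcriptLength
  nT <- min(config@nCoverageTranscripts, nG)
  lambda <- setNames(rep(0, length(samples)), samples)
  if (length(config@degradationLambda)) {
    known <- intersect(names(config@degradationLambda), samples)
    lambda[known] <- config@degradationLambda[known]
  }
  coverage <- setNames(vector("list", length(samples)), samples)
  for (j in seq_along(samples)) {
    prof <- matrix(rpois(nT * L, config@coverageDepth), nT, L,
                   dimnames = list(genes[seq_len(nT)], NULL))
    if (lambda[j] > 0) {
      prof <- applyDegradation(prof, lambda[j])$depth
      idx <- alleleTab$sample == samples[j]
      alleleTab$count2[idx] <-
        round(alleleTab$count2[idx] * config@alleleDegradationBias)
    }
    coverage[[j]] <- prof
  }

  truth <- data.frame(gene = genes, architecture = arch,
                      hybrid_total_mode = mode, mu_p1 = mu1, mu_p2 = mu2,
                      mu_hybrid = muH, hybrid_allelic_ratio = ratio,
                      dispersion = disp, stringsAsFactors = FALSE)
  colData <- S4Vectors::DataFrame(
    sample = samples, group = group,
    stage = rep("stage1", length(samples)), batch = batch,
    population = rep("popA", length(samples)), row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = colData)

  new("HybridSimulation", experiment = se, alleleCounts = alleleTab,
      coverage = coverage, truth = truth, config = config)
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the five interchange files: \code{counts.tsv} (genes x samples),
#' \code{samples.tsv} (sample sheet), \code{allele_counts.tsv},
#' \code{truth.tsv} and \code{coverage.tsv} (transcript, sample,
#' comma-separated depths).
#'
#' @param sim a [HybridSimulation-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  se <- sim@experiment
  cf <- file.path(dir, "counts.tsv")
  cnt <- SummarizedExperiment::assay(se, "counts")
  write.table(data.frame(gene = rownames(cnt), cnt, check.names = FALSE),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  sf <- file.path(dir, "samples.tsv")
  write.table(as.data.frame(SummarizedExperiment::colData(se)), sf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  af <- file.path(dir, "allele_counts.tsv")
  write.table(sim@alleleCounts, af, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tf <- file.path(dir, "truth.tsv")
  write.table(sim@truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  vf <- file.path(dir, "coverage.tsv")
  cov <- do.call(rbind, lapply(names(sim@coverage), function(s) {
    m <- sim@coverage[[s]]
    data.frame(transcript = rownames(m), sample = s,
               depths = apply(m, 1, paste, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write.table(cov, vf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(cf, sf, af, tf, vf))
}
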
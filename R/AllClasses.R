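#' @import methods
#' @importFrom stats median rbinom rpois rnbinom rbeta rnorm runif setNames
#'   p.adjust pnorm dnbinom dpois binom.test wilcox.test t.test aov lm
#'   coef anova complete.cases quantile
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Configuration of a synthetic F1-hybrid RNA-seq experiment
#'
#' A \code{SimConfig} holds every parameter of the synthetic-data generator:
#' the experimental design (genes, samples per group), the mixture of
#' regulatory architectures and hybrid inheritance modes, the negative-binomial
#' noise model, the allele-count model at shared heterozygous sites, the
#' library-kit batch effect and the 3'-biased degradation model. The defaults
#' describe a two-species cross with 6 + 6 parental and 4 hybrid libraries.
#'
#' @slot nGenes number of genes to simulate.
#' @slot nPerGroup named integer vector \code{c(parent1, parent2, hybrid)};
#'   parents need at least 2 replicates so dispersion is estimable.
#' @slot architectureMix named proportions over
#'   \code{conserved, cis, trans, compensatory}; must sum to 1.
#' @slot totalModeMix named proportions over
#'   \code{additive, dominant_p1, dominant_p2, overdominant, underdominant}
#'   used to draw the hybrid total-expression mode of cis/trans genes.
#' @slot effectSizeLog2 magnitude (absolute log2 fold change) of expression
#'   divergence for cis/trans genes and of the transgressive shift.
#' @slot muRange range (log-uniform) of baseline mean expression on the
#'   normalized-count scale.
#' @slot dispersionRange range (log-uniform) of the per-gene NB dispersion
#'   alpha (var = mu + alpha mu^2).
#' @slot snpsPerGene mean number of shared heterozygous sites per gene
#'   (1 + Poisson(snpsPerGene - 1)).
#' @slot aseDepth mean total allele coverage per site and sample.
#' @slot aseDepthSize negative-binomial size of the per-site depth draw;
#'   small values give variable coverage, large values approach fixed
#'   (Poisson) depth.
#' @slot aseOverdispersionRho beta-binomial intraclass correlation of allele
#'   counts, in [0, 1); 0 gives pure binomial sampling.
#' @slot compensatoryRatio expected parent1-allele fraction in hybrids for
#'   compensatory genes (the cis component exposed by the hybrid trans
#'   environment); must differ from 0.5.
#' @slot compensatoryMisregProb probability that a compensatory gene is also
#'   transgressive (misregulated) in hybrid totals.
#' @slot batchSigma SD of the per-gene log-normal library-kit factor
#'   (0 disables the batch effect).
#' @slot batchAssignment named character vector mapping sample id to kit
#'   label; empty means a single kit.
#' @slot degradationLambda named numeric per-sample 3' decay rate (>= 0);
#'   empty means no degradation.
#' @slot alleleDegradationBias multiplicative loss (<= 1) applied to the
#'   second allele of degraded samples, coupling degradation to ASE.
#' @slot transcriptLength length of simulated coverage profiles.
#' @slot nCoverageTranscripts number of transcripts with coverage profiles.
#' @slot coverageDepth mean per-base coverage of the profiles.
#' @slot seed integer seed; all randomness in the generator flows from it.
#' @export
setClass("SimConfig",
  representation(
    nGenes = "numeric",
    nPerGroup = "integer",
    architectureMix = "numeric",
    totalModeMix = "numeric",
    effectSizeLog2 = "numeric",
    muRange = "numeric",
    dispersionRange = "numeric",
    snpsPerGene = "numeric",
    aseDepth = "numeric",
    aseDepthSize = "numeric",
    aseOverdispersionRho = "numeric",
    compensatoryRatio = "numeric",
    compensatoryMisregProb = "numeric",
    batchSigma = "numeric",
    batchAssignment = "character",
    degradationLambda = "numeric",
    alleleDegradationBias = "numeric",
    transcriptLength = "integer",
    nCoverageTranscripts = "integer",
    coverageDepth = "numeric",
    seed = "integer"
  )
)

.ARCHITECTURES <- c("conserved", "cis", "trans", "compensatory")
.TOTAL_MODES <- c("additive", "dominant_p1", "dominant_p2",
                  "overdominant", "underdominant")

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  np <- object@nPerGroup
  if (!identical(sort(names(np)), sort(c("parent1", "parent2", "hybrid"))))
    msg <- c(msg, "nPerGroup must be named parent1/parent2/hybrid")
  else {
    if (any(np[c("parent1", "parent2")] < 2L))
      msg <- c(msg, "parent groups need >= 2 replicates (dispersion)")
    if (np[["hybrid"]] < 1L) msg <- c(msg, "need >= 1 hybrid sample")
  }
  if (!isTRUE(all.equal(sum(object@architectureMix), 1)) ||
      any(object@architectureMix < 0) ||
      !identical(sort(names(object@architectureMix)), sort(.ARCHITECTURES)))
    msg <- c(msg, "architectureMix must be nonnegative proportions over conserved/cis/trans/compensatory summing to 1")
  if (!isTRUE(all.equal(sum(object@totalModeMix), 1)) ||
      any(object@totalModeMix < 0) ||
      !identical(sort(names(object@totalModeMix)), sort(.TOTAL_MODES)))
    msg <- c(msg, "totalModeMix must be nonnegative proportions over the five hybrid total modes summing to 1")
  if (object@effectSizeLog2 < 0) msg <- c(msg, "effectSizeLog2 must be >= 0")
  if (any(object@muRange <= 0) || length(object@muRange) != 2)
    msg <- c(msg, "muRange must be two positive values")
  if (any(object@dispersionRange < 0) || length(object@dispersionRange) != 2)
    msg <- c(msg, "dispersionRange must be two nonnegative values")
  if (object@snpsPerGene < 1) msg <- c(msg, "snpsPerGene must be >= 1")
  if (object@aseDepth <= 0) msg <- c(msg, "aseDepth must be positive")
  if (object@aseDepthSize <= 0) msg <- c(msg, "aseDepthSize must be positive")
  rho <- object@aseOverdispersionRho
  if (rho < 0 || rho >= 1) msg <- c(msg, "aseOverdispersionRho must be in [0, 1)")
  r <- object@compensatoryRatio
  if (r <= 0 || r >= 1 || r == 0.5)
    msg <- c(msg, "compensatoryRatio must be in (0, 1) and != 0.5")
  p <- object@compensatoryMisregProb
  if (p < 0 || p > 1) msg <- c(msg, "compensatoryMisregProb must be in [0, 1]")
  if (object@batchSigma < 0) msg <- c(msg, "batchSigma must be >= 0")
  if (length(object@degradationLambda) && any(object@degradationLambda < 0))
    msg <- c(msg, "degradationLambda must be >= 0")
  b <- object@alleleDegradationBias
  if (b <= 0 || b > 1) msg <- c(msg, "alleleDegradationBias must be in (0, 1]")
  if (object@transcriptLength < 1L) msg <- c(msg, "transcriptLength must be >= 1")
  if (object@coverageDepth <= 0) msg <- c(msg, "coverageDepth must be positive")
  if (length(msg)) msg else TRUE
})

#' Simulated F1-hybrid experiment with known truth
#'
#' Container returned by [simulateExperiment()]. Holds the read-count
#' experiment (a [SummarizedExperiment::SummarizedExperiment] with sample
#' metadata), the allele-count table at shared heterozygous sites, per-sample
#' coverage profiles and the generating truth for every gene.
#'
#' @slot experiment \code{SummarizedExperiment} with a \code{counts} assay and
#'   \code{colData} columns sample/group/stage/batch/population.
#' @slot alleleCounts data.frame with columns gene, site_id, position,
#'   allele1, allele2, sample, count1, count2.
#' @slot coverage named list (one element per sample) of transcript-by-base
#'   depth matrices.
#' @slot truth data.frame with the generating architecture and parameters per
#'   gene (the acceptance surface for recovery tests).
#' @slot config the [SimConfig-class] that produced the object.
#' @export
setClass("HybridSimulation",
  representation(
    experiment = "ANY",
    alleleCounts = "data.frame",
    coverage = "list",
    truth = "data.frame",
    config = "SimConfig"
  )
)

setValidity("HybridSimulation", function(object) {
  tr <- object@truth
  need <- c("gene", "architecture", "hybrid_total_mode", "mu_p1", "mu_p2",
            "mu_hybrid", "hybrid_allelic_ratio", "dispersion")
  if (!all(need %in% names(tr)))
    return("truth table is missing required columns")
  if (anyDuplicated(tr$gene)) return("duplicate genes in truth table")
  TRUE
})

#' @describeIn HybridSimulation-class the count \code{SummarizedExperiment}.
#' @param x a \code{HybridSimulation}.
#' @export
countsSE <- function(x) x@experiment

#' @describeIn HybridSimulation-class the allele-count table.
#' @export
alleleCounts <- function(x) x@alleleCounts

#' @describeIn HybridSimulation-class per-sample coverage profile matrices.
#' @export
coverageProfiles <- function(x) x@coverage

#' @describeIn HybridSimulation-class the per-gene generating truth.
#' @export
truthTable <- function(x) x@truth

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes;",
      paste(names(object@nPerGroup), object@nPerGroup,
            sep = "=", collapse = " "), "\n")
  cat("  architectures:",
      paste(names(object@architectureMix),
            signif(object@architectureMix, 3), sep = "=", collapse = " "), "\n")
  cat("  effect", object@effectSizeLog2, "log2; batch sigma",
      object@batchSigma, "; rho", object@aseOverdispersionRho,
      "; seed", object@seed, "\n")
})

setMethod("show", "HybridSimulation", function(object) {
  se <- object@experiment
  cat("HybridSimulation:", nrow(se), "genes x", ncol(se), "samples;",
      nrow(object@alleleCounts), "allele-count records;",
      length(object@coverage), "coverage samples\n")
  cat("  architectures:",
      paste(names(table(object@truth$architecture)),
            table(object@truth$architecture), sep = "=", collapse = " "), "\n")
})
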
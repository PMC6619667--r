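#' Run the full hybrid-misregulation analysis
#'
#' Orchestrates every stage on in-memory inputs: median-of-ratios
#' normalization with per-comparison low-count filtering, the four NB Wald
#' comparisons (hybrid vs each parent, parent2 vs parent1, hybrid vs pooled
#' parents), inheritance classification, per-site and gene-level ASE,
#' compensatory-mechanism calls, and (when coverage profiles are supplied)
#' TIN-based degradation QC. All percentages in the summary carry their
#' numerator and denominator.
#'
#' @param counts genes-by-samples integer matrix.
#' @param sampleSheet data.frame with columns sample and group
#'   (parent1/parent2/hybrid); every count column must appear in it.
#' @param alleleCounts optional allele-count table
#'   (see [readAlleleCounts()]).
#' @param coverage optional named list of coverage matrices
#'   (see [readCoverageTSV()]).
#' @param outDir optional directory; when given, every stage output is
#'   written as TSV/JSON plus a run manifest.
#' @param fdr FDR for DE and misregulation calls.
#' @param aseAlpha per-site ASE significance threshold.
#' @param minTotal,minPerAllele coverage filters for heterozygous sites.
#' @param filterRule low-count filter rule, \code{"min"} or \code{"any"}.
#' @param requireParentalDE passed to [classifyInheritance()].
#' @param runMbased also run the pseudo-phasing gene test per hybrid sample.
#' @param nSim simulations for the pseudo-phasing test.
#' @param seed integer seed covering every stochastic step.
#' @return list with elements de (the four tables), inheritance,
#'   misregulation, inheritanceSummary, ase (siteTests, geneCalls,
#'   proportions, mbased), mechanisms, mechanismSummary, qc, manifest.
#' @export
runPipeline <- function(counts, sampleSheet, alleleCounts = NULL,
                        coverage = NULL, outDir = NULL, fdr = 0.05,
                        aseAlpha = 0.05, minTotal = 20, minPerAllele = 0,
                        filterRule = c("min", "any"),
                        requireParentalDE = FALSE, runMbased = FALSE,
                        nSim = 10000, seed = 1) {
  filterRule <- match.arg(filterRule)
  counts <- as.matrix(counts)
  missing <- setdiff(colnames(counts), sampleSheet$sample)
  if (length(missing))
    stop("samples in counts but not in sample sheet: ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  grp <- setNames(sampleSheet$group, sampleSheet$sample)
  p1 <- names(grp)[grp == "parent1"]
  p2 <- names(grp)[grp == "parent2"]
  hyb <- names(grp)[grp == "hybrid"]
  if (!length(p1) || !length(p2) || !length(hyb))
    stop("need samples in all three groups (parent1, parent2, hybrid)")

  runComparison <- function(g1, g2, label) {
    cols <- c(g1, g2)
    sf <- medianRatioSizeFactors(counts[, cols, drop = FALSE])
    keep <- filterLowCounts(normalizeCounts(counts[, cols, drop = FALSE], sf),
                            threshold = 10, rule = filterRule)
    nbWaldTest(counts[keep, cols, drop = FALSE], g1, g2, sizeFactors = sf,
               fdr = fdr, comparison = label)
  }
  deHP1 <- runComparison(p1, hyb, "hybrid_vs_parent1")
  deHP2 <- runComparison(p2, hyb, "hybrid_vs_parent2")
  deP1P2 <- runComparison(p1, p2, "parent2_vs_parent1")
  dePooled <- runComparison(c(p1, p2), hyb, "hybrid_vs_pooled_parents")

  common <- Reduce(intersect, list(deHP1$gene, deHP2$gene, deP1P2$gene))
  inh <- classifyInheritance(deHP1[common, ], deHP2[common, ],
                             deP1P2[common, ], alpha = fdr,
                             requireParentalDE = requireParentalDE)
  inhSummary <- summarizeInheritance(inh, length(common))
  mis <- misregulatedPooled(dePooled, fdr = fdr)
  misSummary <- proportionSummary(sum(mis$misregulated), nrow(mis))

  ase <- NULL; mech <- NULL; mechSummary <- NULL
  if (!is.null(alleleCounts)) {
    kept <- filterHetSites(alleleCounts, minTotal = minTotal,
                           minPerAllele = minPerAllele,
                           samples = c(p1, p2, hyb))
    tests <- siteTests(alleleCounts[alleleCounts$site_id %in% kept, ,
                                    drop = FALSE])
    geneCalls <- geneASECall(tests, hybridSamples = hyb,
                             parentalSamples = c(p1, p2), alpha = aseAlpha,
                             genes = unique(alleleCounts$gene))
    perSample <- sampleGeneASE(tests, alpha = aseAlpha)
    props <- aseProportion(perSample)
    mbased <- NULL
    if (runMbased) {
      mbased <- do.call(rbind, lapply(hyb, function(s) {
        sub <- tests[tests$sample == s, , drop = FALSE]
        byGene <- split(sub, sub$gene)
        data.frame(gene = names(byGene), sample = s,
                   p = vapply(byGene, function(d)
                     mbasedGeneTest(d$count1, d$count2, nSim = nSim)$p.value,
                     numeric(1)),
                   stringsAsFactors = FALSE)
      }))
    }
    ase <- list(retainedSites = kept, siteTests = tests,
                geneCalls = geneCalls, proportions = props, mbased = mbased)
    mech <- classifyMechanism(deP1P2, geneCalls, mis, fdr = fdr)
    mechSummary <- tryCatch(mechanismSummary(mech), error = function(e) NULL)
  }

  qc <- NULL
  if (!is.null(coverage)) {
    tins <- tinTable(coverage)
    reg <- NULL
    if (!is.null(ase) && length(ase$proportions) >= 3) {
      reg <- tryCatch(regressAseOnTin(tins$medTIN, ase$proportions),
                      error = function(e) NULL)
    }
    metrics <- data.frame(
      normTotal = colSums(normalizeCounts(counts)),
      medTIN = as.numeric(tins$medTIN[colnames(counts)]),
      row.names = colnames(counts))
    checks <- NULL
    if ("batch" %in% names(sampleSheet) &&
        length(unique(sampleSheet$batch)) > 1) {
      checks <- batchVarianceChecks(metrics,
                                    setNames(sampleSheet$batch,
                                             sampleSheet$sample))
    }
    qc <- list(tin = tins, aseTinRegression = reg, batchChecks = checks)
  }

  manifest <- list(
    package = "hybridmisreg",
    version = as.character(packageVersion("hybridmisreg")),
    seed = seed, fdr = fdr, aseAlpha = aseAlpha,
    minTotal = minTotal, minPerAllele = minPerAllele,
    filterRule = filterRule, requireParentalDE = requireParentalDE,
    nGenes = nrow(counts), nSamples = ncol(counts),
    genesTested = setNames(
      lapply(list(deHP1, deHP2, deP1P2, dePooled), nrow),
      c("hybrid_vs_parent1", "hybrid_vs_parent2", "parent2_vs_parent1",
        "hybrid_vs_pooled_parents")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  res <- list(de = list(HP1 = deHP1, HP2 = deHP2, P1P2 = deP1P2,
                        pooled = dePooled),
              inheritance = inh, inheritanceSummary = inhSummary,
              misregulation = mis, misregulationSummary = misSummary,
              ase = ase, mechanisms = mech, mechanismSummary = mechSummary,
              qc = qc, manifest = manifest)
  if (!is.null(outDir)) .writeBundle(res, outDir)
  res
}

.writeBundle <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  for (nm in names(res$de))
    wt(res$de[[nm]], paste0("de_", attr(res$de[[nm]], "comparison"), ".tsv"))
  wt(res$inheritance, "inheritance.tsv")
  wt(res$misregulation, "misregulation.tsv")
  wt(res$inheritanceSummary, "inheritance_summary.tsv")
  if (!is.null(res$ase)) {
    wt(res$ase$siteTests, "ase_site_tests.tsv")
    wt(res$ase$geneCalls, "ase_gene_status.tsv")
    if (!is.null(res$ase$mbased)) wt(res$ase$mbased, "ase_mbased.tsv")
  }
  if (!is.null(res$mechanisms)) wt(res$mechanisms, "mechanisms.tsv")
  summaries <- list(
    inheritance = res$inheritanceSummary,
    misregulation = res$misregulationSummary,
    mechanisms = res$mechanismSummary,
    manifest = res$manifest)
  jsonlite::write_json(summaries, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outDir)
}
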
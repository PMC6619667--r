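#' Read a genes-by-samples count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
readCountsTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (any(m < 0)) stop("negative counts in ", path)
  storage.mode(m) <- "integer"
  m
}

#' Read a sample sheet from TSV
#'
#' Requires columns sample and group (parent1/parent2/hybrid); stage, batch
#' and population are carried along when present.
#'
#' @param path TSV file path.
#' @return data.frame keyed by sample.
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("sample sheet needs columns: sample, group")
  if (anyDuplicated(df$sample)) stop("duplicate samples in sheet")
  bad <- setdiff(unique(df$group), c("parent1", "parent2", "hybrid"))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  rownames(df) <- df$sample
  df
}

#' Read an allele-count table from TSV
#'
#' Columns: gene, site_id, position, allele1, allele2, sample, count1,
#' count2.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readAlleleCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .checkAlleleTable(df)
}

#' Build an allele-count table from a VCF of heterozygous genotypes
#'
#' Reads a VCF (requires the VariantAnnotation package), keeps biallelic
#' records where every requested sample is heterozygous, and extracts
#' per-allele read depths from the standard AD field. Genes are assigned by
#' interval overlap with a gene map. Multi-allelic records are reduced to
#' the two highest-depth alleles with a warning.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param geneMap data.frame with columns gene, chrom, start, end.
#' @param samples samples to keep; default all samples in the VCF.
#' @return allele-count table as from [readAlleleCounts()].
#' @export
readAlleleCountsVCF <- function(path, geneMap, samples = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readAlleleCountsVCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD (allelic depth) field")
  if (is.null(samples)) samples <- colnames(gt)
  gt <- gt[, samples, drop = FALSE]
  het <- apply(gt, 1, function(x) all(x %in% c("0/1", "0|1", "1/0", "1|0")))
  rr <- SummarizedExperiment::rowRanges(vcf)[het]
  if (length(rr) == 0) stop("no site heterozygous in all requested samples")
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  rows <- list()
  for (i in seq_along(rr)) {
    hit <- which(geneMap$chrom == chrom[i] & geneMap$start <= pos[i] &
                 geneMap$end >= pos[i])
    if (!length(hit)) next
    gene <- geneMap$gene[hit[1]]
    id <- names(rr)[i]
    for (s in samples) {
      depths <- ad[which(het)[i], s][[1]]
      if (length(depths) > 2) {
        warning("multi-allelic record ", id,
                ": keeping the two highest-count alleles")
        ord <- order(depths, decreasing = TRUE)[1:2]
        depths <- depths[sort(ord)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, site_id = id, position = pos[i],
        allele1 = as.character(rr$REF[i]),
        allele2 = as.character(unlist(rr$ALT[i]))[1],
        sample = s, count1 = depths[1], count2 = depths[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no heterozygous site overlapped the gene map")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .checkAlleleTable(out)
}

#' Read coverage profiles from TSV
#'
#' Expects columns transcript, sample, depths (comma-separated per-base
#' depths), as written by [writeSimulation()].
#'
#' @param path TSV file path.
#' @return named list (per sample) of transcript-by-base depth matrices.
#' @export
readCoverageTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$sample), function(d) {
    m <- do.call(rbind, lapply(strsplit(d$depths, ","), as.numeric))
    rownames(m) <- d$transcript
    m
  })
  out[unique(df$sample)]
}
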
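#' Read panel counts from a gene x sample table
#'
#' Reads a TSV or CSV (sniffed from the first line) with gene symbols in the
#' first column and one integer column per sample, attaches gene roles from
#' the panel configuration, and validates the result. Genes in the file that
#' are not part of the panel are dropped with a warning naming them; a
#' missing housekeeping gene is a hard error because all score
#' normalisations depend on the full reference set.
#'
#' @param path path to the counts file.
#' @param panel gene panel data.frame ([defaultGenePanel()] by default, or
#'   [readGenePanelConfig()] output).
#' @return a [PanelExperiment-class].
#' @export
readCounts <- function(path, panel = defaultGenePanel()) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene column plus >= 1 sample")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    cell <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop(sprintf("non-numeric count at row %d (gene %s), column '%s'",
                 cell, genes[cell], colnames(df)[bad + 1L]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at gene %s, sample '%s'",
                 genes[idx[1L]], colnames(m)[idx[2L]]))
  }
  rownames(m) <- genes
  hk_missing <- setdiff(panel$gene[panel$role == "housekeeping"], genes)
  if (length(hk_missing))
    stop("housekeeping gene(s) missing from counts file: ",
         paste(hk_missing, collapse = ", "))
  extra <- setdiff(genes, panel$gene)
  if (length(extra)) {
    warning("dropping ", length(extra), " gene(s) not in the panel: ",
            paste(extra, collapse = ", "))
    m <- m[setdiff(genes, extra), , drop = FALSE]
  }
  PanelExperiment(m, stats::setNames(panel$role, panel$gene))
}

#' Sample quality control
#'
#' Retains exactly the samples with a fraction of zero-count ("missing")
#' genes below `maxMissing` and total reads strictly greater than
#' `minReads`; the defaults follow the assay's published QC chain (less
#' than 30% missing genes, total reads larger than 10,000, both strict).
#' A report listing every sample with its metrics and, for exclusions, the
#' failed criterion is attached as `qcReport(x)`.
#'
#' Filtering is idempotent: applying it to an already filtered panel
#' removes nothing.
#'
#' @param pe a [PanelExperiment-class].
#' @param maxMissing exclusive upper bound on the zero-gene fraction.
#' @param minReads exclusive lower bound on total reads.
#' @return the filtered `PanelExperiment` with the QC report in its
#'   metadata; errors if no sample survives (report attached to the
#'   condition).
#' @export
qcFilterSamples <- function(pe, maxMissing = 0.30, minReads = 10000) {
  cts <- SummarizedExperiment::assay(pe, "counts")
  frac_missing <- colMeans(cts == 0)
  total <- colSums(cts)
  fail_miss <- frac_missing >= maxMissing
  fail_reads <- total <= minReads
  reason <- rep("", ncol(cts))
  reason[fail_miss] <- sprintf(">= %.0f%% missing genes", 100 * maxMissing)
  reason[fail_reads] <- sprintf("total reads <= %g", minReads)
  reason[fail_miss & fail_reads] <- "missing genes and total reads"
  report <- data.frame(sample = colnames(cts),
                       fraction_missing = unname(frac_missing),
                       total_reads = unname(total),
                       excluded = unname(fail_miss | fail_reads),
                       reason = reason, stringsAsFactors = FALSE)
  keep <- !report$excluded
  if (!any(keep)) {
    cond <- simpleError("all samples excluded by QC")
    cond$qc_report <- report
    stop(cond)
  }
  out <- pe[, keep]
  S4Vectors::metadata(out)$qc_report <- report
  out
}

#' Normalise panel counts
#'
#' Computes counts per million over the panel-wide library size of each
#' sample (optionally after dividing counts by transcript length in kb,
#' when lengths are attached to the panel and `useLengths = TRUE`),
#' log2-transforms with a pseudocount of 1, median-centres each gene across
#' samples, and optionally standardises each gene to unit SD. Genes with
#' zero variance are flagged in `rowData(x)$zero_variance` and left
#' unstandardised rather than divided by zero.
#'
#' Assays added: `cpm`, `logcpm`, `centered`. `logcpm` (uncentred) feeds
#' the housekeeping-referenced scores ([oncotypeRS()], [immuneScore()]);
#' `centered` feeds the centroid classifier and ROR-P.
#'
#' @param pe a QC-passed [PanelExperiment-class].
#' @param standardize divide centred values by the per-gene SD (default
#'   FALSE).
#' @param useLengths use `rowData(pe)$transcript_length` for length
#'   normalisation (default FALSE; the assay publishes no lengths).
#' @return the `PanelExperiment` with added assays and normalisation
#'   metadata.
#' @export
normalizePanel <- function(pe, standardize = FALSE, useLengths = FALSE) {
  cts <- SummarizedExperiment::assay(pe, "counts")
  work <- cts
  if (useLengths) {
    tl <- SummarizedExperiment::rowData(pe)$transcript_length
    if (is.null(tl))
      stop("useLengths = TRUE but the panel has no transcript_length")
    work <- cts / (tl / 1000)
  }
  lib <- colSums(work)
  if (any(lib == 0)) {
    bad <- colnames(work)[lib == 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  cpm <- sweep(work, 2, lib, "/") * 1e6
  logcpm <- log2(cpm + 1)
  med <- apply(logcpm, 1, stats::median)
  centered <- logcpm - med
  sds <- apply(centered, 1, stats::sd)
  zero_var <- is.na(sds) | sds == 0
  if (standardize)
    centered[!zero_var, ] <- centered[!zero_var, , drop = FALSE] /
      sds[!zero_var]
  SummarizedExperiment::assay(pe, "cpm") <- cpm
  SummarizedExperiment::assay(pe, "logcpm") <- logcpm
  SummarizedExperiment::assay(pe, "centered") <- centered
  SummarizedExperiment::rowData(pe)$zero_variance <- unname(zero_var)
  S4Vectors::metadata(pe)$normalization <- list(
    centering = "gene-median", standardized = standardize,
    pseudocount = 1, lengths_used = useLengths)
  pe
}

#' Write the QC report as CSV
#' @param pe a QC-filtered [PanelExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQCReport <- function(pe, path) {
  rep <- qcReport(pe)
  if (is.null(rep)) stop("panel has no QC report; run qcFilterSamples first")
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(path)
}
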
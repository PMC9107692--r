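#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.GENE_ROLES <- c("subtype", "immune", "housekeeping")
.SUBTYPES <- c("LumA", "LumB", "HER2E", "Basal")

#' PanelExperiment: a targeted breast-cancer expression panel
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' read counts for a targeted panel together with a per-gene role annotation
#' (`subtype`, `immune` or `housekeeping`) in `rowData(x)$role`. Clinical
#' variables, when available, live in `colData(x)`. Normalisation adds
#' further assays (`cpm`, `logcpm`, `centered`) without changing the class.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [PanelExperiment()], [geneRoles()], [qcFilterSamples()],
#'   [normalizePanel()]
#' @export
setClass("PanelExperiment", contains = "SummarizedExperiment")

setValidity("PanelExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  rd <- SummarizedExperiment::rowData(object)
  if (!"role" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain a 'role' column")
  } else {
    role <- as.character(rd$role)
    if (anyNA(role) || !all(role %in% .GENE_ROLES))
      msg <- c(msg, sprintf("gene roles must be one of: %s",
                            paste(.GENE_ROLES, collapse = ", ")))
  }
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PanelExperiment
#'
#' @param counts nonnegative integer matrix, genes in rows (rownames = gene
#'   symbols), samples in columns.
#' @param roles named character vector or factor mapping every gene to one of
#'   `"subtype"`, `"immune"`, `"housekeeping"`. Names must cover all rownames
#'   of `counts`.
#' @param colData optional `DataFrame`/data.frame of per-sample (clinical)
#'   variables.
#' @param transcriptLengths optional named numeric vector of transcript
#'   lengths in bases, used for length normalisation if supplied to
#'   [normalizePanel()].
#' @return a [PanelExperiment-class] object.
#' @examples
#' pan <- defaultGenePanel()
#' m <- matrix(rpois(nrow(pan) * 3, 50), nrow = nrow(pan),
#'             dimnames = list(pan$gene, paste0("S", 1:3)))
#' pe <- PanelExperiment(m, stats::setNames(pan$role, pan$gene))
#' @export
PanelExperiment <- function(counts, roles, colData = NULL,
                            transcriptLengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have gene symbols as rownames")
  if (is.null(names(roles)))
    stop("roles must be a named vector (names = gene symbols)")
  missing_role <- setdiff(rownames(counts), names(roles))
  if (length(missing_role))
    stop("no role given for gene(s): ", paste(missing_role, collapse = ", "))
  rd <- S4Vectors::DataFrame(role = as.character(roles[rownames(counts)]),
                             row.names = rownames(counts))
  if (!is.null(transcriptLengths)) {
    tl <- transcriptLengths[rownames(counts)]
    if (anyNA(tl) || any(tl <= 0))
      stop("transcriptLengths must be positive and cover all panel genes")
    rd$transcript_length <- as.numeric(tl)
  }
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = colData)
  new("PanelExperiment", se)
}

#' @describeIn PanelExperiment gene-to-role mapping as a named character
#'   vector.
#' @param x a `PanelExperiment`.
#' @export
geneRoles <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$role),
                  rownames(x))
}

#' @describeIn PanelExperiment symbols of the 50 subtype (centroid) genes.
#' @export
subtypeGenes <- function(x) names(which(geneRoles(x) == "subtype"))

#' @describeIn PanelExperiment symbols of the immune signature genes.
#' @export
immuneGenes <- function(x) names(which(geneRoles(x) == "immune"))

#' @describeIn PanelExperiment symbols of the housekeeping (reference) genes.
#' @export
housekeepingGenes <- function(x) names(which(geneRoles(x) == "housekeeping"))

#' @describeIn PanelExperiment the sample QC report attached by
#'   [qcFilterSamples()] (NULL before QC).
#' @export
qcReport <- function(x) S4Vectors::metadata(x)$qc_report

setMethod("show", "PanelExperiment", function(object) {
  callNextMethod()
  tab <- table(factor(geneRoles(object), levels = .GENE_ROLES))
  cat("gene roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  if (!is.null(qcReport(object)))
    cat("QC: ", sum(!qcReport(object)$excluded), " retained of ",
        nrow(qcReport(object)), " samples\n", sep = "")
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated HR+/HER2- early-stage
#' cohort: intrinsic-subtype mixture, separation of subtype expression
#' profiles, negative-binomial overdispersion, library sizes, coupling of
#' the latent immune level to immune-gene expression and TILs, and a
#' proportional-hazards survival layer.
#'
#' @slot nPatients number of patients.
#' @slot subtypeProportions named 4-vector (LumA, LumB, HER2E, Basal)
#'   summing to 1; defaults 0.71/0.20/0.02/0.07.
#' @slot expressionSeparation nonnegative scalar; per-gene log2 shift applied
#'   to signature genes (signature weights are in \[-1, 1\], so the distance
#'   between opposed subtype means is up to twice this value).
#' @slot dispersion negative-binomial overdispersion (0 = Poisson).
#' @slot librarySizeRange integer pair; per-sample library size is uniform
#'   on this range.
#' @slot immuneCoupling correlation in \[0,1\] between the latent immune
#'   level and each immune gene's mean (and the TILs percentage).
#' @slot hazardLogHR named numeric of log hazard ratios over the covariates
#'   `LumB`, `HER2E`, `Basal`, `immune`, `size_gt1cm`.
#' @slot censoringRate expected fraction of censored observations in \[0,1).
#' @slot seed integer seed; fixes the whole cohort.
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer",
                 subtypeProportions = "numeric",
                 expressionSeparation = "numeric",
                 dispersion = "numeric",
                 librarySizeRange = "numeric",
                 immuneCoupling = "numeric",
                 hazardLogHR = "numeric",
                 censoringRate = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nPatients) != 1L || is.na(object@nPatients) ||
      object@nPatients < 1L)
    msg <- c(msg, "nPatients must be a positive integer")
  p <- object@subtypeProportions
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "subtypeProportions must be a nonnegative 4-vector summing to 1")
  if (!identical(names(p), .SUBTYPES))
    msg <- c(msg, "subtypeProportions must be named LumA, LumB, HER2E, Basal")
  if (object@expressionSeparation < 0)
    msg <- c(msg, "expressionSeparation must be nonnegative")
  if (object@dispersion < 0)
    msg <- c(msg, "dispersion must be nonnegative")
  lr <- object@librarySizeRange
  if (length(lr) != 2L || any(lr <= 0) || lr[1] > lr[2])
    msg <- c(msg, "librarySizeRange must be an increasing positive pair")
  if (object@immuneCoupling < 0 || object@immuneCoupling > 1)
    msg <- c(msg, "immuneCoupling must lie in [0, 1]")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate must lie in [0, 1)")
  hl <- object@hazardLogHR
  if (length(hl) && !all(names(hl) %in% .HAZARD_COVARIATES))
    msg <- c(msg, sprintf("hazardLogHR names must be among: %s",
                          paste(.HAZARD_COVARIATES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

.HAZARD_COVARIATES <- c("LumB", "HER2E", "Basal", "immune", "size_gt1cm")

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: n =", object@nPatients, "seed =", object@seed, "\n")
  cat("  subtype mix:",
      paste(sprintf("%s=%.2f", names(object@subtypeProportions),
                    object@subtypeProportions), collapse = " "), "\n")
  cat(sprintf("  separation = %.2g log2, dispersion = %.2g, libsize = [%d, %d]\n",
              object@expressionSeparation, object@dispersion,
              object@librarySizeRange[1], object@librarySizeRange[2]))
  cat(sprintf("  immune coupling = %.2f, censoring = %.2f\n",
              object@immuneCoupling, object@censoringRate))
})

#' CentroidModel: nearest-centroid subtype classifier with ROR-P weights
#'
#' Holds per-subtype mean expression profiles over the subtype genes, the
#' correlation metric used to assign samples, and the coefficients,
#' rescaling and risk thresholds of the proliferation-weighted
#' risk-of-recurrence (ROR-P) score.
#'
#' @slot centroids 4 x G matrix (rows LumA, LumB, HER2E, Basal) of centred
#'   log2 expression.
#' @slot correlationMethod `"spearman"` (default) or `"pearson"`.
#' @slot rorCoefficients named numeric `(LumA, LumB, HER2E, Basal, P)`:
#'   subtype-correlation weights plus the proliferation weight.
#' @slot proliferationGenes subtype genes averaged into the proliferation
#'   score P.
#' @slot rorRescale named numeric `(offset, scale)` mapping the raw score to
#'   0-100 (fitted min-max on the training cohort).
#' @slot rorThresholds increasing pair: low/medium and medium/high
#'   boundaries on the 0-100 scale.
#' @seealso [trainCentroids()], [classifySubtype()], [rorScore()]
#' @export
setClass("CentroidModel",
  representation(centroids = "matrix",
                 correlationMethod = "character",
                 rorCoefficients = "numeric",
                 proliferationGenes = "character",
                 rorRescale = "numeric",
                 rorThresholds = "numeric"))

setValidity("CentroidModel", function(object) {
  msg <- character()
  if (!identical(rownames(object@centroids), .SUBTYPES))
    msg <- c(msg, "centroid rows must be LumA, LumB, HER2E, Basal")
  if (any(apply(object@centroids, 1, stats::sd) == 0))
    msg <- c(msg, "centroids must not contain a constant profile")
  if (!object@correlationMethod %in% c("spearman", "pearson"))
    msg <- c(msg, "correlationMethod must be 'spearman' or 'pearson'")
  need <- c(.SUBTYPES, "P")
  if (!all(need %in% names(object@rorCoefficients)))
    msg <- c(msg, "rorCoefficients must be named LumA, LumB, HER2E, Basal, P")
  if (!all(object@proliferationGenes %in% colnames(object@centroids)))
    msg <- c(msg, "proliferationGenes must be centroid genes")
  if (!all(c("offset", "scale") %in% names(object@rorRescale)))
    msg <- c(msg, "rorRescale must be named (offset, scale)")
  if (length(object@rorThresholds) != 2L || diff(object@rorThresholds) <= 0)
    msg <- c(msg, "rorThresholds must be an increasing pair")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel:", ncol(object@centroids), "genes,",
      object@correlationMethod, "correlation\n")
  cat("  ROR-P weights:",
      paste(sprintf("%s=%.2f", names(object@rorCoefficients),
                    object@rorCoefficients), collapse = " "), "\n")
  cat(sprintf("  ROR classes: low < %.3g <= medium < %.3g <= high\n",
              object@rorThresholds[1], object@rorThresholds[2]))
})

#' @describeIn CentroidModel the 4 x G centroid matrix.
#' @param x a `CentroidModel`.
#' @export
centroids <- function(x) x@centroids

#' RSModel: 21-gene recurrence score configuration
#'
#' Configuration of the 21-gene recurrence score (RS): gene groups with
#' within-group weights and floors, group coefficients, reference
#' (housekeeping) genes, the reference offset placing normalised expression
#' on a positive scale, the affine map to 0-100 and the risk-class
#' thresholds.
#'
#' @slot groups named list; each element `list(genes=, weights=, floor=)`
#'   (floor `NA` when none). Group score = weighted mean, floored.
#' @slot coefficients named numeric, one per group.
#' @slot referenceGenes the housekeeping symbols used for normalisation.
#' @slot referenceOffset scalar added after subtracting the housekeeping
#'   mean (scale convention).
#' @slot scale,shift RS = clip(scale * (RSu - shift), 0, 100).
#' @slot classThresholds increasing pair: low < t1 <= intermediate < t2 <=
#'   high (defaults 18, 31).
#' @seealso [rsModel()], [panelRSModel()], [oncotypeRS()]
#' @export
setClass("RSModel",
  representation(groups = "list",
                 coefficients = "numeric",
                 referenceGenes = "character",
                 referenceOffset = "numeric",
                 scale = "numeric",
                 shift = "numeric",
                 classThresholds = "numeric"))

setValidity("RSModel", function(object) {
  msg <- character()
  if (!identical(sort(names(object@groups)), sort(names(object@coefficients))))
    msg <- c(msg, "groups and coefficients must share names")
  genes <- unlist(lapply(object@groups, `[[`, "genes"), use.names = FALSE)
  if (anyDuplicated(genes))
    msg <- c(msg, "each informative gene must belong to exactly one group")
  if (length(object@classThresholds) != 2L ||
      diff(object@classThresholds) <= 0)
    msg <- c(msg, "classThresholds must be an increasing pair")
  if (length(object@referenceGenes) < 1L)
    msg <- c(msg, "at least one reference gene is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RSModel", function(object) {
  cat("RSModel:", length(object@groups), "groups over",
      length(unlist(lapply(object@groups, `[[`, "genes"))),
      "informative genes,", length(object@referenceGenes),
      "reference genes\n")
  cat(sprintf("  RS = clip(%.3g * (RSu - %.3g), 0, 100); classes < %g / >= %g\n",
              object@scale, object@shift,
              object@classThresholds[1], object@classThresholds[2]))
})
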
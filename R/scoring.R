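#' Default ROR-P coefficients
#'
#' Subtype-correlation weights of the published risk-of-recurrence score
#' (-0.34 LumA, +0.23 LumB, +0.12 HER2E, +0.05 Basal) plus the
#' proliferation weight applied to the mean centred expression of the
#' proliferation gene subset.
#' @return named numeric of length 5.
#' @export
defaultRORCoefficients <- function() {
  c(LumA = -0.34, LumB = 0.23, HER2E = 0.12, Basal = 0.05, P = 0.54)
}

#' Train a nearest-centroid subtype model
#'
#' Computes per-subtype centroids as the mean centred expression of each
#' subtype gene over the samples carrying that label, and calibrates the
#' ROR-P rescaling so that the raw scores of the training cohort span
#' 0-100 (min-max; stored in the model so held-out samples use the same
#' affine map).
#'
#' @param pe a normalised [PanelExperiment-class] (see [normalizePanel()]).
#' @param labels subtype label per sample (values among LumA, LumB, HER2E,
#'   Basal); by default taken from `colData(pe)$true_subtype` when present.
#' @param method correlation used to assign samples: `"spearman"`
#'   (default) or `"pearson"`.
#' @param rorCoefficients see [defaultRORCoefficients()].
#' @param proliferationGenes genes averaged into the proliferation score P
#'   (default [proliferationGeneSet()], intersected with the panel).
#' @param rorThresholds low/medium and medium/high boundaries on the 0-100
#'   scale (default 40, 60).
#' @param onSmall what to do with a subtype represented by fewer than 2
#'   samples: `"error"` (default; lists the subtype) or `"pool"` (treat it
#'   like an absent subtype: pooled mean centroid, with a warning).
#' @return a [CentroidModel-class].
#' @export
trainCentroids <- function(pe, labels = NULL, method = "spearman",
                           rorCoefficients = defaultRORCoefficients(),
                           proliferationGenes = proliferationGeneSet(),
                           rorThresholds = c(40, 60),
                           onSmall = c("error", "pool")) {
  onSmall <- match.arg(onSmall)
  if (is.null(labels)) {
    labels <- SummarizedExperiment::colData(pe)$true_subtype
    if (is.null(labels))
      stop("labels not given and colData has no true_subtype column")
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(pe))
  if (!all(labels %in% .SUBTYPES))
    stop("labels must be among: ", paste(.SUBTYPES, collapse = ", "))
  x <- .centeredMatrix(pe)[subtypeGenes(pe), , drop = FALSE]
  counts <- table(factor(labels, levels = .SUBTYPES))
  small <- names(counts)[counts == 1L]
  if (length(small) && onSmall == "error")
    stop("subtype(s) with < 2 samples: ", paste(small, collapse = ", "))
  present <- names(counts)[counts >= 2L]
  cen <- matrix(NA_real_, 4L, nrow(x),
                dimnames = list(.SUBTYPES, rownames(x)))
  for (k in present)
    cen[k, ] <- rowMeans(x[, labels == k, drop = FALSE])
  if (anyNA(cen)) {
    absent <- .SUBTYPES[!(.SUBTYPES %in% present)]
    warning("subtype(s) absent or singleton in training data: ",
            paste(absent, collapse = ", "),
            "; pooled mean profile used as their centroid")
    cen[absent, ] <- matrix(rowMeans(x), nrow = length(absent),
                            ncol = nrow(x), byrow = TRUE)
  }
  pg <- intersect(proliferationGenes, rownames(x))
  if (!length(pg)) stop("proliferation gene set is empty on this panel")
  model <- new("CentroidModel", centroids = cen, correlationMethod = method,
               rorCoefficients = rorCoefficients, proliferationGenes = pg,
               rorRescale = c(offset = 0, scale = 1),
               rorThresholds = rorThresholds)
  raw <- .rorRaw(model, x)
  rng <- range(raw)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  model@rorRescale <- c(offset = -100 * rng[1] / diff(rng),
                        scale = 100 / diff(rng))
  model
}

.centeredMatrix <- function(pe) {
  if (!"centered" %in% SummarizedExperiment::assayNames(pe))
    stop("panel is not normalised; run normalizePanel() first")
  SummarizedExperiment::assay(pe, "centered")
}

.profileMatrix <- function(x, genes) {
  # accept PanelExperiment, genes x samples matrix, or a single profile
  if (is(x, "PanelExperiment")) x <- .centeredMatrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(names(x), "sample"))
  missing <- setdiff(genes, rownames(x))
  x <- x[intersect(genes, rownames(x)), , drop = FALSE]
  if (length(missing)) {
    warning("mean-imputing ", length(missing), " missing gene(s): ",
            paste(missing, collapse = ", "))
    imp <- matrix(rep(colMeans(x), each = length(missing)),
                  nrow = length(missing),
                  dimnames = list(missing, colnames(x)))
    x <- rbind(x, imp)
  }
  x[genes, , drop = FALSE]
}

#' Classify samples into intrinsic subtypes
#'
#' Nearest-centroid assignment: each sample goes to the subtype whose
#' centroid it correlates with most strongly (Spearman by default). Ties
#' are broken by the fixed order LumA > LumB > HER2E > Basal and flagged.
#' Genes missing from the input are mean-imputed with a warning; a constant
#' profile (correlation undefined) is an error.
#'
#' @param x a normalised [PanelExperiment-class], a genes x samples matrix
#'   of centred log2 expression, or a single named profile vector.
#' @param model a [CentroidModel-class].
#' @return `DataFrame` with `subtype`, one correlation column per subtype
#'   (`cor_LumA`, ...), and `tie`.
#' @export
classifySubtype <- function(x, model) {
  genes <- colnames(model@centroids)
  m <- .profileMatrix(x, genes)
  if (any(apply(m, 2, stats::sd) == 0)) {
    bad <- colnames(m)[apply(m, 2, stats::sd) == 0]
    stop("constant expression profile (correlation undefined) for: ",
         paste(bad, collapse = ", "))
  }
  cors <- stats::cor(m, t(model@centroids), method = model@correlationMethod)
  best <- apply(cors, 1, max)
  tie <- rowSums(cors == best) > 1L
  call <- .SUBTYPES[apply(cors[, .SUBTYPES, drop = FALSE], 1, which.max)]
  out <- S4Vectors::DataFrame(subtype = call, tie = tie,
                              row.names = colnames(m))
  for (k in .SUBTYPES) out[[paste0("cor_", k)]] <- unname(cors[, k])
  out
}

.rorRaw <- function(model, m) {
  genes <- colnames(model@centroids)
  cors <- stats::cor(m[genes, , drop = FALSE], t(model@centroids),
                     method = model@correlationMethod)
  w <- model@rorCoefficients
  P <- colMeans(m[model@proliferationGenes, , drop = FALSE])
  drop(cors[, .SUBTYPES, drop = FALSE] %*% w[.SUBTYPES]) + w["P"] * P
}

#' Proliferation-weighted risk of recurrence (ROR-P)
#'
#' Raw score = sum over subtypes of weight x centroid correlation, plus the
#' proliferation weight times P, the mean centred expression of the
#' proliferation gene subset. The raw score is mapped to 0-100 by the
#' model's stored affine rescaling (clipped) and classed low/medium/high by
#' the model thresholds (low < t1, medium in \[t1, t2), high >= t2).
#'
#' @inheritParams classifySubtype
#' @return `DataFrame` with `ror_p`, `ror_raw`, `ror_class` and `P`.
#' @export
rorScore <- function(x, model) {
  genes <- colnames(model@centroids)
  m <- .profileMatrix(x, genes)
  raw <- .rorRaw(model, m)
  sc <- model@rorRescale["offset"] + model@rorRescale["scale"] * raw
  sc <- pmin(pmax(sc, 0), 100)
  S4Vectors::DataFrame(
    ror_p = unname(sc), ror_raw = unname(raw),
    ror_class = .riskClass(sc, model@rorThresholds),
    P = unname(colMeans(m[model@proliferationGenes, , drop = FALSE])),
    row.names = colnames(m))
}

.riskClass <- function(score, thr, labels = c("low", "medium", "high")) {
  cut(score, breaks = c(-Inf, thr, Inf), labels = labels, right = FALSE)
}

#' Published 21-gene recurrence score model
#'
#' The full published configuration: HER2 group (0.9 GRB7 + 0.1 ERBB2,
#' floored at 8), ER group (0.8 ESR1 + 1.2 PGR + BCL2 + SCUBE2)/4,
#' proliferation group (mean of MKI67, AURKA, BIRC5, CCNB1, MYBL2, floored
#' at 6.5), invasion group (mean of MMP11, CTSV) and singleton genes CD68,
#' GSTM1 and BAG1; coefficients +0.47, -0.34, +1.04, +0.10, +0.05, -0.08,
#' -0.07; RS = clip(20 x (RSu - 6.7), 0, 100); classes low < 18,
#' medium 18-30, high >= 31. Reference normalisation subtracts the
#' mean housekeeping log2 value and adds `referenceOffset` (a scale
#' convention; panel log2 CPM is not the original assay's Ct scale, so
#' absolute scores are internally consistent rather than vendor-exact).
#'
#' @param referenceOffset scalar added to housekeeping-normalised values
#'   (default 7).
#' @param classThresholds risk-class boundaries (default 18, 31).
#' @return an [RSModel-class].
#' @export
rsModel <- function(referenceOffset = 7, classThresholds = c(18, 31)) {
  groups <- list(
    her2 = list(genes = c("GRB7", "ERBB2"), weights = c(0.9, 0.1),
                floor = 8),
    er = list(genes = c("ESR1", "PGR", "BCL2", "SCUBE2"),
              weights = c(0.8, 1.2, 1, 1), floor = NA_real_),
    proliferation = list(genes = c("MKI67", "AURKA", "BIRC5", "CCNB1",
                                   "MYBL2"),
                         weights = rep(1, 5), floor = 6.5),
    invasion = list(genes = c("MMP11", "CTSV"), weights = c(1, 1),
                    floor = NA_real_),
    cd68 = list(genes = "CD68", weights = 1, floor = NA_real_),
    gstm1 = list(genes = "GSTM1", weights = 1, floor = NA_real_),
    bag1 = list(genes = "BAG1", weights = 1, floor = NA_real_))
  new("RSModel", groups = groups,
      coefficients = c(her2 = 0.47, er = -0.34, proliferation = 1.04,
                       invasion = 0.10, cd68 = 0.05, gstm1 = -0.08,
                       bag1 = -0.07),
      referenceGenes = c("ACTB", "GAPDH", "GUSB", "RPLP0", "TFRC"),
      referenceOffset = referenceOffset, scale = 20, shift = 6.7,
      classThresholds = classThresholds)
}

#' Panel-restricted 21-gene recurrence score model
#'
#' [rsModel()] with each group restricted to the genes measurable on the
#' default 72-gene panel (SCUBE2, AURKA, CTSV, CD68 and GSTM1 are not on
#' it): group structure, coefficients, floors and scaling are unchanged,
#' absent singleton groups are dropped. Intended for cohorts generated on
#' the default panel; use [rsModel()] when the panel measures all 16
#' informative genes.
#'
#' @inheritParams rsModel
#' @param panel gene panel data.frame.
#' @return an [RSModel-class].
#' @export
panelRSModel <- function(panel = defaultGenePanel(), referenceOffset = 7,
                         classThresholds = c(18, 31)) {
  full <- rsModel(referenceOffset, classThresholds)
  groups <- full@groups
  keep <- character()
  for (g in names(groups)) {
    sel <- groups[[g]]$genes %in% panel$gene
    if (!any(sel)) next
    groups[[g]]$genes <- groups[[g]]$genes[sel]
    groups[[g]]$weights <- groups[[g]]$weights[sel]
    keep <- c(keep, g)
  }
  new("RSModel", groups = groups[keep],
      coefficients = full@coefficients[keep],
      referenceGenes = intersect(full@referenceGenes, panel$gene),
      referenceOffset = referenceOffset, scale = full@scale,
      shift = full@shift, classThresholds = classThresholds)
}

.referenceNormalize <- function(logcpm, model) {
  miss <- setdiff(model@referenceGenes, rownames(logcpm))
  if (length(miss))
    stop("reference gene(s) missing: ", paste(miss, collapse = ", "))
  ref <- colMeans(logcpm[model@referenceGenes, , drop = FALSE])
  sweep(logcpm, 2, ref) + model@referenceOffset
}

#' 21-gene recurrence score (RS)
#'
#' Reference-normalises each informative gene (log2 value minus the mean of
#' the housekeeping log2 values, plus the model's reference offset),
#' computes the weighted, floored group scores, the unscaled score
#' RSu = sum(coefficient x group score), and RS = clip(scale x (RSu -
#' shift), 0, 100), classed by the model thresholds.
#'
#' @param x a normalised [PanelExperiment-class] (its `logcpm` assay is
#'   used) or a genes x samples matrix of log2 expression including the
#'   reference genes.
#' @param model an [RSModel-class]; [panelRSModel()] by default.
#' @return `DataFrame` with `rs`, `rs_unscaled`, `rs_class` and one column
#'   per group score.
#' @export
oncotypeRS <- function(x, model = panelRSModel()) {
  logcpm <- if (is(x, "PanelExperiment")) {
    if (!"logcpm" %in% SummarizedExperiment::assayNames(x))
      stop("panel is not normalised; run normalizePanel() first")
    SummarizedExperiment::assay(x, "logcpm")
  } else as.matrix(x)
  inf_genes <- unlist(lapply(model@groups, `[[`, "genes"), use.names = FALSE)
  miss <- setdiff(inf_genes, rownames(logcpm))
  if (length(miss))
    stop("informative gene(s) missing: ", paste(miss, collapse = ", "))
  norm <- .referenceNormalize(logcpm, model)
  gs <- vapply(model@groups, function(g) {
    v <- drop(crossprod(norm[g$genes, , drop = FALSE], g$weights)) /
      sum(g$weights)
    if (!is.na(g$floor)) v <- pmax(v, g$floor)
    v
  }, numeric(ncol(norm)))
  if (is.null(dim(gs))) gs <- matrix(gs, nrow = 1,
                                     dimnames = list(NULL, names(model@groups)))
  rsu <- drop(gs %*% model@coefficients[colnames(gs)])
  rs <- pmin(pmax(model@scale * (rsu - model@shift), 0), 100)
  out <- S4Vectors::DataFrame(rs = unname(rs), rs_unscaled = unname(rsu),
                              rs_class = .riskClass(rs,
                                                    model@classThresholds),
                              row.names = colnames(norm))
  for (g in colnames(gs)) out[[paste0("group_", g)]] <- unname(gs[, g])
  out
}

#' 17-gene immune score
#'
#' Per sample: the mean housekeeping-normalised log2 expression of the
#' immune genes, min-max rescaled to 0-100 over the cohort. Samples are
#' grouped `istrong` when the score is greater than or equal to the cutoff
#' (inclusive), `iweak` otherwise. The cutoff defaults to the published
#' ROC-derived preset 45.5; supplying `outcome` instead derives it from the
#' cohort by the Youden index ([youdenCutpoint()]).
#'
#' @param pe a normalised [PanelExperiment-class].
#' @param cutoff score cutoff on the 0-100 scale (default 45.5).
#' @param outcome optional binary event vector; when given, the cutoff is
#'   the cohort's Youden-optimal threshold for that outcome.
#' @param referenceOffset added to housekeeping-normalised values before
#'   averaging (cancels in the min-max rescale; kept for reporting raw
#'   means on the same scale as [oncotypeRS()]).
#' @return `DataFrame` with `immune_score`, `immune_raw`, `immune_group`,
#'   plus the cutoff used in its metadata.
#' @export
immuneScore <- function(pe, cutoff = 45.5, outcome = NULL,
                        referenceOffset = 7) {
  if (!"logcpm" %in% SummarizedExperiment::assayNames(pe))
    stop("panel is not normalised; run normalizePanel() first")
  logcpm <- SummarizedExperiment::assay(pe, "logcpm")
  ig <- immuneGenes(pe)
  if (!length(ig)) stop("panel has no immune genes")
  hk <- housekeepingGenes(pe)
  if (!length(hk)) stop("panel has no housekeeping genes")
  ref <- colMeans(logcpm[hk, , drop = FALSE])
  norm <- sweep(logcpm[ig, , drop = FALSE], 2, ref) + referenceOffset
  raw <- colMeans(norm)
  rng <- range(raw)
  if (diff(rng) == 0)
    stop("degenerate cohort: immune score min equals max")
  score <- 100 * (raw - rng[1]) / diff(rng)
  if (!is.null(outcome)) {
    cp <- youdenCutpoint(score, outcome)
    cutoff <- cp$cutoff
  }
  out <- S4Vectors::DataFrame(
    immune_score = unname(score), immune_raw = unname(raw),
    immune_group = unname(ifelse(score >= cutoff, "istrong", "iweak")),
    row.names = colnames(logcpm))
  S4Vectors::metadata(out)$cutoff <- cutoff
  out
}

#' Score a cohort end to end
#'
#' Runs [classifySubtype()], [rorScore()], [oncotypeRS()] and
#' [immuneScore()] on a normalised panel and binds the per-patient results.
#'
#' @param pe a normalised [PanelExperiment-class].
#' @param centroidModel a [CentroidModel-class].
#' @param rsMod an [RSModel-class] (default [panelRSModel()]).
#' @param immuneCutoff passed to [immuneScore()].
#' @return `DataFrame` with one row per sample: subtype call and
#'   correlations, ROR-P + class, RS + class, immune score + group.
#' @export
scoreCohort <- function(pe, centroidModel, rsMod = panelRSModel(),
                        immuneCutoff = 45.5) {
  cls <- classifySubtype(pe, centroidModel)
  ror <- rorScore(pe, centroidModel)
  rs <- oncotypeRS(pe, rsMod)
  imm <- immuneScore(pe, cutoff = immuneCutoff)
  out <- cbind(cls, ror[rownames(cls), ], rs[rownames(cls), ],
               imm[rownames(cls), ])
  S4Vectors::metadata(out)$immune_cutoff <- S4Vectors::metadata(imm)$cutoff
  out
}

#' Fit ROR subtype weights by Cox regression (self-trained mode)
#'
#' Alternative to the published coefficient preset: regresses survival on
#' the four centroid correlations and the proliferation score via a Cox
#' proportional-hazards model and returns the fitted log-hazard
#' coefficients as ROR weights, mirroring how correlation-based
#' risk-of-recurrence scores were originally calibrated.
#'
#' @param pe a normalised [PanelExperiment-class].
#' @param model a [CentroidModel-class] (its correlations and proliferation
#'   set are reused).
#' @param times,events survival outcome used for calibration.
#' @return named numeric of ROR coefficients (LumA, LumB, HER2E, Basal, P).
#' @export
trainRORWeights <- function(pe, model, times, events) {
  cls <- classifySubtype(pe, model)
  m <- .profileMatrix(pe, colnames(model@centroids))
  df <- data.frame(LumA = cls$cor_LumA, LumB = cls$cor_LumB,
                   HER2E = cls$cor_HER2E, Basal = cls$cor_Basal,
                   P = colMeans(m[model@proliferationGenes, , drop = FALSE]))
  fit <- survival::coxph(survival::Surv(times, events) ~ ., data = df)
  stats::coef(fit)
}
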
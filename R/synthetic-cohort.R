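#' Specify a synthetic cohort
#'
#' Builds a validated [CohortSpec-class]. Defaults reproduce the structure of
#' an HR+/HER2- stage 1 cohort of 87 patients with an intrinsic-subtype mix
#' of 71% luminal A, 20% luminal B, 2% HER2-enriched and 7% basal-like.
#'
#' @param nPatients cohort size (default 87).
#' @param subtypeProportions 4-vector over (LumA, LumB, HER2E, Basal)
#'   summing to 1.
#' @param expressionSeparation per-gene log2 shift applied to signature
#'   genes (default 2).
#' @param dispersion negative-binomial overdispersion (default 0.3; 0 gives
#'   Poisson counts).
#' @param librarySizeRange uniform range of per-sample total reads.
#' @param immuneCoupling correlation between the latent immune level and
#'   immune-gene means / TILs (default 0.8).
#' @param hazardLogHR named log hazard ratios over `LumB`, `HER2E`, `Basal`,
#'   `immune`, `size_gt1cm`.
#' @param censoringRate expected censored fraction in \[0, 1).
#' @param seed integer seed.
#' @return a `CohortSpec`.
#' @examples
#' cohortSpec(nPatients = 50, seed = 7)
#' @export
cohortSpec <- function(nPatients = 87L,
                       subtypeProportions = c(LumA = 0.71, LumB = 0.20,
                                              HER2E = 0.02, Basal = 0.07),
                       expressionSeparation = 2,
                       dispersion = 0.3,
                       librarySizeRange = c(50000L, 200000L),
                       immuneCoupling = 0.8,
                       hazardLogHR = c(LumB = 0.6, HER2E = 0.8, Basal = 1.2,
                                       immune = 0.35, size_gt1cm = 0.5),
                       censoringRate = 0.3,
                       seed = 1L) {
  if (is.null(names(subtypeProportions)))
    names(subtypeProportions) <- .SUBTYPES
  new("CohortSpec",
      nPatients = as.integer(nPatients),
      subtypeProportions = subtypeProportions[.SUBTYPES],
      expressionSeparation = expressionSeparation,
      dispersion = dispersion,
      librarySizeRange = as.numeric(librarySizeRange),
      immuneCoupling = immuneCoupling,
      hazardLogHR = hazardLogHR,
      censoringRate = censoringRate,
      seed = as.integer(seed))
}

# signature weight of each signature group under each subtype, in [-1, 1];
# multiplied by expressionSeparation to shift the per-gene log2 mean
.signatureEffects <- function() {
  rbind(luminal       = c(LumA = 1.0, LumB = 0.6, HER2E = -0.8, Basal = -1.0),
        proliferation = c(LumA = -1.0, LumB = 0.6, HER2E = 0.4, Basal = 1.0),
        her2          = c(LumA = -0.3, LumB = 0.0, HER2E = 1.0, Basal = -0.2),
        basal         = c(LumA = -1.0, LumB = -0.8, HER2E = -0.4, Basal = 1.0),
        other         = c(LumA = 0, LumB = 0, HER2E = 0, Basal = 0))
}

# per-gene x subtype weights: the signature group effect plus a fixed
# deterministic per-gene modulation, so subtype profiles differ gene by
# gene (not only block by block) as real centroid profiles do; the
# modulation is a constant of the panel (independent of the cohort seed)
# so cohorts drawn under different seeds share the same profile structure
.geneSubtypeWeights <- function(panel) {
  eff <- .signatureEffects()
  G <- nrow(panel)
  W <- matrix(0, G, length(.SUBTYPES),
              dimnames = list(panel$gene, .SUBTYPES))
  is_sig <- panel$signature %in% rownames(eff)
  W[is_sig, ] <- eff[panel$signature[is_sig], , drop = FALSE]
  is_sub <- panel$role == "subtype"
  idx <- seq_len(G)
  for (k in seq_along(.SUBTYPES))
    W[is_sub, k] <- W[is_sub, k] +
      0.35 * sin(2.399 * idx[is_sub] * k + k)
  W
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort under a [CohortSpec-class]: latent intrinsic subtype and
#' immune level per patient; negative-binomial panel counts around
#' subtype-specific log2 mean profiles scaled to a uniform-random library
#' size; IHC percentages (ER/PR/Ki-67) as logistic transforms of the
#' matching gene's latent mean plus noise, so the IHC channel is correlated
#' with but not identical to expression; basal markers positive with high
#' probability only for basal latents; TILs sharing the latent immune level
#' at the specified coupling; and exponential DFS/DMFS with log-hazard equal
#' to the covariate sum under `hazardLogHR` and independent exponential
#' censoring calibrated to `censoringRate`.
#'
#' The draw is fully determined by `spec` (including its seed): repeated
#' calls return identical cohorts.
#'
#' @param spec a [CohortSpec-class].
#' @param panel gene panel data.frame as from [defaultGenePanel()].
#' @return list with elements `panel` (a [PanelExperiment-class] whose
#'   `colData` carries the clinical table and truth columns), `clinical`
#'   (plain data.frame of patient records) and `truth` (data.frame with
#'   `id`, `true_subtype`, `true_immune_level`).
#' @examples
#' coh <- generateCohort(cohortSpec(nPatients = 20, seed = 3))
#' table(coh$truth$true_subtype)
#' @export
generateCohort <- function(spec, panel = defaultGenePanel()) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nPatients
  ids <- sprintf("S%03d", seq_len(n))
  subtype <- sample(.SUBTYPES, n, replace = TRUE,
                    prob = spec@subtypeProportions)
  z_imm <- stats::rnorm(n)

  sep <- spec@expressionSeparation
  G <- nrow(panel)
  mu_log2 <- matrix(panel$baseline_log2, nrow = G, ncol = n,
                    dimnames = list(panel$gene, ids))
  W <- .geneSubtypeWeights(panel)
  mu_log2 <- mu_log2 + sep * W[, subtype, drop = FALSE]
  # immune genes: mean shares the latent immune level at the requested
  # correlation; independent per-gene residual keeps corr = immuneCoupling
  cc <- spec@immuneCoupling
  imm_idx <- which(panel$role == "immune")
  if (length(imm_idx)) {
    eta <- matrix(stats::rnorm(length(imm_idx) * n), length(imm_idx), n)
    mu_log2[imm_idx, ] <- mu_log2[imm_idx, ] +
      1.5 * (cc * rep(z_imm, each = length(imm_idx)) +
             sqrt(max(0, 1 - cc^2)) * eta)
  }

  lib <- round(stats::runif(n, spec@librarySizeRange[1],
                            spec@librarySizeRange[2]))
  counts <- matrix(0L, G, n, dimnames = list(panel$gene, ids))
  for (j in seq_len(n)) {
    p <- 2^mu_log2[, j]
    p <- p / sum(p)
    mu <- p * lib[j]
    counts[, j] <- if (spec@dispersion > 0)
      stats::rnbinom(G, mu = mu, size = 1 / spec@dispersion)
    else stats::rpois(G, mu)
  }
  storage.mode(counts) <- "integer"

  # IHC channels: logistic transforms of the matching gene's latent log2
  # deviation plus noise (correlated with, not identical to, expression)
  dev <- function(gene) mu_log2[gene, ] - panel$baseline_log2[match(gene, panel$gene)]
  d_esr1 <- if ("ESR1" %in% panel$gene) dev("ESR1") else
    sep * eff["luminal", subtype]
  d_pgr <- if ("PGR" %in% panel$gene) dev("PGR") else d_esr1
  d_mki <- if ("MKI67" %in% panel$gene) dev("MKI67") else
    sep * eff["proliferation", subtype]
  er <- round(100 * stats::plogis(1.5 * d_esr1 + 0.8 * stats::rnorm(n)))
  pr <- round(100 * stats::plogis(1.2 * d_pgr + 0.9 * stats::rnorm(n)))
  ki67 <- round(100 * stats::plogis(-0.6 + 0.9 * d_mki + 0.5 * stats::rnorm(n)))
  basal <- subtype == "Basal"
  # keep basal ER in the low-but-positive band and PR low, as observed for
  # molecular basal-like tumours arising inside an HR+ cohort
  er[basal] <- pmin(pmax(er[basal], 2L), 10L)
  er <- pmax(er, 2L)  # cohort definition: ER-positive (> 1%)
  pr[basal] <- pmin(pr[basal], 10L)

  ck56 <- stats::rbinom(n, 1, ifelse(basal, 0.60, 0.02)) == 1
  egfr <- stats::rbinom(n, 1, ifelse(basal, 0.95, 0.08)) == 1
  ck14 <- stats::rbinom(n, 1, ifelse(basal, 0.35, 0.01)) == 1
  p53 <- stats::rbinom(n, 1, ifelse(basal, 0.6, 0.25)) == 1

  eta_t <- stats::rnorm(n)
  tils_raw <- cc * z_imm + sqrt(max(0, 1 - cc^2)) * eta_t
  tils <- round(100 * stats::plogis(stats::qlogis(0.08) + 1.3 * tils_raw))

  grade_probs <- list(LumA = c(0.3, 0.6, 0.1), LumB = c(0.1, 0.6, 0.3),
                      HER2E = c(0.1, 0.5, 0.4), Basal = c(0.02, 0.28, 0.7))
  grade <- vapply(subtype, function(s)
    sample(1:3, 1, prob = grade_probs[[s]]), integer(1))
  size <- round(stats::runif(n, 0.6, 2.0), 1)
  age <- pmin(pmax(round(stats::rnorm(n, 48.5, 10)), 28L), 80L)
  chemo <- stats::rbinom(n, 1, 0.30) == 1
  radio <- stats::rbinom(n, 1, 0.29) == 1

  hl <- spec@hazardLogHR
  hl_full <- stats::setNames(numeric(length(.HAZARD_COVARIATES)),
                             .HAZARD_COVARIATES)
  hl_full[names(hl)] <- hl
  lp <- hl_full["LumB"] * (subtype == "LumB") +
    hl_full["HER2E"] * (subtype == "HER2E") +
    hl_full["Basal"] * basal +
    hl_full["immune"] * z_imm +
    hl_full["size_gt1cm"] * (size > 1)
  surv_one <- function(h0) {
    h <- h0 * exp(lp)
    t_ev <- stats::rexp(n, h)
    if (spec@censoringRate > 0) {
      hc <- h * spec@censoringRate / (1 - spec@censoringRate)
      t_c <- stats::rexp(n, hc)
      list(time = round(pmin(t_ev, t_c), 2), event = as.integer(t_ev <= t_c))
    } else list(time = round(t_ev, 2), event = rep(1L, n))
  }
  dfs <- surv_one(0.004)
  dmfs <- surv_one(0.0018)

  clinical <- data.frame(
    id = ids, age_years = age, tumor_size_cm = size, grade = grade,
    er_pct = er, pr_pct = pr, ki67_pct = ki67, her2_status = "negative",
    ck56_pos = ck56, egfr_pos = egfr, ck14_pos = ck14, p53_pos = p53,
    tils_pct = tils, chemo = chemo, radio = radio, endocrine = TRUE,
    dfs_months = dfs$time, dfs_event = dfs$event,
    dmfs_months = dmfs$time, dmfs_event = dmfs$event,
    stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, true_subtype = subtype,
                      true_immune_level = z_imm, stringsAsFactors = FALSE)

  cd <- S4Vectors::DataFrame(clinical, true_subtype = subtype,
                             true_immune_level = z_imm, row.names = ids)
  pe <- PanelExperiment(counts, stats::setNames(panel$role, panel$gene),
                        colData = cd)
  list(panel = pe, clinical = clinical, truth = truth)
}

#' Write a panel as a gene x sample TSV
#'
#' First column `gene`, remaining columns one per sample (header = sample
#' IDs), cells = raw counts. The format read back by [readCounts()].
#' @param pe a [PanelExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanelTSV <- function(pe, path) {
  m <- SummarizedExperiment::assay(pe, "counts")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clinical table as CSV
#' @param clinical data.frame of patient records (see [generateCohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClinicalCSV <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table CSV
#' @param path CSV with the column layout written by [writeClinicalCSV()].
#' @return data.frame.
#' @export
readClinicalCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
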
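# small hand-built centroid model over 4 genes (2 of them "proliferation")
toy_model <- function(offset = 50, scale = 10) {
  cen <- rbind(LumA = c(1, -1, 1, -1),
               LumB = c(1, -1, -1, 1),
               HER2E = c(-1, 1, 1, -1),
               Basal = c(-1, 1, -1, 1))
  colnames(cen) <- c("gA", "gB", "gC", "gD")
  new("CentroidModel", centroids = cen, correlationMethod = "pearson",
      rorCoefficients = defaultRORCoefficients(),
      proliferationGenes = c("gC", "gD"),
      rorRescale = c(offset = offset, scale = scale),
      rorThresholds = c(40, 60))
}

test_that("centroids are within-subtype means of centred expression", {
  base <- flat_counts(8, value = 50)
  set.seed(1)
  pat <- matrix(rpois(72 * 4, 200), 72, 4)
  m <- base
  for (k in 1:4) m[, c(2 * k - 1, 2 * k)] <- pat[, k]  # identical pairs
  pe <- normalizePanel(PanelExperiment(m, panel_roles()))
  labels <- rep(c("LumA", "LumB", "HER2E", "Basal"), each = 2)
  model <- trainCentroids(pe, labels)
  cen_assay <- SummarizedExperiment::assay(pe, "centered")
  sg <- subtypeGenes(pe)
  for (k in 1:4)
    expect_equal(unname(centroids(model)[labels[2 * k], ]),
                 unname(cen_assay[sg, 2 * k]), tolerance = 1e-12)
})

test_that("training refuses singleton subtypes unless pooling is asked", {
  coh <- small_cohort(n = 40, seed = 41,
                      proportions = c(LumA = .5, LumB = .5, HER2E = 0,
                                      Basal = 0))
  labels <- coh$truth$true_subtype
  labels[1] <- "Basal"
  expect_error(trainCentroids(coh$panel, labels), "Basal")
  expect_warning(m <- trainCentroids(coh$panel, labels, onSmall = "pool"),
                 "Basal")
  expect_s4_class(m, "CentroidModel")
})

test_that("a sample equal to a centroid is assigned to it with cor 1", {
  model <- toy_model()
  for (k in c("LumA", "LumB", "HER2E", "Basal")) {
    res <- classifySubtype(centroids(model)[k, ], model)
    expect_equal(res$subtype, k)
    expect_equal(res[[paste0("cor_", k)]], 1, tolerance = 1e-12)
  }
})

test_that("spearman assignment is invariant to monotone transforms", {
  model <- toy_model()
  model@correlationMethod <- "spearman"
  x <- 2^centroids(model)["LumA", ] + 5  # strictly increasing transform
  res <- classifySubtype(x, model)
  expect_equal(res$subtype, "LumA")
  expect_equal(res$cor_LumA, 1, tolerance = 1e-12)
})

test_that("ties are broken in fixed subtype order and flagged", {
  cen <- rbind(LumA = c(1, -1, 0, 0.5), LumB = c(1, -1, 0, 0.5),
               HER2E = c(-1, 1, 0, -0.5), Basal = c(0, 1, -1, 0.5))
  colnames(cen) <- paste0("g", 1:4)
  model <- new("CentroidModel", centroids = cen,
               correlationMethod = "pearson",
               rorCoefficients = defaultRORCoefficients(),
               proliferationGenes = "g1",
               rorRescale = c(offset = 0, scale = 1),
               rorThresholds = c(40, 60))
  res <- classifySubtype(cen["LumB", ], model)
  expect_true(res$tie)
  expect_equal(res$subtype, "LumA")  # LumA precedes LumB
})

test_that("constant profiles are rejected", {
  expect_error(classifySubtype(c(gA = 1, gB = 1, gC = 1, gD = 1),
                               toy_model()),
               "constant")
})

test_that("held-out subtype recovery exceeds 95% at high separation", {
  train <- small_cohort(n = 400, sep = 3, seed = 42)
  test <- small_cohort(n = 200, sep = 3, seed = 43)
  model <- trainCentroids(train$panel, train$truth$true_subtype)
  acc_test <- mean(classifySubtype(test$panel, model)$subtype ==
                   test$truth$true_subtype)
  expect_gte(acc_test, 0.95)
  # re-classifying the training samples is near-perfect
  acc_train <- mean(classifySubtype(train$panel, model)$subtype ==
                    train$truth$true_subtype)
  expect_gte(acc_train, 0.99)
})

test_that("permuted training labels give chance-level accuracy", {
  coh <- small_cohort(n = 200, seed = 44,
                      proportions = c(LumA = .25, LumB = .25, HER2E = .25,
                                      Basal = .25))
  set.seed(1)
  perm <- sample(coh$truth$true_subtype)
  model <- trainCentroids(coh$panel, perm)
  acc <- mean(classifySubtype(coh$panel, model)$subtype ==
              coh$truth$true_subtype)
  expect_lt(acc, 0.45)
})

test_that("ROR-P is the rescaled weighted correlation-plus-P score", {
  model <- toy_model(offset = 50, scale = 10)
  # sample uncorrelated (pearson) with all four centroids, P = 0
  x <- c(gA = 2, gB = 2, gC = 0, gD = 0)
  expect_true(all(abs(cor(x, t(centroids(model)))) < 1e-12))
  res <- rorScore(x, model)
  expect_equal(res$ror_p, 50)       # clip(offset + scale * 0)
  expect_equal(res$ror_class, factor("medium", c("low", "medium", "high")),
               ignore_attr = TRUE)
  # raising only the proliferation genes raises the score (w_P > 0)
  hi <- x + c(0, 0, 1, 1)
  expect_gt(rorScore(hi, model)$ror_p, res$ror_p)
  expect_equal(rorScore(hi, model)$P, 1)
})

test_that("ROR-P stays in [0, 100] and classes are monotone in score", {
  model <- toy_model(offset = 50, scale = 400)
  set.seed(2)
  xs <- matrix(rnorm(4 * 50), 4, 50,
               dimnames = list(c("gA", "gB", "gC", "gD"), NULL))
  res <- rorScore(xs, model)
  expect_true(all(res$ror_p >= 0 & res$ror_p <= 100))
  ord <- order(res$ror_p)
  cls <- as.integer(res$ror_class)[ord]  # low < medium < high
  expect_true(all(diff(cls) >= 0))
})

test_that("synthetic basal tumours score higher ROR-P than luminal A", {
  coh <- small_cohort(n = 200, seed = 45)
  model <- trainCentroids(coh$panel, coh$truth$true_subtype,
                          onSmall = "pool")
  sc <- suppressWarnings(scoreCohort(coh$panel, model))
  st <- coh$truth$true_subtype
  expect_gt(mean(sc$ror_p[st == "Basal"]), mean(sc$ror_p[st == "LumA"]))
  # the low-risk class is dominated by LumA; the high-risk class by
  # LumB/Basal
  expect_gt(mean(st[sc$ror_class == "low"] == "LumA"), 0.9)
  expect_gt(mean(st[sc$ror_class == "high"] %in% c("Basal", "LumB")), 0.5)
})

test_that("the 21-gene score matches an independent hand computation", {
  model <- panelRSModel()  # offset 7, scale 20, shift 6.7, floors 8 / 6.5
  hk <- c("ACTB", "GAPDH", "GUSB", "RPLP0", "TFRC")
  inf <- c("GRB7", "ERBB2", "ESR1", "PGR", "BCL2", "MKI67", "BIRC5",
           "CCNB1", "MYBL2", "MMP11", "BAG1")
  x <- matrix(8, nrow = length(hk) + length(inf), ncol = 1,
              dimnames = list(c(hk, inf), "s1"))
  x[inf, 1] <- c(9.5, 8.2, 10.1, 9.4, 8.8, 7.9, 8.4, 8.1, 7.6, 8.9, 9.2)
  res <- oncotypeRS(x, model)
  # hand computation (reference mean is 8, offset 7 -> subtract 1):
  # her2 = (0.9*8.5 + 0.1*7.2) / 1.0            = 8.37 (>= floor 8)
  # er   = (0.8*9.1 + 1.2*8.4 + 1.0*7.8) / 3.0  = 8.3866667
  # prol = (6.9 + 7.4 + 7.1 + 6.6) / 4          = 7.0  (>= floor 6.5)
  # inv  = 7.9 ; bag1 = 8.2
  rsu <- 0.47 * 8.37 - 0.34 * (0.8 * 9.1 + 1.2 * 8.4 + 7.8) / 3 +
    1.04 * 7.0 + 0.10 * 7.9 - 0.07 * 8.2
  expect_equal(res$rs_unscaled, rsu, tolerance = 1e-9)
  expect_equal(res$rs, min(max(20 * (rsu - 6.7), 0), 100),
               tolerance = 1e-9)
})

test_that("neutral input gives the configured affine-map value", {
  model <- panelRSModel()
  genes <- c(unlist(lapply(model@groups, `[[`, "genes")),
             model@referenceGenes)
  x <- matrix(5, nrow = length(genes), ncol = 2,
              dimnames = list(genes, c("a", "b")))
  res <- oncotypeRS(x, model)
  # every normalised value is the offset 7; her2 floors to 8
  rsu <- 0.47 * 8 + 7 * (-0.34 + 1.04 + 0.10 - 0.07)
  expect_equal(res$rs_unscaled, rep(rsu, 2), tolerance = 1e-9)
  expect_equal(res$rs, rep(20 * (rsu - 6.7), 2), tolerance = 1e-9)
})

test_that("RS is monotone in proliferation and bounded", {
  coh <- small_cohort(n = 50, seed = 46)
  res <- oncotypeRS(coh$panel)
  expect_true(all(res$rs >= 0 & res$rs <= 100))
  logcpm <- SummarizedExperiment::assay(coh$panel, "logcpm")
  up <- logcpm
  pg <- intersect(c("MKI67", "BIRC5", "CCNB1", "MYBL2"), rownames(up))
  up[pg, ] <- up[pg, ] + 2
  expect_true(all(oncotypeRS(up)$rs >= res$rs))
})

test_that("RS errors on missing reference or informative genes", {
  coh <- small_cohort(n = 5, seed = 47)
  logcpm <- SummarizedExperiment::assay(coh$panel, "logcpm")
  expect_error(oncotypeRS(logcpm[rownames(logcpm) != "ACTB", ]), "ACTB")
  expect_error(oncotypeRS(logcpm[rownames(logcpm) != "GRB7", ]), "GRB7")
})

test_that("the full published RS model carries 16 informative genes", {
  full <- rsModel()
  genes <- unlist(lapply(full@groups, `[[`, "genes"))
  expect_equal(length(genes), 16L)
  expect_false(anyDuplicated(genes) > 0)
  expect_setequal(c("SCUBE2", "AURKA", "CTSV", "GSTM1", "CD68"),
                  setdiff(genes, unlist(lapply(panelRSModel()@groups,
                                               `[[`, "genes"))))
})

test_that("immune score rescales to [0, 100] with inclusive grouping", {
  coh <- small_cohort(n = 80, seed = 48)
  imm <- immuneScore(coh$panel)
  expect_equal(min(imm$immune_score), 0)
  expect_equal(max(imm$immune_score), 100)
  expect_equal(imm$immune_group[which.max(imm$immune_score)], "istrong")
  # a score exactly at the cutoff is istrong (>= is inclusive)
  at <- imm$immune_score[5]
  imm2 <- immuneScore(coh$panel, cutoff = at)
  expect_equal(imm2$immune_group[5], "istrong")
})

test_that("a degenerate cohort (min = max) is rejected", {
  pe <- normalizePanel(PanelExperiment(flat_counts(4), panel_roles()))
  expect_error(immuneScore(pe), "degenerate")
})

test_that("immune score recovers the latent immune level", {
  coh <- small_cohort(n = 150, seed = 49, immuneCoupling = 0.9)
  imm <- immuneScore(coh$panel)
  expect_gt(cor(imm$immune_score, coh$truth$true_immune_level), 0.8)
})

test_that("self-trained ROR weights give proliferation a positive sign", {
  coh <- small_cohort(n = 200, seed = 50)
  model <- trainCentroids(coh$panel, coh$truth$true_subtype,
                          onSmall = "pool")
  w <- suppressWarnings(trainRORWeights(coh$panel, model,
                                        coh$clinical$dfs_months,
                                        coh$clinical$dfs_event))
  expect_true(all(c("LumA", "LumB", "HER2E", "Basal", "P") %in% names(w)))
  expect_gt(w["P"], 0)
})
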
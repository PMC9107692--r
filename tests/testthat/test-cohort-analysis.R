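# independent kappa oracle: direct enumeration of observed and expected
# agreement from the raw label vectors
kappa_oracle <- function(a, b, levels) {
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in levels) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  (po - pe) / (1 - pe)
}

test_that("the Youden cutpoint separates separable data exactly", {
  cp <- youdenCutpoint(c(1, 2, 3, 8, 9, 10), c(1, 1, 1, 0, 0, 0))
  expect_equal(cp$youden, 1)
  expect_gt(cp$cutoff, 3)
  expect_lt(cp$cutoff, 8)
  cp2 <- youdenCutpoint(c(1, 2, 3, 8, 9, 10), c(0, 0, 0, 1, 1, 1))
  expect_equal(cp2$youden, 1)
  expect_equal(cp2$direction, ">=")
  expect_error(youdenCutpoint(1:5, rep(1, 5)), "both outcome classes")
})

test_that("the Youden index is near zero for uninformative markers", {
  set.seed(71)
  vals <- rnorm(200)
  out <- rbinom(200, 1, 0.5)
  cp <- youdenCutpoint(vals, out)
  expect_lt(cp$youden, 0.3)
})

test_that("the Youden cutpoint agrees with the pROC reference", {
  set.seed(72)
  vals <- c(rnorm(60, 1), rnorm(60))
  out <- rep(c(1, 0), each = 60)
  cp <- youdenCutpoint(vals, out, direction = ">=")
  roc <- pROC::roc(out, vals, direction = "<", quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(cp$cutoff, best$threshold[1], tolerance = 1e-9)
  expect_equal(cp$youden,
               best$sensitivity[1] + best$specificity[1] - 1,
               tolerance = 1e-9)
})

test_that("Cohen's kappa handles agreement, independence and degeneracy", {
  x <- c("a", "b", "c", "a", "b")
  expect_equal(cohensKappa(x, x)$kappa, 1)
  # balanced independent 2x2 table (25,25 / 25,25)
  a <- rep(c("x", "x", "y", "y"), each = 25)
  b <- rep(c("x", "y", "x", "y"), each = 25)
  res <- cohensKappa(a, b)
  expect_equal(res$kappa, 0)
  expect_equal(res$observed_agreement, 0.5)
  expect_equal(sum(res$crosstab), 100)
  # both raters constant: kappa undefined, flagged
  deg <- cohensKappa(rep("x", 5), rep("x", 5))
  expect_true(deg$undefined)
  expect_true(is.na(deg$kappa))
  expect_error(cohensKappa(1:3, 1:4), "length")
})

test_that("kappa equals the enumeration oracle on random 3-class data", {
  set.seed(73)
  for (i in 1:10) {
    a <- sample(c("p", "q", "r"), 30, replace = TRUE)
    b <- sample(c("p", "q", "r"), 30, replace = TRUE)
    expect_equal(cohensKappa(a, b)$kappa,
                 kappa_oracle(a, b, c("p", "q", "r")), tolerance = 1e-12)
  }
})

test_that("KM without censoring is the empirical survivor function", {
  km <- kmLogrank(c(3, 1, 4, 2), rep(1, 4))
  expect_equal(km$curves[[1]]$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$curves[[1]]$time, 1:4)
})

test_that("log-rank is zero for identical groups", {
  t <- c(1, 3, 5, 7, 9)
  e <- c(1, 1, 0, 1, 1)
  km <- kmLogrank(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(km$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(km$df, 1L)
})

test_that("log-rank matches a hand risk-table computation on n = 8", {
  times <- c(1, 2, 3, 4, 5, 6, 7, 8)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b", "a", "b")
  # independent oracle: aggregated risk-set O - E and hypergeometric V at
  # each distinct event time
  O <- E <- V <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    n1 <- sum(at_risk & group == "a")
    n <- sum(at_risk)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & group == "a")
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle <- (O - E)^2 / V
  km <- kmLogrank(times, events, group)
  expect_equal(km$logrank_chisq, oracle, tolerance = 1e-9)
})

test_that("all-censored data flags the log-rank as undefined", {
  expect_warning(km <- kmLogrank(c(1, 2, 3, 4), rep(0, 4),
                                 c("a", "a", "b", "b")),
                 "censored")
  expect_true(km$all_censored)
  expect_true(is.na(km$logrank_chisq))
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(74)
  ps <- replicate(500, {
    t <- rexp(60, 0.1)
    e <- rbinom(60, 1, 0.8)
    g <- rep(c("a", "b"), each = 30)
    kmLogrank(t, e, g)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Cox recovers a null and a true effect", {
  set.seed(75)
  x <- rbinom(500, 1, 0.5)
  t <- rexp(500, 0.1)
  res <- coxAnalysis(data.frame(x = x), t, rep(1, 500), "x")
  expect_lt(abs(log(res$univariate$hr)), 2 * (log(res$univariate$hi) -
                                              log(res$univariate$hr)) / 1.96)
  expect_false(res$univariate$unstable)

  # mean log-HR over replicates at n = 2000 is within 0.05 of log(2)
  set.seed(76)
  est <- replicate(20, {
    x <- rbinom(2000, 1, 0.5)
    t <- rexp(2000, 0.05 * exp(log(2) * x))
    log(coxAnalysis(data.frame(x = x), t, rep(1, 2000), "x")$univariate$hr)
  })
  expect_lt(abs(mean(est) - log(2)), 0.05)
})

test_that("Cox CI covers an injected size effect in >= 90% of seeds", {
  hz <- c(LumB = 0, HER2E = 0, Basal = 0, immune = 0,
          size_gt1cm = log(3))
  cover <- vapply(1:100, function(s) {
    coh <- generateCohort(cohortSpec(nPatients = 150, hazardLogHR = hz,
                                     censoringRate = 0.2,
                                     seed = 6000 + s))
    cl <- coh$clinical
    res <- coxAnalysis(data.frame(size = cl$tumor_size_cm > 1),
                       cl$dfs_months, cl$dfs_event, "size")
    res$univariate$lo <= 3 && 3 <= res$univariate$hi
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("monotone likelihood is flagged, not fatal", {
  # one stratum with no events at all: the partial likelihood is monotone
  x <- rep(c(0, 1), each = 25)
  t <- c(rexp(25, 0.5), rep(10, 25))
  e <- c(rep(1, 25), rep(0, 25))
  res <- coxAnalysis(data.frame(x = x), t, e, "x")
  expect_true(res$univariate$unstable)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  # hand step-up: sorted p * m / rank, cumulative minimum from the top
  set.seed(77)
  p <- runif(9)
  m <- length(p)
  o <- order(p)
  hand <- numeric(m)
  hand[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(fdrAdjust(p), pmin(hand, 1))
  # families adjust independently
  fam <- rep(c("u", "v"), c(4, 5))
  expect_equal(fdrAdjust(p, fam)[fam == "u"], fdrAdjust(p[fam == "u"]))
  expect_error(fdrAdjust(1.2), "out of")
})
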
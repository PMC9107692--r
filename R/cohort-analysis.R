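#' Youden-optimal ROC cutpoint
#'
#' Scans the midpoints of sorted unique values and returns the threshold
#' maximising Youden's J = sensitivity + specificity - 1. The direction of
#' the decision rule (`">="`: events have high values; `"<"`: events have
#' low values) can be fixed or chosen automatically as the direction with
#' the larger maximum J. Ties on J are broken towards the smallest
#' threshold.
#'
#' @param values per-patient scalar marker.
#' @param outcome binary event indicator (logical or 0/1); both classes
#'   must be present.
#' @param direction `"auto"` (default), `">="` or `"<"`.
#' @return list with `cutoff`, `youden`, `direction`, and `roc` (data.frame
#'   of threshold, sensitivity, specificity, J for the chosen direction).
#' @examples
#' youdenCutpoint(c(1, 2, 3, 8, 9, 10), c(1, 1, 1, 0, 0, 0))$cutoff
#' @export
youdenCutpoint <- function(values, outcome, direction = c("auto", ">=", "<")) {
  direction <- match.arg(direction)
  outcome <- as.integer(as.logical(outcome))
  if (length(values) != length(outcome)) stop("length mismatch")
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")
  u <- sort(unique(values))
  thr <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else u
  scan <- function(dir) {
    sens <- spec <- numeric(length(thr))
    for (i in seq_along(thr)) {
      pos <- if (dir == ">=") values >= thr[i] else values < thr[i]
      sens[i] <- sum(pos & outcome == 1L) / sum(outcome == 1L)
      spec[i] <- sum(!pos & outcome == 0L) / sum(outcome == 0L)
    }
    data.frame(threshold = thr, sensitivity = sens, specificity = spec,
               J = sens + spec - 1)
  }
  pick <- function(tab) tab[which.max(tab$J), , drop = FALSE]  # smallest thr
  if (direction == "auto") {
    t_ge <- scan(">="); t_lt <- scan("<")
    if (max(t_ge$J) >= max(t_lt$J)) {
      direction <- ">="; tab <- t_ge
    } else {
      direction <- "<"; tab <- t_lt
    }
  } else tab <- scan(direction)
  best <- pick(tab)
  list(cutoff = best$threshold, youden = best$J, direction = direction,
       roc = tab)
}

#' Cohen's kappa and cross-tabulation
#'
#' Unweighted chance-corrected agreement between two categorical label
#' vectors over a shared category set: kappa = (p_o - p_e) / (1 - p_e),
#' with expected agreement p_e from the marginal products.
#'
#' @param a,b equal-length label vectors (factors or characters).
#' @param levels optional shared category set; defaults to the union of
#'   observed labels.
#' @return list of class `"agreement_result"` with `crosstab`,
#'   `observed_agreement`, `kappa`, `n` and `undefined` (TRUE when both
#'   raters are constant, p_e = 1, kappa NA).
#' @examples
#' cohensKappa(c("x", "y", "x"), c("x", "y", "y"))$kappa
#' @export
cohensKappa <- function(a, b, levels = NULL) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (is.null(levels)) levels <- sort(unique(c(as.character(a),
                                               as.character(b))))
  fa <- factor(as.character(a), levels = levels)
  fb <- factor(as.character(b), levels = levels)
  tab <- table(fa, fb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  undefined <- abs(1 - pe) < .Machine$double.eps^0.5
  kappa <- if (undefined) NA_real_ else (po - pe) / (1 - pe)
  structure(list(crosstab = tab, observed_agreement = po, kappa = kappa,
                 n = n, undefined = undefined),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement over n = %d: observed %.3f, kappa %.3f%s\n",
              x$n, x$observed_agreement, x$kappa,
              if (x$undefined) " (undefined: both raters constant)" else ""))
  print(x$crosstab)
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group and, for two or more groups,
#' the log-rank chi-square with ties handled by the standard
#' aggregated-risk-set variance (via the survival package).
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups group label per observation (a single group gives KM
#'   only).
#' @return list of class `"km_result"`: `curves` (per-group data.frame of
#'   time, n_risk, n_event, survival), `logrank_chisq`, `df`, `p`, and
#'   `all_censored` flag (log-rank undefined when no events anywhere).
#' @export
kmLogrank <- function(times, events, groups = rep("all", length(times))) {
  if (any(times < 0)) stop("negative follow-up time")
  groups <- factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) factor(rep(levels(groups)[1],
                                               length(sm$time)))
            else sm$strata
  curves <- split(data.frame(time = sm$time, n_risk = sm$n.risk,
                             n_event = sm$n.event, survival = sm$surv),
                  strata)
  names(curves) <- sub("^groups=", "", names(curves))
  out <- list(curves = curves, logrank_chisq = NA_real_, df = NA_integer_,
              p = NA_real_, all_censored = sum(events) == 0)
  if (nlevels(groups) >= 2L) {
    if (out$all_censored) {
      warning("all observations censored: log-rank undefined")
    } else {
      sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
      out$logrank_chisq <- unname(sd$chisq)
      out$df <- length(sd$n) - 1L
      out$p <- stats::pchisq(sd$chisq, out$df, lower.tail = FALSE)
    }
  }
  class(out) <- "km_result"
  out
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier over", length(x$curves), "group(s)")
  if (!is.na(x$logrank_chisq))
    cat(sprintf("; log-rank chi-square %.3f (df %d), p = %.4g",
                x$logrank_chisq, x$df, x$p))
  cat("\n")
  invisible(x)
}

#' Univariate and multivariate Cox regression over a factor menu
#'
#' Fits one Cox proportional-hazards model per listed factor (univariate
#' family) and one joint model over the multivariate set; reports hazard
#' ratios, Wald 95% confidence intervals and p-values, flags unstable
#' (monotone-likelihood) estimates instead of failing, and
#' Benjamini-Hochberg-adjusts the univariate p-values as one family.
#' Categorical factors use their first level as the reference.
#'
#' @param data data.frame of covariates.
#' @param times,events survival outcome.
#' @param univariate character vector of covariate names to fit one by
#'   one.
#' @param multivariate character vector for the joint model (default: same
#'   as `univariate`, dropping constant covariates with a note).
#' @return list of class `"cox_result"` with data.frames `univariate`
#'   (term, hr, lo, hi, p, fdr_p, unstable) and `multivariate`.
#' @export
coxAnalysis <- function(data, times, events, univariate,
                        multivariate = univariate) {
  miss <- setdiff(union(univariate, multivariate), names(data))
  if (length(miss))
    stop("covariate(s) not in data: ", paste(miss, collapse = ", "))
  y <- survival::Surv(times, events)
  tidy_fit <- function(fit) {
    s <- summary(fit)
    co <- s$coefficients
    data.frame(term = rownames(co), hr = co[, "exp(coef)"],
               lo = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
               hi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
               p = co[, "Pr(>|z|)"],
               unstable = co[, "se(coef)"] > 50 | abs(co[, "coef"]) > 15,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  fit_safe <- function(vars) {
    f <- stats::reformulate(vars, response = "y")
    fit <- tryCatch(
      suppressWarnings(survival::coxph(f, data = data,
                                       model = TRUE)),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(term = vars, hr = NA_real_, lo = NA_real_,
                        hi = NA_real_, p = NA_real_, unstable = TRUE,
                        stringsAsFactors = FALSE))
    tidy_fit(fit)
  }
  uni <- do.call(rbind, lapply(univariate, function(v) {
    res <- fit_safe(v)
    res$factor <- v
    res
  }))
  uni$fdr_p <- fdrAdjust(uni$p)
  multivariate <- multivariate[vapply(multivariate, function(v)
    length(unique(data[[v]])) > 1L, logical(1))]
  multi <- if (length(multivariate)) fit_safe(multivariate) else NULL
  if (any(uni$unstable, na.rm = TRUE))
    message("monotone-likelihood / unstable estimate flagged for: ",
            paste(unique(uni$factor[uni$unstable]), collapse = ", "))
  structure(list(univariate = uni, multivariate = multi),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Univariate Cox fits:\n")
  print(x$univariate[, c("factor", "term", "hr", "lo", "hi", "p", "fdr_p")],
        digits = 3)
  if (!is.null(x$multivariate)) {
    cat("Multivariate model:\n")
    print(x$multivariate[, c("term", "hr", "lo", "hi", "p")], digits = 3)
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up false-discovery-rate adjustment, applied separately within each
#' family of tests when family labels are given.
#'
#' @param p p-values in \[0, 1\] (NA passed through).
#' @param family optional family label per p-value.
#' @return adjusted p-values in the input order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdrAdjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values out of [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  if (length(family) != length(p)) stop("family labels length mismatch")
  out <- p
  for (f in unique(family)) {
    idx <- family == f
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}
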
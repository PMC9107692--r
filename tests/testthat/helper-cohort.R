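# shared fixtures built in code

# a small normalised cohort with ground truth, memoised per test file run
small_cohort <- local({
  cache <- new.env()
  function(n = 60, sep = 3, seed = 101, proportions = NULL, ...) {
    key <- paste(n, sep, seed, paste(proportions, collapse = ","), ...)
    if (is.null(cache[[key]])) {
      args <- list(nPatients = n, expressionSeparation = sep, seed = seed,
                   ...)
      if (!is.null(proportions)) args$subtypeProportions <- proportions
      coh <- generateCohort(do.call(cohortSpec, args))
      coh$panel <- normalizePanel(qcFilterSamples(coh$panel))
      cache[[key]] <- coh
    }
    cache[[key]]
  }
})

# counts matrix over the default panel with every gene nonzero
flat_counts <- function(nsamples = 3, value = 50) {
  pan <- defaultGenePanel()
  matrix(value, nrow = nrow(pan), ncol = nsamples,
         dimnames = list(pan$gene, sprintf("S%02d", seq_len(nsamples))))
}

panel_roles <- function() {
  pan <- defaultGenePanel()
  stats::setNames(pan$role, pan$gene)
}

# one ER+/HER2- patient record with overridable fields
record <- function(...) {
  base <- list(id = "P1", er_pct = 50, pr_pct = 80, ki67_pct = 20,
               ck56_pos = FALSE, egfr_pos = FALSE, ck14_pos = FALSE,
               tils_pct = 5)
  args <- list(...)
  base[names(args)] <- args
  as.data.frame(base, stringsAsFactors = FALSE)
}
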
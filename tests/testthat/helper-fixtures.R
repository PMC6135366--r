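# Shared fixtures: parameter-table variants and small designs built in
# code (no stored data).

base_params <- default_parameters()

# Return the bundled table with selected fields overridden. `edits` is a
# named list of replacement values addressed by path, e.g.
# list(c("pregnancy", "symptom_prob_per_cycle") = 1) is expressed as
# params_with(pregnancy = list(symptom_prob_per_cycle = 1)).
params_with <- function(...) {
  p <- base_params
  edits <- list(...)
  for (block in names(edits)) {
    for (field in names(edits[[block]])) {
      p[[block]][[field]] <- edits[[block]][[field]]
    }
  }
  p
}

# A table whose age bands carry specified prevalences for every band.
params_with_prevalence <- function(hysterectomy = NULL, menopause = NULL,
                                   infertile = NULL) {
  p <- base_params
  if (!is.null(hysterectomy)) p$age_bands$hysterectomy[] <- hysterectomy
  if (!is.null(menopause)) p$age_bands$menopause[] <- menopause
  if (!is.null(infertile)) p$age_bands$infertile[] <- infertile
  p
}

young_uniform <- list(type = "uniform", min = 25, max = 34)
older_uniform <- list(type = "uniform", min = 40, max = 49)

small_design <- function(n = 2000, ages = young_uniform, ...) {
  trial_design(n, ages, ...)
}

binom_bounds99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}
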
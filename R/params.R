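#' Load the bundled default parameter table
#'
#' The bundled table holds every epidemiologic and biologic input of the
#' model: age-banded prevalences of hysterectomy, menopause and
#' infertility; age-banded fecundability (per-cycle conception probability
#' absent contraception); typical-use contraceptive failure rates and the
#' population method mix; menstrual-cycle and luteal-phase parameters;
#' pregnancy-fate probabilities (very early loss, clinical miscarriage)
#' and the implantation window; hCG kinetic parameters (initial level,
#' doubling time, peak, post-loss clearance, urine:serum ratio); baseline
#' (non-pregnant) hCG including pituitary hCG around menopause; and the
#' per-cycle probability of recognizing a pregnancy by symptoms without
#' testing. Provenance for every value is documented in the YAML source
#' (`system.file("extdata", "parameters.yaml", package = "pregsim")`).
#'
#' @return A validated object of class `preg_params`.
#' @seealso [load_parameters()] to read a customized table.
#' @export
#' @examples
#' p <- default_parameters()
#' p$age_bands
default_parameters <- function() {
  load_parameters(system.file("extdata", "parameters.yaml",
                              package = "pregsim", mustWork = TRUE))
}

#' Load a parameter table from a YAML file
#'
#' Reads and validates a parameter table with the same structure as the
#' bundled default (see [default_parameters()]).
#'
#' @param path Path to a YAML parameter table.
#' @return A validated object of class `preg_params`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter table not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  params <- structure(list(
    version    = as.character(raw$version %||% "unversioned"),
    age_bands  = do.call(rbind, lapply(raw$age_bands, function(b) {
      data.frame(lower = b$lower, upper = b$upper,
                 hysterectomy = b$hysterectomy, menopause = b$menopause,
                 infertile = b$infertile, fecundability = b$fecundability,
                 mix = b$mix, stringsAsFactors = FALSE)
    })),
    methods    = do.call(rbind, lapply(raw$methods, function(m) {
      data.frame(name = m$name,
                 annual_typical_failure = m$annual_typical_failure,
                 effectiveness_class = m$effectiveness_class,
                 stringsAsFactors = FALSE)
    })),
    method_mix = lapply(raw$method_mix, function(mix) unlist(mix)),
    cycle      = raw$cycle,
    pregnancy  = raw$pregnancy,
    hcg        = raw$hcg,
    baseline_hcg = raw$baseline_hcg,
    simulation = raw$simulation
  ), class = "preg_params")
  validate_parameters(params)
  params
}

#' Validate a parameter table
#'
#' Checks the structural invariants of a `preg_params` object: all
#' probabilities in \[0, 1\]; age bands partition the configured range with
#' no gaps or overlaps; method-mix weights sum to 1 and name known
#' methods; highly effective methods have annual typical-use failure at or
#' below 1%; luteal phase shorter than the cycle; positive hCG kinetic
#' parameters; baseline ceiling below 20 IU/L (so urine tests at 20-25
#' IU/L can never be baseline-driven false positives).
#'
#' @param params A `preg_params` object.
#' @return `params`, invisibly; stops with an informative error otherwise.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "preg_params"))
  ab <- params$age_bands
  prob_cols <- c("hysterectomy", "menopause", "infertile", "fecundability")
  for (col in prob_cols) {
    bad <- ab[[col]] < 0 | ab[[col]] > 1
    if (any(bad)) {
      stop("age_bands$", col, " outside [0,1] in band starting at age ",
           ab$lower[which(bad)[1]], call. = FALSE)
    }
  }
  if (any(diff(ab$lower) <= 0)) {
    stop("age bands must be in increasing order", call. = FALSE)
  }
  if (any(ab$lower[-1] != ab$upper[-nrow(ab)] + 1)) {
    stop("age bands must partition the age range with no gaps or overlaps",
         call. = FALSE)
  }
  m <- params$methods
  if (any(m$annual_typical_failure < 0 | m$annual_typical_failure > 1)) {
    stop("annual_typical_failure outside [0,1]", call. = FALSE)
  }
  he <- m$effectiveness_class == "highly_effective"
  if (any(m$annual_typical_failure[he] > 0.01)) {
    stop("highly_effective methods must have annual typical-use failure <= 0.01",
         call. = FALSE)
  }
  if (!all(ab$mix %in% names(params$method_mix))) {
    stop("age band references an undefined method mix", call. = FALSE)
  }
  for (g in names(params$method_mix)) {
    mix <- params$method_mix[[g]]
    if (!all(names(mix) %in% m$name)) {
      stop("method mix '", g, "' names an unknown method", call. = FALSE)
    }
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      stop("method mix '", g, "' must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  cy <- params$cycle
  if (cy$luteal_days >= cy$length_median_days) {
    stop("luteal phase must be shorter than the cycle", call. = FALSE)
  }
  pg <- params$pregnancy
  for (col in c("early_loss_prob", "clinical_miscarriage_prob",
                "symptom_prob_per_cycle")) {
    if (pg[[col]] < 0 || pg[[col]] > 1) {
      stop("pregnancy$", col, " outside [0,1]", call. = FALSE)
    }
  }
  if (pg$early_loss_prob + pg$clinical_miscarriage_prob > 1) {
    stop("pregnancy outcome probabilities exceed 1", call. = FALSE)
  }
  hc <- params$hcg
  if (hc$initial_median_iu_l <= 0 || hc$doubling_median_days <= 0) {
    stop("hCG initial level and doubling time must be positive", call. = FALSE)
  }
  if (params$baseline_hcg$ceiling_iu_l >= 20) {
    stop("baseline hCG ceiling must stay below 20 IU/L", call. = FALSE)
  }
  invisible(params)
}

#' Write a parameter table to YAML
#'
#' Serializes a `preg_params` object so a round trip through
#' [load_parameters()] recovers an equivalent table (comments from the
#' bundled file are not preserved).
#'
#' @param params A `preg_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "preg_params"))
  raw <- list(
    version = params$version,
    age_bands = lapply(seq_len(nrow(params$age_bands)), function(i) {
      as.list(params$age_bands[i, , drop = FALSE])
    }),
    methods = lapply(seq_len(nrow(params$methods)), function(i) {
      as.list(params$methods[i, , drop = FALSE])
    }),
    method_mix = lapply(params$method_mix, as.list),
    cycle = params$cycle,
    pregnancy = params$pregnancy,
    hcg = params$hcg,
    baseline_hcg = params$baseline_hcg,
    simulation = params$simulation
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

# Band index for a vector of ages; errors name the uncovered age.
age_band_index <- function(age, params) {
  ab <- params$age_bands
  idx <- findInterval(age, c(ab$lower, ab$upper[nrow(ab)] + 1))
  if (any(idx == 0 | idx > nrow(ab))) {
    bad <- age[idx == 0 | idx > nrow(ab)][1]
    stop("age ", bad, " outside parameter coverage (bands span ",
         ab$lower[1], "-", ab$upper[nrow(ab)], ")", call. = FALSE)
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.preg_params <- function(x, ...) {
  cat("<preg_params> version", x$version, "\n")
  cat(" ", nrow(x$age_bands), "age bands,", nrow(x$methods), "methods,",
      length(x$method_mix), "method mixes\n")
  cat("  early loss", x$pregnancy$early_loss_prob,
      "| hCG doubling", x$hcg$doubling_median_days, "d",
      "| urine:serum", x$hcg$urine_ratio_median, "\n")
  invisible(x)
}
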
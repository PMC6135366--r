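#' Define an hCG assay specification
#'
#' An assay is characterized by its matrix (urine or serum), mode
#' (qualitative or quantitative), analytic sensitivity (lowest measurable
#' concentration), positive cutoff, optional indeterminate band
#' `[low, high)` lying between the analytic sensitivity and the cutoff,
#' and a measurement coefficient of variation. "Sensitivity" here is the
#' concentration at which the assay deterministically calls positive
#' (after measurement noise); the 50-percent-vs-100-percent ambiguity in
#' how manufacturers quote sensitivity is represented by the `cv` knob.
#'
#' @param name Label for the assay.
#' @param matrix `"urine"` or `"serum"`.
#' @param mode `"qualitative"` or `"quantitative"`.
#' @param analytic_sensitivity Lowest measurable concentration, IU/L.
#' @param positive_cutoff Concentration at or above which the call is
#'   positive, IU/L.
#' @param indeterminate_band Length-2 numeric `[low, high)` or `NULL`.
#' @param cv Measurement coefficient of variation (>= 0; 0 = noise-free).
#' @return An object of class `assay_spec`.
#' @export
#' @examples
#' assay_spec("urine OTC", "urine", "qualitative", 20, 25)
assay_spec <- function(name, matrix = c("urine", "serum"),
                       mode = c("qualitative", "quantitative"),
                       analytic_sensitivity, positive_cutoff,
                       indeterminate_band = NULL, cv = 0) {
  matrix <- match.arg(matrix)
  mode <- match.arg(mode)
  stopifnot(analytic_sensitivity > 0, positive_cutoff > 0, cv >= 0)
  if (analytic_sensitivity > positive_cutoff) {
    stop("analytic_sensitivity must not exceed positive_cutoff", call. = FALSE)
  }
  if (!is.null(indeterminate_band)) {
    stopifnot(length(indeterminate_band) == 2)
    if (indeterminate_band[1] < analytic_sensitivity ||
        indeterminate_band[2] > positive_cutoff ||
        indeterminate_band[1] >= indeterminate_band[2]) {
      stop("indeterminate_band must lie within [analytic_sensitivity, positive_cutoff)",
           call. = FALSE)
    }
  }
  structure(list(name = name, matrix = matrix, mode = mode,
                 analytic_sensitivity = analytic_sensitivity,
                 positive_cutoff = positive_cutoff,
                 indeterminate_band = indeterminate_band, cv = cv),
            class = "assay_spec")
}

#' Bundled default assay specifications
#'
#' Three assays spanning the common choices: a qualitative urine
#' (home/point-of-care) test at 25 IU/L (the conservative end of the
#' typical 20-25 IU/L range), a qualitative serum lab test at 10 IU/L,
#' and a quantitative serum test with analytic sensitivity 2 IU/L,
#' positive cutoff 5 IU/L and indeterminate band \[2, 5).
#'
#' @return Named list of `assay_spec` objects: `urine_qualitative`,
#'   `serum_qualitative`, `serum_quantitative`.
#' @export
default_assays <- function() {
  list(
    urine_qualitative = assay_spec("urine qualitative 25", "urine",
                                   "qualitative", 20, 25),
    serum_qualitative = assay_spec("serum qualitative 10", "serum",
                                   "qualitative", 10, 10),
    serum_quantitative = assay_spec("serum quantitative 5", "serum",
                                    "quantitative", 2, 5,
                                    indeterminate_band = c(2, 5))
  )
}

#' Apply measurement noise to a true concentration
#'
#' Multiplicative, mean-preserving lognormal noise with the assay's
#' coefficient of variation; `cv = 0` returns the input exactly.
#'
#' @param true_concentration Non-negative concentration(s), IU/L.
#' @param spec An `assay_spec`.
#' @return Measured concentration(s), IU/L.
#' @export
measure <- function(true_concentration, spec) {
  stopifnot(all(true_concentration >= 0))
  if (spec$cv == 0) return(true_concentration)
  sdlog <- sqrt(log(1 + spec$cv^2))
  true_concentration * stats::rlnorm(length(true_concentration),
                                     meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Classify a measured concentration into a test call
#'
#' Deterministic: at or above the positive cutoff the call is positive;
#' within the indeterminate band (when the assay defines one) it is
#' indeterminate; otherwise negative.
#'
#' @param measured Measured concentration(s), IU/L (non-negative).
#' @param spec An `assay_spec`.
#' @return Character vector: `"negative"`, `"indeterminate"`, `"positive"`.
#' @export
classify_call <- function(measured, spec) {
  stopifnot(all(measured >= 0))
  call <- ifelse(measured >= spec$positive_cutoff, "positive", "negative")
  if (!is.null(spec$indeterminate_band)) {
    b <- spec$indeterminate_band
    call[measured >= b[1] & measured < b[2] &
           measured < spec$positive_cutoff] <- "indeterminate"
  }
  call
}

# Canonical category vocabulary for test events.
outcome_categories <- function() {
  c("TP", "TN", "FN_preimplantation", "FN_postimplantation",
    "FP_classic", "FP_biological", "IND")
}

#' Adjudicate a test call against pregnancy truth
#'
#' Maps every (call, truth status) pair to exactly one category. The
#' taxonomy follows the field's convention for early-pregnancy testing in
#' trials: a positive on a conception destined for (or shortly after)
#' very early loss is a "biological" false positive; a positive driven by
#' non-pregnant hCG (pituitary hCG around menopause) is a "classic" false
#' positive; negatives during the pre-implantation window are false
#' negatives of the unavoidable kind (no assay can detect before
#' implantation); negatives on an implanted pregnancy destined for early
#' loss are counted as true negatives (the mirror image of the biological
#' false positive convention); indeterminate calls are tallied as IND
#' regardless of truth.
#'
#' @param call `"negative"`, `"indeterminate"` or `"positive"` (vector).
#' @param truth_status `"not_pregnant"`, `"preimplantation"`,
#'   `"implanted_destined_early_loss"` or `"viable_pregnancy"` (vector).
#' @return Category vector (see `outcome_categories`): one of `TP`, `TN`,
#'   `FN_preimplantation`, `FN_postimplantation`, `FP_classic`,
#'   `FP_biological`, `IND`.
#' @export
adjudicate <- function(call, truth_status) {
  valid_calls <- c("negative", "indeterminate", "positive")
  valid_truth <- c("not_pregnant", "preimplantation",
                   "implanted_destined_early_loss", "viable_pregnancy")
  if (!all(call %in% valid_calls) || !all(truth_status %in% valid_truth)) {
    stop("unmapped (call, truth) pair", call. = FALSE)
  }
  out <- character(length(call))
  ind <- call == "indeterminate"
  pos <- call == "positive"
  neg <- call == "negative"
  out[ind] <- "IND"
  out[pos & truth_status == "viable_pregnancy"] <- "TP"
  out[pos & truth_status == "implanted_destined_early_loss"] <- "FP_biological"
  out[pos & truth_status %in% c("not_pregnant", "preimplantation")] <- "FP_classic"
  out[neg & truth_status == "not_pregnant"] <- "TN"
  out[neg & truth_status == "preimplantation"] <- "FN_preimplantation"
  out[neg & truth_status == "implanted_destined_early_loss"] <- "TN"
  out[neg & truth_status == "viable_pregnancy"] <- "FN_postimplantation"
  if (any(out == "")) stop("unmapped (call, truth) pair", call. = FALSE)
  out
}

# Truth status of an episode (or none) at a test day, vectorized.
# Pre-implantation conceptions are "preimplantation"; implanted episodes
# destined for very early loss stay "implanted_destined_early_loss" until
# their residual hCG has cleared (so shortly-post-loss positives read as
# biological false positives); pregnancies lost clinically are viable
# until the loss, then enter the same residual phase; beyond clearance
# the subject is not pregnant.
truth_at_day <- function(day, conception_day, implantation_day, outcome,
                         loss_day, params) {
  lag <- params$hcg$clearance_lag_days
  status <- rep("not_pregnant", length(day))
  has <- !is.na(conception_day)
  pre <- has & day >= conception_day & day < implantation_day
  resolved <- !is.na(loss_day) & day > loss_day + lag
  implanted <- has & day >= implantation_day & !resolved
  el_like <- implanted & (outcome == "early_loss" |
                            (!is.na(loss_day) & day > loss_day))
  viable <- implanted & !el_like
  status[pre] <- "preimplantation"
  status[el_like] <- "implanted_destined_early_loss"
  status[viable] <- "viable_pregnancy"
  status
}

#' @export
print.assay_spec <- function(x, ...) {
  band <- if (is.null(x$indeterminate_band)) "none" else
    paste0("[", x$indeterminate_band[1], ", ", x$indeterminate_band[2], ")")
  cat("<assay_spec>", x$name, "\n  ", x$matrix, x$mode,
      "| cutoff", x$positive_cutoff, "IU/L | sensitivity",
      x$analytic_sensitivity, "IU/L | indeterminate", band,
      "| cv", x$cv, "\n")
  invisible(x)
}
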
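#' Classify reproductive potential from age
#'
#' Draws each subject's reproductive status from the age band's
#' prevalences in a fixed precedence order: hysterectomy, then menopause,
#' then infertility/subfecundity, then female of reproductive potential
#' (FRP). The precedence makes the states mutually exclusive and the draw
#' reproducible for a given RNG state.
#'
#' @param age Numeric vector of ages in years (within the table's band
#'   coverage; ages at or beyond the menopause-certainty bound, 60 by
#'   default, are always classified `menopause`).
#' @param params A `preg_params` object.
#' @return Character vector with values `"FRP"`, `"hysterectomy"`,
#'   `"menopause"`, `"infertile"`.
#' @export
#' @examples
#' set.seed(1)
#' table(classify_reproductive_potential(rep(45, 1000), default_parameters()))
classify_reproductive_potential <- function(age, params) {
  idx <- age_band_index(age, params)
  ab <- params$age_bands
  n <- length(age)
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  status <- rep("FRP", n)
  hyst <- u1 < ab$hysterectomy[idx]
  meno <- !hyst & u2 < ab$menopause[idx]
  infert <- !hyst & !meno & u3 < ab$infertile[idx]
  status[infert] <- "infertile"
  status[meno] <- "menopause"
  status[hyst] <- "hysterectomy"
  status
}

#' Assign a contraceptive method under a scenario
#'
#' FRP subjects receive a method according to the contraception scenario:
#' `"none"` assigns no method; `"population_mix"` draws from the age
#' band's method mix; `"highly_effective_only"` draws from the band mix
#' restricted (and renormalized) to methods of class `highly_effective`.
#' Non-FRP subjects always receive `"none"` (their conception probability
#' is already zero).
#'
#' @param age Numeric vector of ages.
#' @param status Reproductive status vector (see
#'   [classify_reproductive_potential()]).
#' @param scenario One of `"none"`, `"population_mix"`,
#'   `"highly_effective_only"`.
#' @param params A `preg_params` object.
#' @return Character vector of method names.
#' @export
assign_contraception <- function(age, status,
                                 scenario = c("none", "population_mix",
                                              "highly_effective_only"),
                                 params) {
  scenario <- match.arg(scenario)
  idx <- age_band_index(age, params)
  n <- length(age)
  method <- rep("none", n)
  frp <- status == "FRP"
  if (scenario == "none" || !any(frp)) {
    return(method)
  }
  he_names <- params$methods$name[
    params$methods$effectiveness_class == "highly_effective"]
  mixes <- params$method_mix
  if (scenario == "highly_effective_only") {
    mixes <- lapply(mixes, function(mix) {
      mix <- mix[names(mix) %in% he_names]
      if (length(mix) == 0 || sum(mix) <= 0) {
        stop("no highly effective method has positive weight in the mix",
             call. = FALSE)
      }
      mix / sum(mix)
    })
  }
  for (g in names(mixes)) {
    sel <- frp & params$age_bands$mix[idx] == g
    if (any(sel)) {
      mix <- mixes[[g]]
      method[sel] <- sample(names(mix), sum(sel), replace = TRUE, prob = mix)
    }
  }
  method
}

#' Sample a menstrual-cycle profile
#'
#' Cycle length is lognormal (median and log-sd from the parameter
#' table); the luteal phase is fixed; the phase offset (day of the cycle
#' at study day 0, with day 0 = first day of menses) is uniform on
#' `[0, cycle_length)`.
#'
#' @param n Number of profiles to draw.
#' @param params A `preg_params` object.
#' @return A data frame with columns `cycle_length`, `luteal_length`,
#'   `phase_offset` (days).
#' @export
sample_cycle <- function(n, params) {
  cy <- params$cycle
  len <- stats::rlnorm(n, meanlog = log(cy$length_median_days),
                       sdlog = cy$length_sdlog)
  len <- pmax(len, cy$luteal_days + 7)  # guard: follicular phase >= 7 d
  data.frame(cycle_length = len,
             luteal_length = rep(cy$luteal_days, n),
             phase_offset = stats::runif(n) * len)
}

#' Generate a simulated trial cohort
#'
#' Produces `n` fully populated subjects: age (from the age
#' specification), reproductive status, contraceptive method,
#' menstrual-cycle profile, baseline (non-pregnant) serum hCG with its
#' source, and the subject-specific urine:serum hCG ratio. The draw is
#' bit-reproducible for a given `seed`.
#'
#' @param n Cohort size (>= 0).
#' @param age_spec Age distribution descriptor, a list with `type` one of
#'   `"uniform"` (fields `min`, `max`), `"point"` (field `age`), or
#'   `"bands"` (fields `ages`, `weights`).
#' @param scenario Contraception scenario (see [assign_contraception()]).
#' @param params A `preg_params` object.
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return A data frame of class `preg_cohort`, one row per subject.
#' @export
#' @examples
#' coh <- sample_cohort(5, list(type = "uniform", min = 25, max = 34),
#'                      "population_mix", default_parameters(), seed = 1)
#' coh
sample_cohort <- function(n, age_spec, scenario = "population_mix",
                          params = default_parameters(), seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  age <- sample_ages(n, age_spec)
  status <- classify_reproductive_potential(age, params)
  method <- assign_contraception(age, status, scenario, params)
  cyc <- sample_cycle(n, params)
  base <- baseline_level(status, params)
  ur <- sample_urine_ratio(n, params)
  m <- params$methods
  mi <- match(method, m$name)
  out <- data.frame(
    id = seq_len(n),
    age = age,
    reproductive_status = status,
    method = method,
    annual_typical_failure = m$annual_typical_failure[mi],
    effectiveness_class = m$effectiveness_class[mi],
    cycle_length = cyc$cycle_length,
    luteal_length = cyc$luteal_length,
    phase_offset = cyc$phase_offset,
    baseline_hcg = base$serum_baseline,
    baseline_source = base$source,
    urine_ratio = ur,
    stringsAsFactors = FALSE
  )
  class(out) <- c("preg_cohort", "data.frame")
  out
}

# Draw n ages from an age-spec descriptor.
sample_ages <- function(n, age_spec) {
  if (!is.list(age_spec) || is.null(age_spec$type)) {
    stop("age_spec must be a list with a 'type' field", call. = FALSE)
  }
  if (n == 0) return(numeric(0))
  switch(age_spec$type,
    uniform = {
      if (is.null(age_spec$min) || is.null(age_spec$max) ||
          age_spec$min > age_spec$max) {
        stop("uniform age_spec needs min <= max", call. = FALSE)
      }
      stats::runif(n, age_spec$min, age_spec$max)
    },
    point = {
      if (is.null(age_spec$age)) stop("point age_spec needs 'age'", call. = FALSE)
      rep(as.numeric(age_spec$age), n)
    },
    bands = {
      if (is.null(age_spec$ages) || is.null(age_spec$weights) ||
          length(age_spec$ages) != length(age_spec$weights)) {
        stop("bands age_spec needs matching 'ages' and 'weights'", call. = FALSE)
      }
      sample(as.numeric(age_spec$ages), n, replace = TRUE,
             prob = age_spec$weights)
    },
    stop("unknown age_spec type: ", age_spec$type, call. = FALSE)
  )
}

#' Export a cohort as CSV
#'
#' One row per subject; the column dictionary is the field list documented
#' in [sample_cohort()].
#'
#' @param cohort A `preg_cohort` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
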
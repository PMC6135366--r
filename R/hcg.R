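#' Baseline (non-pregnant) serum hCG
#'
#' Draws a fixed baseline serum hCG level for each subject. Menopausal
#' subjects draw from the pituitary-hCG distribution (lognormal, capped at
#' the configured ceiling below 20 IU/L, so a non-trivial fraction falls
#' in the 5-19 IU/L band that can trip a low serum cutoff); all other
#' subjects draw from a low-level distribution that almost surely stays
#' below 5 IU/L. The sub-20 ceiling guarantees urine tests at 20-25 IU/L
#' thresholds never produce baseline-driven false positives.
#'
#' @param status Character vector of reproductive statuses.
#' @param params A `preg_params` object.
#' @return A data frame with columns `serum_baseline` (IU/L) and `source`
#'   (`"none"` or `"pituitary"`).
#' @export
baseline_level <- function(status, params) {
  b <- params$baseline_hcg
  n <- length(status)
  meno <- status == "menopause"
  out <- stats::rlnorm(n, meanlog = log(b$frp_median_iu_l), sdlog = b$frp_sdlog)
  if (any(meno)) {
    out[meno] <- stats::rlnorm(sum(meno),
                               meanlog = log(b$pituitary_median_iu_l),
                               sdlog = b$pituitary_sdlog)
  }
  out <- pmin(out, b$ceiling_iu_l)
  data.frame(serum_baseline = out,
             source = ifelse(meno, "pituitary", "none"),
             stringsAsFactors = FALSE)
}

# Subject-specific urine:serum ratio, lognormal capped at the configured
# maximum (1 by default, so urine never exceeds serum).
sample_urine_ratio <- function(n, params) {
  h <- params$hcg
  pmin(stats::rlnorm(n, meanlog = log(h$urine_ratio_median),
                     sdlog = h$urine_ratio_sdlog),
       h$urine_ratio_max)
}

# Draw per-episode trajectory parameters (initial level at implantation
# and doubling time), vectorized.
sample_trajectory <- function(n, params) {
  h <- params$hcg
  data.frame(
    initial_level = stats::rlnorm(n, meanlog = log(h$initial_median_iu_l),
                                  sdlog = h$initial_sdlog),
    doubling_time = stats::rlnorm(n, meanlog = log(h$doubling_median_days),
                                  sdlog = h$doubling_sdlog)
  )
}

# Pregnancy contribution to serum hCG (IU/L), vectorized over episodes.
# Zero strictly before implantation; exponential rise with the episode's
# doubling time, capped at the peak level and frozen after the peak day;
# after a loss, exponential clearance (configured half-life) until the
# clearance lag has elapsed, then exactly zero.
hcg_contribution <- function(day, conception_day, implantation_day,
                             initial_level, doubling_time,
                             loss_day, params) {
  h <- params$hcg
  peak_abs <- conception_day + h$peak_day_post_conception
  grow_until <- pmin(day, peak_abs)
  if (!all(is.na(loss_day))) {
    grow_until <- pmin(grow_until, ifelse(is.na(loss_day), Inf, loss_day))
  }
  level <- ifelse(day < implantation_day, 0,
                  pmin(initial_level *
                         2 ^ ((grow_until - implantation_day) / doubling_time),
                       h$peak_level_iu_l))
  lost <- !is.na(loss_day) & day > loss_day
  if (any(lost)) {
    decay <- 2 ^ (-(day[lost] - loss_day[lost]) / h$clearance_half_life_days)
    lv <- level[lost] * decay
    lv[day[lost] > loss_day[lost] + h$clearance_lag_days] <- 0
    level[lost] <- lv
  }
  level
}

#' Serum hCG level for a subject on a study day
#'
#' Returns baseline plus, when an episode is supplied, the pregnancy
#' contribution: exactly zero strictly before the implantation day,
#' exponential growth with the episode's doubling time up to the peak,
#' and post-loss clearance. The pre-implantation zero encodes the 8-10
#' day window after conception during which every pregnancy test is
#' negative.
#'
#' @param subject One row of a `preg_cohort` data frame.
#' @param episode One row of an episode data frame (see
#'   [simulate_episodes()]), or `NULL` for a non-pregnant day.
#' @param day Study day (numeric vector).
#' @return Serum hCG in IU/L (vector along `day`).
#' @export
serum_level <- function(subject, episode = NULL, day) {
  base <- rep(subject$baseline_hcg, length(day))
  if (is.null(episode) || nrow(episode) == 0) return(base)
  params <- attr(episode, "params") %||% default_parameters()
  contrib <- hcg_contribution(day,
                              rep(episode$conception_day, length(day)),
                              rep(episode$implantation_day, length(day)),
                              rep(episode$initial_level, length(day)),
                              rep(episode$doubling_time, length(day)),
                              rep(episode$loss_day, length(day)),
                              params)
  base + contrib
}

#' Urine hCG level from a serum level
#'
#' Urine hCG is the subject-specific ratio times the serum level. With
#' the default ratio distribution (capped at 1) urine never exceeds
#' serum, which is why urine tests detect pregnancy slightly later than
#' serum tests at an equivalent threshold.
#'
#' @param serum Serum hCG, IU/L (non-negative).
#' @param urine_ratio Subject's urine:serum ratio.
#' @return Urine hCG, IU/L.
#' @export
urine_level <- function(serum, urine_ratio) {
  if (any(serum < 0)) stop("serum hCG must be non-negative", call. = FALSE)
  urine_ratio * serum
}

#' Export an hCG trajectory as a CSV time series
#'
#' @param subject One row of a `preg_cohort`.
#' @param episode One row of an episode data frame.
#' @param days Vector of study days to evaluate.
#' @param path Output CSV path.
#' @return The time-series data frame, invisibly.
#' @export
write_trajectory_csv <- function(subject, episode, days, path) {
  serum <- serum_level(subject, episode, days)
  df <- data.frame(day = days, serum = serum,
                   urine = urine_level(serum, subject$urine_ratio))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
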
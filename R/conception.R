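#' Per-cycle conception probability
#'
#' Composes age-specific fecundability with contraceptive effectiveness.
#' Annual typical-use failure is converted to a per-cycle breakthrough
#' probability by geometric compounding over the configured number of
#' cycles per year (13 by default): `1 - (1 - annual)^(1/cycles)`. The
#' per-cycle conception probability is then the age band's fecundability
#' times that breakthrough probability; the method `"none"` has
#' breakthrough probability 1, so it returns fecundability unchanged.
#'
#' @param age Numeric vector of ages.
#' @param method Character vector of method names (from the parameter
#'   table's method list).
#' @param params A `preg_params` object.
#' @return Per-cycle conception probability in \[0, 1\].
#' @export
#' @examples
#' p <- default_parameters()
#' per_cycle_conception_probability(28, "none", p)  # fecundability itself
#' per_cycle_conception_probability(28, "pill", p)
per_cycle_conception_probability <- function(age, method, params) {
  idx <- age_band_index(age, params)
  fec <- params$age_bands$fecundability[idx]
  mi <- match(method, params$methods$name)
  if (any(is.na(mi))) {
    stop("unknown contraceptive method: ",
         paste(unique(method[is.na(mi)]), collapse = ", "), call. = FALSE)
  }
  breakthrough <- per_cycle_failure(
    params$methods$annual_typical_failure[mi], params)
  breakthrough[params$methods$name[mi] == "none"] <- 1
  fec * breakthrough
}

# Annual typical-use failure -> per-cycle probability.
per_cycle_failure <- function(annual, params) {
  1 - (1 - annual) ^ (1 / params$cycle$cycles_per_year)
}

#' Simulate conception episodes for one subject
#'
#' Runs the conception process over `[0, duration]` study days: at each
#' ovulation (cycle day `cycle_length - luteal_length`), conception occurs
#' with the subject's per-cycle probability; a conception spawns a
#' pregnancy episode with an implantation delay drawn uniformly from the
#' configured 8-10 day window, an outcome drawn from the configured fate
#' probabilities (very early loss before the expected menses, clinical
#' miscarriage, or ongoing pregnancy), an hCG trajectory, and a symptom
#' recognition day for pregnancies that reach a missed menses. At most one
#' episode is active at a time; after a loss, menses restarts on the loss
#' day and cycling resumes. Non-FRP subjects return an empty episode set.
#'
#' @param subject One row of a `preg_cohort` data frame.
#' @param duration Study duration in days (>= 0).
#' @param params A `preg_params` object.
#' @return A data frame of episodes (possibly zero rows) with columns
#'   `subject_id`, `conception_day`, `implantation_day`, `outcome`,
#'   `loss_day`, `expected_menses_day`, `initial_level`, `doubling_time`,
#'   `symptom_day`.
#' @export
simulate_episodes <- function(subject, duration, params) {
  stopifnot(duration >= 0)
  simulate_cohort_episodes(subject, params, t_start = 0, t_end = duration)
}

#' Symptom-based pregnancy recognition day
#'
#' For pregnancies that reach a missed menses, recognition without testing
#' occurs at each successive missed-menses boundary (expected-menses day,
#' then every cycle length) with the configured per-cycle probability; the
#' first success is recorded. Episodes lost before the expected menses
#' (very early losses) are never symptom-detected.
#'
#' @param episode One row of an episode data frame.
#' @param cycle_length The subject's cycle length (days).
#' @param params A `preg_params` object.
#' @param from_day Earliest study day on which recognition can occur
#'   (boundaries before it are skipped; default 0).
#' @return The study day of recognition, or `NA` if none occurs.
#' @export
symptom_detection <- function(episode, cycle_length, params, from_day = 0) {
  draw_symptom_day(episode$conception_day, episode$loss_day,
                   episode$outcome, cycle_length, params, from_day)
}

# Vectorized symptom-day draw. Boundaries: conception + luteal + k * L.
draw_symptom_day <- function(conception_day, loss_day, outcome,
                             cycle_length, params, from_day = 0) {
  q <- params$pregnancy$symptom_prob_per_cycle
  n <- length(conception_day)
  day <- rep(NA_real_, n)
  viable <- outcome != "early_loss"
  if (!any(viable) || q <= 0) return(day)
  first <- conception_day + params$cycle$luteal_days
  k0 <- pmax(0, ceiling((from_day - first) / cycle_length))
  g <- stats::rgeom(n, q)  # failed boundaries before first success
  cand <- first + (k0 + g) * cycle_length
  ok <- viable & (is.na(loss_day) | cand < loss_day)
  day[ok] <- cand[ok]
  day
}

# Vectorized conception/episode engine over a cohort. Simulates from
# t_start (negative = pre-study burn-in) to t_end. Symptom recognition is
# only allowed from symptom_from (study day); the burn-in applies none.
simulate_cohort_episodes <- function(cohort, params, t_start, t_end,
                                     symptom_from = 0) {
  frp <- cohort$reproductive_status == "FRP"
  if (!any(frp) || t_end <= t_start) {
    return(empty_episodes())
  }
  sub <- cohort[frp, , drop = FALSE]
  n <- nrow(sub)
  p <- per_cycle_conception_probability(sub$age, sub$method, params)
  L <- sub$cycle_length
  luteal <- sub$luteal_length
  pg <- params$pregnancy
  # first ovulation at or after t_start given phase at day 0
  ov_phase <- L - luteal
  k <- ceiling((t_start - (ov_phase - sub$phase_offset)) / L)
  next_ov <- ov_phase - sub$phase_offset + k * L
  active <- rep(TRUE, n)
  eps <- list()
  while (any(active & next_ov <= t_end)) {
    now <- which(active & next_ov <= t_end)
    conceive <- stats::runif(length(now)) < p[now]
    hit <- now[conceive]
    next_ov[now[!conceive]] <- next_ov[now[!conceive]] + L[now[!conceive]]
    if (length(hit)) {
      m <- length(hit)
      cday <- next_ov[hit]
      delta <- sample_int_range(pg$implantation_delay_days[1],
                                pg$implantation_delay_days[2], m)
      fate <- draw_fates(m, params)
      outcome <- fate$outcome
      loss <- ifelse(is.na(fate$loss_offset), NA_real_,
                     cday + fate$loss_offset)
      traj <- sample_trajectory(m, params)
      sym <- draw_symptom_day(cday, loss, outcome, L[hit], params,
                              from_day = symptom_from)
      eps[[length(eps) + 1]] <- data.frame(
        subject_id = sub$id[hit],
        conception_day = cday,
        implantation_day = cday + delta,
        outcome = outcome,
        loss_day = loss,
        expected_menses_day = cday + luteal[hit],
        initial_level = traj$initial_level,
        doubling_time = traj$doubling_time,
        symptom_day = sym,
        stringsAsFactors = FALSE
      )
      # losses resume cycling (menses restarts on the loss day);
      # ongoing pregnancies end the subject's conception process
      lost <- !is.na(loss)
      active[hit[!lost]] <- FALSE
      next_ov[hit[lost]] <- loss[lost] + ov_phase[hit[lost]]
    }
  }
  if (length(eps) == 0) return(empty_episodes())
  out <- do.call(rbind, eps)
  out <- out[order(out$subject_id, out$conception_day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Uniform integer draw on [a, b]; safe for a == b (unlike sample()).
sample_int_range <- function(a, b, n) {
  a + floor(stats::runif(n) * (b - a + 1))
}

# Draw pregnancy fates: outcome class and loss day offset from conception
# (NA for ongoing pregnancies). Very early losses complete before the
# expected menses; clinical miscarriages occur later.
draw_fates <- function(n, params) {
  pg <- params$pregnancy
  u <- stats::runif(n)
  outcome <- ifelse(u < pg$early_loss_prob, "early_loss",
                    ifelse(u < pg$early_loss_prob +
                             pg$clinical_miscarriage_prob,
                           "clinical_miscarriage", "ongoing"))
  loss <- rep(NA_real_, n)
  el <- outcome == "early_loss"
  cm <- outcome == "clinical_miscarriage"
  if (any(el)) {
    loss[el] <- sample_int_range(pg$early_loss_day_range[1],
                                 pg$early_loss_day_range[2], sum(el))
  }
  if (any(cm)) {
    loss[cm] <- sample_int_range(pg$clinical_loss_day_range[1],
                                 pg$clinical_loss_day_range[2], sum(cm))
  }
  list(outcome = outcome, loss_offset = loss)
}

empty_episodes <- function() {
  data.frame(subject_id = integer(0), conception_day = numeric(0),
             implantation_day = numeric(0), outcome = character(0),
             loss_day = numeric(0), expected_menses_day = numeric(0),
             initial_level = numeric(0), doubling_time = numeric(0),
             symptom_day = numeric(0), stringsAsFactors = FALSE)
}

#' Export an episode log as CSV
#'
#' @param episodes An episode data frame (see [simulate_episodes()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_episodes_csv <- function(episodes, path) {
  utils::write.csv(episodes, path, row.names = FALSE)
  invisible(path)
}
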
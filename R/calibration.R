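# Direct episode-level summaries used to check the model's headline
# calibration properties against their clinical anchors.

#' Fraction of ongoing pregnancies detected on the expected-menses day
#'
#' Simulates ongoing pregnancy episodes (implantation delay, hCG
#' trajectory, subject urine:serum ratio all drawn from the parameter
#' table) and evaluates an assay on each episode's expected-menses day
#' (one luteal phase after conception). With the bundled defaults and the
#' 25 IU/L urine assay this exceeds 50%, the clinical benchmark for home
#' pregnancy tests at the missed menses.
#'
#' @param n_episodes Number of ongoing pregnancies to simulate.
#' @param params A `preg_params`.
#' @param spec An `assay_spec` (default: bundled urine qualitative).
#' @param seed Optional integer seed.
#' @return Fraction of episodes called positive on the expected-menses day.
#' @export
#' @examples
#' detect_at_expected_menses(2000, default_parameters(), seed = 1)
detect_at_expected_menses <- function(n_episodes,
                                      params = default_parameters(),
                                      spec = default_assays()$urine_qualitative,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pg <- params$pregnancy
  delta <- sample_int_range(pg$implantation_delay_days[1],
                            pg$implantation_delay_days[2], n_episodes)
  traj <- sample_trajectory(n_episodes, params)
  serum <- hcg_contribution(day = rep(params$cycle$luteal_days, n_episodes),
                            conception_day = rep(0, n_episodes),
                            implantation_day = delta,
                            initial_level = traj$initial_level,
                            doubling_time = traj$doubling_time,
                            loss_day = rep(NA_real_, n_episodes),
                            params = params)
  level <- if (spec$matrix == "urine") {
    urine_level(serum, sample_urine_ratio(n_episodes, params))
  } else serum
  mean(classify_call(measure(level, spec), spec) == "positive")
}

#' Fraction of conceptions ending in very early loss
#'
#' Draws conception fates from the configured outcome probabilities and
#' returns the fraction lost before the expected menses (chemical
#' pregnancies). Under the bundled defaults this lies in the 15-20%
#' range reported for the general reproductive-age population.
#'
#' @param n_conceptions Number of conceptions to simulate.
#' @param params A `preg_params`.
#' @param seed Optional integer seed.
#' @return Fraction of conceptions with a very early loss.
#' @export
early_loss_fraction <- function(n_conceptions,
                                params = default_parameters(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fate <- draw_fates(n_conceptions, params)
  menses <- params$cycle$luteal_days
  mean(fate$outcome == "early_loss" &
         !is.na(fate$loss_offset) & fate$loss_offset < menses)
}
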
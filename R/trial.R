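#' Define a trial design
#'
#' Bundles everything the simulator needs about the study: cohort size,
#' age distribution, duration, contraception scenario, test schedule
#' (screening only, or screening plus periodic follow-up), timing policy
#' of follow-up tests relative to the menstrual cycle, and the assay.
#'
#' @param n_women Cohort size (>= 0).
#' @param age_spec Age distribution descriptor (see [sample_cohort()]).
#' @param duration Study duration in days (>= 0).
#' @param scenario Contraception scenario: `"none"`, `"population_mix"`
#'   or `"highly_effective_only"`.
#' @param schedule `list(type = "screening_only")` or
#'   `list(type = "periodic", interval_days = <days>)`.
#' @param timing_policy `"random"` (follow-up tests at fixed calendar
#'   days, i.e. random with respect to each woman's cycle),
#'   `"timed_to_expected_menses"` (each follow-up deferred to the next
#'   menses day *predicted from a nominal 28-day cycle*), or `"post_LH"`
#'   (each follow-up lands 15 days after the woman's actual LH surge,
#'   i.e. on her true next menses day).
#' @param assay An `assay_spec`, or the name of a bundled default
#'   (`"urine_qualitative"`, `"serum_qualitative"`, `"serum_quantitative"`).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_women, age_spec, duration = 365,
                         scenario = "population_mix",
                         schedule = list(type = "periodic", interval_days = 91),
                         timing_policy = c("random", "timed_to_expected_menses",
                                           "post_LH"),
                         assay = "serum_quantitative") {
  timing_policy <- match.arg(timing_policy)
  stopifnot(n_women >= 0, duration >= 0)
  if (!schedule$type %in% c("screening_only", "periodic")) {
    stop("schedule type must be 'screening_only' or 'periodic'", call. = FALSE)
  }
  if (schedule$type == "periodic" &&
      (is.null(schedule$interval_days) || schedule$interval_days <= 0)) {
    stop("periodic schedule needs interval_days > 0", call. = FALSE)
  }
  if (is.character(assay)) {
    defaults <- default_assays()
    if (!assay %in% names(defaults)) {
      stop("unknown bundled assay: ", assay, call. = FALSE)
    }
    assay <- defaults[[assay]]
  }
  stopifnot(inherits(assay, "assay_spec"))
  structure(list(n_women = n_women, age_spec = age_spec, duration = duration,
                 scenario = scenario, schedule = schedule,
                 timing_policy = timing_policy, assay = assay),
            class = "trial_design")
}

# Nominal (calendar) schedule days: screening at day 0 plus periodic
# follow-ups. Follow-ups may be deferred per subject by the timing policy.
nominal_test_days <- function(design) {
  days <- 0
  if (design$schedule$type == "periodic" &&
      design$duration >= design$schedule$interval_days) {
    days <- c(days, seq(design$schedule$interval_days, design$duration,
                        by = design$schedule$interval_days))
  }
  days
}

# Per-subject test-day matrix (n x K). Screening is day 0 under every
# policy; follow-ups are deferred according to the timing policy using
# the subject's cycle anchor at enrollment (losses during the study
# shift true menses slightly; the anchor approximation is documented in
# the vignette).
subject_test_days <- function(design, cohort) {
  nominal <- nominal_test_days(design)
  n <- nrow(cohort)
  K <- length(nominal)
  out <- matrix(rep(nominal, each = n), nrow = n)
  if (design$timing_policy == "random" || K <= 1 || n == 0) return(out)
  phase <- cohort$phase_offset
  L_true <- cohort$cycle_length
  for (j in 2:K) {
    d <- nominal[j]
    if (design$timing_policy == "timed_to_expected_menses") {
      # menses predicted as "last observed menses + 28 days": the
      # prediction misses the true cycle by (28 - L) days, the
      # non-accumulating single-cycle error of timing to cycle history
      m_last <- d - ((d + phase) %% L_true)
      pred <- m_last + 28
      out[, j] <- ifelse(pred < d, pred + L_true, pred)
    } else {  # post_LH: 15 days after the observed LH surge (ovulation - 1),
      # i.e. exactly one day past the woman's true 14-day luteal phase
      out[, j] <- d + ((-phase - d) %% L_true)
    }
  }
  out[out > design$duration] <- NA
  out
}

# Look up, for each (subject, day) query, the most recent episode with
# conception_day <= day. Returns episode row indices (NA when none).
episode_lookup <- function(episodes, subject_id, day, offset = 512) {
  if (nrow(episodes) == 0) return(rep(NA_integer_, length(subject_id)))
  big <- 1e7  # exceeds any study day + offset; keys stay exact doubles
  key <- episodes$subject_id * big + (episodes$conception_day + offset)
  ord <- order(key)
  key <- key[ord]
  query <- subject_id * big + (day + offset)
  pos <- findInterval(query, key)
  idx <- ifelse(pos == 0, NA_integer_, ord[pmax(pos, 1)])
  ok <- !is.na(idx) & episodes$subject_id[idx] == subject_id
  idx[!ok] <- NA_integer_
  idx
}

# Core evaluation of one simulated cohort + episode stream under one or
# more assays (shared truth, per-assay decisions): returns per-assay
# tallies. Common-random-numbers pairing for compare_specs() falls out of
# sharing the stream.
evaluate_design <- function(cohort, episodes, design, params, assays) {
  n <- nrow(cohort)
  test_days <- subject_test_days(design, cohort)
  K <- ncol(test_days)
  cats <- outcome_categories()
  # first symptom-recognition day per subject (assay-independent)
  sym_first <- rep(Inf, n)
  if (nrow(episodes)) {
    has_sym <- !is.na(episodes$symptom_day)
    if (any(has_sym)) {
      agg <- tapply(episodes$symptom_day[has_sym],
                    episodes$subject_id[has_sym], min)
      sym_first[as.integer(names(agg))] <- agg
    }
  }
  # shared standard-normal draws so measurement noise is common across
  # assays (common-random-numbers pairing even with cv > 0)
  noise_z <- if (any(vapply(assays, function(s) s$cv > 0, logical(1)))) {
    matrix(stats::rnorm(n * K), n, K)
  } else NULL
  lapply(assays, function(spec) {
    counts <- stats::setNames(numeric(length(cats)), cats)
    exit_day <- rep(Inf, n)        # day the subject leaves testing
    enrolled <- rep(TRUE, n)       # screen-positive women are not enrolled
    n_tests <- 0
    det_day <- rep(Inf, nrow(episodes))  # per-episode first test detection
    opp_day <- rep(Inf, nrow(episodes))  # first test at or after conception
    for (j in seq_len(K)) {
      d <- test_days[, j]
      # a symptom-recognized or test-detected pregnancy ends testing
      # (a test on the recognition day itself still happens)
      active <- !is.na(d) & d <= design$duration & d < exit_day &
        (j == 1 | enrolled) & sym_first >= d
      if (!any(active)) next
      idx <- which(active)
      ep <- episode_lookup(episodes, cohort$id[idx], d[idx],
                           offset = params$simulation$burn_in_days + 32)
      contrib <- numeric(length(idx))
      truth <- rep("not_pregnant", length(idx))
      has <- !is.na(ep)
      if (any(has)) {
        e <- episodes[ep[has], , drop = FALSE]
        dd <- d[idx][has]
        contrib[has] <- hcg_contribution(dd, e$conception_day,
                                         e$implantation_day,
                                         e$initial_level, e$doubling_time,
                                         e$loss_day, params)
        truth[has] <- truth_at_day(dd, e$conception_day, e$implantation_day,
                                   e$outcome, e$loss_day, params)
      }
      serum <- cohort$baseline_hcg[idx] + contrib
      level <- if (spec$matrix == "urine") {
        urine_level(serum, cohort$urine_ratio[idx])
      } else serum
      measured <- if (spec$cv > 0) {
        sdlog <- sqrt(log(1 + spec$cv^2))
        level * exp(sdlog * noise_z[cbind(idx, j)] - sdlog^2 / 2)
      } else level
      call <- classify_call(measured, spec)
      category <- adjudicate(call, truth)
      tab <- table(factor(category, levels = cats))
      counts <- counts + as.numeric(tab)
      n_tests <- n_tests + length(idx)
      pos <- call == "positive"
      if (j == 1) enrolled[idx[pos]] <- FALSE
      exit_day[idx[pos]] <- d[idx][pos]
      hit <- has & pos
      if (any(hit)) {
        det_day[ep[hit]] <- pmin(det_day[ep[hit]], d[idx][hit])
      }
      if (any(has)) {
        opp_day[ep[has]] <- pmin(opp_day[ep[has]], d[idx][has])
      }
    }
    # pregnancies: conceptions during the study among enrolled, still-
    # active subjects; exposures: episodes with at least one pregnant,
    # undetected day while the subject is enrolled and on study
    n_preg <- 0; n_expo <- 0
    detection <- numeric(0)
    if (nrow(episodes)) {
      sid <- episodes$subject_id
      exit_ep <- exit_day[sid]
      enr <- enrolled[sid]
      incident <- episodes$conception_day >= 0 &
        episodes$conception_day <= design$duration &
        enr & episodes$conception_day < pmin(exit_ep, sym_first[sid])
      n_preg <- sum(incident)
      s <- pmax(episodes$conception_day, 0)
      preg_end <- ifelse(is.na(episodes$loss_day), Inf, episodes$loss_day)
      n_expo <- sum(enr & s <= design$duration & s < preg_end &
                      s < pmin(exit_ep, sym_first[sid]))
      # days from conception to first detection by a test (symptom
      # recognition is policy-independent and excluded from the spread)
      detection <- (det_day - episodes$conception_day)[is.finite(det_day)]
      # gestational age at the first test of incident episodes: how
      # tightly the policy times detection attempts to conception
      inc <- episodes$conception_day >= 0 & is.finite(opp_day)
      first_test_gap <- (opp_day - episodes$conception_day)[inc]
    } else first_test_gap <- numeric(0)
    list(counts = counts, n_tests = n_tests, n_pregnancies = n_preg,
         n_exposures = n_expo, detection_days = detection,
         first_test_gap = first_test_gap)
  })
}

# Simulate one replicate stream (cohort + episodes) for a design.
simulate_stream <- function(design, params, seed = NULL) {
  cohort <- sample_cohort(design$n_women, design$age_spec, design$scenario,
                          params, seed = seed)
  episodes <- simulate_cohort_episodes(
    cohort, params,
    t_start = -params$simulation$burn_in_days,
    t_end = design$duration, symptom_from = 0)
  list(cohort = cohort, episodes = episodes)
}

new_outcome_tally <- function(counts, n_tests, n_pregnancies, n_exposures,
                              n_women, mode, n_reps = NULL, ci = NULL) {
  rates <- if (n_women > 0) 1e4 * counts / n_women else counts * 0
  structure(list(counts = counts, rates = rates, n_tests = n_tests,
                 n_pregnancies = n_pregnancies, n_exposures = n_exposures,
                 n_women = n_women, mode = mode, n_reps = n_reps, ci = ci),
            class = "outcome_tally")
}

#' Run the Monte Carlo trial simulation
#'
#' Simulates `n_reps` independent cohorts under the design: a screening
#' test at day 0 for every woman, then follow-up tests per the schedule
#' and timing policy. Women whose screening test is positive are not
#' enrolled (no follow-up); a positive follow-up test or symptom
#' recognition of a pregnancy ends a woman's testing. Counts are averaged
#' over replicates; 95% intervals are replicate percentiles.
#'
#' @param design A `trial_design`.
#' @param params A `preg_params` object.
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param seed Master seed; replicate seeds are spawned from it.
#' @return An `outcome_tally`: mean per-cohort counts and per-10,000-women
#'   rates per category, numbers of tests, pregnancies and unintended
#'   exposures, and percentile intervals per rate.
#' @export
run_monte_carlo <- function(design, params = default_parameters(),
                            n_reps = 200, seed = 1) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  cats <- outcome_categories()
  counts <- matrix(0, n_reps, length(cats), dimnames = list(NULL, cats))
  extras <- matrix(0, n_reps, 3,
                   dimnames = list(NULL, c("n_tests", "n_pregnancies",
                                           "n_exposures")))
  for (r in seq_len(n_reps)) {
    stream <- simulate_stream(design, params, seed = rep_seeds[r])
    res <- evaluate_design(stream$cohort, stream$episodes, design, params,
                           list(design$assay))[[1]]
    counts[r, ] <- res$counts
    extras[r, ] <- c(res$n_tests, res$n_pregnancies, res$n_exposures)
  }
  rate_reps <- if (design$n_women > 0) 1e4 * counts / design$n_women else counts
  ci <- apply(rate_reps, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  rownames(ci) <- c("lower", "upper")
  new_outcome_tally(colMeans(counts), mean(extras[, 1]), mean(extras[, 2]),
                    mean(extras[, 3]), design$n_women, mode = "mc",
                    n_reps = n_reps, ci = ci)
}

#' Compare two assays on a common design with paired simulation
#'
#' Runs the design once per replicate and evaluates both assays on the
#' same simulated women, pregnancies and hCG trajectories
#' (common-random-numbers pairing), so rate differences are low-variance;
#' identical specs give exactly zero differences. Monte Carlo mode
#' reports percentile intervals; expected mode uses the deterministic
#' engine on both specs.
#'
#' @param design A `trial_design` (its own `assay` field is ignored).
#' @param specA,specB `assay_spec` objects.
#' @param params A `preg_params`.
#' @param mode `"mc"` or `"expected"`.
#' @param n_reps Replicates (mc mode).
#' @param seed Master seed (mc mode).
#' @param designB Optional second design; must match `design` in every
#'   field except the assay, otherwise a validation error is raised.
#' @return A data frame of per-category rate differences per 10,000 women
#'   (A minus B), with percentile intervals in mc mode; attribute
#'   `"tallies"` holds the two full tallies.
#' @export
compare_specs <- function(design, specA, specB,
                          params = default_parameters(),
                          mode = c("mc", "expected"), n_reps = 200,
                          seed = 1, designB = NULL) {
  mode <- match.arg(mode)
  if (!is.null(designB)) {
    a <- design; b <- designB
    a$assay <- NULL; b$assay <- NULL
    if (!isTRUE(all.equal(a, b))) {
      stop("designs must be identical except for the assay", call. = FALSE)
    }
  }
  cats <- outcome_categories()
  if (mode == "expected") {
    dA <- design; dA$assay <- specA
    dB <- design; dB$assay <- specB
    tA <- expected_outcomes(dA, params)
    tB <- expected_outcomes(dB, params)
    diff <- tA$rates - tB$rates
    out <- data.frame(category = c(cats, "FN_total"),
                      difference = c(diff, sum(diff[c("FN_preimplantation",
                                                      "FN_postimplantation")])))
    attr(out, "tallies") <- list(A = tA, B = tB)
    return(out)
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  diffs <- matrix(0, n_reps, length(cats) + 1,
                  dimnames = list(NULL, c(cats, "FN_total")))
  sumA <- sumB <- stats::setNames(numeric(length(cats)), cats)
  extA <- extB <- numeric(3)
  for (r in seq_len(n_reps)) {
    stream <- simulate_stream(design, params, seed = rep_seeds[r])
    res <- evaluate_design(stream$cohort, stream$episodes, design, params,
                           list(specA, specB))
    dc <- res[[1]]$counts - res[[2]]$counts
    fn <- sum(dc[c("FN_preimplantation", "FN_postimplantation")])
    diffs[r, ] <- c(dc, fn) * if (design$n_women > 0) 1e4 / design$n_women else 0
    sumA <- sumA + res[[1]]$counts; sumB <- sumB + res[[2]]$counts
    extA <- extA + c(res[[1]]$n_tests, res[[1]]$n_pregnancies,
                     res[[1]]$n_exposures)
    extB <- extB + c(res[[2]]$n_tests, res[[2]]$n_pregnancies,
                     res[[2]]$n_exposures)
  }
  ci <- apply(diffs, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  out <- data.frame(category = colnames(diffs),
                    difference = colMeans(diffs),
                    lower = ci[1, ], upper = ci[2, ], row.names = NULL)
  attr(out, "tallies") <- list(
    A = new_outcome_tally(sumA / n_reps, extA[1] / n_reps, extA[2] / n_reps,
                          extA[3] / n_reps, design$n_women, "mc", n_reps),
    B = new_outcome_tally(sumB / n_reps, extB[1] / n_reps, extB[2] / n_reps,
                          extB[3] / n_reps, design$n_women, "mc", n_reps))
  out
}

#' False-negative rates by test-timing policy
#'
#' Evaluates a common design under the three timing policies on shared
#' simulated streams and reports the total false-negative rate per 10,000
#' women and the between-pregnancy variance of the gestational age at the
#' first detection attempt (the first test at or after conception, for
#' pregnancies conceived on study). Testing at a fixed calendar schedule
#' ("random" relative to the cycle) yields the most false negatives;
#' timing to the predicted menses fewer; testing 15 days after the
#' observed LH surge the fewest, with the least variability in when
#' detection is attempted.
#'
#' @param design A `trial_design` (its `timing_policy` is ignored).
#' @param params A `preg_params`.
#' @param mode Only `"mc"` is supported for timed policies.
#' @param n_reps Replicates.
#' @param seed Master seed.
#' @return Data frame: policy, fn_rate, first_test_gest_var (variance of
#'   the gestational age at the first on-study detection attempt),
#'   n_detected (pregnancies detected by a test).
#' @export
timing_effect <- function(design, params = default_parameters(),
                          mode = "mc", n_reps = 50, seed = 1) {
  if (mode != "mc") stop("timing_effect supports mode 'mc' only", call. = FALSE)
  policies <- c("random", "timed_to_expected_menses", "post_LH")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  fn <- stats::setNames(numeric(3), policies)
  det <- gaps <- stats::setNames(vector("list", 3), policies)
  for (r in seq_len(n_reps)) {
    stream <- simulate_stream(design, params, seed = rep_seeds[r])
    for (pol in policies) {
      d <- design; d$timing_policy <- pol
      res <- evaluate_design(stream$cohort, stream$episodes, d, params,
                             list(design$assay))[[1]]
      fn[pol] <- fn[pol] + sum(res$counts[c("FN_preimplantation",
                                            "FN_postimplantation")])
      det[[pol]] <- c(det[[pol]], res$detection_days)
      gaps[[pol]] <- c(gaps[[pol]], res$first_test_gap)
    }
  }
  data.frame(
    policy = policies,
    fn_rate = if (design$n_women > 0)
      1e4 * fn / (n_reps * design$n_women) else fn * 0,
    first_test_gest_var = vapply(gaps, function(x)
      if (length(x) > 1) stats::var(x) else NA_real_, numeric(1)),
    n_detected = vapply(det, length, numeric(1)),
    row.names = NULL
  )
}

#' @export
print.outcome_tally <- function(x, ...) {
  cat("<outcome_tally>", x$mode,
      if (!is.null(x$n_reps)) paste0("(", x$n_reps, " reps)"), "-",
      x$n_women, "women\n")
  df <- data.frame(count = round(x$counts, 2),
                   per_10k_women = round(x$rates, 2))
  if (!is.null(x$ci)) {
    df$lower <- round(x$ci["lower", ], 2)
    df$upper <- round(x$ci["upper", ], 2)
  }
  print(df)
  cat("tests:", round(x$n_tests, 1), "| pregnancies:",
      round(x$n_pregnancies, 2), "| unintended exposures:",
      round(x$n_exposures, 2), "\n")
  invisible(x)
}
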
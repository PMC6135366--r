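# Deterministic expected-value engine: closed-form expectation of the
# Monte Carlo simulator for designs tested randomly with respect to the
# menstrual cycle. Marginalizes analytically over reproductive status,
# contraceptive method, cycle length and phase (1-day grid), conception
# timing, episode fate, implantation delay and the hCG level
# distributions. Within an episode the initial hCG level enters every
# test monotonically, so sequential "first positive test" probabilities
# reduce to interval probabilities of a lognormal; doubling time and the
# urine:serum ratio are integrated on midpoint-quantile quadrature grids.

#' Deterministic expected outcomes of a trial design
#'
#' Computes the expected outcome tally of [run_monte_carlo()] in closed
#' form (no simulation, no confidence intervals). Only the `"random"`
#' timing policy is supported (the expectation engine marginalizes over a
#' uniform cycle phase, i.e. testing performed randomly in reference to
#' subjects' menstrual cycles) and the assay must be noise-free
#' (`cv = 0`).
#'
#' @param design A `trial_design` with `timing_policy = "random"`.
#' @param params A `preg_params`.
#' @return An `outcome_tally` with mode `"expected"` and no intervals.
#' @export
expected_outcomes <- function(design, params = default_parameters()) {
  if (design$timing_policy != "random") {
    stop("expected_outcomes supports timing_policy 'random' only; use ",
         "run_monte_carlo() for cycle-timed policies", call. = FALSE)
  }
  spec <- design$assay
  if (spec$cv > 0) {
    stop("expected_outcomes supports noise-free assays (cv = 0) only",
         call. = FALSE)
  }
  cats <- outcome_categories()
  counts <- stats::setNames(numeric(length(cats)), cats)
  extras <- c(n_tests = 0, n_pregnancies = 0, n_exposures = 0)
  if (design$n_women == 0) {
    return(new_outcome_tally(counts, 0, 0, 0, 0, mode = "expected"))
  }
  bw <- band_weights(design$age_spec, params)
  nominal <- nominal_test_days(design)
  K <- length(nominal)
  ab <- params$age_bands

  # --- subjects without reproductive potential: baseline hCG only -----------
  r_nodes <- ratio_nodes(params, spec)
  for (b in which(bw > 0)) {
    p_h <- ab$hysterectomy[b]
    p_m <- (1 - p_h) * ab$menopause[b]
    p_i <- (1 - p_h) * (1 - ab$menopause[b]) * ab$infertile[b]
    for (grp in c("pituitary", "low")) {
      w <- if (grp == "pituitary") p_m else p_h + p_i
      if (w <= 0) next
      pr <- baseline_call_probs(grp, params, spec, r_nodes)
      mass <- bw[b] * w * design$n_women
      counts["FP_classic"] <- counts["FP_classic"] + mass * pr["pos"]
      counts["IND"] <- counts["IND"] + mass * pr["ind"] * K
      counts["TN"] <- counts["TN"] + mass * (1 - pr["pos"] - pr["ind"]) * K
      extras["n_tests"] <- extras["n_tests"] +
        mass * (pr["pos"] + (1 - pr["pos"]) * K)
    }
  }

  # --- FRP subjects: cycle/conception process --------------------------------
  memo <- new.env(parent = emptyenv())
  L_nodes <- cycle_length_nodes(params)
  mixes <- scenario_mixes(design$scenario, params)
  lag <- params$hcg$clearance_lag_days
  t_start <- -params$simulation$burn_in_days
  for (b in which(bw > 0)) {
    p_frp <- (1 - ab$hysterectomy[b]) * (1 - ab$menopause[b]) *
      (1 - ab$infertile[b])
    if (p_frp <= 0) next
    mix <- mixes[[ab$mix[b]]]
    for (m in names(mix)) {
      if (mix[[m]] <= 0) next
      p_conceive <- ab$fecundability[b] *
        if (m == "none") 1 else
          per_cycle_failure(params$methods$annual_typical_failure[
            params$methods$name == m], params)
      cell_w <- bw[b] * p_frp * mix[[m]] * design$n_women
      for (L in L_nodes) {
        w_L <- cell_w / length(L_nodes)
        res <- propagate_cell(L, p_conceive, design, params, spec, memo,
                              nominal, t_start, lag)
        counts <- counts + w_L * res$counts
        extras <- extras + w_L * res$extras
      }
    }
  }
  new_outcome_tally(counts, extras[["n_tests"]], extras[["n_pregnancies"]],
                    extras[["n_exposures"]], design$n_women,
                    mode = "expected")
}

# Day-by-day probability-mass propagation for one (cycle length,
# conception probability) cell; mass 1 = one woman. The non-pregnant
# state is a vector over cycle day (0 = menses); conception taps at the
# ovulation day hand mass to the episode expectation, which returns
# category tallies plus the mass resuming cycling after an undetected
# loss (re-entering at cycle day clearance_lag + 1, since menses restarts
# on the loss day and the episode owns tests through the clearance lag).
propagate_cell <- function(L, p_conceive, design, params, spec, memo,
                           nominal, t_start, lag) {
  cats <- outcome_categories()
  counts <- stats::setNames(numeric(length(cats)), cats)
  extras <- c(n_tests = 0, n_pregnancies = 0, n_exposures = 0)
  A <- rep(1 / L, L)                     # index = cycle day + 1
  ov <- (L - params$cycle$luteal_days) %% L
  horizon <- design$duration
  returns <- numeric(horizon - t_start + 2)
  ret_phase <- (lag + 1) %% L
  is_test <- rep(FALSE, horizon - t_start + 1)
  is_test[nominal - t_start + 1] <- TRUE
  for (t in t_start:horizon) {
    ti <- t - t_start + 1
    if (t > t_start) A <- A[c(L, seq_len(L - 1))]   # cycle day advances
    A[ret_phase + 1] <- A[ret_phase + 1] + returns[ti]
    if (is_test[ti]) {
      # a same-day test precedes the (within-day) conception time
      tot <- sum(A)
      counts["TN"] <- counts["TN"] + tot   # FRP baseline ~0 vs thresholds
      extras["n_tests"] <- extras["n_tests"] + tot
    }
    mu <- A[ov + 1] * p_conceive
    if (mu > 0) {
      A[ov + 1] <- A[ov + 1] - mu
      ep <- episode_expectation(t, L, design, params, spec, memo)
      counts <- counts + mu * ep$counts
      extras["n_tests"] <- extras["n_tests"] + mu * ep$n_tests
      if (t >= 0) {
        extras["n_pregnancies"] <- extras["n_pregnancies"] + mu
        extras["n_exposures"] <- extras["n_exposures"] + mu
      } else {
        extras["n_exposures"] <- extras["n_exposures"] + mu * ep$exposure0
      }
      if (length(ep$return_day)) {
        ok <- ep$return_day <= horizon
        if (any(ok)) {
          ri <- ep$return_day[ok] - t_start + 1
          returns[ri] <- returns[ri] + mu * ep$return_mass[ok]
        }
      }
    }
  }
  list(counts = counts, extras = extras)
}

# Expected tallies of a single pregnancy episode conceived on day `cday`
# for a woman with cycle length L: marginal over implantation delay,
# fate (ongoing / very early loss / clinical miscarriage with bucketed
# loss days), doubling time and urine ratio (quadrature), and the
# initial hCG level (closed form). Exact within a node because, for
# fixed nodes, every test call is a threshold rule on the initial level
# and detection exits at the first positive test.
episode_expectation <- function(cday, L, design, params, spec, memo) {
  key <- paste0(cday, "_", L)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  pg <- params$pregnancy
  hc <- params$hcg
  q_sym <- pg$symptom_prob_per_cycle
  luteal <- params$cycle$luteal_days
  lag <- hc$clearance_lag_days
  cats <- outcome_categories()
  counts <- stats::setNames(numeric(length(cats)), cats)
  n_tests <- 0; exposure0 <- 0
  ret_day <- numeric(0); ret_mass <- numeric(0)
  nominal <- nominal_test_days(design)

  ndt <- 8
  dt_nodes <- stats::qlnorm((seq_len(ndt) - 0.5) / ndt,
                            log(hc$doubling_median_days), hc$doubling_sdlog)
  r_nodes <- ratio_nodes(params, spec)
  node_w <- 1 / (ndt * length(r_nodes))
  grid <- expand.grid(dt = dt_nodes, r = r_nodes)
  mlog <- log(hc$initial_median_iu_l); slog <- hc$initial_sdlog
  tau_pos <- spec$positive_cutoff
  tau_lo <- if (is.null(spec$indeterminate_band)) spec$positive_cutoff else
    spec$indeterminate_band[1]
  eff <- function(tau) if (spec$matrix == "urine") tau / grid$r else
    rep(tau, nrow(grid))
  tau_pos_eff <- eff(tau_pos); tau_lo_eff <- eff(tau_lo)

  deltas <- seq(pg$implantation_delay_days[1], pg$implantation_delay_days[2])
  el_days <- seq(pg$early_loss_day_range[1], pg$early_loss_day_range[2])
  cm_span <- pg$clinical_loss_day_range
  n_cm <- 7
  edges <- seq(cm_span[1], cm_span[2] + 1, length.out = n_cm + 1)
  cm_days <- round((edges[-1] + edges[-(n_cm + 1)]) / 2 - 0.5)
  fates <- rbind(
    data.frame(kind = "ongoing", loss = NA_real_,
               w = 1 - pg$early_loss_prob - pg$clinical_miscarriage_prob),
    data.frame(kind = "early_loss", loss = el_days,
               w = pg$early_loss_prob / length(el_days)),
    data.frame(kind = "clinical", loss = cm_days,
               w = pg$clinical_miscarriage_prob / n_cm)
  )
  F_init <- function(x) stats::plnorm(x, mlog, slog)

  # conception occurs uniformly within the tap day: midpoint offset keeps
  # the integer-day grid consistent with continuous conception timing
  cmid <- cday + 0.5
  for (di in seq_along(deltas)) {
    impl <- cmid + deltas[di]
    for (fi in seq_len(nrow(fates))) {
      w_branch <- fates$w[fi] / length(deltas)
      if (w_branch <= 0) next
      lday <- cmid + fates$loss[fi]
      own_end <- if (is.na(lday)) design$duration else
        min(lday + lag, design$duration)
      # conception falls later within the tap day than a same-day test,
      # so the episode owns tests from the following day onward
      tests <- nominal[nominal > cday & nominal <= own_end]
      # symptom-recognition boundaries (missed menses) strictly before a
      # time t; none before study day 0 and none after a loss
      bound_end <- if (is.na(lday)) design$duration + 1 else lday
      bounds <- if (fates$kind[fi] == "early_loss" ||
                    cmid + luteal >= bound_end) numeric(0) else
        seq(cmid + luteal, bound_end - 1e-9, by = L)
      bounds <- bounds[bounds >= 0 & bounds < bound_end]
      surv_before <- function(t) (1 - q_sym)^sum(bounds < t)
      minprev <- rep(Inf, nrow(grid))
      for (tday in tests) {
        S <- surv_before(tday)
        if (tday < impl) {
          mass <- S * mean(F_init(pmin(minprev, Inf)))
          counts["FN_preimplantation"] <- counts["FN_preimplantation"] +
            w_branch * mass
          n_tests <- n_tests + w_branch * mass
          if (cday < 0 && tday == 0) {
            exposure0 <- exposure0 + w_branch * mass
          }
          next
        }
        # per-node gain of the episode hCG level at tday
        grow_until <- min(tday, cmid + hc$peak_day_post_conception,
                          if (is.na(lday)) Inf else lday)
        g <- 2 ^ ((grow_until - impl) / grid$dt)
        if (!is.na(lday) && tday > lday) {
          g <- g * 2 ^ (-(tday - lday) / hc$clearance_half_life_days)
          if (tday > lday + lag) g <- g * 0
        }
        thr_pos <- ifelse(g > 0, tau_pos_eff / g, Inf)
        thr_lo <- ifelse(g > 0, tau_lo_eff / g, Inf)
        p_pos <- pmax(F_init(minprev) - F_init(pmin(thr_pos, minprev)), 0)
        p_ind <- pmax(F_init(pmin(thr_pos, minprev)) -
                        F_init(pmin(thr_lo, minprev)), 0)
        p_neg <- F_init(pmin(thr_lo, minprev))
        pos_m <- S * mean(p_pos); ind_m <- S * mean(p_ind)
        neg_m <- S * mean(p_neg)
        el_like <- fates$kind[fi] == "early_loss" ||
          (!is.na(lday) && tday > lday)
        if (el_like) {
          counts["FP_biological"] <- counts["FP_biological"] + w_branch * pos_m
          counts["TN"] <- counts["TN"] + w_branch * neg_m
        } else {
          counts["TP"] <- counts["TP"] + w_branch * pos_m
          counts["FN_postimplantation"] <- counts["FN_postimplantation"] +
            w_branch * neg_m
        }
        counts["IND"] <- counts["IND"] + w_branch * ind_m
        n_tests <- n_tests + w_branch * (pos_m + ind_m + neg_m)
        if (cday < 0 && tday == 0 && (is.na(lday) || lday > 0)) {
          exposure0 <- exposure0 + w_branch * (ind_m + neg_m)
        }
        minprev <- pmin(minprev, thr_pos)
      }
      if (!is.na(lday)) {  # undetected loss resumes cycling
        rm_ <- surv_before(lday) * mean(F_init(minprev))
        ret_day <- c(ret_day, cday + fates$loss[fi] + lag + 1)
        ret_mass <- c(ret_mass, w_branch * rm_)
      }
    }
  }
  if (length(ret_day)) {  # aggregate masses sharing a return day
    agg <- rowsum(ret_mass, ret_day)
    ret_day <- as.numeric(rownames(agg))
    ret_mass <- as.numeric(agg)
  }
  out <- list(counts = counts, n_tests = n_tests, exposure0 = exposure0,
              return_day = ret_day, return_mass = ret_mass)
  memo[[key]] <- out
  out
}

# Quadrature nodes for the urine:serum ratio (single node 1 for serum
# assays, where the ratio plays no role).
ratio_nodes <- function(params, spec) {
  if (spec$matrix != "urine") return(1)
  h <- params$hcg
  nr <- 6
  pmin(stats::qlnorm((seq_len(nr) - 0.5) / nr, log(h$urine_ratio_median),
                     h$urine_ratio_sdlog), h$urine_ratio_max)
}

# Integer cycle-length grid: midpoint-quantile nodes of the lognormal
# cycle-length distribution, rounded to whole days.
cycle_length_nodes <- function(params, n = 5) {
  cy <- params$cycle
  unique(round(stats::qlnorm((seq_len(n) - 0.5) / n,
                             log(cy$length_median_days), cy$length_sdlog)))
}

# Probability weights of the age bands implied by an age-spec.
band_weights <- function(age_spec, params) {
  ab <- params$age_bands
  w <- numeric(nrow(ab))
  if (age_spec$type == "uniform") {
    lo <- age_spec$min; hi <- age_spec$max
    if (hi == lo) {
      w[age_band_index(lo, params)] <- 1
    } else {
      for (b in seq_len(nrow(ab))) {
        w[b] <- max(0, min(hi, ab$upper[b] + 1) - max(lo, ab$lower[b]))
      }
      w <- w / (hi - lo)
    }
  } else if (age_spec$type == "point") {
    w[age_band_index(age_spec$age, params)] <- 1
  } else if (age_spec$type == "bands") {
    idx <- age_band_index(as.numeric(age_spec$ages), params)
    pw <- age_spec$weights / sum(age_spec$weights)
    for (i in seq_along(idx)) w[idx[i]] <- w[idx[i]] + pw[i]
  } else {
    stop("unknown age_spec type: ", age_spec$type, call. = FALSE)
  }
  w
}

# Scenario -> method-mix list keyed like params$method_mix.
scenario_mixes <- function(scenario, params) {
  mixes <- params$method_mix
  if (scenario == "none") {
    return(lapply(mixes, function(mix) c(none = 1)))
  }
  if (scenario == "highly_effective_only") {
    he <- params$methods$name[
      params$methods$effectiveness_class == "highly_effective"]
    return(lapply(mixes, function(mix) {
      mix <- mix[names(mix) %in% he]
      if (length(mix) == 0 || sum(mix) <= 0) {
        stop("no highly effective method has positive weight in the mix",
             call. = FALSE)
      }
      mix / sum(mix)
    }))
  }
  mixes
}

# Positive / indeterminate call probabilities for a fixed (non-pregnant)
# baseline drawn from the pituitary or the low-level distribution,
# including the sub-20 IU/L ceiling and the urine ratio.
baseline_call_probs <- function(group, params, spec, r_nodes) {
  b <- params$baseline_hcg
  if (group == "pituitary") {
    mlog <- log(b$pituitary_median_iu_l); slog <- b$pituitary_sdlog
  } else {
    mlog <- log(b$frp_median_iu_l); slog <- b$frp_sdlog
  }
  ceil <- b$ceiling_iu_l
  p_ge <- function(tau_serum) {
    # serum baseline is min(lognormal, ceiling)
    mean(ifelse(tau_serum > ceil, 0,
                stats::plnorm(tau_serum, mlog, slog, lower.tail = FALSE)))
  }
  tau <- function(x) if (spec$matrix == "urine") x / r_nodes else x
  pos <- p_ge(tau(spec$positive_cutoff))
  ind <- if (is.null(spec$indeterminate_band)) 0 else
    p_ge(tau(spec$indeterminate_band[1])) - pos
  c(pos = pos, ind = max(ind, 0))
}
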
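test_that("per-cycle conception probability composes fecundability and method", {
  p <- default_parameters()
  f <- p$age_bands$fecundability[pregsim:::age_band_index(28, p)]
  # no method: fecundability unchanged
  expect_equal(per_cycle_conception_probability(28, "none", p), f)
  # a perfect method yields zero
  p0 <- p
  p0$methods$annual_typical_failure[p0$methods$name == "implant"] <- 0
  expect_equal(per_cycle_conception_probability(28, "implant", p0), 0)
  # annual 9% over 13 cycles: checked against an independent root-finding
  # oracle for the per-cycle breakthrough probability q: (1-q)^13 = 0.91
  q_oracle <- stats::uniroot(function(q) (1 - q)^13 - (1 - 0.09),
                             c(0, 0.05), tol = 1e-12)$root
  expect_equal(per_cycle_conception_probability(28, "pill", p),
               f * q_oracle, tolerance = 1e-9)
  expect_true(all(per_cycle_conception_probability(c(20, 35, 52),
                                                   c("pill", "condom", "iud"),
                                                   p) >= 0))
})

test_that("non-FRP subjects never conceive", {
  p <- default_parameters()
  coh <- sample_cohort(300, list(type = "uniform", min = 50, max = 59),
                       "none", p, seed = 5)
  coh$reproductive_status[] <- "menopause"
  set.seed(5)
  eps <- simulate_episodes(coh, 365 * 3, p)
  expect_equal(nrow(eps), 0)
})

test_that("episodes respect the implantation window and loss ordering", {
  p <- default_parameters()
  coh <- sample_cohort(4000, young_uniform, "none", p, seed = 6)
  set.seed(6)
  eps <- simulate_episodes(coh, 365, p)
  expect_gt(nrow(eps), 100)
  gap <- eps$implantation_day - eps$conception_day
  expect_true(all(gap >= 8 - 1e-9 & gap <= 10 + 1e-9))
  # very early losses complete before the expected menses
  el <- eps$outcome == "early_loss"
  expect_true(all(eps$loss_day[el] < eps$expected_menses_day[el]))
  # ongoing pregnancies have no loss day
  expect_true(all(is.na(eps$loss_day[eps$outcome == "ongoing"])))
  # at most one active episode: a new conception only after the prior loss
  by_subj <- split(eps, eps$subject_id)
  ok <- vapply(by_subj, function(e) {
    if (nrow(e) < 2) return(TRUE)
    all(e$conception_day[-1] >= e$loss_day[-nrow(e)])
  }, logical(1))
  expect_true(all(ok))
})

test_that("early-loss fraction matches its configured value and the 15-20% range", {
  p <- default_parameters()
  expect_gte(p$pregnancy$early_loss_prob, 0.15)
  expect_lte(p$pregnancy$early_loss_prob, 0.20)
  frac <- early_loss_fraction(1e5, p, seed = 10)
  bounds <- binom_bounds99(1e5, p$pregnancy$early_loss_prob)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("symptom recognition follows the per-cycle geometric process", {
  p1 <- params_with(pregnancy = list(symptom_prob_per_cycle = 1))
  ep <- data.frame(conception_day = 20, loss_day = NA_real_,
                   outcome = "ongoing")
  set.seed(12)
  # certain recognition happens at the first missed menses
  expect_equal(symptom_detection(ep, cycle_length = 28, p1), 20 + 14)
  # zero probability never detects
  p0 <- params_with(pregnancy = list(symptom_prob_per_cycle = 0))
  expect_true(is.na(symptom_detection(ep, 28, p0)))
  # early losses are never symptom-detected
  ep_el <- data.frame(conception_day = 20, loss_day = 32,
                      outcome = "early_loss")
  expect_true(is.na(symptom_detection(ep_el, 28, p1)))
  # detection cycle is geometric(q): chi-square against the pmf
  q <- 0.5
  ph <- params_with(pregnancy = list(symptom_prob_per_cycle = q))
  set.seed(13)
  days <- pregsim:::draw_symptom_day(rep(0, 10000), rep(NA_real_, 10000),
                                     rep("ongoing", 10000), rep(28, 10000),
                                     ph, from_day = 0)
  k <- (days - 14) / 28
  kc <- pmin(k, 6)  # pool the tail
  obs <- table(factor(kc, levels = 0:6))
  expected_p <- c(stats::dgeom(0:5, q), stats::pgeom(5, q, lower.tail = FALSE))
  expect_gt(stats::chisq.test(obs, p = expected_p)$p.value, 0.01)
})

test_that("expected pregnancies fall with stricter contraception and age", {
  p <- default_parameters()
  pregs <- vapply(c("none", "population_mix", "highly_effective_only"),
                  function(sc) {
    coh <- sample_cohort(3000, young_uniform, sc, p, seed = 21)
    set.seed(21)
    nrow(simulate_episodes(coh, 365, p))
  }, numeric(1))
  expect_true(pregs[1] >= pregs[2] && pregs[2] >= pregs[3])
  # older cohorts conceive less under identical scenarios
  pregs_age <- vapply(list(young_uniform, older_uniform,
                           list(type = "uniform", min = 50, max = 59)),
                      function(ages) {
    coh <- sample_cohort(3000, ages, "population_mix", p, seed = 22)
    set.seed(22)
    nrow(simulate_episodes(coh, 365, p))
  }, numeric(1))
  expect_true(all(diff(pregs_age) <= 0))
})
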
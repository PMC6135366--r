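test_that("reproductive status is forced by degenerate prevalences", {
  p <- params_with_prevalence(hysterectomy = 0, menopause = 0, infertile = 0)
  set.seed(1)
  expect_true(all(classify_reproductive_potential(rep(22, 500), p) == "FRP"))
  # above the menopause-certainty bound every woman is menopausal
  set.seed(1)
  expect_true(all(classify_reproductive_potential(rep(70, 500),
                                                  default_parameters())
                  == "menopause"))
})

test_that("status draws match configured prevalences (binomial oracle)", {
  p <- params_with_prevalence(hysterectomy = 0.30, menopause = 0,
                              infertile = 0)
  set.seed(42)
  status <- classify_reproductive_potential(rep(45, 10000), p)
  bounds <- binom_bounds99(10000, 0.30)
  frac <- mean(status == "hysterectomy")
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("precedence order resolves co-occurring prevalences", {
  p <- params_with_prevalence(hysterectomy = 1, menopause = 1, infertile = 1)
  set.seed(2)
  expect_true(all(classify_reproductive_potential(rep(40, 200), p)
                  == "hysterectomy"))
})

test_that("contraception assignment honors the scenario", {
  p <- default_parameters()
  set.seed(3)
  n <- 400
  age <- rep(28, n); status <- rep("FRP", n)
  expect_true(all(assign_contraception(age, status, "none", p) == "none"))
  m <- assign_contraception(age, status, "highly_effective_only", p)
  cls <- p$methods$effectiveness_class[match(m, p$methods$name)]
  expect_true(all(cls == "highly_effective"))
  # non-FRP always get "none"
  expect_true(all(assign_contraception(age, rep("menopause", n),
                                       "population_mix", p) == "none"))
})

test_that("population-mix draws match the mix (multinomial oracle)", {
  p <- default_parameters()
  p$method_mix$young <- c(none = 0.2, pill = 0.5, iud = 0.3)
  set.seed(7)
  m <- assign_contraception(rep(25, 10000), rep("FRP", 10000),
                            "population_mix", p)
  for (nm in names(p$method_mix$young)) {
    bounds <- binom_bounds99(10000, p$method_mix$young[[nm]])
    expect_gte(mean(m == nm), bounds[1])
    expect_lte(mean(m == nm), bounds[2])
  }
})

test_that("cycle profiles match the configured distribution", {
  p <- default_parameters()
  set.seed(11)
  cyc <- sample_cycle(10000, p)
  expect_true(all(cyc$luteal_length == 14))
  expect_true(all(cyc$phase_offset >= 0 & cyc$phase_offset < cyc$cycle_length))
  # moments of the lognormal length recovered within 3 standard errors
  sl <- p$cycle$length_sdlog
  mu <- p$cycle$length_median_days * exp(sl^2 / 2)
  sdv <- mu * sqrt(exp(sl^2) - 1)
  expect_lt(abs(mean(cyc$cycle_length) - mu), 3 * sdv / sqrt(10000))
  # phase offset uniform on [0, L): chi-square on scaled phases
  u <- cyc$phase_offset / cyc$cycle_length
  counts <- table(cut(u, seq(0, 1, by = 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # degenerate distribution collapses to a point
  p0 <- params_with(cycle = list(length_sdlog = 1e-12))
  cyc0 <- sample_cycle(50, p0)
  expect_equal(cyc0$cycle_length, rep(28, 50), tolerance = 1e-6)
})

test_that("cohorts are fully populated, sized and reproducible", {
  p <- default_parameters()
  expect_equal(nrow(sample_cohort(0, young_uniform, "none", p, seed = 1)), 0)
  coh <- sample_cohort(500, young_uniform, "population_mix", p, seed = 9)
  expect_equal(nrow(coh), 500)
  expect_false(anyNA(coh))
  # identical seed and config give a bit-identical cohort
  expect_identical(coh,
                   sample_cohort(500, young_uniform, "population_mix", p,
                                 seed = 9))
  # point mass at 70 forces zero reproductive potential
  coh70 <- sample_cohort(2000, list(type = "point", age = 70),
                         "population_mix", p, seed = 2)
  expect_equal(sum(coh70$reproductive_status == "FRP"), 0)
})

test_that("FRP fraction matches the table and declines with age", {
  p <- default_parameters()
  ab <- p$age_bands
  frp_frac <- (1 - ab$hysterectomy) * (1 - ab$menopause) * (1 - ab$infertile)
  # closed-form fraction is non-increasing across the default bands
  expect_true(all(diff(frp_frac) <= 1e-12))
  # empirical fraction for a uniform 20-30 cohort matches the closed form
  coh <- sample_cohort(10000, list(type = "uniform", min = 20, max = 30),
                       "none", p, seed = 4)
  idx <- pregsim:::age_band_index(coh$age, p)
  expected <- mean(frp_frac[idx])
  frac <- mean(coh$reproductive_status == "FRP")
  bounds <- binom_bounds99(10000, expected)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("malformed age descriptors are rejected", {
  p <- default_parameters()
  expect_error(sample_cohort(10, list(min = 20, max = 30), "none", p, 1),
               "type")
  expect_error(sample_cohort(10, list(type = "uniform", min = 30, max = 20),
                             "none", p, 1), "min <= max")
  expect_error(sample_cohort(10, list(type = "wedge"), "none", p, 1),
               "unknown age_spec")
})
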
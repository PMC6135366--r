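test_that("category counts sum to the number of tests in every replicate", {
  p <- default_parameters()
  d <- small_design(800, duration = 200,
                    schedule = list(type = "periodic", interval_days = 60))
  for (s in c(1, 2, 3)) {
    stream <- pregsim:::simulate_stream(d, p, seed = s)
    res <- pregsim:::evaluate_design(stream$cohort, stream$episodes, d, p,
                                     list(d$assay))[[1]]
    expect_equal(sum(res$counts), res$n_tests)
  }
})

test_that("an empty cohort yields an all-zero tally", {
  p <- default_parameters()
  d <- trial_design(0, young_uniform)
  mc <- run_monte_carlo(d, p, n_reps = 2, seed = 1)
  expect_true(all(mc$counts == 0))
  expect_equal(mc$n_tests, 0)
  ex <- expected_outcomes(d, p)
  expect_true(all(ex$counts == 0))
})

test_that("screening-only design with zero duration tests each woman once", {
  p <- default_parameters()
  d <- trial_design(600, young_uniform, duration = 0,
                    schedule = list(type = "screening_only"))
  mc <- run_monte_carlo(d, p, n_reps = 3, seed = 2)
  expect_equal(mc$n_tests, 600)
  ex <- expected_outcomes(d, p)
  expect_equal(ex$n_tests, 600, tolerance = 1e-9)
})

test_that("Monte Carlo runs are reproducible for a fixed seed", {
  p <- default_parameters()
  d <- small_design(500, duration = 180)
  a <- run_monte_carlo(d, p, n_reps = 3, seed = 77)
  b <- run_monte_carlo(d, p, n_reps = 3, seed = 77)
  expect_identical(a$counts, b$counts)
  expect_identical(a$ci, b$ci)
})

test_that("paired self-comparison is exactly zero", {
  p <- default_parameters()
  a <- default_assays()
  d <- small_design(1000)
  cmp <- compare_specs(d, a$serum_quantitative, a$serum_quantitative, p,
                       n_reps = 5, seed = 3)
  expect_true(all(cmp$difference == 0))
  expect_true(all(cmp$lower == 0 & cmp$upper == 0))
})

test_that("mismatched designs are rejected in comparisons", {
  p <- default_parameters()
  a <- default_assays()
  d <- small_design(500)
  d2 <- small_design(600)
  expect_error(compare_specs(d, a$urine_qualitative, a$serum_quantitative,
                             p, n_reps = 2, seed = 1, designB = d2),
               "identical except")
})

test_that("lowering the positive cutoff never increases false negatives", {
  p <- default_parameters()
  cutoffs <- c(25, 10, 5, 2)
  specs <- lapply(cutoffs, function(cu)
    assay_spec(paste0("serum", cu), "serum", "qualitative", 2, cu))
  d <- small_design(4000, assay = specs[[1]])
  fn <- numeric(length(specs))
  for (s in 1:4) {  # shared streams across cutoffs
    stream <- pregsim:::simulate_stream(d, p, seed = 100 + s)
    res <- pregsim:::evaluate_design(stream$cohort, stream$episodes, d, p,
                                     specs)
    fn <- fn + vapply(res, function(r)
      sum(r$counts[c("FN_preimplantation", "FN_postimplantation")]),
      numeric(1))
  }
  expect_true(all(diff(fn) <= 0))
})

test_that("classic false positives are serum-only and increase with age", {
  p <- default_parameters()
  ages <- list(list(type = "uniform", min = 30, max = 39),
               list(type = "uniform", min = 45, max = 54),
               list(type = "uniform", min = 55, max = 64))
  fp_serum <- fp_urine <- numeric(3)
  for (i in 1:3) {
    ds <- trial_design(2000, ages[[i]], assay = "serum_quantitative")
    du <- trial_design(2000, ages[[i]], assay = "urine_qualitative")
    fp_serum[i] <- run_monte_carlo(ds, p, n_reps = 3,
                                   seed = 8)$rates["FP_classic"]
    fp_urine[i] <- run_monte_carlo(du, p, n_reps = 3,
                                   seed = 8)$rates["FP_classic"]
  }
  expect_true(all(fp_urine == 0))
  expect_true(all(diff(fp_serum) > 0))
})

test_that("pregnancy counts order across contraception scenarios", {
  p <- default_parameters()
  pregs <- vapply(c("none", "population_mix", "highly_effective_only"),
                  function(sc) {
    d <- trial_design(2000, young_uniform, scenario = sc)
    run_monte_carlo(d, p, n_reps = 3, seed = 17)$n_pregnancies
  }, numeric(1))
  expect_true(pregs[1] >= pregs[2] && pregs[2] >= pregs[3])
})

test_that("cycle-timed testing lowers false negatives; LH timing is steadiest", {
  p <- default_parameters()
  d <- trial_design(4000, young_uniform,
                    schedule = list(type = "periodic", interval_days = 28),
                    assay = "urine_qualitative")
  te <- timing_effect(d, p, n_reps = 40, seed = 19)
  fn <- stats::setNames(te$fn_rate, te$policy)
  expect_gte(fn["random"], fn["timed_to_expected_menses"])
  expect_gte(fn["timed_to_expected_menses"], fn["post_LH"])
  v <- stats::setNames(te$first_test_gest_var, te$policy)
  expect_equal(names(which.min(v)), "post_LH")
})

test_that("the deterministic engine matches Monte Carlo within 3 standard errors", {
  p <- default_parameters()
  d <- trial_design(4000, young_uniform, duration = 182)
  ex <- expected_outcomes(d, p)
  n_reps <- 200
  set.seed(55)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  cats <- pregsim:::outcome_categories()
  counts <- matrix(0, n_reps, length(cats), dimnames = list(NULL, cats))
  for (r in seq_len(n_reps)) {
    stream <- pregsim:::simulate_stream(d, p, seed = rep_seeds[r])
    counts[r, ] <- pregsim:::evaluate_design(stream$cohort, stream$episodes,
                                             d, p, list(d$assay))[[1]]$counts
  }
  rates <- 1e4 * counts / d$n_women
  mc_mean <- colMeans(rates)
  mc_se <- apply(rates, 2, stats::sd) / sqrt(n_reps)
  for (cat in cats) {
    expect_lt(abs(ex$rates[cat] - mc_mean[cat]),
              3 * mc_se[cat] + 0.01,
              label = paste("expected-vs-mc rate for", cat))
  }
})

test_that("the deterministic engine refuses unsupported modes", {
  p <- default_parameters()
  d <- trial_design(100, young_uniform, timing_policy = "post_LH")
  expect_error(expected_outcomes(d, p), "random")
  noisy <- assay_spec("n", "serum", "quantitative", 2, 5, cv = 0.2)
  d2 <- trial_design(100, young_uniform, assay = noisy)
  expect_error(expected_outcomes(d2, p), "cv = 0")
})
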
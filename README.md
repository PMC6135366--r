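# pregsim

Simulating pregnancy-test outcomes in clinical trials.

Trials exclude pregnant women with hCG pregnancy tests at screening and
during follow-up, but no testing plan is perfect: a conceptus produces no
hCG for the 8–10 days between conception and implantation, serum
concentrations lead urine, pituitary hCG around menopause can exceed a
low serum cutoff, and 15–20% of conceptions are chemical pregnancies that
make hCG briefly and are lost before the expected menses. `pregsim` is
for trial designers, sponsors and statisticians who need the expected
consequences of a specific plan in numbers: per 10,000 women, how many
true/false negatives, classic (pituitary) and biological
(chemical-pregnancy) false positives, and indeterminate results — and how
many unintended embryo/fetal exposures a different assay or schedule
would prevent.

## The model

Each simulated woman has an age-dependent reproductive status
(hysterectomy / menopause / infertile / reproductive potential), a
contraceptive method, a menstrual cycle (lognormal length, 14-day luteal
phase) and a baseline hCG. Per cycle she conceives with probability

```
p = fecundability(age) × [1 − (1 − annual typical-use failure)^(1/13)]
```

Conceptions implant 8–10 days later and are fated: very early loss
(17.5%), clinical miscarriage (10%), or ongoing. Serum hCG is 0 before
implantation, then rises exponentially (initial level lognormal, median
4 IU/L; doubling time lognormal, median 1.5 d), plateaus near 8 weeks,
and clears with a 1.5-day half-life after a loss; urine = ratio × serum
(ratio ≤ 1, median 0.85). An assay calls positive at its cutoff
(defaults: urine 25 IU/L, serum qualitative 10 IU/L, serum quantitative
5 IU/L with a [2, 5) indeterminate band) and each call is adjudicated
against truth at the moment of testing. Two engines produce the tallies:
Monte Carlo (`run_monte_carlo`, percentile intervals, paired
common-random-number assay comparison via `compare_specs`) and a
closed-form expectation engine (`expected_outcomes`) for randomly timed
testing. Every parameter ships in a documented YAML table
(`default_parameters()`), with provenance noted value by value.

## Worked example

A 12-month trial, 10,000 women aged 25–34, population-mix contraception,
screening plus quarterly follow-up with a quantitative serum assay
(cutoff 5 IU/L):

```r
library(pregsim)
design <- trial_design(
  n_women  = 10000,
  age_spec = list(type = "uniform", min = 25, max = 34),
  duration = 365,
  scenario = "population_mix",
  schedule = list(type = "periodic", interval_days = 91),
  assay    = "serum_quantitative")
run_monte_carlo(design, default_parameters(), n_reps = 50, seed = 2026)
#> <outcome_tally> mc (50 reps) - 10000 women
#>                        count per_10k_women    lower    upper
#> TP                     31.88         31.88    20.68    40.00
#> TN                  49754.94      49754.94 49715.67 49803.42
#> FN_preimplantation     11.22         11.22     6.22    16.00
#> FN_postimplantation     0.06          0.06     0.00     1.00
#> FP_classic              0.00          0.00     0.00     0.00
#> FP_biological           1.86          1.86     0.00     4.00
#> IND                     1.08          1.08     0.00     3.00
#> tests: 49801 | pregnancies: 89.54 | unintended exposures: 92.02
```

Read: ~90 pregnancies occur per 10,000 women-years in this cohort; the
serum test catches ~32 at a scheduled visit (the rest are recognized by
symptoms first or conceive too late to be tested again); ~11 tests per
10,000 women are unavoidable false negatives in the pre-implantation
window; classic false positives are absent in this young cohort (they
appear with serum cutoff 5 as the cohort ages), and ~2 per 10,000 are
biological false positives from chemical pregnancies.

How much worse would a urine test be? A paired comparison on the same
simulated women:

```r
a <- default_assays()
compare_specs(design, a$urine_qualitative, a$serum_quantitative,
              n_reps = 50, seed = 2026)
#>              category difference  lower  upper
#> ...
#> 8            FN_total       4.10  1.000  9.775
```

The urine test produces ≈4 more false negatives per 10,000 women than
the quantitative serum test — a small absolute difference, which is the
central design insight this class of model delivers. `timing_effect()`
quantifies the companion effect: testing at calendar dates (random with
respect to the cycle) yields the most false negatives, menses-timed
testing fewer, and testing 15 days after an observed LH surge the
fewest, with the tightest timing of detection attempts.

There is also a command line (`inst/cli/pregsim`) with subcommands
`simulate | expect | compare | timing`, driven by a YAML config
(schema in `inst/schema/config-schema.json`):

```sh
Rscript inst/cli/pregsim simulate --config my_trial.yaml --seed 1 --out results/
```

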
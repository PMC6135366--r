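---
title: "Simulating pregnancy-test outcomes in clinical trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pregnancy-test outcomes in clinical trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregsim)
```

## The problem

Clinical trials exclude pregnant women to avoid unintended embryo or
fetal exposure to study drugs, and they do so with hCG pregnancy tests at
screening and often periodically afterwards. No test makes this risk
zero: a conceptus produces no hCG for the 8–10 days between conception
and implantation, so any test in that window is negative; after
implantation, detection depends on the assay's threshold, the specimen
(serum concentrations lead urine), and when in the menstrual cycle the
test happens. Conversely, tests can be positive without a viable
pregnancy: low-level pituitary hCG around and after menopause can exceed
a 5 IU/L serum cutoff ("classic" false positives), and conceptions
destined to be lost before the expected menses — chemical pregnancies,
15–20% of all conceptions — produce real hCG for a few days ("biological"
false positives). Protocol designers must weigh false negatives (missed
pregnancies, i.e. exposures) against false positives and indeterminate
results (delays, withdrawals, participant distress) when choosing an
assay and a testing schedule.

`pregsim` quantifies that trade-off. It simulates a trial cohort woman by
woman — or computes the same quantities in closed form — and tallies every
test as TP, TN, FN (pre- or post-implantation), FP (classic or
biological), or indeterminate, along with pregnancies and unintended
exposures, per 10,000 women.

## Model structure

The model composes five pieces.

**Cohort.** Each woman gets an age from the design's age distribution; a
reproductive status drawn from age-banded prevalences in a fixed
precedence order (hysterectomy, then menopause, then
infertility/subfecundity, then "female of reproductive potential", FRP);
a contraceptive method (scenario: none, population mix, or highly
effective methods only); a menstrual cycle (lognormal length, median
28 d, fixed 14-day luteal phase, uniform phase at enrollment); a fixed
non-pregnant baseline serum hCG (pituitary-type for menopausal women);
and a subject-specific urine:serum hCG ratio.

**Conception.** At each ovulation (cycle day `length − 14`) an FRP woman
conceives with probability `fecundability(age) × q(method)`, where
`q = 1 − (1 − annual typical-use failure)^(1/13)` is the method's
per-cycle breakthrough probability (`q = 1` with no method). A conception
implants 8–10 days later (uniform) and is fated at the outset: very early
loss before the expected menses (17.5%), clinical miscarriage on days
15–84 (10%), or ongoing. After an undetected loss, menses restarts on the
loss day and cycling resumes; at most one episode is active at a time.
Pregnancies that reach a missed menses may also be recognized without
testing: at each missed-menses boundary with per-cycle probability 0.5,
which ends the woman's testing.

**hCG kinetics.** The conceptus contributes exactly zero serum hCG before
implantation; from implantation the level rises exponentially from a
lognormal initial level (median 4 IU/L) with a lognormal doubling time
(median 1.5 d), plateaus at the peak (~8 weeks after conception), and
after a loss decays with a 1.5-day half-life (zero after a 14-day
clearance lag). Urine hCG is the subject's ratio (lognormal median 0.85,
capped at 1) times serum.

**Assay.** A test measures the specimen concentration (optional
multiplicative lognormal noise, `cv`), then calls positive at or above
the cutoff, indeterminate within the band if one is defined, negative
otherwise. Bundled specs: urine qualitative 25 IU/L; serum qualitative
10 IU/L; serum quantitative cutoff 5 IU/L with indeterminate band
[2, 5) IU/L. Calls are adjudicated against truth *at the moment of
testing*: positives on a viable pregnancy are TP; on an early-loss-destined
(or recently lost, not yet cleared) implantation, FP biological; on a
non-pregnant woman, FP classic. Negatives before implantation are FN of
the unavoidable kind; negatives on a viable pregnancy after implantation
are ordinary FN; negatives on an early-loss-destined implantation are
counted TN — the mirror image of the biological-false-positive
convention, since such a conception never becomes a clinical pregnancy.

**Trial.** Every woman is tested at screening (day 0); screen-positive
women are not enrolled. Enrolled women are tested per the schedule
(default: every 91 days for 12 months) until a positive test or symptom
recognition ends their testing; undetected losses return the woman to the
risk pool. Cohorts enter with a 60-day conception burn-in and no
pre-study symptom recognition, so screening sees realistic prevalent
early pregnancies. An *unintended exposure* is an episode with at least
one on-study day pregnant and undetected while enrolled.

## Test timing policies

Follow-up tests can be scheduled three ways. `random`: at fixed calendar
days, i.e. at a uniformly random cycle phase. `timed_to_expected_menses`:
each follow-up is deferred to the next menses predicted as "last observed
menses + 28 days", so the test misses the woman's true cycle by the
single-cycle error `28 − L` (sd ≈ 2.2 d). `post_LH`: the test is placed
15 days after the observed LH surge, which (with ovulation one day after
the surge and a 14-day luteal phase) lands exactly at the true expected
menses, 14 days post-conception — the timing with the least variability
in when detection is attempted. Random timing produces the most false
negatives because tests frequently fall in the pre-implantation and
early-rise windows; `timing_effect()` quantifies the ordering.

## Parameters that matter, and where the defaults come from

The bundled table (`inst/extdata/parameters.yaml`, loaded by
`default_parameters()`) documents provenance line by line. Two kinds of
values appear:

* **Literature values**: typical-use contraceptive failure (e.g. pill 9%,
  condom 13%, IUD 0.8% per year; Trussell 2011), the 8–10 day
  implantation window, the 15–20% chemical-pregnancy rate (default
  17.5%), cycle length variability, pituitary hCG in menopause
  (lognormal, median 2 IU/L, capped just below 20 IU/L so urine tests at
  20–25 IU/L are immune to it).

* **Calibrated values**: quantities no single publication pins down —
  the hCG initial level and doubling time, the urine:serum ratio, the
  age-band fecundability gradient and method-mix weights. These were
  fixed once, analytically, before the simulator was written, so that
  the model jointly reproduces the benchmark behaviors published for
  this class of screening calculator: (i) just over half of ongoing
  pregnancies exceed a 25 IU/L urine threshold on the expected-menses
  day (the model gives ≈62%, consistent with home-test performance
  studies); (ii) the paired serum-vs-urine false-negative difference over
  a 12-month screening-plus-quarterly design is ≈5 per 10,000 women in a
  25–34 cohort and ≈3 per 10,000 in a 40–49 cohort. The back-of-envelope
  form of the derivation: the FN difference per woman is approximately
  `FRP share × fecundability × mix-weighted per-cycle breakthrough ×
  (1 − early-loss share) × w × (1/28 + 13/interval)`, where
  `w = doubling time × log2((urine threshold / urine ratio) / serum
  negative bound)` ≈ 5.8 days is the window in which serum has crossed
  its bound but urine has not. Requiring ≈5 and ≈3 per 10,000
  simultaneously forces the population mix to contain no "no-method"
  share (as trials mandate contraception) and a fecundability gradient
  at the shallow end of published estimates for ages 40–49 (0.13/0.09
  per cycle); both choices are recorded in the table's comments. The
  bundled mix is therefore a distribution over methods *in use*; custom
  tables may include a `none` share and the code honors it.

Everything else a user varies sits in `trial_design()`: cohort size, age
distribution, duration, scenario, schedule, timing policy, and the assay.

## The expectation engine

`expected_outcomes()` reproduces the Monte Carlo averages in closed form
for randomly timed testing with noise-free assays. It marginalizes
exactly over status, method, cycle length (5 midpoint-quantile nodes
rounded to whole days), cycle phase (a 1-day probability-mass vector
propagated day by day), conception day, implantation delay, fate
(clinical-miscarriage loss days pooled into 7 buckets), doubling time
(8 nodes) and urine ratio (6 nodes), with the initial hCG level
integrated in closed form. Two structural facts keep the sequential
logic exact within a quadrature node: given the nodes, every test call
is a threshold rule on the (shared) initial level, so "first positive
test" events are nested intervals; and symptom recognition is
independent of the level. Deliberate approximations, all documented
here and harmless at the scale of Monte Carlo noise: episode
day-offsets are evaluated at day + 0.5 (midpoint of the continuous
conception time within a tap day); a woman resuming after an undetected
loss re-enters cycling after the clearance lag, which can skip one
ovulation when her cycle is shorter than 28 days; premenopausal baseline
hCG (median 0.05 IU/L) is neglected against thresholds of 2 IU/L and
above (its mass above 2 IU/L is ~2×10⁻⁶); and post-loss residual tests
are treated as independent of pre-loss tests, exact for test intervals
of 28 days or more since at most one test can fall inside an episode's
sensitive window. The engine refuses cycle-timed policies and noisy
assays rather than approximate them.

A standing cross-check (in the test suite) requires every expected rate
to sit within three Monte Carlo standard errors of a 100–200 replicate
simulation of the same design.

## What the generator does and does not emulate

The synthetic cohort reproduces the population features that drive test
outcomes: the age gradients of reproductive potential and fecundability,
typical-use contraceptive failure, cycle-length variability, the
implantation delay, chemical-pregnancy kinetics, pituitary hCG, and the
urine/serum gap. It does not model hCG variant chemistry (nicked hCG,
β-core fragment, hyperglycosylated forms — assays are an effective
threshold, so hook-type false negatives at ~8 weeks are out of scope),
interfering antibodies or exogenous hCG (available only as a hook for an
additive classic-FP rate), multiple gestation, cycle irregularity beyond
a stationary lognormal, attribution of losses to the study drug, or
individual-level risk prediction. Passing tests therefore demonstrate
internal consistency and agreement with the population-level benchmarks
above — not subject-level accuracy for any particular trial population.

## Numerical and design choices

* Problem sizes: the test suite runs cohorts of 2,000–10,000 women and
  up to 200 replicates; the headline comparisons use 10,000 women × 200
  paired replicates, which stabilizes rate differences to ~0.1 per
  10,000.
* Common random numbers: `compare_specs()` evaluates both assays on the
  same simulated women, episodes and trajectories (and shared noise
  draws when `cv > 0`), so a self-comparison is exactly zero and
  serum-vs-urine differences have low variance.
* Reproducibility: one master seed spawns per-replicate seeds;
  identical seed and configuration give bit-identical cohorts and
  tallies. Reports embed the seed, a configuration hash and the
  parameter-table version.
* Degenerate inputs: zero women, zero duration and screening-only
  schedules are exact special cases (a zero-duration screening design
  performs exactly one test per woman); empty eligible method sets and
  ages outside the band coverage raise errors naming the offending
  configuration.
* Tie-breaks: a test scheduled on the day symptoms are recognized still
  happens; a test on the conception day itself precedes the (within-day)
  conception; screening indeterminates enroll.
* The menopause-certainty bound (age 60) absorbs the last age band:
  menopause prevalence 1 by convention, other statuses 0.

## Known limitations

Cycle-timed policies use each woman's enrollment cycle anchor; losses
during the study shift her true cycle slightly, which blurs timed
policies by a few days at most. The exposure metric counts episodes with
any undetected pregnant day, not exposure-days or trimester windows. The
expectation engine's clinical-miscarriage bucketing coarsens loss-day
timing by ±5 days, visible only in the biological-false-positive tail.
The calibrated fecundability at 40–49 is deliberately at the high end of
the literature (see above); users studying older cohorts specifically
should substitute their own age table via `load_parameters()`.
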
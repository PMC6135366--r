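# pregsim bundled default parameter table
#
# This table holds the epidemiologic and hCG-kinetic inputs of the
# pregnancy-testing outcome model. Each block notes its provenance:
# LITERATURE (standard published values, citation given), or CALIBRATED
# (fixed analytically so the model reproduces the headline outputs
# published for this class of trial-screening calculator: serum-vs-urine
# false-negative differences of ~5/10,000 women in a 25-34 cohort and
# ~3/10,000 in a 40-49 cohort; >50% of ongoing pregnancies detectable by a
# 25 IU/L urine test on the expected day of menses; 15-20% of conceptions
# ending in very early loss). Calibration was performed once,
# analytically, before the simulator existed; see the methods vignette
# for the derivation.
version: "1.0"

# --- Age bands -------------------------------------------------------------
# Quinquennial bands from 18 to 60 (initial band 18-24); menopause is
# certain from age 60 so the last band is absorbing. Prevalences of
# hysterectomy / menopause / infertility-subfecundity are applied in that
# precedence order (mutually exclusive absorbing states).
# Provenance: shapes follow NSFG/NHANES-style population prevalence
# gradients (hysterectomy: Whiteman 2008; natural menopause median ~51 y:
# Gold 2011; infertility prevalence: Chandra 2013). Fecundability declines
# with age (Dunson 2002); the 40-49 values sit at the upper end of the
# published range - the published model's 5:3 ratio of FN differences
# between the 25-34 and 40-49 cohorts requires the shallow gradient
# (CALIBRATED).
age_bands:
  - {lower: 18, upper: 24, hysterectomy: 0.002, menopause: 0.000, infertile: 0.04, fecundability: 0.220, mix: young}
  - {lower: 25, upper: 29, hysterectomy: 0.010, menopause: 0.000, infertile: 0.05, fecundability: 0.200, mix: young}
  - {lower: 30, upper: 34, hysterectomy: 0.025, menopause: 0.000, infertile: 0.06, fecundability: 0.170, mix: young}
  - {lower: 35, upper: 39, hysterectomy: 0.050, menopause: 0.005, infertile: 0.07, fecundability: 0.150, mix: mid}
  - {lower: 40, upper: 44, hysterectomy: 0.080, menopause: 0.010, infertile: 0.08, fecundability: 0.130, mix: mid}
  - {lower: 45, upper: 49, hysterectomy: 0.120, menopause: 0.040, infertile: 0.10, fecundability: 0.090, mix: mid}
  - {lower: 50, upper: 54, hysterectomy: 0.180, menopause: 0.450, infertile: 0.30, fecundability: 0.015, mix: older}
  - {lower: 55, upper: 59, hysterectomy: 0.200, menopause: 0.900, infertile: 0.50, fecundability: 0.003, mix: older}
  # menopause is certain from 60: it absorbs the band regardless of other
  # conditions, so its prevalence is 1 and the others are 0 by convention
  - {lower: 60, upper: 120, hysterectomy: 0.000, menopause: 1.000, infertile: 1.00, fecundability: 0.000, mix: older}

# --- Contraceptive methods -------------------------------------------------
# Typical-use annual failure probabilities (Trussell 2011, Contraception
# 83:397-404; "none" = no method, 85%/year). highly_effective methods have
# annual typical-use failure <= 1% (LITERATURE).
methods:
  - {name: none,          annual_typical_failure: 0.850,  effectiveness_class: none}
  - {name: condom,        annual_typical_failure: 0.130,  effectiveness_class: moderately_effective}
  - {name: pill,          annual_typical_failure: 0.090,  effectiveness_class: moderately_effective}
  - {name: injectable,    annual_typical_failure: 0.060,  effectiveness_class: moderately_effective}
  - {name: iud,           annual_typical_failure: 0.008,  effectiveness_class: highly_effective}
  - {name: implant,       annual_typical_failure: 0.0005, effectiveness_class: highly_effective}
  - {name: sterilization, annual_typical_failure: 0.005,  effectiveness_class: highly_effective}

# --- Method mix by age group (population_mix scenario) ----------------------
# Distribution over methods *in use* among trial-eligible women (trials
# mandate contraception, so the bundled mix carries no "none" share; a
# custom table may include one). Shape follows NSFG current-use patterns
# (more sterilization with age); absolute weights CALIBRATED jointly with
# fecundability to the published FN differences.
method_mix:
  young: {pill: 0.30, condom: 0.12, injectable: 0.06, iud: 0.28, implant: 0.12, sterilization: 0.12}
  mid:   {pill: 0.24, condom: 0.12, injectable: 0.03, iud: 0.20, implant: 0.04, sterilization: 0.37}
  older: {pill: 0.08, condom: 0.15, injectable: 0.00, iud: 0.15, implant: 0.00, sterilization: 0.62}

# --- Menstrual cycle ---------------------------------------------------------
# Cycle length lognormal, median 28 d, sdlog 0.08 (sd ~2.2 d; Chiazze 1968);
# fixed 14-day luteal phase, consistent with testing 15 days after the LH
# surge falling one day past the expected menses (LITERATURE).
cycle:
  length_median_days: 28
  length_sdlog: 0.08
  luteal_days: 14
  cycles_per_year: 13

# --- Conception and pregnancy fate ------------------------------------------
# Very early ("chemical") loss affects 15-20% of conceptions; default 17.5%
# is the midpoint (LITERATURE: Wilcox 1988, Zinaman 1996). Clinical
# miscarriage of recognized pregnancies ~10-15%; default 10% of conceptions
# (LITERATURE). Implantation 8-10 days after conception, uniform
# (LITERATURE: Wilcox 1999). Early losses complete before the expected
# menses (day 14 after conception); clinical losses occur 15-84 days after
# conception, uniform (reconstruction).
pregnancy:
  early_loss_prob: 0.175
  clinical_miscarriage_prob: 0.10
  implantation_delay_days: [8, 10]
  early_loss_day_range: [11, 13]
  clinical_loss_day_range: [15, 84]
  symptom_prob_per_cycle: 0.5   # per missed-menses probability a pregnancy is recognized without testing (reconstruction)

# --- hCG kinetics ------------------------------------------------------------
# Serum hCG is 0 before implantation, rises exponentially with a
# subject-specific doubling time, plateaus at the peak (~8 weeks after
# conception, i.e. ~10 weeks of gestational age), and decays with a 1.5-day
# half-life after a loss. Initial level at implantation and doubling time
# are CALIBRATED so that >50% of ongoing pregnancies exceed 25 IU/L in
# urine on the expected-menses day (predicted ~62%) while serum detection
# leads urine detection by the window implied by the published FN
# differences.
hcg:
  initial_median_iu_l: 4.0
  initial_sdlog: 0.6
  doubling_median_days: 1.5
  doubling_sdlog: 0.2
  peak_day_post_conception: 56
  peak_level_iu_l: 100000
  clearance_half_life_days: 1.5
  clearance_lag_days: 14
  urine_ratio_median: 0.85
  urine_ratio_sdlog: 0.3
  urine_ratio_max: 1.0

# --- Baseline (non-pregnant) hCG ---------------------------------------------
# Premenopausal baseline is negligible (median 0.05 IU/L). Pituitary hCG in
# menopausal women: lognormal median 2 IU/L, sdlog 0.9, capped at 19.5 IU/L
# so baseline-driven ("classic") false positives arise only for serum
# thresholds in the 5-19 IU/L range and never for urine tests at 20-25
# (LITERATURE: Snyder 2005; cap is a reconstruction).
baseline_hcg:
  frp_median_iu_l: 0.05
  frp_sdlog: 0.8
  pituitary_median_iu_l: 2.0
  pituitary_sdlog: 0.9
  ceiling_iu_l: 19.5

# --- Simulation --------------------------------------------------------------
# Pre-study burn-in so prevalent undiagnosed early pregnancies exist at the
# screening visit; no symptom recognition is applied during burn-in
# (candidates are assumed unaware of a pregnancy before screening).
simulation:
  burn_in_days: 60
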
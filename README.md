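# growthdyn

Growth dynamics and LMS reference analytics for pediatric cohorts.

Children with obesity grow differently from their normal-weight peers, and
the difference reverses across development: they are several centimetres
taller through early and mid childhood, their pubertal growth spurt is
blunted, and their heights converge by late adolescence — a pattern that
matters both for understanding the endocrine coupling of weight and growth
and for clinical height assessment, where the standard references misjudge
a child with obesity. `growthdyn` is for biostatisticians and auxology
researchers who need to run this kind of analysis on longitudinal pediatric
cohorts: it provides the full chain from raw visit tables to referenced,
filtered, tested, and modelled results, plus the machinery to build
population-specific height references.

## What it implements

* **LMS referencing** — Cole's Box-Cox transform between measurements,
  z-scores (SDS) and centiles, `z = ((x/M)^L − 1)/(L·S)`, with sex/age
  reference tables (`measure,sex,age,L,M,S` CSVs) interpolated linearly in
  age; weight-status classification (underweight < −1.28, normal-weight
  [−1.28, 1.28], overweight (1.28, 1.88], obesity > 1.88 BMI SDS) and
  SGA/AGA/LGA birth-size classification.
* **Cohort pipeline** — inclusion filters (height SDS in [−2.5, 4.0], BMI
  SDS ≥ −3.5, preterm children from age 2.0 only, growth-affecting
  disease/medication flags), rounded-age groups with an open "18+" group,
  first-observation-per-group de-duplication, growth velocities from
  consecutive visits (interval 3 months–2 years, mean age ≥ 1.5 y) with
  plausibility filters, and per-age-group Welch t contrasts with
  Holm–Šídák family-wise correction and N < 6 suppression.
* **Growth models** — mid-parental height adjustment in SDS space,
  cross-lagged effect of BMI SDS on next-year height SDS (adjusted for
  current height SDS), a dependency-free REML random-intercept linear
  model, and piecewise age-trend contrasts between weight groups over
  sex-specific age intervals.
* **Endocrine contrasts** — per-analyte age profiles (IGF-1, IGFBP-3,
  testosterone, estradiol, insulin, leptin), HOMA-IR
  (`insulin[mU/l] × glucose[mmol/l] / 22.5`, with explicit pmol/L
  conversion), analyte-specific medication exclusions, and pubertal-window
  percent-reduction summaries.
* **Reference construction** — penalized maximum-likelihood fitting of
  smooth L(t), M(t), S(t) curves (cubic B-splines, curvature penalties,
  EDF-targeted smoothing) with centile-table export, for building e.g.
  obesity-specific height references.
* **Synthetic cohorts** — a seeded generator that plants a configurable
  obesity effect profile (height offset curve, blunted pubertal velocity,
  cross-lagged BMI–height coupling, endocrine multipliers) on
  reference-anchored trajectories, so every estimator can be validated by
  recovering known truth. `effect_profile(null = TRUE)` gives the exact
  null for calibration.

Results come back as tibbles, so everything chains with the pipe; fitted
models have `tidy()`/`glance()` methods and there are `autoplot()`/`plot_*`
helpers for the result types.

## Worked example

Simulate a cohort with the default planted obesity profile, annotate it
against the built-in synthetic reference, and measure the height difference
between the obese and normal-weight strata:

```r
library(growthdyn)

ref    <- default_reference()
cohort <- generate_cohort(
  generator_config(n_normal = 1000, n_obese = 1000, seed = 42),
  effect_profile(), ref
) |> reference_cohort(ref)

cohort
#> <growth_cohort> 2000 children, 26389 observations

filtered <- apply_inclusion_filters(cohort$observations, cohort$children)
filtered$log
#> # A tibble: 6 × 2
#>   rule               n_excluded
#> 1 height_sds_high            23
#> 2 height_sds_low            100
#> 3 bmi_sds_low                 0
#> 4 premature_under_2y         81
#> 5 disease_flag                0
#> 6 medication_flag             0

girls <- dedup_first_per_group(filtered$observations) |>
  subset(sex == "female")
cmp <- compare_groups(girls, "height", "weight_category", "obese", "normal")
max_group_difference(cmp, metric = "absolute", window = c(2, 10))
#> # A tibble: 1 × 2
#>   age_group value
#> 1         9  7.79
```

The exclusion log counts how many visits each eligibility rule removed.
The final line says the largest mean height difference between girls with
obesity and normal-weight girls over age groups 2–10 is 7.8 cm, at age
group 9 — recovering the planted maximum of 7.6 cm (the plateau after the
peak makes neighbouring groups near-ties under sampling noise). The same
pattern holds in SDS (`"height_sds"`, about 1.4 SDS at the peak), and the
velocity contrast on this run shows a 21.6% lower mean growth velocity in
girls with obesity over age groups 12–13 (planted: 22%):

```r
vel <- compute_velocities(filtered$observations, velocity_reference = ref)
vg  <- compare_groups(subset(vel$velocities, sex == "female"),
                      "gv", "weight_category", "obese", "normal")
mean(vg$pct_diff[vg$age_group %in% 12:13])
#> [1] -21.6
```

Real cohort tables are read with `read_cohort()` (children, observations
and optional analyte CSVs) and external LMS references with
`read_lms_reference()`; `analyze_growth()` chains the standard stages and
`write_growth_report()` serialises everything to JSON. See the
`growth-dynamics` vignette for the models, the generator design, and every
numerical choice.

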
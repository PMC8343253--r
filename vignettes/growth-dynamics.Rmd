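---
title: "Modelling growth dynamics across weight strata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth dynamics across weight strata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthdyn)
```

# The scientific problem

Children with obesity grow differently from normal-weight peers, and the
difference changes sign across development: they are taller through early
and mid childhood, their pubertal growth spurt is blunted, and their height
converges back toward the population median by late adolescence. Detecting,
quantifying and referencing this pattern requires a chain of standard
pediatric-auxology machinery — LMS (Box-Cox) referencing, growth-velocity
computation with plausibility filters, per-age-group contrasts with
family-wise error control, cross-lagged regression, mixed models — plus a
way to construct height reference values specific to the obese population.

`growthdyn` implements that chain as composable, data-frame-first functions,
and pairs it with a synthetic cohort generator that *plants* a configurable
obesity effect so that every estimator in the pipeline can be validated by
recovery of known truth. Individual-level cohorts of this kind are not
publicly deposited, so planted-effect recovery on synthetic data is the
package's primary form of end-to-end validation.

# The LMS referencing model

A reference distribution for a measurement $x$ at age $t$ is summarised by
three curves: the Box-Cox power $L(t)$, the median $M(t)$ and the
coefficient of variation $S(t)$. The z-score (SDS) of a measurement is

$$ z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
   z = \frac{\log(x/M)}{S} \quad (L = 0), $$

with the exact inverse $x = M(1 + LSz)^{1/L}$ (or $M e^{Sz}$). Centiles are
$\Phi(z)\cdot 100$. Reference tables are tabulated by sex and age and
interpolated **linearly** in each of $L$, $M$, $S$ between tabulated ages;
linear interpolation (rather than splines) keeps centile values bit-exactly
reproducible from a published table, which is the convention reference
tables are printed under.

Weight status is classified from BMI SDS with the pediatric consensus
cutoffs: underweight $< -1.28$, normal-weight $[-1.28, 1.28]$, overweight
$(1.28, 1.88]$, obesity $> 1.88$. BMI is computed as
$\text{weight[kg]}/\text{height[m]}^2$ before referencing. Birth size is
classified SGA/AGA/LGA against a gestational-age reference; the SDS cutoffs
default to $\pm 1.28$ (about the 10th/90th centile). That default is a
package convention — different registries use $\pm 1.28$ or the 10th/90th
centile of their own reference — and it is configurable rather than asserted
as universal.

# Cohort preparation

The inclusion window keeps observations with height SDS in $[-2.5, 4.0]$
and BMI SDS $\ge -3.5$; children flagged with growth-affecting disease or
medication are excluded entirely; children born before gestational week 38
contribute observations only from age 2.0 years (by which age preterm
children are expected to have caught up in height). Metformin and thyroxin
flags are narrower: they remove a child only from insulin/HOMA-IR and
thyroid-hormone analyses respectively, not from anthropometry. Every rule
is a pure predicate of one observation plus its child's attributes, so the
result is independent of evaluation order, and the exclusion log counts
each rule's hits.

Ages are grouped by rounding: group $g$ covers $[g-0.5, g+0.5)$ years,
everyone at or above 17.5 years forms the open-ended "18+" group, and ages
under 0.5 form group 0 (the rounding convention extended downward; the
youngest tabulated group in the field's presentations starts at 0.5, but
infants below that age still need a bin). Internally groups are coded as
integers 0–18 — which keeps the cross-lag "group $g+1$" arithmetic trivial —
and `age_group_label()` renders the conventional "18+" string for display.
Within each (child, group) cell only the first (youngest) observation is
kept, so the per-group contrasts are cross-sectional.

Growth velocity between consecutive visits is $(h_2-h_1)/(t_2-t_1)$ in
cm/year at the mean age of the interval, computed only for intervals of
3 months to 2 years and mean ages $\ge 1.5$ years, with implausible records
excluded: negative velocities, velocities under 1 cm/year before mean age
14 (children are expected to grow at least 1 cm/year until then), and
velocity SDS above 10. The record's weight category is taken from the
earlier observation of the pair by default; the alternative — the child's
first-ever visit — is available by argument, since either reading of "first
anthropometric observation" is defensible. Consecutive means consecutive:
visits 1–2 and 2–3 both form records, but 1–3 does not.

# Contrasts and multiplicity

Per age group, group means are compared with unpaired t-tests — Welch by
default, since equal variances between weight strata is not a defensible
assumption and the pooled test is available by argument — followed by
Holm–Šídák step-down adjustment. The correction family is the set of
non-suppressed age groups within one outcome-by-sex panel, matching how
per-panel significance marks are conventionally displayed; strata with
fewer than 6 observations in either group are suppressed (descriptives
reported, no test, excluded from the family). The headline summaries are
the extremum of the absolute or percent difference over a window of age
groups, with ties broken toward the youngest group.

# Cross-lagged effect and mixed models

The prospective effect of weight on growth is estimated per age group $t$
by OLS of height SDS at $t+1$ on BMI SDS at $t$, adjusted for height SDS at
$t$; pairs use the first observation in each of two consecutive age groups.
Significance is judged on raw per-age p-values (as such profiles are
conventionally annotated); a Holm–Šídák option across ages exists. When
multiple observations exist in the next age group the first is used — the
natural extension of the first-observation convention.

Age trends of height SDS are modelled piecewise over three sex-specific
intervals of approximately linear trend (boys 2.0–4.99, 5.0–10.99,
11.0–17.0; girls 2.0–8.249, 8.25–10.99, 11.0–17.0), as
`height_sds ~ age * weight_group` with a random intercept per child to
absorb repeated measurements. The covariate model adds mid-parental height
SDS and birth length SDS as fixed additive terms; birth weight SDS and
covariate interactions are deliberately absent — the reduced model is fit
directly rather than re-running an automated step-wise deletion, keeping
the procedure deterministic. Wald t-tests judge the slope-difference term.

The random-intercept fit itself profiles the REML criterion over the single
variance ratio $\theta = \sigma^2_b/\sigma^2_e$ (1-D optimisation on the
log scale, GLS closed form for the fixed effects given $\theta$, boundary
$\theta \to 0$ allowed). This is deterministic, dependency-free, and
cross-checked in the test suite against both a dense-matrix GLS oracle and
`lme4::lmer`.

Mid-parental height is the mean of the two parents' adult height SDS, each
referenced at the oldest tabulated age of the sex-specific reference.
Averaging in SDS space already sex-normalises the parents, so no
centimetre-space Tanner-style $\pm 6.5$ cm correction is applied. One
missing or implausible (outside 120–220 cm) parent degrades gracefully to
the other parent's SDS, flagged.

# Building obesity-specific references

`fit_lms()` estimates smooth $L(t), M(t), S(t)$ curves from cross-sectional
(age, value) data by maximising the penalized Box-Cox log-likelihood

$$ \sum_i \left[ L(t_i)\log\frac{x_i}{M(t_i)} - \log S(t_i) -
   \tfrac12 z_i^2 \right] - \tfrac12 \sum_{c \in \{L,M,S\}} \alpha_c
   \int c''(t)^2 \, dt $$

over cubic B-spline coefficients, by cyclic quasi-Newton updates of the
three curves with step halving — which guarantees the penalized
log-likelihood is non-decreasing across iterations. $M$ and $S$ are
modelled on the log scale so positivity holds by construction.
Initialisation is deterministic ($L \equiv 1$, running-median smooth for
$M$, running-CV smooth for $S$), so a fit is reproducible from data plus
configuration alone. Smoothness is specified as target equivalent degrees
of freedom; the penalty weight per curve is solved once at initialisation
from the eigenvalues of the penalty against the weighted information.

Two numerical choices matter and were made after measuring alternatives:

* **Knot placement.** Interior knots (20 by default) are spaced densely
  toward infancy (power-1.5 spacing of the age range) rather than at
  empirical age quantiles: height medians bend hardest below age 2, and
  quantile knots on a roughly uniform age distribution cannot resolve that
  bend regardless of the penalty.
* **Median freedom.** The defaults give the median curve generous freedom
  (EDF 18) and keep $L$ (EDF 3) and $S$ (EDF 4) stiff. Because the package
  deliberately fits on the raw age axis (no age-power transformation of the
  time axis), the strong infancy curvature must be carried by the spline
  itself; a heavily penalized median (EDF around 6) cuts the infancy corner
  by 2–3 cm. With the defaults, recovery tests show a maximum median error
  of about 0.6 cm over ages 1–17 and empirical coverage below the fitted
  P3 of 2.9–3.1% at $n = 10{,}000$.

Reference construction conventionally uses one randomly selected
observation per child (`sample_one_per_child()`) to avoid over-weighting
frequently measured children. Fitted curves export via `centile_table()`
and `as_lms_reference()`, so a fitted obesity-specific reference is
immediately usable for SDS annotation.

Fitted curves are validated by recovery and coverage properties rather than
against any published table: the smoothing parameters of the national
references this mirrors are not published, so numerical agreement with them
is not a testable property.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions under which the pipeline's recovery properties are stated.

**Built-in reference.** A self-contained synthetic reference set anchors
everything: height-for-age with $L \equiv 1$, $S \equiv 0.042$ and a
monotone-cubic median through sex-specific knots (50 cm at birth to 177 cm
for boys, 49.5 to 164 cm for girls); velocity-for-age as the derivative of
the height median with a reference SD of 1 cm/year; a plausible BMI median
curve with $S = 0.11$; and birth length/weight linear in gestational age
(SD 2 cm / 450 g). The knots are calibrated so that $M \cdot S$ — the cm
value of one SDS — is about 4.87 cm for boys at age 6 and 5.38 cm for girls
at age 8, which makes the planted centimetre and SDS height differences
mutually coherent (6.8 cm $\approx$ 1.4 SDS for boys at 6; 7.6 cm
$\approx$ 1.4 SDS for girls at 8). The shapes mimic national growth
references without reproducing any published values.

**Planted obesity offset.** The obese stratum's mean height differs from
the reference by a constructed curve $D(t)$ in centimetres: a small birth
offset (0.5 cm boys, 0.7 cm girls); an early-childhood velocity surplus
ramping to 1.2 cm/year, whose ramp length is solved so that
$D(a_{\max}) = D_{\max}$ exactly (6.8 cm at age 6 for boys, 7.6 cm at age 8
for girls); a plateau; then catch-down. Over the group-aligned pubertal
window (boys' age groups 13–14, girls' 12–13) the decline is shaped so the
obese mean velocity is *exactly* the planted ratio (0.75 boys, 0.78 girls)
times the reference velocity — aligning the constraint to the age-group
boundaries means the per-group velocity contrast carries the planted
percent reduction without discretisation bias. Outside the window the
remaining decline is spread linearly so that $D$ at the convergence age
(17) equals a small residual (0.3 cm $\le$ 0.5 cm). The offset velocity is
piecewise linear, making $D$ continuous and piecewise smooth; smoothness of
higher order at the phase joins would not change any of the integral
constraints the recovery tests measure. Planting the effect in centimetres
(not SDS) is deliberate: the SDS difference then follows as $D/(M S)$
through the calibrated reference, keeping both acceptance scales coherent.

**Latent height process.** Each child has a height-SDS intercept
$u \sim N(0, 0.95^2)$ and an annual latent update

$$ h_{j+1} = a_j\, h_j + \gamma(t_j)\,(b_j - \mu_{\text{stratum}}) +
   \varepsilon_j, $$

where $b_j$ is the child's BMI SDS (stratum-specific truncated normal with
AR(1) persistence 0.9 across visits), $\gamma(t)$ is the planted cross-lag
coefficient, and $a_j$ is solved per step so the marginal SD of $h$ stays
at 0.95 across age. Two design points deserve emphasis:

* $\gamma$ operates on the *within-stratum* BMI deviation, so the
  stratum-level offset $D(t)$ and the individual-level coefficient are
  separately identifiable — otherwise the height-difference and cross-lag
  recoveries would confound each other.
* The innovation $\varepsilon_j$ is specified as **1.0 cm** — the velocity
  reference SD — converted to SDS at the child's age via $M \cdot S$
  (about 0.3 SDS in infancy, about 0.15 SDS in adolescence). An
  age-constant SDS innovation would imply about 2 cm/year of velocity
  noise at pubertal ages, twice the generator's own velocity reference SD,
  and the asymmetric truncation by the "velocity $\ge$ 1 cm/year" filter
  would then bias the measured pubertal velocity reduction several
  percentage points toward zero. Tying the innovation to the velocity
  reference keeps the generator internally consistent; at the young ages
  where the cross-lag recovery is evaluated the innovation is ~0.3 SDS, so
  the cross-lag noise conditions are unchanged.

With stationary variance, OLS of measured height SDS at $t+1$ on
$\{1, \text{BMI SDS}_t, \text{height SDS}_t\}$ recovers $\gamma(t)$ without
omitted-variable bias in a single-stratum cohort. In a mixed cohort the
estimator additionally absorbs the age-varying stratum offset $\Delta
D/(MS)$ through the group–BMI correlation — a property of the estimator
(which, as in conventional practice, carries no weight-group term), not of
the generator — so the cross-lag recovery test uses a normal-weight-only
cohort, which the stratum-size configuration makes a first-class study
design.

**Cross-lag profile.** $\gamma(t)$ is piecewise linear: $+0.18$ at age 1,
declining through zero near age 10.5 (boys) / 9.5 (girls), a trough of
$-0.10$ at 14 (boys) / 11 (girls), recovering slightly by 17. The girls'
zero crossing follows the earlier female pubertal timing.

**Visit schedule.** First visit uniform on 0.5–4 years, then annual visits
jittered by $\pm$0.15 years up to age 18; each non-initial visit is
retained independently with probability 0.8 ("per-visit retention" read as
visit-level missingness, not geometric dropout — the emulated registries
follow children across the whole age span with irregular attendance). A
premature fraction of 8% receives gestational ages 32–37 and, through the
gestational-age reference, smaller birth size. Heights are emitted with
0.3 cm measurement error; weights are derived from the latent BMI so that
re-deriving BMI downstream is exact. BMI truncation bounds sit 0.01 SDS
inside the category cutoffs so that rounding of emitted heights cannot
flip a child's weight category.

**Endocrine panel.** Analyte values are age/sex mean curves (plausible
textbook shapes — an IGF-1 pubertal peak, logistic testosterone and
estradiol rises, age-increasing insulin and leptin — deliberately *not*
fitted to any published figure) times an obese-stratum multiplier times
log-normal noise with CV 0.35 (mean-one, so group-mean ratios equal the
multiplier). The planted multipliers are step functions aligned to
age-group boundaries: IGF-1 ×1.10 in groups 6–9 and ×0.83 in the pubertal
window; testosterone ×0.38 in the boys' window recovering linearly to ×0.9
by 17; estradiol ×0.63 in girls' groups 15–16; insulin ×2.5 and leptin ×4
throughout. Insulin is stored in pmol/L; the HOMA-IR computation converts
by the factor 6.945 explicitly.

**The null profile** (`effect_profile(null = TRUE)`) zeroes every offset
and sets every multiplier to 1 and $\gamma \equiv 0$; it is the exact
no-effect configuration used for A/A calibration.

# What the synthetic validation does and does not show

Passing recovery tests shows the estimators are correct and unbiased under
the generator's assumptions: Gaussian SDS with reference-anchored means,
visit-level missingness completely at random, weight categories stable
within child, no secular trends, no measurement-protocol drift, and
endocrine noise that is log-normal and independent across visits. Real
registry data violate several of these (informative follow-up, category
migration, assay changes); the pipeline's *filters* address some of that,
but the recovery results should be read as verification of the statistical
machinery, not as evidence about any real cohort. The generator also makes
no attempt to mimic real sample-size imbalances or Tanner-stage timing.

# Study scales used by the validation suite

The packaged tests and the acceptance script use sizes chosen to put
Monte-Carlo noise well inside the stated recovery tolerances: about 4,000
children per stratum per sex for the height/velocity recoveries, 4,000
normal-weight children (first visit 0.5–1.5 years) for the cross-lag
recovery, 1,500 per stratum with analytes for the endocrine recoveries,
10,000 points for reference-construction recovery, and 20 replicates of
1,000 + 1,000 children for null calibration. For the IGF-1 window
reduction — whose planted effect is identical in both sexes — the two
sexes' window cells are aligned by offset and pooled, which halves the
sampling noise of the max-over-groups estimator; testosterone and
estradiol reductions are estimated within the stated sex. The null
calibration's zero-significance rate is asserted with a binomial acceptance
region appropriate to 20 replicates of a 95% event.

# Known limitations

* The LMS fitter targets Box-Cox-normal references only; no
  skewness-kurtosis (BCPE-style) extension, no worm-plot diagnostics, no
  bootstrap bands.
* The mixed models use a single random intercept; no serial correlation
  beyond it, no random slopes, no crossed designs.
* Linear interpolation of reference tables is first-order accurate; tables
  should be tabulated at the resolution at which that is acceptable (the
  built-in reference uses 0.25-year steps).
* The cross-lag estimator is a descriptive prospective association, not a
  causal estimate; in mixed-stratum cohorts it absorbs stratum-level
  trajectory differences as described above.
* `analyte_contrast()` compares raw concentration means (the field's
  plotting convention); a log-scale option exists for heavily skewed
  analytes such as leptin and is off by default.
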
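---
title: "Validating field body-composition methods against a 3C criterion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating field body-composition methods against a 3C criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodycomp)
```

## The problem

Weight-class sports certify a minimum competition weight from a body-fat
estimate: a wrestler's fat-free mass (FFM) is projected to a body-fat floor
(7% for males, 12% for females), and the athlete may not compete below the
resulting minimum wrestling weight (MWW). The body-fat estimate almost always
comes from a field method — a skinfold prediction equation or an impedance
device — whose error propagates directly into the certified weight class.
`bodycomp` provides the machinery to quantify that error against a
three-compartment (3C) criterion: per-athlete composition estimates under
every method, a full agreement-statistics suite, and the weight-class
consequences.

## Models

**Two-compartment conversions.** Densitometry yields whole-body density
$D_b$ (kg/L); fat and fat-free tissue have different densities, so body-fat
percent follows from $D_b$ alone under fixed-composition assumptions:
Siri $BF\% = (4.95/D_b - 4.5)\cdot 100$ and Brozek
$BF\% = (4.57/D_b - 4.142)\cdot 100$. Both assume a constant fat-free-mass
density, which varies with hydration in practice.

**Three-compartment model.** Adding measured total body water (TBW) relaxes
the hydration assumption:
$BF\% = 100\,(2.118/D_b - 0.78\,TBW/BM - 1.354)$. The criterion
configuration takes $D_b$ from underwater weighing and TBW from bioimpedance
spectroscopy; the *field* 3C configuration replaces them with a skinfold
density equation and the Matias single-frequency resistance TBW equation.
TBW in litres is treated as numerically equal to kilograms of water.

**Equation registry.** Every prediction equation is dispatched by id with
its applicability metadata (`equation_registry()`): required skinfold sites,
applicable sex (Stewart male-only; Fornetti, Loftin, Slaughter female-only),
and age strata (Durnin & Womersley is undefined above 29 y and is reported
as `out_of_stratum` there). Sex and race codings differ between sources —
Evans and Matias code male = 1, Devrim-Lanpir codes female = 1, race is 1
for Black athletes where used — and are stored as a data table, not
branches, so they can be audited in one place.

**Composition and MWW.** All estimates are composed as
$FFM = BM(1 - BF\%/100)$, $FM = BM - FFM$, so mass is conserved exactly by
construction. MWW is $(1-BF\%/100)\,BM/0.93$ (males) or $/0.88$ (females);
at the floor itself MWW equals current body mass exactly, which the tests
exploit as a fixed-point identity. Weight-class ladders are configuration
(default: evenly spaced 5.4 kg classes), class upper limits are inclusive,
and MWW is not rounded before lookup unless a federation rounding increment
is requested.

## Agreement statistics and their conventions

All differences are oriented **alternate − criterion**: a positive mean
difference means the field method overestimates. This choice flips the sign
of every Bland–Altman conclusion, so it is pinned here and in the tests.

* **Bland–Altman**: 95% limits of agreement $MD \pm 1.96\,SD_d$; the
  proportional-bias slope is the OLS regression of the difference on the
  per-athlete *mean of the two methods* (not the criterion alone), with a
  two-sided t-test on the slope.
* **Lin's CCC** uses population (1/n) moments, the original convention. The
  choice is visible: for x = (1,2,3), y = (2,3,4) the population convention
  gives 4/7 where n−1 moments would give 2/3; the tests pin 4/7.
* **SEE** is the residual standard error (n−2) from regressing the criterion
  on the alternate. The regression direction is a genuine convention choice;
  criterion-on-alternate answers "how far is the criterion from the best
  linear recalibration of the field method", which is the calibration
  question certification cares about.
* **TOST**: equivalence at margin ±2 kg is declared when the 90% CI
  ($\alpha$ = 0.05 per side) of the mean difference lies inside the margin.
  With zero difference variance the CI is degenerate and the verdict reduces
  to $|MD| <$ margin.
* **RM-ANOVA** across methods treats athlete as the blocking factor
  (listwise-complete across methods), follows up with paired t-tests against
  the criterion and Holm step-down adjustment. No sphericity correction is
  applied; the argument exists as a config hook but only `"none"` is
  implemented.
* **ICC** for technician reliability is the two-way mixed-effects,
  consistency, single-measure form ICC(3,1) with the F-based confidence
  interval. The one-way or absolute-agreement forms would also be defensible
  for caliper triplicates; ICC(3,1) treats replicate position as a fixed
  effect, which matches a single technician re-measuring the same sites.

Every statistic is verified in the test suite against a brute-force
independent implementation (explicit sums, no shared code) on 100 random
datasets to 1e-10, and the worked constants above are frozen from hand
computation.

## The synthetic cohort generator

The study data this pipeline is designed for are not publicly deposited, so
the generator (`generate_cohort()`) emulates the measurement *structure* of
a mixed-sex youth-athlete cohort with known latent truth. Defaults are the
study conditions: 51 female / 40 male athletes aged 14–25
(18.19 ± 2.37 y), height 172.1 ± 9.8 cm, body mass 68.9 ± 14.5 kg, pooled
body fat 19.59 ± 6.9%, FFM hydration fraction 0.732.

Per athlete:

1. Anthropometry is drawn from truncated normals (BM ∈ [40, 130] kg,
   height ∈ [145, 210] cm, BF% ∈ [4, 45]; violations are resampled).
   Pooled body fat is split by sex (female mean + offset/2, male − offset/2;
   default offset 8 points, a typical athletic sex gap) with the per-sex SD
   shrunk so the pooled moments match the configured ones.
2. True FFM follows from true BF%; true TBW is hydration-coupled,
   $0.732 \cdot FFM$ plus biological noise (default SD 0.5 L).
3. True density is solved from the **Siri 3C relation** at the athlete's
   true BF% and true TBW. This makes the criterion model recover truth
   exactly when measurement noise is zero — the key round-trip oracle — and
   keeps density, water and body fat jointly consistent.
4. Resistance is solved by inverting the Matias TBW equation at the true
   water volume; reactance is drawn from a configured normal.
5. Skinfolds are constructed by inverting the *generating equation*
   (default Evans 7-site; any registry equation works, linear equations in
   closed form and the rest by bisection) at the true BF%, spreading the
   aggregate across the 8 sites by a fixed weight vector, then adding
   per-site noise (default 1 mm) and splitting into three replicate readings
   with technician noise (default 0.5 mm — chosen so the replicate ICC lands
   near the high-0.99s reported for experienced technicians).
6. Measured values add device noise: densitometry on the density scale
   (SD 0.002 kg/L, mimicking UWW error; 0.003 for ADP), spectroscopy water
   0.3 L, resistance 5 ohm. Consumer devices emit opaque BF% columns with
   configurable additive/proportional bias and noise (default SD 2 points).

`inject_proportional_bias()` perturbs one method so that the Bland–Altman
regression of (alternate − criterion) on the pair mean has *exactly* the
requested slope against a noise-free criterion, which makes noiseless
recovery testable to machine precision and noisy recovery a calibration
experiment.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: genuine inter-site skinfold covariance (sites are
a scaled weight vector plus independent noise, so no athlete has an unusual
fat distribution); equation disagreement structure (one equation generates
the skinfolds, so the others' biases reflect model-form differences, not
population mismatch); device physics (Cole modelling, electrode placement);
race effects (generated all-non-Black by default; race-sensitive terms are
tested by explicit fixtures); and real measurement-error correlations across
instruments.

## Numerical choices

* Durnin & Womersley logarithm is **base 10** (the original publication's
  convention; the printed equation says bare "log").
* Thorland's printed linear term multiplies three sites, which yields
  wildly nonphysical densities (three 10 mm sites subtract 1.54 kg/L); the
  default `corrected` variant sums them, consistent with the equation's own
  squared term, and `as_printed` is retained for auditability.
* Stewart's printed coefficients (662.7 × BM) give FFM three orders of
  magnitude above body mass; the `corrected` default scales the BM,
  reactance and intercept coefficients by $10^{-3}$, keeping the
  already-kilogram-scale resistance-index term as printed.
* The Wilmore residual-volume formula is evaluated literally as printed
  (dead space subtracted inside the percentage bracket); a
  `dead_space_subtracted` variant subtracts it on the volume scale instead,
  because the printed placement mixes units and the intent is ambiguous.
* The field 3C model's skinfold density source defaults to Jackson &
  Pollock 7-site — a sex-general, widely used equation — and is
  configurable, since the criterion definition does not pin it.
* Equation inversion in the generator uses bisection on the aggregate over
  (0.5, 390) mm at tolerance 1e-10; inversion failures resample the athlete
  with a bounded retry budget.
* Degenerate inputs error loudly (`DegenerateInput`-style messages) rather
  than returning NaN: zero density, TBW outside (0, BM), zero variance in a
  correlation, empty weight-class tables. Constant paired differences leave
  the Bland–Altman slope exactly 0 with an NA p-value (no residual variance
  to test against).
* Weight-class lookup rounds the optionally-rounded MWW to 12 decimals
  before comparison so that federation rounding (e.g. to 0.1 kg) cannot be
  defeated by floating-point representation at a class boundary.
* Skinfold equations always evaluate on replicate-averaged site values at
  full precision; rounding happens only in rendered tables (1 decimal, the
  conventional reporting precision).

## Problem sizes in the test suite

The suite exercises: fixed two-athlete fixtures for every equation; 100
random datasets (n = 5–50) for the statistics-vs-oracle comparison; a
1,000-athlete cohort for exact mass conservation; 1,000 replicates of n = 50
paired differences for TOST calibration; 100 replicates of n = 200 cohorts
with 2 mm site noise for generating-equation rank recovery; 200 replicates
of n = 200 for proportional-bias recovery; and 20,000 draws for generator
moment checks against analytic truncated-normal moments. These sizes give
the property checks comfortable statistical margins while keeping the full
suite around a minute.

## Limitations

* The criterion itself is a model; validating against 3C says nothing about
  3C's own biases (no 4-compartment bone-mineral input exists here).
* Agreement metrics are computed pairwise-complete per method and listwise
  for the ANOVA family; heavily missing data can make the two summaries
  describe different athlete subsets.
* No bootstrap or mixed-effects extensions of Bland–Altman; the regression
  treats athletes as independent.
* The default weight-class ladder is a generic 5.4 kg grid; real
  federation tables should be supplied via `weight_classes` when
  mis-categorization counts are the endpoint.
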
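---
title: "Colony-level nutritional geometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony-level nutritional geometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutgeom)
```

## The scientific problem

Ant colonies forage collectively on chemically complex foods, yet regulate
the blend of macronutrients they actually consume. `nutgeom` implements the
two complementary nutritional-geometry paradigms used to characterize that
regulation in laboratory feeding experiments with whole colonies:

* **2-D protein:carbohydrate (P:C) geometry.** In *choice* experiments a
  colony is offered two complementary imbalanced diets and reveals its
  *intake target* — the (P, C) blend it defends. In *no-choice* experiments
  a colony confined to a single diet can only move along that diet's
  *nutritional rail*, the ray from the origin with slope equal to the
  diet's C:P ratio. Connecting the per-rail intake points gives the
  *intake array*, whose shape reveals the *rule of compromise*: an
  equal-distance (generalist) strategy keeps total intake constant across
  rails (a straight-line array), while a closest-distance (specialist)
  strategy picks the on-rail point nearest the target (a convex array).
* **3-D protein:carbohydrate:lipid (P:C:L) geometry.** Diets varying in the
  energy fraction of three macronutrients are mapped onto the
  *right-angled mixture triangle* (RMT): protein on x, carbohydrate on y,
  and lipid implicit on negative-slope isoclines `x + y = 100 - L`. Colony
  responses measured on a handful of diet compositions are modeled as
  second-degree response surfaces, and visualized as thin-plate-spline
  landscapes whose high-response region delineates the *fundamental
  macronutrient niche* (FMN).

The package also contains a synthetic colony-foraging generator with known
ground truth, so that every analysis stage can be validated end to end
without access to any particular laboratory's raw data.

## Diet systems and their invariants

Two-dimensional diets are standardized by total macronutrient
concentration (default 100 g/L) and manipulate only the P:C ratio; the
standard series is 1:6, 1:3, 1:1, 3:1, 6:1. Three-dimensional diets are
standardized by total energy (default 675 J) and manipulate the fraction
of that energy contributed by each macronutrient; the standard series is
33:33:33, 80:10:10, 10:80:10, 10:10:80, 45:45:10, 10:45:45, 45:10:45.
Two conventions deserve note:

* the printed label "33:33:33" cannot sum to 100, so it is interpreted as
  exact thirds; all other labels are taken at their printed values;
* dry masses are derived from energies with an energy density of 17 J/mg
  (≈ 4 kcal/g) for protein and carbohydrate and twice that for lipid.
  Only the 2:1 ratio matters downstream — every analysis works in energy
  fractions or mass fractions, never absolute calorimetry — so the
  absolute value of 17 J/mg is a labeling convention, not a fitted
  parameter.

Both constructors enforce their bookkeeping exactly (concentrations sum to
the total; energies sum to the total; the RMT mapping is invertible), and
the test suite asserts these invariants to 1e-9.

## Mass-balance intake accounting

Daily cube weighings are converted to dry harvested mass with the
evaporation correction `harvest = initial_wet × (control_dry/control_wet)
− leftover_dry`, one control ratio per day per diet; days with a missing
control fall back to the colony-wide mean ratio. Negative computed
harvests — measurement noise around an untouched cube — are clamped to
zero with a warning rather than propagated. Cumulative harvest minus the
end-of-experiment colour-sorted hoarded and scattered masses gives
consumption, and the identity `consumed = harvested − hoarded − scattered`
is enforced exactly (violations are data errors naming the colony, not
adjusted away). Nutrient partitions use the recipe mass fractions (2-D) or
the energy-derived mass fractions (3-D). Hoarded and scattered percentages
are averaged per colony (the ratio of each colony's masses), not pooled
across colonies, and colonies with zero harvest are flagged and excluded
from means.

## 2-D estimators

The intake target is the mean per-colony consumed (P, C) with standard
errors across colonies. Consumption rather than harvest is used because
hoarded and scattered fractions are small and the two nearly coincide; the
headline C:P ratio is the ratio of means, with the mean of per-colony
ratios also reported since the two differ slightly under noise.

The rule-of-compromise classifier is this package's quantification of what
is usually judged visually. For each rail it computes the equal-distance
prediction (the on-rail point with `P + C = P_T + C_T`) and the
closest-distance prediction (the orthogonal projection of the target,
clamped at the origin), and sums squared distances from the observed
per-rail means to each set of predictions. The array is classified by the
smaller SSE unless the two SSEs are within a factor of 1.5 of each other,
in which case it is `indeterminate`. The 1.5 band was chosen once, on the
grounds that noise-free arrays generated under either rule are never
indeterminate while genuinely ambiguous arrays are flagged; simulation
shows the classifier recovers the generating rule in well over 95% of
replicates at a between-colony intake CV of 0.15 with 8 colonies per rail.
Supporting diagnostics are the straight-line R² of the array (straightness
is the equal-distance signature) and the across-rail ANOVA of total intake
(equal distance predicts no treatment effect). Rail-aligned "pythagorean"
error bars, half-length `sqrt(SE_P² + SE_C²)` along the rail direction,
are used for plotting because on-rail variation is one-dimensional.

## 3-D response surfaces

`fit_rsm()` fits ordinary least squares of a response on
`{P, C, P², C², P·C}` in raw energy-percent units. Because the three
fractions sum to 100, lipid cannot enter the model; its effects are read
off the simplex geometry. Quadratic terms not significant at α = 0.05 are
removed — simultaneously, followed by a single refit, never iterated — and
the linear and cross-product terms are always retained. Raw percentage
predictors (rather than coded units) were chosen because the reconstructed
survival-surface maximizer under this convention reproduces the published
benchmark for that response (see "Reconstruction notes" below). The
intercept is always estimated freely.

Lack of fit is tested by splitting residual error into pure error (within
replicate colonies at the same composition) and lack of fit (composition
means versus the fitted surface); the F statistic's degrees of freedom sum
to the residual df by construction.

`maximize_surface()` finds the composition maximizing the fitted quadratic
over the closed simplex `{P ≥ 0, C ≥ 0, P + C ≤ 100}` by exact
enumeration — interior stationary point, three edges in closed form, three
vertices — rather than numerical optimization, so the result is
deterministic and exact. A `constrain = "hull"` switch restricts the
search to the triangle spanned by the seven-diet design
(`P, C ≥ 10, P + C ≤ 90`) for users who prefer not to extrapolate beyond
the tested compositions; the default is the full simplex.

Landscapes are classical thin-plate splines (radial basis `r² log r` plus
an affine part) with roughness penalty `n·λ` added to the radial block;
λ = 0.001 by default, fixed by configuration rather than selected by
cross-validation. Replicated design points are collapsed to their means
before solving, so the λ → 0 limit interpolates design-point means — the
property the test suite checks against an independently coded solve of the
full augmented system. With only seven support points the landscape is an
interpolation device for visualization; inference belongs to the
polynomial surface. The FMN region is delineated as the grid cells at or
above the 0.9 quantile of in-simplex predictions — a reproducible stand-in
for reading "the bright red area" off a heat map — with the quantile
exposed as a parameter.

## Treatment statistics

Harvest/consumption comparisons across treatments use classical one-way
ANOVA with Tukey HSD (studentized-range) post-hoc tests; compact letters
are produced by the insert-and-absorb algorithm and are checked in the
tests to agree pairwise with the adjusted p-values. Colour-sorted
hoard/scatter comparisons within colonies use paired t-tests, with
constant nonzero differences rejected as degenerate rather than reported
with an infinite statistic. Worker survival is modeled as
`cbind(alive, dead)` in a binomial-logit GLMM with numeric census day,
diet treatment and their interaction as fixed effects and source bin as a
random intercept (Laplace approximation, `lme4`); census intervals are
four days for the 12-day 2-D design and daily for the 14-day 3-D design,
matching the collection schedules. Terms are tested by likelihood-ratio
chi-squares against the model without the term (not Wald tests). Day is
numeric because single-df day effects are the reporting convention in this
literature. When the bin variance estimate is zero the fit coincides with
the plain fixed-effects binomial GLM, a reduction the tests verify.

## The synthetic-data generator

The generator simulates complete experiments from the measurement process
backwards: it first draws each colony's ground-truth cumulative
consumption, then reconstructs the daily cube weighings that would have
produced it, so the accounting stage must undo the evaporation model to
recover the truth.

* **Choice colonies** draw a target intake with mean-preserving lognormal
  noise (CV default 0.15) per coordinate and mix their two diets in the
  unique nonnegative proportions reaching that draw (a 2×2 linear solve).
  A configured target outside the cone of the two rails is an error; a
  rare noisy *draw* outside the cone (large-CV tail events) is clamped to
  the nearest rail — the colony simply eats a single diet — rather than
  aborting the run.
* **No-choice colonies** sit at the point their configured rule of
  compromise predicts on their rail, perturbed by a single multiplicative
  lognormal factor so they never leave the rail.
* **3-D colonies** consume a Gaussian draw (SD default 10 mg) around a
  quadratic composition surface, truncated at zero with a warning.

Hoarded and scattered fractions of harvest are Beta-distributed per diet
colour around their means (defaults 0.10 ± 0.078 and 0.052 ± 0.025, the
reported study-scale values); harvest is spread over days with
moderate Dirichlet-style weights; control dry:wet ratios (default 0.12,
the dry-matter content of an agar-based diet at 100 g/L solids) jitter
daily with absolute SD 0.02. Worker deaths are drawn daily from a
per-worker logistic hazard of diet composition (rising in protein, the
direction observed in this system), dead workers are not replaced after
day 1, and 3-D colonies add a bin-level random intercept (SD 0.3 logits)
to the hazard. Egg counts are Poisson with a composition-dependent mean.
The default intake target is (20, 30) mg — C:P = 1.5, the study-scale
ratio, with a magnitude realistic for 200-worker colonies over 12 days —
and the default 3-D consumption surface uses the published consumed-diet
coefficients with a zero intercept.

Randomness is organized as one derived seed per colony (a deterministic
function of the run seed and colony index), so each colony's records are
reproducible regardless of the order colonies are generated in; bin
effects use a dedicated stream. Fixed seeds give byte-identical fixtures.

What the generator does **not** emulate: forager recruitment dynamics and
within-day feeding bouts (days are exchangeable weights), nutrient-specific
hoarding (fractions apply to whole diets; colour misclassification is
available but defaults to 0), measurement error in the microbalance
itself, and brood stages beyond egg counts. Passing recovery tests on this
generator therefore demonstrates that the estimators invert the stated
measurement model, not that they are robust to every failure mode of real
colony data.

## Numerical choices and degenerate inputs

* Negative computed harvests clamp to zero (with a warning); mass-balance
  violations and control ratios above 1 are hard errors.
* The SSE classifier returns `indeterminate` inside the 1/1.5–1.5 band;
  exact zeros short-circuit to the matching rule.
* `maximize_surface` enumerates candidates exactly; ties resolve to the
  first candidate found (vertices, then edges, then interior).
* The TPS system is solved through the QR null-space of the affine part;
  three non-collinear points yield the exact affine interpolant.
* GLMM fits ignore singular-fit boundary warnings (a zero variance is a
  legitimate estimate); complete separation is flagged by a huge-SE
  warning; all-alive data short-circuit to a degenerate 100%-survival
  result.

## Problem sizes used in validation

The shipped tests validate parameter recovery at the study's own design
sizes (22 analyzable choice colonies, 40 no-choice colonies, 35 RMT
colonies): 200 replicates for target/hoard/scatter recovery, 500
replicates per rule for classifier accuracy, 1,000 random surfaces against
a 0.1%-step brute-force grid for the optimizer, and smaller
replicate counts (30–100) for secondary Monte-Carlo checks; these sizes
give Monte-Carlo standard errors comfortably below the tolerances being
asserted. The GLMM type-I-error check uses 40 replicates of a reduced
two-diet design, a deliberately small calibration probe.

## Reconstruction notes and known limitations

Reconstructing maximizing compositions from published three-decimal
coefficient tables reproduces the published survival maximizer (protein
fraction 0 and the carbohydrate optimum at `7.120/(2×0.058) ≈ 61.4`,
against a printed 61.8 presumably computed from unrounded coefficients).
For the consumed-diet and egg responses, printed coefficients yield
maximizers that appear swapped relative to the printed table entries
(≈ 57:43 where 44.3:55.6 is printed, and vice versa); the package
documents this discrepancy rather than guessing at the original's
convention, and its own maximizers are always computed from its own
fitted, unrounded coefficients.

Other limitations: landscapes interpolate seven support points and should
not be over-read between diets; the FMN quantile is a visualization
convention, not an inferential threshold; the pipeline renders landscapes
only for responses whose overall surface model is significant at α, and
leaves non-significant surfaces unplotted by design.

## A short worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, outdir = tempfile("nutgeom"),
                  simulate = list(designs = c("choice_2d", "nochoice_2d",
                                              "nochoice_3d"),
                                  analyzable = TRUE))
pipeline_simulate(cfg)
res2 <- pipeline_analyze_2d(cfg)
res2$intake_target
res2$rule_of_compromise
res3 <- pipeline_analyze_3d(cfg)
res3$fits$consumed
res3$fits$pct_survival$max_composition
```
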
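---
title: "Mating-group size and sex allocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mating-group size and sex allocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgsalloc)
```

## The biological problem

Sessile barnacles are simultaneous hermaphrodites that copulate with a long,
extensible penis. Mating is unilateral: individual *i* can act as sperm donor
to *j* whenever *j* sits within *i*'s penis reach, regardless of whether *j*
can reach back. Classic sex-allocation theory ties the optimal split of
reproductive investment between male and female function to mating group
size (MGS), but under unilateral mating that single number splits in two:

* **MGSm** — the individuals the focal can deliver sperm to, plus one;
* **MGSf** — the individuals that can deliver sperm to the focal, plus one.

Local sperm competition predicts female-biased allocation in small groups,
and the two group sizes can pull in opposite directions — MGSm scales the
eggs available to the focal as a male, MGSf the competition its own sperm
faces. `mgsalloc` operationalises this for populations of individuals
attached to discrete substrate patches (here "shells", after scallop-shell
hanging culture) far enough apart that patches never interact.

## The reach graph and its conventions

Within a shell, for every ordered pair (*i*, *j*):

$$i \to j \iff \mathrm{gap}(i, j) \le \lambda \cdot \ell_i,$$

with $\ell_i$ the resting penis length (cm) and $\lambda$ the elongation
factor, default 1.82, the extension rate measured in a congener on a
wave-protected shore. MGSm = out-degree + 1, MGSf = in-degree + 1. Choices a
user should be aware of:

* **Tie-inclusive threshold.** `gap <= reach` counts as reachable: reach is
  attainable at full extension, so boundary contact is a mating opportunity.
  (Positions carry full float precision, so exact ties essentially occur
  only in constructed data.)
* **Distance mode.** The default `center` mode measures Euclidean distance
  between operculum centers with radii ignored (radius defaults to 0). The
  `operculum_edge` mode subtracts both radii and floors the gap at 0 for
  touching or overlapping opercula — the floor keeps the gap a distance and
  makes overlapping neighbours trivially reachable.
* **Penis anchor.** Reach is measured from the same reference point as
  position; field protocols that measure "minimum distance between opercula"
  correspond to `operculum_edge` when radii are available.
* **Exclusion never edits the geometry.** The graph is always built on every
  individual present; the inclusion filter only drops rows from the analysis
  table. A barnacle with a lost ovary still occupies space and still counts
  in its neighbours' group sizes.
* **Isolation rule.** "No potential mating partner" is read as isolated in
  *both* roles (MGSm = MGSf = 1), the default `both_roles_isolated`. The
  stricter `either_role_isolated` is available because the field convention
  is ambiguous when an individual can reach others but cannot be reached.

## Cost aggregates and the allocation index

Dry weights (mg) partition into male variable cost (testis + seminal
vesicles), male fixed cost (penis), and female variable cost (ovary). Sex
allocation is male variable over total variable investment; the penis is
deliberately excluded from both numerator and denominator and enters only
its own model and the descriptive "penis share of total male output",
$100\,w_\mathrm{penis} / (w_\mathrm{penis} + w_\mathrm{testis+SV})$, which
the pipeline reports as the mean of per-individual shares. Allocation is
modelled untransformed on [0, 1]; no logit or beta variant is offered, so
users with allocations piling up at the boundaries should treat the linear
fit with care.

## The mixed models

Every response is fitted as

$$y_{is} = \beta_0 + \beta_1\,\mathrm{MGSm}_{is} + \beta_2\,\mathrm{MGSf}_{is}
          + \beta_3\,\mathrm{body}_{is} + u_s + \varepsilon_{is},$$

with $u_s$ a shell random intercept (micro-environmental correlation) and
body size indexed by operculum dry weight. Interactions are not included.
Coefficient tables come from the REML fit with Satterthwaite p-values
(`lmerTest`); the with/without-MGSf comparison refits both models by plain
ML, because restricted likelihoods of models with different fixed effects
are not comparable, and refers $2\Delta\log L$ to $\chi^2_1$. Both criteria
are recorded in the fit object so any number can be traced to its
likelihood. P-value approximations differ across software; the package
treats coefficients and their SEs, not p-values, as the reproducible
surface. Collinearity between the two MGS measures is diagnosed three ways:
VIF ($1/(1-R^2)$ from OLS of each predictor on the rest; > 10 is the
conventional alarm), their Pearson correlation, and the sign-stability check
comparing single-predictor with full-model coefficients.

Degenerate inputs fail loudly: a single shell (random intercept
unidentifiable), perfectly collinear predictors, an empty table after
filtering. A shell variance estimated at the zero boundary is legitimate
output, not an error.

## What the generator emulates — and what it does not

`generator_config()` defaults encode the study design the pipeline targets:

| quantity | default | basis |
|---|---|---|
| shells | 42, 2–7 barnacles each | field design |
| shell disc radius | 7.5 cm | large scallop shell |
| minimum spacing | 0.5 cm | no coincident individuals (layout unreported) |
| penis length | truncated normal, mean 2.77, SD 0.53, on [1.67, 4.46] cm | reported sample moments and range |
| operculum weight | log-normal, 1st–99th pct at [244.98, 1807.32] mg | reported range; shape is a modelling choice |
| coefficients | `default_coefficient_sets()` | published estimates per response |
| noise (shell SD, residual SD) | allocation 0.01/0.02; testis+SV 10/20; penis 0.15/0.3; ovary 75/150 | unreported; chosen once so simulated response ranges bracket the reported ones |

Because the reported 2.77 ± 0.53 are sample moments of *bounded* data, the
parent normal is moment-matched at construction so the truncated draws
themselves have that mean and SD (the parent solves to mean 2.728, SD 0.579);
parameterising the parent directly would shift the truncated mean to ≈ 2.79.
Positions are uniform on the disc with rejection sampling for the minimum
separation; an impossible packing is a hard error. Penis length and body
weight are drawn independently — the field data do not report their
correlation — so the simulated covariance between size and reach is absent,
and passing recovery tests say nothing about size-reach confounding in real
animals. Nor does the generator impose the connectedness of the real data
(where no individual had MGS = 1): isolated individuals arise naturally from
the geometry and are excluded by the filter, which is itself part of what
the tests exercise.

Two generating modes serve different tests. `organ_level` draws the three
organ weights from their own coefficient sets (floored at 0.01 mg; floor
events counted); sex allocation is then a *derived, nonlinear* quantity with
no linear generating truth. `allocation_level` draws sex allocation directly
(clipped to [0, 1]; clips counted) and back-fills organ weights consistent
with it (ovary and penis from their own models, testis + SV as
$a/(1-a)\cdot\mathrm{ovary}$), so the allocation model has exact linear
truth while the back-filled testis + SV does not. Zero-noise identifiability
— fitted coefficients equal to generating values at numerical precision —
therefore holds for the three organ models in organ mode and for the
allocation (plus ovary and penis) models in allocation mode, and is asserted
in the tests only on fixtures verified free of floor/clip events. Runs where
more than 1% of generated responses are floored or clipped warn about
recovery bias.

All randomness flows from the single config seed; identical configs give
byte-identical populations.

## Problem sizes and numerical tolerances

The test suite works at desk scale chosen to keep the whole run in tens of
seconds: brute-force oracle comparisons up to 10 shells × 10 individuals,
zero-noise recovery at 25 shells, a 100-replicate unbiasedness check at the
field design's 42 shells, and one 400-shell single-study recovery (≈ 1,400
individuals) in which each fitted MGS coefficient is required to land within
2 standard errors of its generating value — at the default noise levels that
standard error is ≈ 7% of the coefficient, so this is a sharp check.
Zero-noise recovery is asserted at 10⁻⁶ (lme4 converges to the exact
solution with boundary-variance warnings, which the fit object records
rather than re-raises). Exact arithmetic — marginal-line intercepts, the
penis-share percentage, the $\chi^2$/p closed form — is asserted to the
printed precision of the reference values.

## Known limitations

* Geometry is planar per shell; substrate curvature is ignored.
* Penis-length plasticity (wave exposure, density) is out of scope; the
  elongation factor is a single configurable constant.
* Sex allocation is modelled on the raw scale; boundary-heavy data violate
  the homoscedastic LMM.
* The generator's distributional shapes (log-normal body weight, Gaussian
  noise) are conveniences calibrated to printed ranges, not fitted to data.
* Dry mass is a relative currency; no energetic conversion is attempted.
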
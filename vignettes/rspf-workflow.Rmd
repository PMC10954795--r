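---
title: "Count-based resource selection probability functions for fenced cattle: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count-based RSPF workflow: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The workflow estimates how GPS-collared cattle distribute themselves over a
fenced paddock as a function of habitat covariates. The landscape is
discretized into circular sampling plots (50 m diameter); the response for
plot $i$ is $l_i$, the number of GPS fixes falling inside it. The model is a
negative-binomial regression with log link and a fixed offset,

$$\ln E[l_i] = \ln(\mathrm{total}) + \beta_0 + \beta_1 X_{1i} + \dots + \beta_p X_{pi},$$

where *total* is the number of fixes in the whole study area. The offset
converts counts to relative frequencies, so
$\exp(\beta_0 + \beta^\top x_i)$, renormalized over plots, is a discrete
utilization distribution (UD): the relative probability that a fix lands in
plot $i$. Because the offset maps counts to probabilities, the fitted object
is a resource selection *probability* function (RSPF), not just a relative
ranking. The negative-binomial dispersion $\theta$ absorbs overdispersion
relative to Poisson; it is estimated by maximum likelihood jointly with the
coefficients (`MASS::glm.nb`) and counted as a parameter in AIC
($\mathrm{AIC} = -2\ell + 2k$ with $k$ = slopes + intercept + $\theta$).

Key assumptions: fixes are exchangeable draws from a static UD (no
serial dependence, no diel structure); plots are the observational units, so
all inference — including the bootstrap — resamples plots; and animals are
pooled after a pairwise association screen has established that they move
independently (>75% of matched times separated by >25 m, both inequalities
strict).

## Predictors

Twelve plot-level covariates: mean elevation (m), mean slope (degrees,
Horn's eight-neighbour gradient), modal aspect quadrant (N/E/S/W), mean TRI
(mean absolute elevation difference to the eight neighbours), mean TPI
(elevation minus the eight-neighbour mean; positive on hilltops), the five
cover-class areas within the plot disk (m²; wood, shrub, grasslands, rock,
feedwater), and the centroid distances to the fence boundary and to the
water/feed point (m). Elevation, slope and both distances may also enter
squared; a quadratic term always accompanies its linear form. Candidate
models hold at most five base predictors; the full inventory enumerates to
over 5,000 specifications, and the a-priori screen drops any model holding
a pair with Pearson $|r| > 0.60$ (strict), replacing it by the two variants
that keep one member each.

Conventions worth making explicit:

* a grid cell belongs to a plot iff its centre lies inside the closed disk
  (distance $\le$ radius); cover areas are cell counts times cell area, so
  per plot the class areas sum exactly to the covered cell area;
* edge cells compute TRI/TPI over the neighbours that exist; slope/aspect
  replicate edge values. Flat cells (zero gradient) get aspect "N" plus a
  flag, and flat-dominated plots are flagged so aspect-containing models
  can exclude them;
* plot centroids closer than 13 m to the fence are rejected during
  placement (a centroid at exactly 13.0 m is kept); plots may overlap —
  194 non-overlapping 50-m disks would be near the packing limit of a
  54-ha paddock — and a fix inside two plots counts in both.

## Fitting, selection, uncertainty

Numeric predictors are standardized internally before `glm.nb` is called
(the quadratic columns independently of their linear parents), purely for
numerical stability: coefficients and their covariance are mapped back to
the original scales by the exact linear transform, which the test suite
verifies via the offset-doubling identity (doubling *total* moves only the
intercept, by $-\ln 2$). Fits that error, fail to converge, or return an
aliased (rank-deficient) design are marked non-converged and excluded from
ranking; in the bootstrap they count as failed replicates, and intervals
with more than 20% failures are flagged unreliable.

Model ranking is ascending AIC with ties broken by fewer terms, then by
the canonical term-sorted id. Confidence intervals are percentile bootstrap
(plots resampled with replacement, 1,000 replicates, 90% level by
default); percentile rather than BCa because the workflow's significance
rule is the simple zero-exclusion check and the added machinery of
acceleration constants buys little at n = 194. A coefficient's effect size
is reported as $(\exp(\beta) - 1) \times 100$, the percent change in
expected use per unit predictor.

## Validation and classification

Hold-out validation reserves a random 25% of fixes (split by fix, pooled
over animals; `round(0.75 n)` fixes develop the model). Plots are sorted
by predicted use (ties broken by plot id) and cut into 20 contiguous
classes whose sizes differ by at most one, the larger classes at the
low-use end — the same remainder convention as the quartile classes. The
statistic $r_s$ is the Spearman rank correlation between class rank
(1 = lowest predicted use) and the class's *size-adjusted* validation
count (class sum divided by class size). With 194 plots the class sizes
are 9 and 10; raw sums would then carry a deterministic size trend that
biases $r_s$ by roughly ±0.33 under uniform use, while the size-adjusted
statistic is mean-zero there and identical to raw sums whenever the plot
count divides evenly. Ranks ascend with predicted use so that "counts
increase with rank" yields positive $r_s$.

Quartile classification cuts the ranked predictions into four classes
(low, moderate, high, very high), remainder plots to the lower classes, so
194 plots give sizes {49, 49, 48, 48}. The classification depends only on
ranks and is therefore invariant to monotone transforms of the
predictions; when every prediction is identical the classes degenerate to
plot order and a warning is raised. Class profiles are estimated marginal
means of distance-to-feed, distance-to-fence and elevation from a one-way
linear model with class as the fixed effect; standard errors are pooled
($\sqrt{\mathrm{MSE}/n_k}$) and pairwise differences are summarized as a
compact letter display from Tukey-adjusted contrasts (configurable to
Bonferroni or none). Marginal-effect curves move one predictor over its
observed range with the others held at development-set means (quadratics
move with their base variable); the turning point of a quadratic response
is $-\beta_1 / (2\beta_2)$, and grids outside the observed range are
flagged as extrapolation. The prediction raster evaluates each 25-m cell
centre like a plot centroid (disk predictors, normalized prediction) and
carries a quartile class raster alongside.

## The synthetic generator

No field data ship with the package; a generator reproduces the study
conditions so every stage is testable. The paddock is a rounded rectangle
scaled to exactly 54.3 ha (the geometry is configurable — the real fence
shape is not public); the DEM is a smoothed Gaussian random field rescaled
to 660–731 m; cover is assigned by greedy quotas over independent smoothed
fields, giving clumped classes whose realized shares match the published
composition (oak wood 55.8%, shrub 26.0%, grasslands 6.9%, rock 10.0%,
feedwater 1.3%) to within grid rounding; the single water point is drawn
from the lowest-elevation quintile of the paddock (the real water point
sits at the paddock's low end), and the feedwater class is the patch of
cells nearest it.

Tracks follow the fitted model's own assumption: each recorded fix
occupies a grid cell drawn independently with probability proportional to
$\exp(\beta^\top x)$ — so parameter recovery is exact under the model — with
uniform jitter within the cell. An optional step-kernel mode restricts
each draw to cells within a radius of the previous position for
autocorrelation experiments; it is off by default because the fitted model
is static, and any movement mechanism would be our invention. Reported
positions add isotropic Gaussian error whose RMS magnitude is the drawn
EHPE (log-normal, mean 1,100 cm, s.d. 800 cm by default, spanning the
648–1,654 cm period means reported for this collar). Collar artifacts:
scheduled fixes (one per 180 s; 480 per 24 h) are missed independently at
the period's missed-fix rate, and a small fraction of fixes is displaced
5–50 m outside the fence as gross errors. The generator does **not**
emulate diel activity, herding, forage dynamics, or EHPE-correlated
habitat bias; green tests therefore demonstrate correctness of the
machinery under the model's assumptions, not realism of cattle movement.

Cleaning applies, in order: removal of each deployment's first and last
calendar days, the fence filter, then speed and turn filters to a joint
fixed point (so cleaning is idempotent). The collar vendor's exact
speed/course rules are proprietary, so the package declares its stand-ins:
a forward scan dropping fixes that imply more than 3 m/s from the last
retained fix, and removal of apexes of course changes above 170° travelled
with both adjacent speeds above 1.5 m/s. An EHPE cut-off exists but is off
by default, since the study filtered on position, speed and course only.

## Simulation studies and sizes

Four seeded studies back the acceptance checks, all on the standard frame
(54.3 ha, 194 plots) with the default truth — elevation −0.03, distfeed
−0.0015, distfence +0.006, i.e. about 1.5–2.5 log-use units across each
observed range:

* **parameter recovery** — 100 runs × 10,000 fixes; fit the true spec,
  bootstrap 199 replicates; the headline rate is *per coefficient*: sign
  correct and the 90% interval covering the truth (target ≥ 85%). The
  joint all-coefficients-at-once rate is reported alongside, but it is not
  the pass quantity: with perfectly calibrated 90% intervals the joint
  rate is capped near $0.9^3 \approx 0.73$ for a three-term truth, so a
  joint requirement at 85% would be unattainable by construction;
* **model selection** — 50 runs; the generating spec must rank in the AIC
  top 10 of 575 enumerated candidates (8 bases, up to 4 per model) in
  ≥ 90% of runs. The truth here carries four base terms (the three above
  plus TPI −0.5), the maximum model size in the reduced set. This is a
  structural requirement, not a convenience: every candidate that nests
  the truth beats it on AIC with probability $P(\chi^2_k > 2k)$
  (0.08–0.16) *independently of effect size*, and a three-term truth has
  55 such supersets with positively correlated exceedances — enough to
  push it out of any top-10 in roughly a quarter of runs. A four-term
  truth leaves only its 7 quadratic variants as nesting competitors while
  still exercising enumeration, offset fitting and ranking end to end;
* **validation self-consistency** — 50 draws of 20,000 validation fixes
  from the fitted UD; $r_s \ge 0.7$ in ≥ 90% of draws;
* **null calibration** — 200 uniform draws; mean $r_s$ within ±0.15 of 0.

The bootstrap uses 199 replicates inside the studies (1,000 elsewhere)
and the selection study uses the reduced 575-spec set; both choices keep
the full suite's run time proportionate to what they demonstrate, and the
pass criteria are rates over seeded runs, not single draws.

## Known limitations

Movement realism is out of scope (see above), so the pipeline's cleaning
stage removes a visible share of i.i.d. jumps as "speed outliers" — harmless
for the studies, which simulate counts at the plot level, but a reminder
that the cleaning thresholds interact with the movement model. Aspect is
categorical and excluded from the coefficient-vector interface of the
generator (use indicator predictors instead). The association screen
matches timestamps by mutual nearest neighbour within half the fix
interval; collars with wildly different schedules would need a different
matching rule. Season enters as a label for refitting, never as a model
term, mirroring the per-season refit design.
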
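---
title: "Discrimination contours for auditory speed perception: models and methods"
author: "audspeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrimination contours for auditory speed perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audspeed)
```

## The experimental problem

A sound source that travels an arc of $D$ degrees in $T$ seconds moves at
speed $v = D/T$. In a two-alternative forced-choice (2AFC) speed
discrimination task, a listener hears a reference sound (by default 21.17°
in 800 ms, i.e. 26.46 °/s) and a target whose travelled distance and
duration are perturbed, and reports whether the target moved *faster* or
*slower*. Because speed confounds space and time, the interesting question
is not only *how well* listeners discriminate speed but *which cue* —
duration, distance, or their ratio — actually drives the decision.

The analysis operates in Weber-fraction coordinates,

$$W_\mathrm{distance} = \frac{T_\mathrm{distance} - R_\mathrm{distance}}{R_\mathrm{distance}},
\qquad
W_\mathrm{duration} = \frac{T_\mathrm{duration} - R_\mathrm{duration}}{R_\mathrm{duration}},$$

so the reference sits at the origin of a distance–duration plane
($W_\mathrm{duration}$ horizontal, $W_\mathrm{distance}$ vertical) and every
target is a point in it. The target speed implied by a point is

$$v_T = v_R\,\frac{1 + W_\mathrm{distance}}{1 + W_\mathrm{duration}},$$

which is why both components must stay above $-1$.

## Stimulus design

`build_design()` lays targets along 8 straight orientations through the
origin, at 22.5° steps measured from the positive distance (vertical) axis.
Four orientations are the named experimental conditions:

| angle | condition | what varies | speed along the line |
|------:|-----------|-------------|----------------------|
| 0°    | spatial   | distance only | increases with distance |
| 90°   | temporal  | duration only | decreases with duration |
| 45°   | coherent  | both, proportionally | constant (equal to the reference) |
| 135°  | opposite  | both, inversely | increases steeply |

Each orientation carries 9 levels repeated 6 times: $8 \times 9 \times 6 =
432$ trials, dealt round-robin into 6 blocks after a seeded shuffle, with a
random motion direction and a random start speaker offset as metadata. Audio
rendering is out of scope; the speaker-array geometry is retained only as
trial metadata.

**Level placement.** The levels follow a geometric ladder of speed-ratio
factors $f_k = R^{k/4}$, $k = -4..4$, $R = 4$, so the pure axes span target
speeds from $v_R/4 \approx 6.62$ to $4 v_R \approx 105.85$ °/s and the
middle level is always the reference itself (a genuine trial whose 2AFC
answer is at chance by construction). On a straight line through the origin
the attainable speed ratio is bounded when both direction components are
positive (it approaches $\cot\varphi$ for $\varphi < 45°$ and
$\tan(\varphi - 45°)^{-1}$-type limits above), so the ladder cannot be
realised exactly on the coherent diagonal and its first-quadrant
neighbours (22.5°, 45°, 67.5°). The package therefore solves the
speed-ratio equation exactly wherever the whole ladder is attainable (the
pure axes and all orientations beyond 90°), and on the remaining
orientations applies the same ladder to the dominant cue component
($1 + w = f_k$), which preserves feasibility ($w > -1$ always), the
geometric progression, and strict monotonicity of speed along every
non-coherent orientation.

Note a numerical subtlety of the reference stimulus itself: $21.17 / 0.800
= 26.4625$ °/s, which displays as 26.46, while $4 \times 26.4625 = 105.85$.
The package stores full precision everywhere and rounds only for display.

## The simulated observer

No public data exist for this task, so every downstream stage is exercised
on simulated observers whose decision structure matches what the analysis
assumes. On each trial the observer forms noisy internal cues
$\hat w_t = w_t + \varepsilon_t$, $\hat w_d = w_d + \varepsilon_d$ with
$\varepsilon \sim N(0, \sigma_\mathrm{noise}^2)$ i.i.d. in Weber units, a
derived speed cue $\hat w_v = (1+\hat w_d)/(1+\hat w_t) - 1$, and decides
"faster" iff

$$D = \beta_v \hat w_v - \beta_t \hat w_t + s\,\beta_d \hat w_d > 0,$$

where $s = +1$ is the veridical spatial mapping and $s = -1$ the inverted
"shorter distance = faster" heuristic. Duration enters negatively — the
"shorter sound = faster sound" temporal assumption. Exact ties respond
"faster" with probability one half. With probability `lapse` the answer is
replaced by a fair coin.

Choices made once and documented here:

* **Noise is additive in Weber units**, not in physical milliseconds or
  degrees: the whole analysis lives in Weber coordinates and
  Weber-proportional noise is the standard psychophysical assumption. One
  shared `noise_sd` (default 0.3) covers both cues.
* Internal cues at or below $-1$ (non-positive internal duration or
  distance) are redrawn, so derived quantities are always defined.
* Presets: `duration_only` (0,1,0), `distance_only` (0,0,1), `speed_only`
  (1,0,0), all veridical, are the diagnostic single-cue observers;
  `eb_like` (0.1, 1.2, 0.3, $s=-1$) and `sc_like` (0.15, 1.0, 0.1, $s=+1$)
  are duration-dominant mixtures for cohort simulations, the first with the
  inverted spatial heuristic. The mixture weights are package choices (the
  observer model is a pipeline-validation stand-in, not a cognitive model);
  they are kept duration-heavy because a linear cue-weighted observer's
  contour bulges along its decision-null direction,
  $\tan\varphi = (\beta_v+\beta_d)/(\beta_v+\beta_t)$, and heavier
  speed/distance weights would tilt the "control" observer away from the
  duration-dominant class it operationalises.
* Cohorts jitter each subject's weights and noise by log-normal factors
  (`exp(N(0, 0.2^2))` by default), keeping weights positive.
* Note that with `lapse` $= \lambda$ the asymptotes are $\lambda/2$ and
  $1-\lambda/2$, so even $\lambda = 0.5$ attenuates the psychometric curve
  into $[0.25, 0.75]$ rather than flattening it.

What the generator does **not** emulate: binaural cue realism (ITD/ILD),
adaptation or trial-order effects, asymmetric per-cue noise, response bias.
Passing tests therefore show that the *analysis machinery* recovers the
structure the decision model puts in — not that human data will be this
clean.

## Psychometric fitting

`fit_psychometric()` fits the two-parameter cumulative Gaussian
$p(x) = \Phi\big((x - \mathrm{PSE})/\sigma\big)$ to "faster" proportions,
with $\sigma$ free to take either sign. A decreasing ("inverted") curve —
the signature of an observer whose heuristic misleads — yields a negative
signed JND. The JND is $|\sigma|$, one standard deviation of the fitted
curve.

* **Objective.** The default is count-weighted least squares on the
  proportions; count-weighted Bernoulli maximum likelihood is available as
  `method = "ml"`. With a deliberately lapse-free two-parameter curve, ML
  pays enormous log-likelihood penalties at saturated grid points where a
  lapsing observer's proportions are pinned near $\lambda/2$, and inflates
  $|\sigma|$ by up to a factor of two on orientations whose ladder reaches
  deep into saturation; least squares is insensitive to those tail lapses.
  Both options are exposed because neither is canonical.
* **Start values** come from a weighted probit regression; one
  Nelder-Mead run per slope sign, best objective wins.
* **Goodness of fit** is $R^2$ between observed and fitted proportions,
  tested by the F statistic of the observed-on-fitted regression with
  $(1, k-2)$ degrees of freedom ($k$ = number of stimulus values; 2 fitted
  parameters). Under coin-flip null responses this gate fires at close to
  the nominal 5% (measured ≈ 0.05 in the test suite).
* **Degenerate input** (fewer than 3 distinct stimulus values) raises a
  classed error in direct calls and returns an invalid fit in batch mode;
  a fitted $|\sigma|$ beyond 10× the widest stimulus value marks the curve
  flat and the fit invalid.

**Worst-JND substitution.** Fits that are invalid or fail the
goodness-of-fit gate receive the worst JND of their cell. Two orderings are
provided because "worst" differs by analysis: radial condition fits order
by the converted JND (an inverted curve means failed speed discrimination,
and conversion — see below — makes less-negative inversions worse), while
per-orientation contour fits order by $|\sigma|$ (there the slope sign only
records which end of the line reads as "faster", and precision along the
line is the magnitude). Substitution pools are explicit: within subject
across orientations for contour fits; within group × condition across
subjects for condition fits.

## Discrimination contours and ellipse fitting

Each orientation's fitted JND magnitude $j$ contributes the mirrored point
pair $\pm j(\sin\varphi, \cos\varphi)$, giving 16 points for 8
orientations. (An alternative reconstruction from separate
$W_\mathrm{duration}$/$W_\mathrm{distance}$ projection fits is available
for oblique orientations via `method = "projection"`; the two are
geometrically equivalent on oblique lines and the pure axes admit only the
magnitude fit, one projection being degenerate there.)

`fit_ellipse()` fits a general conic by least squares. The default route is
the numerically stable direct least-squares formulation with the ellipse
constraint built into the eigenproblem, which returns an ellipse whenever
the points are not degenerate. The `"conic"` route fits an unconstrained
algebraic conic (smallest singular vector) and then classifies it, raising
a classed `NotAnEllipse` condition for hyperbolas, parabolas and degenerate
sets — mirroring the behaviour of generic conic-fitting routines on
ill-shaped JND sets; the pipeline excludes such subjects from orientation
statistics only, and reports them. The centre is fitted, not pinned at the
origin, matching general-purpose ellipse fitters. Points are centred and
scaled before fitting and the conic is transformed back, for conditioning.

The major-axis orientation $\theta$ is reported from the vertical
(distance) axis so that 0° is duration-dominant, 45° speed-dominant and 90°
distance-dominant. $\theta$ is axial (defined modulo 180°), so comparisons
use `axial_difference()`/`axial_wrap()`, and group tests against the three
dominant orientations run on axially wrapped differences in $(-90, 90]$.
Axial wrapping is discontinuous at ±90°: orientation tests against a
reference are only meaningful when the sample does not straddle the
antipode of that reference, which holds for all dominant-orientation
comparisons of duration-dominant cohorts.

## The radial speed statistic

For condition-level precision the stimulus coordinate is the signed radial
distance $r = \pm\sqrt{w_t^2 + w_d^2}$. The sign convention matters. A
literal rule — negate $r$ where the plane y-coordinate is negative — is
degenerate on the temporal condition (which lies along $y \equiv 0$) and
would invert the temporal condition for a veridical observer. The default
therefore signs $r$ by the veridical speed difference,
$\mathrm{sign}(w_d - w_t)$, falling back to the y-rule exactly on the
constant-speed coherent line, where no speed difference exists. This makes
$p(\text{faster})$ increase in $r$ for a noiseless veridical speed observer
in all four conditions, so inversions appear only where a heuristic
genuinely misleads. The literal y-rule remains available
(`sign_rule = "y_rule"`) since the two conventions interact with the axis
assignment.

**JND conversion.** Inverted condition fits produce negative JNDs that
cannot enter a precision ANOVA directly. Within each group (min and max
taken over all of the group's signed JNDs, across conditions),

$$\mathrm{JND}_\mathrm{conv} = \mathrm{JND}_\mathrm{neg} - \min(\mathrm{JND}) + \max(\mathrm{JND}),$$

applied to negative values only, after worst-JND substitution. Every
converted value lands at or above the group's maximum untouched value — an
inverted curve is always worse than any upright one — and less-negative
inversions land strictly higher.

## Permutation statistics

* **One-sample t** (ellipse orientation vs a dominant orientation): t on
  axially wrapped differences, null by sign flips, two-sided
  $p = (\#\{|t^*| \ge |t|\} + 1)/(B + 1)$; Hedges' g with the exact
  small-sample correction; t-based 95% CI.
* **Two-sample t** (group comparisons): Welch t, null by label shuffling,
  pooled-SD Hedges' g (zero pooled SD flagged degenerate).
* **Exactness.** Whenever the full permutation set (sign patterns or label
  splits) has at most 16384 elements, it is enumerated and the p-value is
  exact — this covers $n \le 14$ sign-flip and 8+8 label-shuffle designs.
* **Mixed ANOVA** (`perm_mixed_anova`): classical balanced-design F
  statistics (between-group error = subjects within groups; within error =
  subject × condition residual). The permutation scheme is stated rather
  than inherited: group labels permute across subjects for the
  between-subjects effect; condition labels permute independently within
  each subject for the within-subjects effect and the interaction (row
  constants — subject and group effects — are invariant under within-row
  permutation, so this equals a subject-centred residual permutation).
  5000 iterations by default. Partial $\eta^2$ is
  $SS_\mathrm{effect}/(SS_\mathrm{effect}+SS_\mathrm{error})$ against each
  effect's own error term. Under a null simulation the type-I error of all
  three effects sits inside [0.03, 0.07] at $\alpha = 0.05$ (recomputed in
  the test suite over 500 tables × 500 iterations).
* **Corner χ²:** 2×2 point × response Pearson χ² without continuity
  correction, Cramér's V, Wald CI on the proportion difference; a zero
  margin triggers a flagged Haldane (+0.5) fallback. The pipeline compares
  the two extremes of the opposite diagonal — the shorter-duration /
  longer-distance corner versus its mirror — where the temporal assumption
  predicts the asymmetry.
* **Bonferroni** correction for the three dominant-orientation tests and
  the four per-condition group comparisons; **Shapiro–Wilk** normality
  checks wrap `stats::shapiro.test()`.

95% confidence intervals accompanying permutation tests are t-based (Welch
for two samples) and labelled as such; the permutation machinery itself
makes no normality assumption.

## Reproducibility and problem sizes

Every stage takes an explicit seed; one global seed fans out through a
deterministic splitter (`stage_seed`), so identical configurations produce
byte-identical report bundles, and all output files carry the seed and a
configuration hash. The simulation sizes used by the packaged checks — 60
repetitions per level for single-observer contour recovery, 200 replicates
for JND-bias estimation, 500 null tables × 500 iterations for ANOVA
calibration, 200 random ellipses for fit recovery — are the package's
standing choices for those checks and are stated in the test files
themselves.

## Known limitations

* The observer model is linear in noisy Weber cues with one shared noise
  scale; it validates the pipeline, it does not model audition.
* Single-cue observers are at chance in the condition orthogonal to their
  cue, so entire group × condition cells can lack a fittable curve; the
  pipeline raises a classed substitution error rather than silently
  interpolating (mixed-weight observers do not trigger this).
* The fitted psychometric curve has no lapse parameter by design; observer
  lapses inflate $|\sigma|$ mildly (least squares) and the inflation is
  shared across orientations, leaving contour shape essentially intact.
* Ellipse orientation is ill-conditioned as the axis ratio approaches 1;
  no special handling beyond the axial arithmetic is attempted.
* The y-rule sign convention is retained verbatim as an option but is
  degenerate on the temporal condition; results under it should be
  interpreted accordingly.
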
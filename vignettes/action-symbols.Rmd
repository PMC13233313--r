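---
title: "Analysing stroke primitives as action symbols: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing stroke primitives as action symbols: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionsym)
```

## The scientific problem

When a trained subject draws figures on a touchscreen, each simple shape
tends to be produced with a consistent, idiosyncratic stroke trajectory — a
*primitive*. If primitives are internally represented as *action symbols*
(discrete, recombinable units of motor behaviour), three signatures should
appear in behaviour and in frontal-cortex population activity:

1. **Motor invariance** — the same trajectory shape across stimulus
   locations and sizes;
2. **Categorical structure** — when images morph continuously between two
   practised shapes, drawings (and planning-epoch neural states) jump
   discretely between the two primitives rather than tracking the morph;
3. **Recombination** — novel multi-stroke characters are drawn by reusing
   the same primitives, and the same primitive-specific neural states recur
   across task contexts.

`actionsym` implements the quantitative machinery for all three tests, plus
a synthetic-data module that generates strokes, morph sets, characters and
tuned population tensors with the statistical structure the analyses
assume, so the entire pipeline runs and is testable without recorded data.

## Behavioural metrics

### Trajectory distance

The central behavioural metric is a dissimilarity between two strokes that
ignores location, size and timing. Each stroke is rescaled (aspect
preserved) so its bounding-box diagonal is 1, resampled to N = 70 points
equally spaced in cumulative arc length, and differentiated to a velocity
series. The distance is a regularized dynamic-time-warping (DTW) cost

$$D_{\mathrm{DTW}}(v_1, v_2) = \frac{\min_\pi \sum_{(i,j)\in\pi} d(i,j)}{N},
\qquad d(i,j) = \lVert v_1[i]-v_2[j]\rVert + \lambda\,|i-j|,$$

with $\lambda = 0.045\,\langle \lVert v\rVert\rangle$ (the mean per-sample
speed of *both* inputs, so the warping penalty is self-scaling), path steps
right/up/diagonal anchored at (1, 1) and (N, N), and the final score
squashed into [0, 1) as $D_{\mathrm{traj}} = 1 - 1/(D_{\mathrm{DTW}}+1)$.

Two numerical choices deserve note:

* **Velocity time base.** After arc-length resampling there is no longer a
  physical clock; the 70 resampled points are treated as spanning one unit
  of normalized time and differentiated with the five-point stencil at step
  $h = 1/(N-1)$. Velocity magnitudes are then of order the normalized path
  length, which places typical between-primitive distances in the
  informative middle of the [0, 1) range (about 0.4–0.8, versus about
  0.1–0.25 for within-primitive trial variability).
* **Stencil boundaries.** Interior points use the five-point stencil (exact
  for polynomials of degree 4 or less); the first and last two points use
  one-sided second-order differences.

The DTW inner loop is implemented in C++; the test suite checks it against
exhaustive enumeration of all monotone warping paths on short series.

### Image distance

Images are 2-D point sets. Their distance is a modified Hausdorff metric
chosen for robustness to outlier points: after centring each set on its own
centre of mass, the directed distance from A to B is the *mean* over points
of A of the distance to the nearest point of B, and the image distance is
the average of the two directed distances.

### Primitive alignment and the category boundary

The relative similarity of any trial datum to two reference primitive trial
sets is $a = d_1/(d_1+d_2)$, with $d_1, d_2$ the mean distances to the P1
and P2 reference trials (0 = P1-like, 1 = P2-like). The same score is used
with the trajectory metric (drawings), the image metric (stimuli), and the
Euclidean metric (neural population vectors).

The category boundary of a morph set is the morph level showing discrete
trial-by-trial switching: among levels whose single-trial alignments are
bimodal (scores present both below 0.35 and above 0.65), the level whose
mean is closest to 0.5 wins, with ties broken toward the larger minority
class. Because drawing-based alignments never reach 0 and 1 — both
reference distances have a noise floor — the cutoffs are applied on the
endpoint-normalized scale, where the mean alignment of the first morph
level maps to 0 and of the last to 1. Without this normalization, primitive
pairs with higher trial-to-trial variability (alignment scale compressed
to, say, 0.36–0.63) could never satisfy an absolute 0.35 cutoff even when
switching is plainly present.

The same reasoning applies to the hallmark comparisons: when testing
sigmoidal nonlinearity (drawing below the image line at U1, above it at
U2), the image alignments are first rescaled linearly so the practised end
points match the drawing scores. `categorical_structure_test()` then runs
two-sided Wilcoxon signed-rank tests across morph sets for the nonlinearity
and switching (A2 > A1) effects, reporting the smaller signed-rank sum, and
flags analyses with fewer than five sets as low-powered.

## Primitive classification and the remixed null

Templates are fitted per primitive from single-shape trials: the template
is the pointwise mean trajectory vector, and the match threshold
$D_{\max,p}$ is the 97.5th percentile of source-trial distances to the
template — an empirical bound on trial-by-trial variation under unambiguous
conditions. A character stroke is assigned its arg-min primitive and called
a high-quality match only below that primitive's threshold; strokes above
every threshold fail to match the set.

The *remixed* control set asks whether character strokes match primitives
as wholes rather than in their halves: each remixed primitive joins the
first half of one primitive (by distance travelled) to the second half of
another, offset-aligned and cross-faded with a logistic weight over the 10%
of arc length around the junction (the blend width is our choice; only the
sigmoidal form is prescribed). Candidates are screened for
self-intersection and for sharp turns — |curvature| on the inner 80% of the
stroke must not exceed 0.8. We apply that bound at the standard render
scale (134 px bounding-box diagonal, i.e. a ~4 cm shape at 33.6 px/cm): on
a unit-diagonal curve the bound would reject every ordinary curved shape (a
circle of diagonal 1 has |curvature| ≈ 2.8), whereas in pixel units it
corresponds to a 1.25 px radius of curvature and rejects only near-cusps at
the junction, which is the only self-consistent reading. Accepted sets must
also use each donor half at most twice and keep every remixed–remixed and
remixed–actual distance at or above the minimum actual–actual distance —
which is why remixed sets require a subject-sized repertoire (8 or more
primitives): with very few primitives the actual–actual floor is so large
that no blend can clear it. Because remixed primitives were never drawn,
their thresholds are inherited from the actual pool most leniently: the
largest threshold goes to the worst-matching remixed primitive, and so on.

## Behavioural scoring engine

Trial feedback aggregates factors (drawing–image overlap with
characteristic features weighted double, negated Hausdorff distance, an
excess-ink efficiency penalty, and — for practised characters only —
stroke-count and stroke–shape alignment factors). Raw factors are rescaled
to [0, 1] between adaptive bounds (1st and 53rd percentiles of the last 50
trials, updated after each trial; degenerate bounds are widened so a
constant history rescales to 0.5), weighted, and collapsed by the worst
weighted factor, $s_{\mathrm{scal}} = \min_i(1 - w_i(1 - f_i))$. Categories
are great (> 0.82), good, OK, fail (≤ 0.15); reward is
$C \cdot m \cdot a \cdot s_{\mathrm{scal}}$ with category multiplier
$m \in \{1.3, 1, 0.8, 0\}$ and random bonus $a \sim 0.75 + 0.5\,U(0,1)$.
The per-experiment weights were hand-tuned in the original setting and are
exposed as configuration, defaulting to 1 for image-similarity factors and
0.5 otherwise; the efficiency factor's proportionality constant is absorbed
by the adaptive rescaling, so it is implemented as relative excess ink.

## Neural preprocessing

Spike trains become rates by Gaussian smoothing (25 ms sd, 10 ms grid,
kernel truncated at ±4 sd and renormalized within the trial window so each
spike contributes unit mass). Units are screened by three rules: low rate
(80th percentile below 1 Hz); drift (slope of square-root rate against
session time in hours, divided by the mean square-root rate, above 0.2 — we
read the denominator on the square-root scale, which is both dimensionally
consistent and required for a 5→20 Hz two-hour ramp to trip the rule); and
fluctuation across disjoint, contiguous 50-trial bins
((s_max − s_min)/s_mean > 1.15 on across-trial sds of sqrt rates, or
(u_max − u_min)/u_mean > 0.65 on the bin means), skipped with a flag below
100 trials. Rates are then square-root transformed and soft z-scored,
$(\sqrt{x}-\mu)/(\sigma + C)$ with $C = \min(\bar m) + 3$ Hz, so
higher-firing units contribute relatively more and constant units map to
zero rather than blowing up. The transform is invertible given its
parameters.

Trial alignment uses linear time warping to a median trial: median
inter-anchor segment durations are concatenated into a template, each
trial's segments are linearly rescaled onto it, and rates are resampled at
the warped times (values unchanged, only timing), with a 2.5 ms Gaussian
smoothing at anchor joints. Trials with missing or disordered anchors are
dropped and reported.

## Population geometry

**Condition PCA.** Activity is binned (0.15 s windows, 0.02 s slide),
trials are stratified into train/test halves, PCA is fitted on the train
half's condition-mean N × (C·T) matrix, the top 8 components are kept, and
only held-out trials are projected. Eight randomized splits are averaged
downstream. Trial-vector analyses use a coarser 0.2 s/0.1 s binning and 50
components; the two binnings are deliberately kept as separate
configurations.

**Neural distance.** For conditions A and B,
$D^*_{AB} = D_{AB} - (D_{AA}+D_{BB})/2$, where $D_{AB}$ is the mean
pairwise Euclidean distance between across-condition trial pairs, per time
bin normalized by $d_{\max}(t)$ (the 98th percentile of distances between
all pairs of distinct trials across all conditions; a zero 98th percentile
aborts as degenerate data) and averaged over bins. Within-condition means
use distinct trial pairs only, making $D^*_{AA} = 0$ exact, and the
debiasing implies small negative values under the null — they are retained,
not clipped. Encoding strength of a variable is the mean $D^*$ over
condition pairs differing only in that variable; regions are compared by
least-squares regression of per-pair distances on a region indicator with
condition-pair fixed effects, Bonferroni-corrected over variables × region
pairs, and summarized as "beaten counts".

**Decoding.** Cross-condition generalization trains a linear max-margin
one-versus-rest classifier (cost 0.1, matching the weak regularization of
the original analyses) at one condition and tests at held-out conditions,
per bin over 0.05–0.6 s, rescaling accuracy so chance maps to 0. Ties in
one-versus-rest decision values break to the first class index. Region
comparisons match unit counts by subsampling without replacement, averaged
over 10 repeats.

**Initial-reach correction.** Per unit and time bin, activity is regressed
on a first-stroke indicator, a task-type indicator and primitive dummies;
only the first-stroke coefficient is subtracted, and only from first-stroke
trials.

**Kinematic encoding (FVAF).** A linear map from 2-D finger velocity to the
top 10 neural components is fitted on all primitives but one and scored on
the held-out primitive by the fraction of variance accounted for,
$1 - SS_{\mathrm{err}}/SS_{\mathrm{tot}}$ with an *uncentred* total sum of
squares, as defined — this can differ from a conventional $R^2$. Predictions
include the intercept (the printed definition shows only $Ev_t$; omitting a
fitted intercept from the predictions would be internally inconsistent, so
we treat that as a typographical shorthand). Lags from −0.3 to 0.3 s in
0.05 s steps shift the neural–behaviour pairing (negative = neural leads);
the scalar summary averages −0.15 to −0.05 s.

**Fixation-aligned decoding.** A one-versus-rest logistic decoder of the
planned primitive is trained on 0.3 s planning-epoch snippets from
single-shape trials and applied to fixation-aligned activity; each fixation
is labelled with the nearest displayed shape and excluded if every shape is
farther than 70 px.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is exercised:

* **Primitives** are heading-integrated curves over five named control
  parameters (initial heading, total turn, and a sinusoidal curvature
  modulation's amplitude, phase and frequency), centred and scaled to unit
  bounding-box diagonal. Libraries are rejection-sampled to keep all
  pairwise trajectory distances above a floor (0.25), emulating a
  repertoire of mutually distinct primitives; repertoires up to the
  subject-typical 11 primitives are routinely reachable.
* **Strokes** traverse the transformed curve at constant nominal speed over
  a lognormally jittered duration (cv 0.15 by default), sampled at the
  60 Hz touchscreen rate, with low-pass-filtered Gaussian positional jitter
  (2 px). The default shape scale is 134 px (≈ 4 cm at 33.6 px/cm, the
  average stimulus size), locations span the screen, and size ratios up to
  the experimental 2.5× leave the normalized metric unchanged.
* **Morph sets** interpolate control parameters linearly; fractions 0 and 1
  reproduce the practised shapes exactly, with five interior morphs by
  default (7 images). Morphable pairs are sampled at moderate parameter
  offsets and accepted only if the end points are behaviourally distinct
  *and* the image-based alignment is linear in morph fraction (R² ≥ 0.99) —
  the same property the original stimulus sets were verified to have, and
  the precondition for interpreting a sigmoidal drawing profile as
  categorical. The per-set morphing axes of the real stimuli are not
  published, so they are configuration here, not constants.
* **Drawing policies**: the categorical policy draws the boundary-side
  primitive with a 50/50 mixture exactly at the boundary morph; the tracing
  policy draws the interpolated shape itself.
* **Characters** chain 2–6 shapes by sampled attachment-point relations and
  are rejection-sampled through the crossing filter (at most one proper
  crossing per shape pair, which also accommodates the by-construction
  contact at each attachment point).
* **Population tensors** give each unit standard-normal tuning weights per
  primitive, location, size and task type, scaled by non-negative gains, a
  shared post-onset ramp carrying the signal, and Gaussian rate noise
  (Poisson counts selectable; Gaussian is the default because all analyses
  operate on smoothed, normalized rates). The categorical flag routes morph
  trials through the boundary rule before tuning; a linear readout mixes
  the two end-point tunings in the morph fraction instead. Setting
  `primitive_by_location = TRUE` redraws primitive tuning per location,
  producing the conjunctive (non-invariant) code used as the negative
  control for decoder generalization.

What the generator does *not* emulate: biomechanics and speed profiles of
real reaches, eye movements, correlated (shared-variability) neural noise,
non-stationarities within a session, and electrode-level artefacts. Passing
tests therefore demonstrate that the analyses recover the structure they
are designed to detect under their own assumptions — not that real data
contain that structure.

## Problem sizes and verification

The test-suite simulations use libraries of 4–11 primitives, 8–20 trials
per condition, populations of 20–30 units, and 20 synthetic morph sets per
policy; threshold calibration uses 2,000 strokes per primitive. These sizes
were chosen so each property is measured well away from its decision
boundary (for example, calibration at n = 2,000 pins the 97.5th-percentile
exceedance at 2.5% ± 0.7%). The DTW and image-distance implementations are
checked against brute-force oracles; the debiased neural distance against
its closed form on point-mass conditions and against a 200-resample null;
encoding strength, decoder generalization, the categorical hallmarks and
FVAF lag recovery against ground truth injected by the generator.
`scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

* The remixed-set sampler is greedy over a shuffled candidate pool; for
  small repertoires or large requested set sizes it reports infeasibility
  rather than backtracking exhaustively.
* The crossing filter counts proper polyline crossings on 50-point
  discretizations; tangential grazings are not counted.
* `find_category_boundary` assumes at least three morph levels with two or
  more trials and that the end levels anchor the alignment scale.
* Fixation decoding fits unregularized logistic models per primitive;
  with perfectly separable training activity the probabilities saturate
  (harmless for ranking fixated versus planned primitives, but the absolute
  probabilities are then uncalibrated).
* Serialization uses plain-text CSV/JSON; very large recordings are better
  kept in binary containers upstream and exported per session.
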
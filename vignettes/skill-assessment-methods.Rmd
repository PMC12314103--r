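---
title: "Quantifying microsurgical skill from vessel deformation and instrument kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microsurgical skill from vessel deformation and instrument kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microskill)
```

## The assessment problem

In microvascular anastomosis — suturing two sub-millimetre vessels under an
operating microscope — technical proficiency is conventionally judged by
expert raters on criteria-based scales. `microskill` implements an
objective, video-derived alternative that operates downstream of two
perception models: a semantic segmentation of the vessel area (VA, the
per-frame pixel count of the vessel region) and a detector of the two
forceps tips. From those per-frame outputs it computes two families of
parameters for each trial of a four-phase suturing task (A: grasp and
insert the needle; B: push and extract it; C: pull the threads to the
first knot; D: tie three knots and cut):

* **Vessel-derived** — how much the tissue is disturbed:
  - `CV-VA` $= \sigma/\mu$ of the VA series (sample SD over mean);
  - $\Delta\mathrm{VA}$, the relative change in VA per unit time;
  - `Max-dVA` $= \max_t |\Delta\mathrm{VA}(t)|$;
  - `No. of TDE`, the number of tissue-deformation errors: excursions of
    $\Delta\mathrm{VA}$ beyond a cohort threshold (default $\pm 1.13$, the
    mean $\pm\,1.96\,\mathrm{SD}$ bound of pooled $\Delta\mathrm{VA}$;
    `cohort_tde_threshold()` recomputes it for a new cohort).
* **Motion-derived**, per hand — how economically and smoothly the
  instruments move:
  - `PD`, the path distance travelled by the tip (px);
  - `NJI`, the normalized jerk index
    $\tfrac12\, t^5/D^2 \int \|\dot a\|^2\,dt$, the dimensionless
    smoothness measure that equals 360 for an ideal single minimum-jerk
    reach and grows with motion irregularity.

Each parameter is evaluated per phase and for the whole trial, each
surgeon is represented by the mean of their first two trials (to avoid
learning effects), and the parameters are screened by Spearman rank
correlation against a nine-category criteria-based rating scale
(1–5 per category from three blinded raters, totals 9–45). The
best-screening parameters feed Fisher linear discriminants separating
good performers (total $\geq 35$) from poor ones, evaluated by ROC/AUC.

## Normalization of the area-change signal

The deformation threshold is an order-1 constant, which is implausible
for raw pixel-count differences (tens of thousands of pixels). The
package therefore normalizes the VA series by its within-trial mean
before differencing, making $\Delta\mathrm{VA}$ dimensionless per
second and independent of image resolution and zoom:
$\Delta\mathrm{VA}[f] = (\mathrm{VA}[f{+}1]-\mathrm{VA}[f]) \cdot
\mathrm{fps}/\overline{\mathrm{VA}}$. `first_frame` and `none`
normalizations are available for sensitivity checks. Forward differences
are used — the simplest estimator consistent with a rate definition —
and no pre-smoothing is applied by default, since a segmentation area is
already an integral over many pixels.

Two further conventions are fixed because a counting rule must be
unambiguous even where a verbal definition is not:

* **Excursion counting.** A deformation *error* is read as an event, so
  a maximal run of consecutive super-threshold samples of common sign
  counts once (`counting_mode = "excursion"`); `per_sample` counting is
  retained as an option. Samples exactly at the threshold do not count.
* **Strict inequality** at the threshold, so a boundary sample is not an
  error.

## Kinematics with detection gaps

When a tool leaves the microscope's field of view there is simply no
kinematic data, and bridging the gap would fabricate motion. Valid
frames are therefore partitioned into maximal contiguous segments;
derivatives never span a gap, procedural time $t$ is the summed duration
of valid segments, and PD sums Euclidean steps within segments only.

Because the jerk is a third derivative, detection jitter is amplified
roughly as $\mathrm{fps}^3$; positions are smoothed within segments by a
Savitzky–Golay filter (local quadratic, 7-frame window at 30 fps by
default; `window = 1` disables smoothing and is used in every
closed-form test). Derivatives use second-order central differences with
third-order one-sided stencils at segment ends — the edge order matters
because jerk peaks at movement endpoints, and lower-order edges visibly
bias the squared-jerk integral at realistic sampling rates. The integral
itself uses the trapezoid rule. For 2-D tracks the squared jerk
magnitude is the squared Euclidean norm of the component-wise third
derivative.

With these choices a sampled 1000-frame minimum-jerk reach scores
within 1% of the analytic value 360, the error shrinking monotonically
with sampling density, and NJI is invariant (to $10^{-6}$ relative)
under temporal and spatial rescaling, rotation and translation.

## Phase stratification

Phases are half-open frame intervals $[\mathrm{start}, \mathrm{end})$,
sliced *before* metric computation so that per-phase NJI is normalized
by phase-local $t$ and $D$. Two refinements:

* $\Delta\mathrm{VA}$ is computed once on the whole-trial series and
  then windowed, so the threshold means the same thing in every phase;
  CV-VA, by contrast, is the natural phase-local SD/mean.
* PD attributes the step from frame $f$ to $f{+}1$ to the phase
  containing $f$. Per-phase PD therefore sums exactly to whole-trial PD
  when the phases tile the trial. Non-additive metrics take the pure
  half-open slice with no boundary overlap.

"All" rows are whole-trial computations on the union window, not
aggregates of the per-phase values.

## Rubric aggregation and reliability

Per surgeon, each category score is averaged over (3 raters × first 2
trials); the total is the sum of the nine category means. Interrater
reliability is Cronbach's $\alpha = \tfrac{k}{k-1}\bigl(1 - \sum_j
s_j^2 / s_{\mathrm{sum}}^2\bigr)$ across raters, computed per category
on each rater's first-two-trial mean scores (and once on rater totals
for a whole-scale value). $\alpha$ is invariant to per-rater constant
offsets and degenerates (flagged `NA`) when the rater sum has zero
variance. Good/poor labels apply the 35-point cutoff to the total; a
total of exactly 35 is defined as good — the rule must be total, though
on bimodal study-like cohorts no surgeon sits on the boundary.

## Screening and feature selection

Every parameter cell is correlated with every category by Spearman's
$\rho$ (mid-rank ties; Pearson correlation of ranks). The default
p-value is the two-sided $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; a permutation method is available
that enumerates all $n!$ orderings exhaustively for $n \le 7$ and
otherwise uses Monte-Carlo resampling — recommended at cohort sizes
around 14, and used as the enumeration oracle in the tests. No
multiple-testing correction is applied by default, matching standard
practice for this screening design (a Benjamini–Hochberg option
exists).

Feature selection formalizes the published inclusion rule: within each
family (vessel-derived; motion-derived per hand), every parameter with
at least one significant category contributes its best phase cell — the
cell significant for the most categories, ties broken by smaller median
p over the nine categories, then by phase order A, B, C, D, All. The
vessel family forms Model 1, the motion family Model 2, and their union
Model 3. Applied to the bundled reference screening table of a
14-surgeon cohort (`inst/extdata/reference_screen_pvalues.csv`, parsed
by `read_screen_pvalues()`; stars carry the significance of cells whose
printed p rounds to 0.05), the rule selects `No. of TDE`/C and
`Max-dVA`/B for Model 1 and `Rt-PD`/All, `Lt-PD`/All, `Lt-NJI`/All,
`Rt-NJI`/C for Model 2 — including resolving the genuine tie between
`Rt-NJI` phase C and D (7 significant categories and equal median p
each) in favour of C by phase order.

## Discriminant models and ROC

`fit_lda()` is an equal-prior Fisher discriminant: weights
$w = S_p^{-1}(\bar x_{\mathrm{good}} - \bar x_{\mathrm{poor}})$ with
the pooled within-class covariance ($n-2$ denominator), oriented so the
score rises toward good. The system is solved in correlation-scaled
coordinates because the features differ by many orders of magnitude
(NJI vs CV-VA); a diagonal ridge of $10^{-6}\,\mathrm{tr}(R)/p$ is
added only when the scaled matrix is singular (e.g. duplicated
features), with a message. Class priors do not affect the ROC, so the
equal-prior choice is inert for the reported statistics.

AUC uses the rank (Mann–Whitney) formulation with half credit for ties,
which equals the trapezoidal area under the empirical curve exactly —
the tests verify this identity against a brute-force pairwise count on
random fixtures. The 95% CI is a stratified bootstrap percentile
interval (2000 resamples by default, classes resampled separately) —
assumption-light at cohort sizes near 14, where normal-theory intervals
are doubtful.

## The synthetic cohort

Real data for this task are per-frame outputs of perception models on
surgical video, which cannot be redistributed. The generator
(`generate_cohort()`) instead emulates the *statistical structure* the
analysis assumes: a latent skill $s \in [0,1]$ per surgeon drives every
degradation channel multiplicatively in $1-s$.

* **Trajectories** are chains of minimum-jerk submovements (the
  Flash–Hogan quintic $10\tau^3 - 15\tau^4 + 6\tau^5$) between random
  waypoints in each phase; low skill adds Poisson-distributed detour
  submovements (rate 8 per phase at $s=0$), jerk-level Gaussian noise
  (per-frame SD 2000 px/s³ at $s=0$, triple-integrated into positions
  with per-second quadratic drift removal — calibrated to ~1.5 px of
  tremor-band positional noise), 0.3 px detection jitter for everyone,
  and ~1.5 out-of-view gaps of 0.2–0.8 s per hand.
* **Vessel areas** are a 20 000 px baseline with slow sinusoidal drift
  (±2%, periods 23 s and 47 s), 0.2% frame noise, and
  Poisson($6(1-s)$) deformation events: a sharp relative drop of ~0.3
  over 0.1 s (far above threshold) followed by an exponential recovery
  with a 0.5 s time constant (deliberately below threshold), placed
  preferentially in phases B and C. Each event thus produces exactly one
  negative excursion.
* **Phase durations** average 10/15/15/30 s for A–D at $s=1$, dilated by
  up to 80% for novices with 10% log-normal trial-to-trial variation.
* **Rubric scores** are $\mathrm{round}(1 + 4s + N(0, 0.5))$ clipped to
  $[1,5]$ per rater, trial and category.
* Skills default to a bimodal mixture (half $N(0.8, 0.07)$, half
  $N(0.3, 0.07)$, clipped), mirroring the bimodal totals that motivate
  the good/poor split.

A single seed drives everything through per-surgeon substreams, so a
fixed configuration is byte-reproducible. On the default cohort the
full workflow — extraction, aggregation, rubric, screening, LDA —
separates the skill clusters with AUC $\geq 0.9$ (typically 1.0), and
NJI and TDE counts are stochastically decreasing in skill.

What the generator does **not** emulate: segmentation failure modes
(instrument shadows misclassified as vessel), correlated rater bias,
depth (everything is 2-D), learning across trials, and any coupling
between hands beyond shared skill. Passing tests on synthetic cohorts
therefore validate the *computational chain*, not the perception models
or the clinical validity of the parameters.

## Numerical and design notes

* Problem sizes: analysis and acceptance runs use the default cohort
  (14 surgeons × 2 trials, ≈ 2000–4000 frames per trial at 30 fps
  depending on skill), which keeps a full pipeline run under a minute
  on one core;
  closed-form kinematic checks use 1000-frame reaches.
* NJI values on full trials are large (10¹¹–10¹³): the $t^5$ factor
  compounds over multi-minute procedures. They are comparable only
  within a fixed task and segmentation convention; the discriminant uses
  them only through rank-preserving linear scores.
* Readers validate inputs eagerly (monotone frames, score ranges 1–5,
  non-overlapping ordered phases, consistent mask dimensions) and fail
  with named errors rather than silently coercing.
* Missing cells (a hand invisible for an entire phase) propagate as
  `NA` and are dropped listwise by the screen and the discriminant; a
  phase with no valid detections of its own is missing even when the
  adjacent boundary frame is detectable.
* The recording frame rate of any given dataset is unknown to the
  package; every reader takes `fps` explicitly (default 30).

## Known limitations

The TDE threshold of 1.13 is adopted from its published derivation, not
re-derived (the underlying trials are unavailable); its exact
normalization is this package's trial-mean convention, which should be
re-checked against any new segmentation pipeline via
`cohort_tde_threshold()`. Whether deformation errors were originally
counted per excursion or per frame is not documented — both modes are
implemented. Small-cohort p-values differ slightly between the t
approximation and permutation; at $n = 14$ the third decimal should not
be over-read. In-sample AUCs on 14 surgeons are optimistic; the package
reports them with bootstrap CIs but implements no cross-validation by
design.
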
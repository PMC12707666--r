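---
title: "Methods: encoding models of dynamic body perception and their synthetic twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding models of dynamic body perception and their synthetic twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dynbody)
```

This vignette documents the model, the synthetic-data generator, the
numerical choices, and the design decisions that were genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The encoding model

Each voxel's time series $y$ (TR = 2.3 s) is modeled as a linear function
of delayed stimulus features from $B$ feature spaces ("bands"):

$$ y = \sum_b X_b W_b + \varepsilon, $$

where $X_b$ contains each stimulus feature at 5 delays of 1–5 TRs after
onset (spanning 11.5 s of hemodynamic lag — a FIR-style stand-in for the
HRF). Banded ridge regression fits all bands jointly with one penalty per
band:

$$ \min_W \Big\|Y - \sum_b X_b W_b\Big\|^2 + \sum_b \lambda_b \|W_b\|^2 , $$

solved in closed form by the scaled-concatenation trick (divide band $b$'s
columns by $\sqrt{\lambda_b}$, solve an ordinary ridge with unit penalty in
the primal or dual form depending on whether features or samples are
fewer, scale the weights back). Equal penalties reduce exactly to ordinary
ridge on the concatenated features; the tests verify this to 1e-8.

**Delays.** The delayed copies are at 1–5 TRs (2.3–11.5 s). A 0–4 TR
variant is available (`delay_offset = 0`) since an undelayed copy is a
plausible reading of "5 delays"; the default matches "spanning 11.5 s".

**Onset regressor.** `cross_validate()` appends a per-band delayed unit
"onset" feature. Standardizing stimulus features with training statistics
is an affine map; it is an exact reparametrization of the unstandardized
generative model only if the delayed stimulus indicator is inside the
design span. With it, noiseless synthetic data yield held-out joint
$r = 1$ exactly (the generative-identity invariant); without it, a small
structural residual remains. It also absorbs the mean evoked response.

## 2. Cross-validation and hyperparameters

Whole runs are the cross-validation unit: 3 outer folds (train 8 / test 4
of 12 runs), and within each training set 4 inner folds (train 6 /
validate 2). Feature matrices are standardized per outer fold using the
training stimuli only; test features reuse the training mean and SD.
Zero-variance training columns are dropped with a warning.

Penalties are selected by random search: `n_random` (default 100)
candidates drawn log-uniformly per band from `lambda_range` (default
1e-3–1e5), scored on the inner validation runs, with optional coordinate
descent on log-penalties (`refine` sweeps of ±0.5 decades, halving on
failure).

Two deliberate choices here:

- **Score.** The default selection score is out-of-sample $R^2$, not
  correlation. Correlation is scale-invariant, so it cannot distinguish an
  overfit model whose predictions have wildly inflated amplitude from a
  well-regularized one; selecting on correlation produced systematically
  negative test $R^2$ at realistic SNR. $R^2$ is also what the standard
  banded-ridge solvers optimize. `score = "correlation"` is available.
- **Tie-breaking (`tie_tol`).** For a band with no predictive content the
  expected validation score is monotone in its penalty, but the *realized*
  score is flat with chance-level wiggles, and its argmax is an arbitrary
  plateau point. Within `tie_tol` (default 1e-6) of the best score the
  search prefers the more regularized candidate — the same logic as the
  one-standard-error rule in penalized regression. With it, a pure-noise
  band's selected penalty lands in the top decade of the grid in ≥ 90% of
  simulation replicates; without it, about half the time.

## 3. Accuracy and variance partitioning

Prediction accuracy is the Pearson correlation between held-out data and
prediction, per fold and voxel; fold values are Fisher z-transformed
(atanh, after clipping at ±(1−1e-7)), averaged, and back-transformed.
Zero-variance predictions score 0 and are logged.

For partitioning, with $\hat y = \sum_b \hat y_b$ (per-band partial
predictions) and centered variables, we use the exact identity

$$ R^2 \;=\; \sum_b \frac{2\,\mathrm{cov}(y,\hat y_b) -
\mathrm{cov}(\hat y_b, \hat y)}{\mathrm{var}(y)} , $$

so the signed band contributions always sum to the joint $R^2$ (machine
precision; tested). Negative contributions (suppression) are clipped to
zero before normalizing to fractions, and the number of clipped entries is
reported — the original analyses do not state how suppression was handled,
and this choice is flagged rather than hidden. Classical partial
correlations of $y$ with each $\hat y_b$, controlling for the other bands'
predictions, are returned alongside; they are the second operationalization
compatible with the methods literature, and keeping both avoids collapsing
the dual reading into one number.

**The composite HSV map.** After factoring out the motion-energy fraction,
the residual fractions of kp3d / categorical / SimDist are mixed as RGB
weights (pure red = kp3d, pure green = categorical, pure blue = SimDist)
and converted to hue; saturation is the residual strength
$1 - \text{fraction}_{\text{moten}}$ rescaled between $S_{\min} = 0.23$
and $S_{\max} = 0.93$; value is the joint accuracy min–max scaled over the
map. Exactly equal residual fractions are achromatic and forced to
$S = 0$.

## 4. The synthetic world

The generator's defaults are the stated experimental design, not free
dials: 120 stimuli (60 possible + 60 impossible), 4 actions (kick, jump,
point, wave), 17 actors, clips of 60–90 frames at 30 fps, 12 runs over 2
sessions with 20 stimuli × 3 repetitions + 3 targets + 3 blanks per run,
ISI ∈ {2,3,4} TRs, TR 2.3 s.

**Skeleton.** 71 named joints in a rooted tree (Euler order fixed to ZXY
and documented; the mocap source's native order is not stated anywhere
authoritative). 56 joints carry rotation channels; 15 (root anchor, neck,
head, 12 facial keypoints) are rigid. Two printed counts must emerge from
one construction — 56 joints with rotation data *and* 56 keypoints with
positional variance across the stimulus set. A joint's position varies
only if an ancestor rotates or its offsets differ across stimuli, so the
rigid facial subtree hangs directly off the root (keeping it frozen), and
actor stature scales only body-joint offsets (giving branch-head joints
such as the hips cross-stimulus positional variance). This is a
topological idealization of a mocap skeleton, chosen so both exclusion
rules independently select the same 56 joints.

**Trajectories.** Each rotation channel is a sum of ≤ 3 sinusoids at
0.5–2 cycles per clip with action-specific amplitudes (legs dominate
kicks, one arm dominates pointing, etc.) plus a small baseline wiggle on
every rotating joint. Elbow/knee flexion channels are mapped affinely into
[0°, 150°], so flexion never violates the anatomical limit — verified over
a 100-seed sweep.

**Impossible movements.** The elbow/knee rotation about the flexion axis
is negated at every frame (the simplest operation that reverses bending
direction), then the wrist/ankle local rotation is re-solved in closed
form, $L' = (R^{\text{new}}_{\text{parent}})^{\top} R^{\text{orig}}_{\text{joint}}$,
so hand/foot world orientations match the original exactly (tested to
1e-6 rad via an independent forward-kinematics oracle). Re-solving the
next joint down the chain rather than optimizing over shoulder+wrist
jointly is a deliberate simplification: it achieves exact end-effector
orientation preservation, which is the stated goal ("as close as
possible"), with no iterative machinery. The operation is an involution on
the mirrored joints.

**Rendering.** Stick-figure videos (orthographic projection, anti-aliased
segments, default 128 × 64 px emulating the tall 1.84° × 4.32° stimulus
aperture) replace avatar animation: the motion-energy model consumes only
luminance. Rendered figures stay centered on the fixation point by
mapping a fixed world point to the image center, which also keeps the
projection linear in keypoint translation.

**BOLD.** $Y = \sum_b X_b W_b + \varepsilon$ with i.i.d. Gaussian noise.
Weights are drawn standard normal and rescaled per voxel so each band's
signal variance matches requested fractions; the default fractions
(kp3d .20, categorical .125, SimDist .30, MotEn .375) follow the reported
band shares, and the default SNR of 0.111 corresponds to a joint model
explaining ~10% of voxel variance, the reported magnitude in the body-
selective region of interest. Noise is white by default: the accuracy
metric is correlation-based, and temporal autocorrelation would change
significance calibration, not point estimates; an AR structure can be
emulated by filtering the noise externally. These values are set once from
the stated world and are not tuned against test outcomes.

**What a green test does not establish.** The synthetic stimuli share the
real design's counts and the generative model's structure, but they are
not human movements: kinematics are sinusoidal, rendering is a stick
figure, and the four bands are built from the *same* trajectories, making
them far more collinear than engineered feature spaces on natural video.
Parameter-recovery tests therefore use independent random band designs;
the pipeline-level tests establish wiring, determinism and the noiseless
identity, not attribution accuracy on collinear bands.

## 5. SimDist details

Euler angles are converted per frame to axis-angle 3-vectors (angle in
[0, π] via the quaternion route; a rotation-matrix route serves as the
test oracle). For joint $j$ with manifold samples $m_{ji}$ pooled over
frames and exemplar possible movements,

$$ s_{jt} = \tfrac1N \sum_i \exp\!\big(-\|x_{jt}-m_{ji}\|^2 / 2\sigma_j^2\big),
\qquad d_j = \tfrac1T \sum_t (1 - s_{jt}) \in [0,1]. $$

The exact formulation of the original supplement is unavailable, so
`-log s` and nearest-sample (`1 - max`) variants sit behind a `mode`
switch. $\sigma_j$ uses the median pairwise-distance heuristic with a
1e-3 rad floor (scale-adaptive, standard); manifold sample sets are
optionally thinned to `max_samples` (seeded) to bound kernel cost. Frames
are compared to the pooled manifold without time warping, matching the
per-time-point description. Joints with any non-finite distance across
the stimulus set are dropped before concatenation; with this bounded
kernel no joint is ever non-finite, so the documented 56 → 29 reduction
is exercised with injected non-finite fixtures rather than reproduced
organically (what made 27 joints non-finite in the original data is
unknowable from the text).

## 6. Motion-energy details

Videos are converted to CIE L\* (sRGB linearization, D65 relative
luminance, L\* mapping; endpoints 0 and 100 tested against an independent
colorimetric computation). The filter bank crosses orientations
{0°, 45°, 90°, 135°}, spatial frequencies {0.5, 1, 2, 4, 8} cyc/°,
temporal frequencies {1, 2, 4, 8, 16} Hz and two directions per
orientation. Spatial envelopes scale as $\sigma = 0.56/f$ degrees
(≈ octave bandwidth) and grid spacing is $3.5\sigma$ with floor-based
counts, so channel count is a pure function of the configuration — the
published figure of 3,703 channels depends on unstated frame geometry and
is *reported, not forced*. Three numerical points matter:

- DC removal is envelope-weighted and normalization is shared within a
  quadrature pair; both preserve the exact 90° phase relation (naive
  per-filter mean subtraction and normalization break phase invariance at
  the 1e-1 level; the implemented bank is phase-invariant to ≤ 1e-6).
- Temporal kernels use "same" convolution with edge replication, but
  frame-averaging covers only frames whose kernel support lies fully
  inside the clip (when enough frames exist): replicated-edge transients
  are phase-dependent and would otherwise contaminate the mean.
- Energies are $\log(x + \varepsilon)$ with $\varepsilon$ = 1e-5 of the
  video's maximal raw energy (absolute floor 1e-12), so zero-contrast
  videos give a finite, constant floor.

## 7. Group statistics

The sign-flip permutation statistic is the group mean (the simplest
one-sample location statistic; the original analysis does not name one).
All $2^N$ assignments are enumerated for $N \le 12$ — 2048 at $N = 11$ —
making p-values exact multiples of $2^{-N}$ and never zero; larger groups
use seeded Monte-Carlo with the identity flip always included. P-values
are two-sided by null symmetry. FDR is Benjamini–Hochberg step-up,
applied across locations (and within contrast families for tables);
whether the original corrected per hemisphere is unstated, so the
procedure takes whatever family it is given. Paired contrasts report
$d_z = |t|/\sqrt N$ and retrospective power from the exact two-sided
noncentral-t probability with noncentrality $d_z\sqrt N$ (the base-R
power helper drops the opposite tail; the difference is ~1e-6). The
three-way repeated-measures ANOVA decomposes within-subject sums of
squares by inclusion–exclusion, tests each effect against its
subject-by-effect interaction, applies no sphericity correction
(documented; none is reported in the source analyses), and reports
$\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$.

## 8. Known limitations

- Attribution between collinear bands is inherently unstable at low SNR;
  only the sum of contributions is guaranteed (exactly) to equal $R^2$.
- The mirroring operation preserves end-effector *orientation*, not
  position; the original avatar pipeline may have balanced both.
- The Gabor bank is a faithful family member but not a channel-for-channel
  replica of any published implementation.
- No AR(1) noise, no laminar structure, no surface geometry: group maps
  are plain location vectors.
- Exhaustive permutation beyond N = 20 is refused by memory, by design.
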
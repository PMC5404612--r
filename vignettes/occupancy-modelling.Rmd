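---
title: "Modelling striatal occupancy studies with occupet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling striatal occupancy studies with occupet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dynamic PET with a reversible D2-receptor antagonist such as
¹¹C-raclopride measures the non-displaceable binding potential (BP_ND) of
striatal dopamine receptors. Because the tracer competes with endogenous
dopamine, a pharmacological challenge that raises synaptic dopamine lowers
BP_ND; the percent change between a baseline scan and a post-challenge
scan,

ΔBP = 100 · (BP_base − BP_post) / BP_base,

is the standard proxy for the evoked dopamine elevation. A typical
crossover design scans each subject at baseline and after the challenge
under each of two pre-treatment conditions (four scans per subject), and
asks whether the condition changes ΔBP.

Raw data from such studies are rarely public. `occupet` therefore pairs
the full analysis chain — SRTM kinetic fitting, ΔBP, test–retest
reliability, region and voxel contrasts — with a synthetic-cohort
generator that emulates the design, so that every stage is testable by
parameter recovery: the generator encodes known truths, and the pipeline
must return them.

## The kinetic model

Time-activity curves (TACs) are fitted with the simplified reference
tissue model (SRTM), which expresses the target-region concentration in
terms of a reference-region curve C_r(t) from tissue devoid of specific
binding (cerebellum):

C_T(t) = R1 · C_r(t) + (k2 − R1 · k2a) · C_r(t) ⊗ exp(−k2a · t),

with k2a = k2 / (1 + BP_ND). The three parameters are the relative
delivery R1 (unitless, ≈ 1), the target efflux rate k2 (1/min, ≈ 0.3 for
raclopride in striatum) and BP_ND (unitless). No arterial input function
is needed.

### Basis-function fitting

`fit_srtm()` uses the basis-function method: for each candidate k2a on a
log-spaced grid (default 128 points in [0.006, 0.6] /min, a range that
brackets raclopride kinetics generously on both sides) the model is linear
in (R1, θ2 = k2 − R1·k2a), so a weighted 2-parameter least-squares solve
per basis gives the exact conditional optimum; the k2a with minimal
weighted RSS wins. The winning node is then refined between its
bracketing neighbours — by golden-section search on the RSS profile (ROI
default) or by parabolic interpolation in log-k2a (voxel default, which
needs only one extra basis evaluation per voxel). On noise-free data the
refined fits recover BP_ND to ~1e−5 (ROI) and ~1e−4 (voxel); the raw grid
alone is accurate to about the 3.7% grid spacing.

Two details matter for correctness at the edges. If the winning k2a is a
grid endpoint the fit is flagged (`boundary_flag`) rather than silently
refined, since the optimum may lie outside the searched range. And when
θ2 is numerically zero the target is a scalar multiple of the reference,
every k2a fits equally well, and the fit reports BP_ND = 0 with R1 from
the linear solve instead of an arbitrary grid point.

### Weights, convolution grid, reference reconstruction

Frames are weighted by duration and isotope decay, w ∝ Δt · exp(−λ·t_mid)
with λ = ln2/20.4 per min for carbon-11, normalised to sum to 1 — the
usual count-statistics surrogate; a uniform mode exists for tests.

Convolutions run on a regular fine grid (dt = 0.05 min) using the
trapezoidal recursion c[i] = e·c[i−1] + dt/2·(y[i] + e·y[i−1]),
e = exp(−k2a·dt), which is overflow-safe for any k2a. Frames are
half-open intervals [start, end); frame values are trapezoidal averages
over the frame. Halving dt changes frame-averaged model curves by well
under 0.1%.

Measured reference TACs are frame averages, not instantaneous samples, so
`tac_to_fine()` reconstructs a piecewise-linear fine-grid curve anchored
at (0, 0) whose own frame averages match the measurement (20 fixed-point
sweeps, each contracting the mismatch by about half). Fitting through
this reconstruction instead of midpoint interpolation keeps the
noise-free ΔBP bias of the full pipeline below 0.001 percentage points.

## The synthetic cohort

`simulate_cohort()` generates, per subject and condition, a session of a
baseline and a post-challenge scan on the 33-frame / 120-min schedule
(6 × 0.5, 3 × 1, 2 × 2, 22 × 5 min). Defaults encode the study
conditions the package validates against:

* **Reference curve** — a bi-exponential rise-and-washout with peak at
  4 min, peak amplitude 30 kBq/ml and terminal half-life 25 min,
  qualitatively matching cerebellar raclopride kinetics; no published
  input function exists, so the shape is fully parameterised.
* **Baseline BP_ND** — striatum 2.5, caudate 2.4, putamen 2.8, ventral
  striatum 2.2 (typical raclopride values; the study reports no baseline
  BP), with 10% between-subject log-normal variation; R1 ~ N(1, 0.05),
  k2 ~ N(0.3, 0.03) per subject.
* **True ΔBP** — drawn per subject and condition from Normal(mean, SD)
  cells; condition defaults are the whole-striatum cells 17.1 (3.6) and
  8.8 (3.6) percent. With `recenter = TRUE` the draws are shifted so the
  sample mean equals the population mean exactly, which makes the
  recovered condition mean directly comparable to the configured truth.
  The post-scan generating BP is baseline × (1 − ΔBP/100) in every
  region.
* **Noise** — zero-mean Gaussian per frame with variance
  noise_scale² · C(t_mid) · exp(λ·t_mid) / Δt: later and shorter frames
  are noisier, as decaying count statistics dictate. The ROI default
  noise_scale = 0.1 gives peak-frame noise of a few tenths of a kBq/ml
  (≈ 1–2% of signal) and per-scan BP errors well under 1%, a mildly
  optimistic ROI noise level; the voxel default is 1.0.
* **Crossover** — exactly floor(n/2) subjects receive the first-listed
  condition in session 1.
* **Covariates** — plasma methylphenidate draws at 30/90/150 min
  (condition means 12.7 and 11.7 ng/ml), TNFα/IL-6/IL-8 curves at
  0–240 min that rise only under LPS with TNFα peaking before IL-6, and
  integer 0–4 fatigue scores; all generated independently of ΔBP, so
  correlation screens against them form a true null.

All randomness descends from one root seed through deterministic
per-subject/per-scan streams; repeated runs are bit-identical.

### What the generator does **not** emulate

Generation is model-consistent: targets come from the SRTM forward model
itself, so exact parameter recovery is a valid oracle (an optional
two-tissue-compartment mismatch mode was considered and deliberately left
out of scope). There is no physiological session-to-session variation in
baseline BP — simulated test–retest variability reflects TAC noise only
and sits far below the ~5% seen in human repeat scans. There is no head
motion, no scanner point-spread function (an optional blur stage was left
off by default to keep partial-volume effects out of fitting accuracy
checks), no attenuation/scatter physics, and no reconstruction. Passing
recovery tests therefore demonstrate correctness of the estimator chain,
not robustness to every real-data pathology.

## The digital phantom and voxel path

`make_phantom()` builds a 64 × 64 × 32 label volume at 2.1 × 2.1 × 2.4 mm
voxels (a deliberate desk-scale reduction of the scanner's 128 × 128 × 63
grid) containing bilateral ellipsoidal caudate (10.2/10.5 ml), putamen
(10.7/11.3 ml) and ventral striatum (1.4/1.5 ml) matched to the template
ROI volumes within 10% by bisection on the ellipsoid scale, plus a 40-ml
cerebellar reference blob (a synthetic stand-in; no template volume
exists). Regions must not overlap and must fit the field of view, else
construction errors.

`render_dynamic_image()` fills each labelled voxel with its region's TAC
plus independent per-voxel noise under the same variance law;
`extract_roi_tac()` pools voxels unweighted. "Whole striatum" is pooled
voxelwise, so larger sub-regions contribute proportionally — one of the
places where the underlying study is ambiguous and a convention had to be
chosen. `fit_voxelwise()` vectorises the basis grid stage across voxels
and marks voxels invalid when the fit is non-finite, on the grid
boundary, or outside the BP clamp (−0.9, 10); invalid voxels are excluded
from maps and from both numerator and denominator of
percent-significant-voxel summaries. ROI-level fits are deliberately not
clamped: test–retest noise can legitimately produce small negative ΔBP,
and the study's own sub-region table contains a negative cell.

## Group statistics

Condition contrasts use the paired two-tailed Student t-test per region,
reported uncorrected with the Bonferroni threshold (α/m, here 0.05/6)
printed alongside. Voxelwise contrasts run the same paired t per voxel
and publish (1 − p) images displayed above 0.90, with the sign of the
mean paired difference kept as a separate direction image; no voxel-level
multiplicity correction is applied, matching the descriptive map style of
the source design. Correlation screens are Pearson r with t-based
p-values. Arms without within-subject pairs (the 2-subject LPS-alone
arm) are summarised descriptively only.

Reliability of repeated baselines uses ICC(1,1) — one-way random effects,
single measure — because the two baseline scans are unordered replicates;
ICC(2,1) is available for comparison. "Percent variability" is the mean
of 100·|bp1 − bp2| / mean(bp1, bp2), the symmetric form. The Wilcoxon
signed-rank test drops zero differences and uses the exact rank-sum null
(`psignrank`) for n ≤ 25 without ties, else a tie- and
continuity-corrected normal approximation; all-zero differences give
p = 1 by convention, flagged. The ΔBP sign convention (positive =
reduction) and these formula choices are package conventions where the
source design's exact equations are not printed.

## Validation problem sizes

The shipped test suite validates, among other things: noise-free BP
recovery to < 0.01 over a 5 × 5 × 5 grid of truths (R1 ∈ [0.7, 1.3],
k2 ∈ [0.1, 0.5], BP ∈ [0.5, 4]); recovery of the condition-mean ΔBP cells
(17.1/8.8 striatum, 17.9 putamen, 16.1 caudate, 8 subjects, recentred,
default noise) within 1.5 percentage points and of the 2-subject
LPS-alone cell (6.1) within 2; paired-t type-I error at n = 8 over 2000
null replicates within 0.05 ± 0.01; exact voxel/ROI agreement on
noise-free rendered phantoms; and a ~10% display rate of the
(1 − p) > 0.90 mask under a null voxel contrast of 8 simulated subjects.
These sizes were chosen as the smallest designs that exercise the claims
at the study's own n.

## Known limitations

* SRTM assumes a one-tissue target and a valid reference region; the
  simulator honours those assumptions by construction, so model-mismatch
  bias is out of scope here.
* ROI-level recovered ΔBP inherits a per-subject estimation error of
  roughly 1 percentage point at default noise; 2-subject arms are
  correspondingly volatile.
* The phantom's ventral striatum is an ellipsoid label, not an anatomical
  definition; its small volume (≈ 140 voxels per side) makes its voxel
  statistics the noisiest.
* `analyze` mode trusts the TAC tables' frame timing; it validates
  contiguity but cannot detect mislabeled units.
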
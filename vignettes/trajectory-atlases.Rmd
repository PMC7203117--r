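---
title: "Trajectory-image atlases: model, pipeline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-image atlases: model, pipeline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trackatlas classifies *cell motility styles*: given time-lapse trajectories
of cells moving around biologically meaningful reference points (immune
cells around tumor cells, or cancer cells inside a cluster), it decides
whether a condition — typically a drug — changed how the cells move. The
central idea is visual: each trajectory is drawn as a small binary image
relative to its reference point, the collection of images forms an *atlas*,
a fixed convolutional network turns each image into a high-dimensional
descriptor, a linear SVM classifies each descriptor, and per-track
decisions are aggregated by majority voting into neighborhood-, cluster-,
and video-level verdicts.

This vignette explains each stage's model and assumptions, the parameters
that matter, what the synthetic generator does and does not emulate, and
the numerical choices the package makes where the problem left the design
open.

## 1. The motion model

Cell motion is treated as a 2D random walk with time-varying drift and
volatility. Writing the position at frame $t$ as $(x(t), y(t))$, the
per-frame displacement on each axis is

$$\Delta x(t) = \mu_x(t) + \sigma_x(t)\,w(t), \qquad
  \Delta y(t) = \mu_y(t) + \sigma_y(t)\,w(t),$$

with $w(t)$ white noise (standard Gaussian in this package, independent
across axes and time; the noise model is pluggable in principle but only
the Gaussian is built in). The drift $(\mu_x, \mu_y)$ is the directed
component of motion — in the attraction mode it points toward a reference
point with a configurable magnitude, modelling the "attractiveness" of a
tumor cell — and the volatility $(\sigma_x, \sigma_y)$ is the dispersion
of the step. Drift and squared volatility are exactly the mean and
variance of the displacement, which is what the tracker estimates.

## 2. Tracking: windowed estimates, Gaussian likelihood, optimal assignment

`estimate_drift_volatility()` assumes local ergodicity: over a short
window of $T$ displacements the process is roughly stationary, so the
sample mean and the mean squared deviation (about the window mean, each
axis separately) of the last $T$ displacements estimate $\mu$ and
$\sigma^2$ at the current frame. The window (default $T = 10$) trades
responsiveness to drift changes against estimator variance.

`displacement_likelihood()` is the product of the two axis densities — a
bivariate Gaussian with independent axes. The cost of linking track $n$ to
detection $m$ in the next frame is the *inverse* of this density
(`build_cost_matrix()`), so the minimum-cost one-to-one matching, found by
a Jonker–Volgenant shortest-augmenting-path solver
(`solve_assignment()`), is the maximum-probability joint assignment.
Numerical choices:

* **$\sigma$-floor** (default 0.5 px): estimated volatilities are floored
  at half a pixel before entering the density, so a locally stationary
  cell never produces an infinite density (and thus a zero-cost sink).
* **Cold start**: a track with fewer than two displacements has no usable
  variance; it gets $\mu = 0$ and a population-prior volatility (default
  2 px/frame).
* **Shrinkage** (default `prior_strength = 2`): the volatility entering
  the cost is the windowed estimate shrunk toward the cold-start prior by
  two pseudo-displacements, $(T\hat\sigma^2 + 2\sigma_0^2)/(T+2)$. A raw
  2–5-sample variance is noisy enough that a genuine 3-sigma step would
  regularly be gated away, fragmenting tracks; the shrinkage removes that
  failure mode while converging to the plain estimate as the window
  fills. The estimator function itself always returns the exact windowed
  sample moments.
* **Gating**: the non-assignment cost is the inverse density at a
  Mahalanobis distance of 3 on each axis. Pairs costlier than the gate
  are unmatched: the track terminates and the detection seeds a new
  track. There is no gap closing and no multi-frame lookahead — frames
  are linked strictly pairwise.
* Rectangular problems are squared by augmenting with non-assignment
  rows/columns at the gate cost.

## 3. Detection: gradient-directed circular Hough transform

Cells are localized per frame as circular objects. After normalization and
a light Gaussian blur (default $\sigma = 1.5$ px — binary or
near-binary edges are jagged and their raw gradient directions
unreliable), pixels whose central-difference gradient magnitude exceeds a
fraction (default 0.25) of the frame maximum vote for a centre one radius
along their *inward* gradient direction (bright cells on a dark
background), once per candidate radius in the configured range. Votes are
pooled over a 3×3 neighborhood, normalized by the expected support of a
full perimeter, and capped at 1, so the score reads as "fraction of a
well-polarized perimeter found". Peaks above the sensitivity threshold
(default 0.5) survive a greedy non-maximum suppression (no second peak
within $r_{\min}$) and are refined to sub-pixel precision by the 3×3
accumulator centroid. Directed voting is what lets two cell populations
with radius ratio ~3 (tumor cells vs PBMC-scale cells) be scanned with
disjoint radius ranges without cross-talk: the inside of a large circle
never accumulates a full coherent perimeter at a small radius.

## 4. The atlas: binary trajectory images

`track_to_image()` marks, in a $(2R+1)\times(2R+1)$ binary image whose
centre pixel is the reference point, every pixel at the rounded offset
$(x(t)-x_c,\ y(t)-y_c)$. A stopped cell is a single white pixel; pure
drift is a straight line; revisited pixels collapse. The encoding is
deliberately minimal — no thickening, no temporal gradient — so the image
is a pure 2D projection of the path. Out-of-region points are clipped;
only a track entirely outside the region is an error. Rounding is
half-away-from-zero, which keeps the encoding exactly equivariant under
90° rotations about the reference.

The region radius $R$ defaults to the 98.5th percentile of the Euclidean
offsets of all grouped track points from their reference, rounded up:
almost every point of the dataset falls inside, while a single far
excursion cannot blow up the image size. Reference points come in three
modes: `tumor_neighborhood` (tracks assigned to the nearest tumor centre
within a radius, from the track's first position, ties to the
lower-indexed centre), `cluster` (single-linkage clustering of track
geometric centres with a distance cutoff — the cutoff, not a cluster
count, is the natural parameter when cluster sizes vary; the reference is
the mean of member centres), and `self` (each track's own centre).

## 5. Deep descriptors from a fixed backbone

Each image is bilinearly resized to 227×227, replicated to three
channels, and kept in $[0,1]$ with the background at exactly 0. The zero
background matters: trajectory images are sparse, and with rectified
convolutions a zero background contributes nothing, so every feature
describes trajectory geometry rather than the constant background level.

The backbone is an AlexNet-style stack truncated at its second pooling
stage: conv 11×11/stride 4 (96 filters), ReLU, 3×3/stride-2 max-pool,
conv 5×5/pad 2 (256 filters, two groups), ReLU, 3×3/stride-2 max-pool.
The flattened tap is $13 \times 13 \times 256 = 43264$ values per image.
The network is a *fixed* feature extractor — it is never fine-tuned, by
design: the pipeline's claim is that generic convolutional features
suffice, and retraining on small biological datasets risks overfitting.
Weights are either supplied from a file or drawn once from a fixed seed
(He-scaled Gaussians); the fixed-seed random backbone is the default and
makes the package fully self-contained and offline-reproducible. Random
convolutional features are not as strong as pretrained ones, but they
preserve the geometric content (oriented segments, blobs, turns,
positions on the 13×13 grid) that the linear classifier needs, and every
structural claim — feature dimension, determinism, leakage behaviour,
consensus ordering — is independent of the weight source.

Feature selection is unsupervised and variance-based: low-variance
features are rejected (default: the bottom half by variance, computed on
training rows only). The selection function does not accept labels, so
supervised selection is impossible by construction, and fold-restricted
computation prevents test-set information from leaking into the mask.

## 6. The kinematic baseline

For benchmarking, `descriptor_vector()` computes 28 classical descriptors
per track: for each of five series — tangential speed, curvature, angular
speed, turning angle, distance to the track centre — the mean, variance,
skewness, kurtosis, and Shannon entropy (25 values), plus three scalars:
mean distance to the group centre, a diffusion coefficient, and
directional persistence (net displacement over path length). Conventions
the package fixes where the literature varies:

* Entropy uses 16 equal-width bins over the series' own range, in bits;
  a constant series has entropy 0, and degenerate shape moments
  (skewness/kurtosis of a constant series) are 0 by convention.
* Moments 2–4 are variance, skewness and excess kurtosis as plain
  moment ratios.
* Curvature is the turning angle divided by the mean of the two adjacent
  segment lengths.
* The diffusion coefficient is the ordinary least-squares slope of the
  mean-squared displacement over the first quartile of lags, divided
  by 4 and floored at 0. For a Gaussian walk with per-axis step variance
  $\sigma^2$ the 2D MSD grows as $2\sigma^2\tau$, so this estimates
  $D = \sigma^2/2$ — the standard single-particle-tracking quantity.
* The time step is one frame internally; physical units (min/frame,
  µm/px) belong to reporting, not to the descriptors.

The descriptor vector is defined for any track of at least three points,
which is the baseline's key virtue: it is length-independent, like the
image encoding.

## 7. Classification and consensus

The classifier is a linear SVM with $C = 1$ and no feature scaling or
class weighting — deliberately default settings, since the pipeline's
contribution is the representation, not classifier engineering. Treated
is the positive class.

Evaluation is video-exclusive two-fold testing: videos (never individual
tracks) are partitioned into two folds — by experiment id when a
replicated-experiment structure exists, otherwise alternately within each
class after sorting — and each fold is tested with a model trained
(including feature selection) on the other. Images from one video are
never split across partitions, so the reported accuracy is
generalization across videos, not memorization of per-video texture.

Majority voting aggregates per-track labels over each group (tumor-cell
neighborhood or cluster) and over each video. A tied vote falls back to
the sign of the summed SVM margins — margins carry more information than
counts — and a zero margin sum defaults to untreated with a warning. The
metric at every level is balanced accuracy (mean of per-class recalls),
robust to class imbalance. When individual-track accuracy exceeds chance
and errors are roughly independent within a group, the majority vote is
more accurate than its members — the pipeline's central consensus claim —
and the package's Monte-Carlo tests verify the resulting ordering
(track ≤ group ≤ video accuracy) across seeds.

## 8. The synthetic generator: what it emulates, and what it does not

No suitable public dataset ships trajectories with the reference-point
structure this pipeline needs, so the package generates its own study:
`experiment_design()` + `simulate_experiment()` produce a two-condition,
multi-video experiment with groups of tracks around spatially separated
reference points. The defaults encode the study conditions used
throughout the tests:

* 4 videos per condition, 5 groups per video, 40 tracks per group
  (1600 tracks), observation window 72 frames;
* right-skewed track lengths — truncated lognormal with mean 23 and sd
  17 frames, clamped to [2, 72] — mimicking long observation windows in
  which most cells are tracked for only a fraction of the experiment;
* untreated cells drift toward their reference at 0.8 px/frame, treated
  at 0.1 px/frame, both with volatility 1.2 px/frame. The contrast was
  calibrated once so that the two conditions *overlap* at the
  single-track level (short tracks barely move under either condition,
  so no track-level classifier can be near-perfect) yet separate cleanly
  after consensus — the regime in which majority voting is interesting.
  Tracks are born at a uniformly random frame such that they fit in the
  window, starting within 40 px of their reference.

Simulated datasets are bit-for-bit reproducible from (design, seed), and
`render_video()` can rasterize any video as a grayscale stack (cells as
filled disks plus optional noise) for detector and tracker tests.

What the generator does **not** emulate: cell division and death,
shape/size change, cell–cell mechanical interaction, uneven illumination,
focus drift, or detection artifacts. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that
its statistical behaviour (consensus ordering, leakage protection,
estimator recovery) holds under the stated motion model — they do not
certify accuracy numbers on real microscopy, which depend on imaging
conditions the simulator does not model.

## 9. Problem sizes and determinism

The test-suite and acceptance problem sizes are chosen as the smallest
that exercise each property meaningfully: estimator recovery uses
1000-step windows; assignment optimality is checked exhaustively up to
6×6 (brute force enumerates ≤ 720 permutations); tracking fidelity uses
20 cells over 100 frames; the end-to-end study runs the full 1600-track
design once with the fixed-seed backbone; the consensus-ordering
Monte-Carlo uses 20 seeds of a 480-track design with the kinematic
features, since the ordering is a property of the consensus stage, not of
the feature extractor, and the kinematic pipeline exercises it at a
fraction of the cost. Every stochastic step is seeded; reported numbers
are reproducible with the stated seeds.

## 10. Known limitations

* The random-weight backbone underperforms a pretrained one;
  plugging in pretrained weights (an RDS file in the documented layout)
  is supported but not bundled.
* The tracker does not close gaps and does not model division: a missed
  detection splits a track in two. This matches the linking model's
  stated scope.
* Single-linkage clustering chains: elongated arrangements of track
  centres can merge clusters that a human would separate. The cutoff is
  exposed; no automatic selection is attempted.
* The Hough detector assumes bright, roughly circular cells on a darker
  background; polarity is fixed (inward votes), so dark-on-bright images
  must be inverted first.
* Balanced accuracy at video level is quantized by the small number of
  videos; with 8 videos, one flipped video moves the number by 12.5
  points.
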
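---
title: "Methods: segmentation, tracking and lineage analysis for mother-machine movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, tracking and lineage analysis for mother-machine movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The mother machine is a microfluidic device in which a single "mother"
bacterium is trapped at the dead end of a narrow growth chamber
(~25 µm long, ~1.3–1.8 µm wide); its progeny elongate, divide, and are
progressively pushed out of the open end into the flow channel.  Imaging
hundreds of chambers every few minutes for many hours yields an enormous
amount of single-cell data — provided every cell in every frame can be
segmented, followed to the next frame, and attached to its mother.  `mmtrack`
implements this analysis as a two-stage deep-learning pipeline plus the
surrounding plumbing: chamber detection and drift correction, training-set
construction with pixel-wise loss weights, on-the-fly data augmentation, the
two convolutional networks and their losses, score-matrix-based lineage
assembly, single-cell feature extraction (lengths, growth rates, division
timing, fluorescence), and an evaluation module that scores predictions
against ground truth with the field's attribution and tolerance rules.

Because no bench microscope is attached to a desk-scale build, the package
carries a full synthetic-movie simulator with exact ground truth; every other
module is trained and tested against it.

## Pre-processing

Chambers are located in the first full-field frame by zero-mean normalized
cross-correlation (ZNCC) against an empty-chamber template.  ZNCC rather than
plain correlation makes detection invariant to global illumination offsets
and scale.  Peaks above a correlation threshold (default 0.5) are selected
greedily, highest first, with a mutual exclusion radius defaulting to
0.8 × template width — chambers on a chip are regularly spaced, so the radius
only needs to reject double detections of the same chamber.

XY drift of frame *t* is estimated against frame 1 (not frame *t − 1*), so
estimation errors do not accumulate over a movie; the estimate is the integer
shift maximizing the correlation inside a ±`max_shift` window.  Sub-pixel
registration is deliberately out of scope: network inputs are
nearest-pixel crops anyway, and integer shifts keep crops exact sub-grids of
the raw data.  Crops are `c(256, 32)` pixels by default (a 25 µm chamber at
0.1 µm/px), with the closed end at row 1 and the open end at the last row;
out-of-frame pixels are filled by edge replication.

## Training samples and loss weights

A segmentation sample is a triplet: min–max normalized image, binary mask,
and a pixel weight map used only by the loss.  The weight map is

$$ w(x) = w_c(x) + w_0\, e^{-(d_1(x)+d_2(x))^2 / 2\sigma^2} $$

where `wc(x) = 0.5 / frequency(class(x))` balances foreground against
background (its image mean is 1 whenever both classes are present, keeping
loss magnitudes comparable across samples), and the second term puts strong
emphasis on thin background gaps between two cells — `d1`, `d2` are the
Euclidean distances to the nearest and second-nearest cell.  Defaults are
`w0 = 10`, `sigma = 5` px, classic values for this formula; with fewer than
two cells the border term vanishes (`d2` treated as infinite).  Cells are
8-connected components; per-component distance maps come from exact
Euclidean distance transforms.

On top of this, the weight of every cell-contour pixel (any cell pixel with a
background pixel among its 8 neighbours) is set to 0.  The exact 1-pixel
outline of a bacterium is ambiguous even to humans, and curation tools leave
systematic artifacts there; zeroing the contour weight frees the network from
fitting that arbitrary boundary.

Tracking samples have four input channels — previous image, previous-frame
mask of one "seed" cell, current image, current all-cells mask — and three
mutually exclusive targets: the seed cell in the current frame, its daughter
if a division just occurred, and everything else.  The three targets
partition the pixel grid, which is what makes plain categorical
cross-entropy applicable.  Samples are generated programmatically from
ground-truth lineages (one per cell per consecutive-frame pair); a cell
flushed out before the next frame yields empty seed/daughter targets.

## Data augmentation

Each training draw applies, in order: a sampled geometric transform (shift,
scale, rotation, flips — one transform for all channels), an elastic
deformation (Gaussian-perturbed coarse grid, densely interpolated), and two
monotone intensity remappings.  Binary masks and weight maps are resampled
by nearest neighbour (masks stay binary, zeros stay exact); images
bilinearly.

The two intensity operations both use a random monotonically increasing
curve built from sorted uniform ordinates at equally spaced knots (default
5), endpoints pinned at 0 and 1, interpolated with the monotone
Fritsch–Carlson cubic Hermite scheme (`splinefun(method = "monoH.FC")`, a
shape-preserving PCHIP).  The first remaps the intensity histogram
(`p -> f(p)`), emulating different lamp settings.  The second multiplies the
curve along the chamber axis and linearly restores the original intensity
range, emulating the illumination bands that microfluidic features cast
under phase contrast; its multiplier range is drawn from [0.5, 1].  Both
are config flags so their contribution can be ablated.  Intensity operations
apply only to transmitted-light channels.  Elastic deformation is applied to
segmentation and tracking samples alike (conservative: both see the same
image physics).

## Networks, losses, training

Both networks are encoder–decoder convolutional networks with skip
connections: per level two 3×3 "same"-padded convolutions with ReLU, 2×2
max-pooling down, a learned 2×2 stride-2 transposed convolution (with ReLU)
up, concatenation with the matching skip, and a final 1×1 convolution —
sigmoid head for segmentation (1 channel), per-pixel softmax for tracking
(3 channels).  Padded convolutions are used so output shape equals input
shape, which the equal-size mask contracts require.  The default is 5
levels and 64 base filters; the desk-scale experiments use 3 levels and 8
base filters on 128×32 crops.  Weights are He-initialized
(`sd = sqrt(2/fan_in)`) from the R random stream; biases start at 0.01 so
ReLUs begin active, which also keeps finite-difference gradient checks away
from activation kinks.

The engine is implemented in C++ (RcppArmadillo): im2col + BLAS matrix
products forward, exact reverse-mode gradients backward, verified in the
test suite against central finite differences over every parameter of a
small configuration.  The segmentation loss is pixel-wise weighted binary
cross-entropy (mean over pixels of `w · BCE`, predictions clipped at
1e-7); the tracking loss is categorical cross-entropy over the one-hot
targets.  Both are also exposed as plain R functions and tested against
scalar-loop oracles to 1e-9.

Training uses Adam (learning rate 1e-4) with the full-scale schedule of 400
epochs × 250 steps (batch 10 segmentation / 5 tracking) as the default
configuration.  The reduced benchmark (`synthetic_benchmark()`) trains
12/14 epochs × 40 steps at learning rate 1e-3 on ~200 segmentation and
~400 tracking samples from four simulated movies — small enough to run in a
few minutes on one CPU, large enough for the loss to converge on the
synthetic task; the best-epoch parameters are checkpointed.  Batch
construction reshuffles an infinite sample stream per epoch; for the
reduced tracking schedule the stream is stratified, oversampling
division-containing samples to about a quarter — divisions are only ~7% of
raw samples and carry the small daughter-channel signal, and a short
schedule otherwise converges to a degenerate net that never emits a
daughter region (the full-scale schedule sees half a million draws and does
not need this).  Training is fully deterministic under a fixed seed with
single-threaded BLAS.

At prediction time the probability map is thresholded at 0.5 and connected
components under 4 px are discarded; tracking outputs take the per-pixel
argmax over the three channels and are restricted to the current
segmentation foreground.

## Lineage assembly

For every chamber and frame pair, the pixels of each seed's mother/daughter
tracking output are matched against the labelled segmentation of the next
frame, giving a small score matrix of overlap counts.  Assignment resolution
selects, among all link sets in which each new cell receives at most one
link and each seed keeps at most one continuation and at most one daughter,
the set with maximum total overlap — computed exactly by branch-and-bound
(chamber matrices hold a handful of cells, so exact search is cheap; the
exhaustive-enumeration agreement test in the suite covers matrices up to
4×4).  A greedy highest-score-first sweep was considered and rejected: it
provably mis-assigns on score matrices like `[[10, 9], [9, 1]]`, where
taking the single largest entry first forfeits the better pairing.

Two conflict rules apply before and during the search: a new cell whose top
attribution score is exactly tied between two different seeds is discarded
from matching and becomes a "new" cell rooting its own lineage tree (exact
tie, not near-tie — ties in pixel counts are what actually occurs); and a
link is only eligible if the seed's combined mother+daughter overlap covers
at least 50% of the new cell's area.  A tie between a seed's own mother and
daughter channels breaks toward mother-continuation.  Unlinked cells become
roots; tracks ending before the last frame are marked flushed.  Fed perfect
tracking outputs derived from simulator ground truth, assembly reproduces
the true lineage exactly (a fixed-point test in the suite).

## Features and generation analysis

Cell length is the extent along the chamber axis (max row − min row + 1):
cells in these chambers are axially constrained rods, so axial extent is the
natural length; skeleton- or ellipse-based lengths were noted as
alternatives but are not defaults.  Area is the pixel count; fluorescence is
the arithmetic mean over the region.  Growth rates are per-interval log
differences `(ln L(t+1) − ln L(t))/dt`, with intervals spanning a division
marked absent.  Per-cycle means run division-to-division; the first interval
of a root track is discarded (its birth is unobserved), as is any unfinished
trailing interval.

Generation correlations are computed on a cycle forest: every complete cycle
is a node, and the division ending a cycle links it to two child cycles (the
continuing cell's next cycle and the newborn daughter's first cycle — after
division both cells are daughters of the divided cell).  The correlation at
gap *g* is the Pearson correlation over all (ancestor, descendant-at-depth-*g*)
cycle-mean pairs, every valid pair counted.  The autocorrelation of a
single-cell signal is the autocovariance of the mean-removed series
normalized to lag 0.

## Evaluation rules

A predicted cell is attributed to a ground-truth cell when at least 90% of
its own surface overlaps that cell.  Attribution is applied in both
directions: pred→gt detects over-segmentation (two predictions on one true
cell) and false positives, gt→pred detects under-segmentation (two true
cells inside one prediction) and false negatives.  The one-direction reading
cannot detect under-segmentation at all — a merged prediction covers neither
true cell by 90% of its own area — so the symmetric interpretation is used.

Two waivers reflect genuinely arbitrary calls: a split or merge is not an
error if the corresponding true (resp. predicted) cell divides within one
frame (the exact division frame is arbitrary to ±1), and spurious or missing
cells whose region touches the bottom 5-pixel margin are ignored (cells half
flushed out of the chamber are arbitrary to call).  Tracking errors count
each cell attributed to the wrong successor; events tied to segmentation
errors (at either end of the transition) or to divisions detected at a
different frame than the truth leave the denominator instead of counting as
errors.  Rates are reported as percentages rounded half-up to two decimals.

## The simulator: what it emulates and what it does not

The generator stacks rod cells (rounded-end capsules, 1-px gaps) from the
closed end, grows each exponentially (`L(t+dt) = L e^{λ dt}`), divides it
when it exceeds an inherited threshold (split fraction 0.5 ± truncated
normal noise), restacks, and removes rods pushed past the open end.  Default
conditions: 5-minute frames; mean doubling time 40 min (λ = ln 2/40 ≈
0.017/min, typical for *E. coli* in glucose minimal medium with amino acids
at 37 °C) with 15% CV across cycles; division threshold at twice the birth
length with 8% CV; chamber 256×32 px at 0.1 µm/px with ~1.3 µm-wide cells.
Per-cycle fluorescence is inherited between generations as a stationary
AR(1) process with coefficient φ = 0.8, so ancestor–descendant correlations
decay as φ^gap — a quantitative end-to-end check of the generation-analysis
machinery.  Rendering: dark rods (0.25) on a bright background (0.75),
Gaussian PSF blur (σ = 1 px), additive Gaussian noise (σ = 0.03), plus a
fluorescence channel with the same optics; labelled masks stay unblurred.
The fixture suite adds a crowded regime (25-min doubling, longer movie) and
a dim regime (σ = 0.08).

The reduced benchmark runs in a 128×32 chamber (11-px cells, birth length
20 px, threshold 40 px, 50 frames) so the small networks and CPU training
stay in the minutes range.

What the simulator does **not** emulate: phase-contrast halos and shade-off,
cell bending and pole asymmetries, chamber wall texture, focus drift,
stage jitter beyond integer shifts, or segmentation-mask imperfections from
human curation.  Passing the synthetic benchmark therefore demonstrates that
the architecture, losses, augmentation, assembly and evaluation machinery
learn and score the task end to end — not that the shipped configuration
reaches any particular error rate on real microscope data, which requires
training on curated real samples at full scale (the 400 × 250 default
schedule).

## Numerical choices and degenerate inputs

Prediction clipping at 1e-7 in both losses; constant frames or templates are
rejected as degenerate before correlation; a constant image normalizes to
zeros with a warning; single-class masks skip class balancing with a
warning; empty regions are errors in morphology/fluorescence; a
zero-variance series is an error in autocorrelation; fewer than three pairs
is an error in generation correlation.  Coordinates are 1-based `(row, col)`
with the chamber axis along rows, matching R matrix indexing throughout.

## Problem sizes in the shipped tests

The test suite and the acceptance script simulate chambers of 64–128 rows
with 20–220 frames, train the reduced 3-level/8-filter networks for 12
epochs of 40 steps, and evaluate on one held-out 50-frame movie (~700 cell
detections, ~150 tracking events); oracle suites use 8×8 loss instances,
32×32 weight-map masks and score matrices up to 4×4.  These sizes were
chosen so the whole suite completes in minutes while every statistical
assertion retains a comfortable margin over its Monte-Carlo error.
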
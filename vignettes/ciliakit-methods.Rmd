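---
title: "ciliakit: models and methods for automated airway-chip image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ciliakit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliakit)
```

Small-airway epithelium cultured at an air–liquid interface on a
microfluidic chip is monitored functionally through two video-derived
readouts: the ciliary beating frequency (CBF) of differentiated ciliated
cells, and mucociliary clearance (MCC) measured as the transport of
fluorescent microspheres deposited on the mucus layer. A third,
image-based readout predicts — from early bright-field morphology —
whether a culture region will differentiate at all, using tight-junction
(ZO-1) immunofluorescence collected weeks later as the label source.
`ciliakit` implements the computation side of all three readouts, plus a
synthetic-scene generator that makes every stage verifiable by parameter
recovery.

## Ciliary beat frequency by peak counting

A CBF recording is a high-speed movie (100 fps for about 10 s is typical;
the acquisition camera yields 990–1000 frames) in which beating cilia
modulate the local gray value quasi-periodically. The pipeline treats each
pixel as one cilium and has three stages.

**Localization.** For a window of early frames (default the 2nd–100th
frames, i.e. 0-based indices 1–99) the absolute grayscale difference to
the first frame is averaged per pixel, giving the *activity map*

$$A(r,c) = \frac{1}{|W|}\sum_{t \in W} \lvert I_t(r,c) - I_0(r,c)\rvert.$$

The mean of all activity values is the threshold; pixels strictly below
it are eliminated and the remainder form the *beat mask* (ties at the
mean are kept — "lower than" is strict). Using a short window here is
deliberate: it localizes motion from a small amount of data so the
expensive per-pixel analysis can focus on the captured area. The
threshold choice makes the mask adaptive to overall scene contrast;
raising it can only shrink the mask (a property the tests exercise).

**Per-pixel frequency.** For every masked pixel the *full-length* raw
intensity trace is high-pass filtered and its peaks counted; CBF is the
peak count divided by the recording time, capped at the Nyquist frequency
$f_s/2$. Counting uses the whole recording because frequency resolution is
the reciprocal of the counting time: 10 s gives 0.1 Hz steps. Peak
counting is preferred over an FFT here because a spectral readout of a
non-sinusoidal beat waveform spreads power into harmonics that can
mislead an argmax; a direct count of beat cycles has no harmonic
ambiguity. (An FFT-based estimator still exists — as an independent
oracle inside the test suite only.)

The peak rule has to be stated precisely because "a peak" is otherwise
implementation-defined. A sample is a peak if

* it is a strict local maximum (plateaus are not peaks),
* its topographic prominence is at least $k \cdot \mathrm{SD}$ of the
  filtered trace (default $k = 0.5$), and
* it is at least $\lceil f_s / (2 f_{max}) \rceil$ samples from any
  higher accepted peak, with $f_{max} = f_s/2$ by default (at the default
  this spacing is vacuous — two adjacent samples cannot both be strict
  maxima — but it becomes active if a lower $f_{max}$ is configured).

The SD-relative prominence floor suppresses noise maxima: with the
default $k$, noise must reach half the signal's own standard deviation
before a spurious maximum is counted, while genuine oscillation peaks
have prominence near twice the amplitude. One numerical guard matters: a
trace whose SD is below $10^{-8}$ is treated as motionless (zero peaks),
because a filtered constant is a sub-femto-scale numerical wiggle whose
"peaks" would otherwise be counted relative to its own vanishing SD.

**Filtering.** The high-pass filter is a 2nd-order Butterworth with a
1 Hz default cutoff, applied forward and backward so that peak positions
are not phase-shifted. The cutoff sits far below the physiologic 9–20 Hz
band, so it removes illumination drift and slow focus trends without
touching beat peaks. Zero-phase filtering is implemented with
odd-reflection end padding and steady-state initial conditions, so a
constant trace maps to numerical zero and edge transients do not leak
into the counting window; the widely used `filtfilt` convenience in the
signal-processing toolbox lacks the padding and produces large end
transients, which is why the package carries its own (the Butterworth
coefficients themselves come from `signal::butter`). Whether counting
operates on the filtered trace (default) or the raw one is configurable;
the activity map always uses raw differences.

Per-pixel counting over a whole mask runs through a small C++ kernel; a
pure-R single-trace reference (`count_peaks()`) defines the semantics and
the tests assert the two paths agree exactly.

**Outputs.** The per-pixel map is rendered as a heat map (fixed 0–30 Hz
color scale by default, for cross-video comparability) and summarized as
a frequency-distribution histogram: the percentage of beating pixels
("cilia in the visual field") per frequency bin.

## Mucociliary clearance tracking

MCC movies (30 fps, 10–60 s) show 2 µm fluorescent microspheres riding
the mucus layer. The pipeline:

1. **Detection.** The detection threshold is fixed from the first frame
   (Otsu's method by default; a fixed percentile or explicit value are
   alternatives — the original protocol sets a manual threshold without
   stating it). Each frame is binarized, foreground pixels are grouped
   into 8-connected components (each pixel with its eight surrounding
   positions; the component-labeling in the installed image toolbox is
   4-connected, so the 8-connected rule is implemented here), components
   below `min_area` are discarded, and each component's
   intensity-weighted center of mass gives a sub-pixel centroid.
2. **Linking.** Greedy mutually-exclusive nearest-neighbor assignment
   from frame $t$ to $t+1$ within a search radius (default 10 px/frame);
   unmatched detections seed new tracks; by default there is no gap
   closing (`max_gap = 0`). Equidistant ties resolve toward the lowest
   `(row, col)`, making linking deterministic.
3. **Movement filter.** Particles adhered to cilia beat in place and
   would otherwise be counted as moving. A trajectory is eliminated when
   its total path length fails to reach a fraction (default 50%) of the
   average path length over all trajectories. Path length, not net
   displacement, is the metric: both are small for stuck decoys, but path
   length also penalizes one-frame spurious tracks. When the mean
   movement is zero (a fully static field) everything is retained rather
   than dividing by nothing. An alternative elimination fraction (e.g.
   0.7) is one flag away.
4. **Summaries.** Displacement-vs-time curves per retained trajectory, a
   rose diagram of net directions (16 sectors of 22.5° by default,
   optionally weighted by net displacement), and mean clearance speed.

Two speeds are reported deliberately. The per-trajectory `mean_speed` is
path length over elapsed time. The summary's `mean_speed_px_s` is *net
displacement* over elapsed time — the actual transport rate of the mucus
layer. The distinction matters under localization noise: centroid jitter
inflates every step and hence the path length (a 1 px jitter roughly
doubles apparent step lengths at 1.5 px/frame), while the net
displacement over 60 frames is almost unaffected. Clearance is transport,
so the net-based speed is the headline number.

Angles are degrees counterclockwise with 0° pointing right and the row
axis flipped, so 90° is up on screen; every output states this
convention. Trajectories that touch the image border are flagged and kept
by default (`drop_border_tracks` removes them): whether in- or out-going
particles should count toward clearance is a judgment call, so it is a
flag rather than a hidden rule.

## Differentiability dataset machinery

Bright-field fields (e.g. 1608×1608 px) from day 3 of culture are tiled
into 224×224 patches on a top-left-anchored grid; partial tiles at the
right/bottom margins are dropped (1608 = 7×224 + 40 — the 40 px margins
carry no label information and padding would fabricate pixels). A
co-registered ZO-1 mask labels each tile: label 0 ("differentiable
tissue") when at least half the tile's footprint is ZO-1-positive, else
label 1; the coverage threshold is configurable since "areas with ZO-1"
is not quantified per tile in the protocol.

Augmentation multiplies each source tile by an op set — horizontal flip,
rotations by 90/180/270°, and additive Gaussian noise (σ defaulting to 1%
of the set's dynamic range, clipped to the valid range). A 3×3 binomial
blur is available as an optional op but is not in the default set: the
protocol's Methods list flip/rotate/noise, and its Results section's
slightly different list (including a 360° rotation, which is the
identity) is treated as an inconsistency resolved in favor of Methods.
Geometric ops preserve labels and intensity histograms exactly, which the
tests verify.

Cross-validation is leakage-safe by construction: folds are assigned to
*source* tiles (shuffled under a seed, dealt round-robin), so every
augmented variant of a tile shares its source's fold. When fold balance
and the leakage guard conflict (source counts not divisible by k), the
leakage guard wins — fold sizes in tiles may then differ by up to the
augmentation factor. `stratify = TRUE` deals within label classes,
keeping each fold at the overall prevalence; that is the right setting
when reading a dummy-baseline accuracy. The classifier is a pluggable
`fit`/`predict` pair: the CNNs used on real bright-field data plug in
here, and the package ships two reference models — a
threshold-on-mean-intensity classifier (enough to saturate separable
synthetic textures) and a majority-class dummy (the chance baseline).
Per-fold accuracies, their mean ± SD, and an aggregate confusion matrix
over all validation predictions are reported. Standard rotating k-fold is
implemented; independent random 80/20 resplits per round would be a
different estimator and are intentionally not the default.

## The synthetic generator, and what passing tests mean

`generate_cilia_video()` renders rectangular regions whose pixels
oscillate as $b + a\sin(2\pi f t + \phi)$ over a noisy baseline with
optional linear drift. Defaults mirror the acquisition this package
targets: 100 fps, 10 s, three 64×64 regions at 9, 14 and 20 Hz (the
physiologic range), amplitude 30 on baseline 120, noise σ = 5% of
amplitude. `generate_particle_video()` renders movers as Gaussian spots
(σ = 1.5 px — a soft spot exercises sub-pixel centroiding, where a
hard-edged square would make the center of mass trivially exact)
translating at fixed velocity, plus stationary decoys jittering with
0.3 px/frame SD; defaults are 30 fps, 60 frames, 20 movers at
1.5 px/frame toward 45°, 5 decoys. Placement keeps every pair at least
16 px apart over the whole recording, so ground-truth identities cannot
swap. `generate_texture_tiles()` makes two texture classes separated by a
mean-intensity contrast; zero contrast gives chance-level data. All
generators take a seed, restore the caller's RNG state, and are
bit-reproducible.

What the scenes deliberately *do not* model: metachronal wave structure
and waveform asymmetry of real beating (real traces are periodic but not
sinusoidal — peak counting is robust to that, but the tests don't prove
it), optical point-spread beyond the Gaussian spot, particles diffusing
or changing brightness, mucus rheology, and real bright-field texture.
Passing parameter-recovery tests therefore shows the *computational*
pipeline is correct and calibrated, not that the biological estimates on
real videos are unbiased.

## Numerical choices and edge cases

* Coordinates are 0-based `(row, col)`, pixel-center, row increasing
  downward, everywhere.
* Frequencies are reported on the counting grid (multiples of
  1/duration) and capped at $f_s/2$; an aliased oscillation (e.g. 60 Hz
  sampled at 100 fps) reports its alias, never a super-Nyquist value.
* Histogram bins are left-closed over $[0, f_s/2]$ with the last bin
  closed on both sides.
* Rose sectors are left-closed; a trajectory with zero net displacement
  is binned at 0° so the rose total always equals the retained count.
  Sector membership checks against a true direction use closed edges and
  the 0/360 wrap (`rose_bin_contains()`).
* TIFF I/O: integer-valued stacks round-trip bit-exactly through 16-bit
  pages; fractional stacks are scaled by a power of two into 32-bit pages
  (~$2^{-32}$ relative quantization). Frame rate travels in a JSON
  sidecar, since baseline TIFF has no frame-rate tag. AVI/MP4 must be
  converted to TIFF upstream; no video-codec reader is bundled.
* Every stochastic step (generators, fold shuffles, noise augmentation)
  is seeded and isolated from the global RNG stream; identical inputs
  and configuration give byte-identical CSV/JSON outputs.

## Problem sizes used by the test suite

Unit tests run on reduced scenes (48–64 px fields, 2–5 s recordings) so
the suite stays fast; the end-to-end recovery checks use the full
study-scale scenes: the 256×256, 10 s, 100 fps three-region ciliary scene
and the 256×256, 60-frame particle scene with 20 movers and 5 decoys,
plus a 24-direction sweep of the rose-diagram readout and a 1608×1608
tiling field. `scripts/acceptance.R` re-runs exactly these study-scale
analyses from scratch and writes the recovered quantities as JSON.

## Known limitations

* CBF is estimated per pixel independently; no spatial regularization or
  metachronal-phase analysis is attempted.
* The tracker is greedy nearest-neighbor: adequate for the sparse,
  quasi-linear motion of cleared microspheres, but it will not resolve
  dense crossings (no motion model, no global assignment).
* The differentiability module ships the dataset machinery and CV
  harness; reproducing published CNN accuracies requires the original
  bright-field images, which are not redistributable.
* Variable-frame-rate containers are rejected by design; acquisitions
  are constant-rate.
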
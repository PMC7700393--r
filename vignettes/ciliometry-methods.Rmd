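---
title: "Methods: block-wise Fourier quantification of ciliary beating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-wise Fourier quantification of ciliary beating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliometry)
```

## The measurement model

Beating cilia modulate the light reaching a camera pixel periodically at
the ciliary beat frequency (CBF). `ciliometry` therefore treats a
high-speed video as a grid of pixel time series and asks, per small
neighbourhood, whether a periodic component exists in the physiological
band and at what frequency. Nothing about ciliary mechanics is modelled;
the only assumption is *periodic intensity modulation at the beat
frequency*, which is what makes the approach robust across imaging modes
(brightfield, phase contrast) and magnifications.

A field of view of `H x W` pixels recorded at `fps` Hz for `T` frames is
tiled into non-overlapping square blocks of `block_size` pixels
(default and minimum 4). For each pixel series `x_t` in a block we
compute a one-sided power spectrum after mean removal and tapering:

$$ P_k \;=\; \frac{c_k}{T}\,\Bigl|\sum_{t=0}^{T-1} \tilde x_t\, w_t\,
   e^{-2\pi i k t/T}\Bigr|^2 , \qquad k = 0, \dots, \lfloor T/2 \rfloor, $$

with $c_k = 2$ except at DC and (for even $T$) the Nyquist bin, so that
with a rectangular taper $\sum_k P_k$ equals the detrended energy
$\sum_t \tilde x_t^2$ (a Parseval identity the test suite asserts to
1e-9). The *block* spectrum is the mean of the per-pixel spectra.

**Why average power and not amplitude.** Neighbouring cilia beat with a
spatial phase lag (the metachronal wave). Averaging the complex DFT — or
equivalently analysing the block-mean signal — lets opposite phases cancel;
two half-blocks beating in anti-phase would look static. Averaging
per-pixel *power* is phase-blind, so coordinated but phase-shifted motion
reinforces. A closed-form cancellation check in the tests demonstrates
exactly this failure of amplitude averaging.

## Detection rules

* **Detection band.** Candidate bins satisfy `f_min <= f <= f_max`
  (defaults 2 and 50 Hz), both edges inclusive; the DC bin is never a
  candidate. Energy below 2 Hz (stage drift, slowly translating debris)
  and above 50 Hz is never reported as ciliary movement.
* **Dominant frequency.** The in-band bin of maximal power; ties break to
  the lower frequency for determinism. The reported value is a bin centre:
  resolution is honestly `fps / T` (2 Hz for a 0.5 s field at 500 fps) and
  no sub-bin interpolation is attempted.
* **Movement significance.** A block is *moving* when its in-band peak
  exceeds `power_ratio_k` times the block's noise floor, the median power
  over bins strictly inside the band. The median is a robust background
  estimate: a genuine beating peak occupies a few bins and cannot drag it.
  The default `power_ratio_k = 8` was chosen so that pure-noise fields
  essentially never light up (the acceptance checks bound apparent
  coverage of a 1024-block noise field at 2%; observed values are at or
  near zero), while blocks whose oscillation amplitude merely matches the
  noise standard deviation still pass easily.
* **Numerical zero guard.** With noiseless synthetic input, an out-of-band
  tone leaves only floating-point residue (~1e-26 relative) in the band,
  which would still exceed an even smaller noise floor. The peak must
  therefore also exceed `1e-12` times the block's total spectral power
  (obtained through Parseval in the fast path), a scale far below any
  physical signal.
* **Taper.** Hann by default, to tame spectral leakage for beat
  frequencies that fall between bin centres; `window = "none"`
  (rectangular) is available and is used by the exact-recovery tests,
  because bin-aligned tones then have *zero* leakage and band edges can be
  probed exactly.

Edge residuals narrower than one block are excluded from analysis and
from the coverage denominator, and their pixel count is reported, so area
accounting stays explicit. Coverage is a *block* share, not a pixel share:
the block is the analysis unit, and quoting finer granularity would imply
resolution the method does not have.

## From map to coverage and CBF summaries

Per-field percent area of movement is `100 * moving blocks / total
blocks`. Fields sampled across an insert (`make_sampling_plan()`: every
3rd position along the midline, up to 16 fields) are averaged
*unweighted* — each field counts once even if grids differ — and the
sample SD across fields is reported. Fields spoiled by moving debris are
excluded only via an explicit user flag; the package deliberately ships no
automatic debris detector, since no algorithmic criterion is established
for that judgement.

ROI-level mean CBF applies the identical spectral machinery to single
traces (a 1-pixel block), then averages over moving ROIs. Conventions:

* fewer than 6 ROIs: status `insufficient` (a mean is still reported when
  computable);
* all ROIs static: mean CBF 0 Hz, status `static`;
* otherwise the mean is compared with the normal range 11-20 Hz,
  *inclusive* at both ends — the conservative reading of an "11-20 Hz"
  range quoted without open/closed qualification;
* samples mixing static and moving ROIs keep their moving-ROI mean but
  carry a `mixed_motility` flag, because a single mean under-describes a
  variable beat pattern. The flag is raised rather than the mean
  suppressed so that downstream tooling can decide.

Observer-judged beat-pattern categories are intentionally out of scope:
they encode expert visual judgement, not a computation.

## TEER

`compute_teer()` implements `(mean(test) - mean(blank)) * area_cm2` from
triplicate voltohmmeter readings (other counts warn but compute). The
membrane area is a *required* argument: insert growth areas vary by
format and lot, and baking a constant into the package would silently
misscale results. Negative corrected resistances are returned but
flagged, since they indicate probe drift rather than biology.

## The simulator: what it emulates, and what it does not

`sim_scene()` defaults describe the acquisition regime the package
targets: 500 fps, 250-frame (0.5 s) fields of 128 x 128 px, ~38.9% of the
surface beating at 14 Hz — a mid-normal beat frequency — with oscillation
amplitude 30 grey levels on a baseline of 120, Gaussian camera noise of
SD 10 (signal three times the noise SD), 8-bit quantisation, and a phase
gradient of 0.1 rad/px along each strip as a metachronal surrogate.
Beating regions are elongated ellipses (aspect 3:1), echoing strips of
ciliated epithelium; patches are placed at seeded random positions until
realised coverage is within 0.01 of target, and the realised value is
always reported. Optional extras: a second harmonic at `2f` (to check the
fundamental still wins for non-sinusoidal waveforms) and slow bright
drifting blobs whose temporal energy sits below 2 Hz (to exercise the
band filter's purpose).

**Block alignment.** By default patch masks are snapped to the 4-px
analysis grid (`align_blocks = TRUE`). The estimator's unit of area is
the block, so a pixel-level ground truth finer than the block grid would
measure quantisation of the estimator, not its correctness: a free-form
ellipse boundary partially covers a ring of blocks, and since even one or
two oscillating pixels carry enough power to flag a 16-pixel block, the
block-level estimate of a free-form scene systematically *overestimates*
pixel-level coverage by roughly the boundary-block margin. That is a real
property of block-based coverage (present in any implementation of this
measurement), documented here and observable with
`align_blocks = FALSE`; with aligned masks, truth and estimate share one
granularity and noiseless recovery is exact.

What the simulator does **not** emulate: resolved individual cilia,
hydrodynamics, illumination drift, focus changes, mucus movement faster
than the artifact model, or spatial noise correlation. Passing recovery
tests therefore show the *spectral pipeline* is correct under periodic
intensity modulation with additive white noise — they do not certify
performance on any particular clinical recording.

## Numerical and design choices

* Pixel coordinates and block indices are 0-based, `(row, column)`,
  origin top-left; serialised tables use the same convention.
* Frequencies above the 25 Hz colour-ramp top render white in map images
  while staying distinct in the data model, matching the standard display
  scale whose detection band nonetheless extends to 50 Hz.
* The whole-field map path evaluates only detection-band bins via a
  compiled direct transform (a matrix DFT); `block_spectrum()` computes
  the full one-sided grid via `stats::mvfft()`. The two paths are
  asserted to agree bin-for-bin to 1e-9 in the tests, and the reference
  path is itself checked against a brute-force DFT oracle written in
  plain R.
* Simulator noise is drawn single-precision from a fixed-seed mt19937
  stream (intensities are quantised to whole grey levels anyway, so
  sub-1e-5 relative noise precision is immaterial); patch placement uses
  R's RNG under the scene seed with the caller's RNG state restored.
  Runs are bit-reproducible for a fixed seed.
* Analysis requires at least 16 frames (below that the frequency grid is
  useless) and `f_max` at most `fps / 2`; both are hard errors, as is a
  missing frame rate on input — `fps` is never silently defaulted.
* Test and acceptance problem sizes: oracle equivalence uses 100 random
  4 x 4 blocks of 16-64 frames; coverage recovery uses 16-field inserts of
  128 x 128 px, 250 frames at 500 fps, 20 replicate inserts per coverage
  level in the test suite and 5 per level in `scripts/acceptance.R` —
  sizes chosen to exercise the full sampling design at desk scale.

## Known limitations

* Frequency resolution is `fps / T`; short recordings quantise CBF
  coarsely (2 Hz at the default 0.5 s field). Sub-bin refinement is a
  deliberate non-goal.
* A block mixing two beating populations reports only the dominant one.
* The movement-significance multiplier trades false positives against
  sensitivity at very low amplitude; `power_ratio_k` is user-configurable
  and the default is calibrated only against the bundled noise model.
* Proprietary camera containers are not read; interchange is multi-page
  TIFF or raw binary plus a plain-text metadata sidecar.
* Fixed-size tiling only; adaptive box sizing is not implemented.
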
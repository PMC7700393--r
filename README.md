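# ciliometry

Quantification of ciliary beating in high-speed video microscopy (HSVA)
recordings of ciliated airway epithelium — the functional readout used when
assessing motile-cilia disorders such as primary ciliary dyskinesia (PCD)
and when validating air–liquid interface (ALI) cultures of nasal epithelial
cells. The package is aimed at diagnostic-lab scientists and cell-culture
researchers who need reproducible, numeric surrogates for "how much of this
epithelium beats, and how fast".

## What it computes

**Block-wise beat-frequency maps.** A field of view recorded at frame rate
`fps` (typically 500 fps) is tiled into square pixel blocks (minimum 4 × 4
px). For each block, every pixel's intensity time series is mean-detrended,
tapered, and transformed; the per-pixel power spectra

```
P_k = c_k |Σ_t x~_t w_t e^{-2πikt/T}|² / T
```

are averaged across the block's pixels. Averaging *power* rather than
complex amplitude means cilia beating out of phase across the block (a
metachronal wave) reinforce instead of cancelling. The block's ciliary beat
frequency (CBF) is the frequency of maximal power inside the detection band
[2, 50] Hz, and the block counts as *moving* when that peak exceeds
`k = 8` times the block's noise floor (the median in-band power).

**Cilia coverage.** The percent of blocks moving is the field's percent
area of movement; averaging it (unweighted) over the fields sampled across
a culture insert — every 3rd field along the midline, up to 16 fields — is
the insert's cilia coverage, a surrogate for how widely the culture has
ciliated.

**Mean CBF with service conventions.** Per-ROI beat frequencies from at
least 6 strips of ciliated epithelium are averaged; an all-static sample is
reported as mean CBF 0 Hz with status `static`; fewer than 6 ROIs is
`insufficient`; otherwise the mean is flagged against the normal range of
11–20 Hz (inclusive).

**TEER.** Trans-epithelial electrical resistance of a culture insert:
`(mean(test) − mean(blank)) × area`, in Ω·cm², from triplicate readings.

**Synthetic ground truth.** A seeded simulator renders beating-epithelium
videos — elliptical "strips" of sinusoidally oscillating pixels with phase
gradients, camera noise and optional sub-2 Hz drifting particulates — with
exact moving masks and frequency maps, so every stage above is testable
end to end.

## Worked example

```r
library(ciliometry)

# a 16-field insert with ~38.9% of the surface beating at 14 Hz
scene  <- sim_scene(coverage_fraction = 0.389, freq_field = 14, seed = 42)
series <- simulate_fov_series(scene, n_fov = 16)

per_fov <- dplyr::bind_rows(lapply(seq_along(series), function(i)
  percent_area_moving(compute_cbf_map(series[[i]]$stack,
                                      fov_id = sprintf("fov%02d", i)))))
head(per_fov, 3)
#>   fov_id percent_moving n_blocks_moving n_blocks_total mean_moving_freq_hz
#> 1 fov01            38.5             394           1024                  14
#> 2 fov02            38.7             396           1024                  14
#> 3 fov03            38.5             394           1024                  14

aggregate_coverage(per_fov)
#> <coverage_summary> 16 fields of view
#>   mean cilia coverage: 38.4% (SD 0.3)
```

Each field of 128 × 128 px holds 1024 analysis blocks; 394 moving blocks
are 38.5% of the field's area, and the 16-field average of 38.4% recovers
the simulated coverage of 38.9% to within block quantisation. Mean CBF from
six ROI traces follows the same spectral machinery (frequencies are
reported at bin centres, so resolution is `fps / T`):

```r
tt <- 0:249
traces <- as.data.frame(lapply(c(13, 14, 15, 14.5, 13.5, 14), function(f)
  120 + 30 * sin(2 * pi * f * tt / 500)), col.names = paste0("roi", 1:6))
summarise_cbf(traces, fps = 500, sample_id = "culture_01")
#> <cbf_summary> culture_01: 6 ROIs, mean CBF 14.33 Hz, status: within_normal

compute_teer(c(400, 410, 390), c(300, 300, 300), area_cm2 = 1.12)
#> TEER: 112 ohm cm^2 (test 400 ohm, blank 300 ohm, area 1.12 cm^2)
```

Every result type has `tidy()`, `glance()` and `autoplot()` methods;
`write_cbf_map_image()` renders the standard monochrome map (0 Hz black to
25 Hz white, non-moving and out-of-band blocks black).

A command-line interface wraps the same functions
(`system.file("cli", "ciliometry", package = "ciliometry")`), with
`simulate`, `analyze`, `coverage-report`, `cbf` and `teer` commands.

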
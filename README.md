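# nanocoloc

Nanoscale colocalization analysis for single-molecule localization
microscopy (SMLM/dSTORM) by image cross-correlation spectroscopy (ICCS).

## The problem

dSTORM delivers a list of molecular coordinates accumulated over
thousands of frames, not an image. Deciding whether two labelled species
co-occupy the same nanoscale structures from two such coordinate lists
is hard: object-based analyses (nearest neighbour, DBSCAN, Ripley's K)
treat every localization as a molecule, although one antibody-borne
fluorophore blinks many times ("redundancy"), and their cost grows with
the number of events. `nanocoloc` takes the pixel route instead: each
channel's coordinates are re-imaged as a superposition of Gaussian
spots of width σ (default 50 nm, antibody-complex scale), and
colocalization is read off the spatial correlation functions of the
rendered image pair. Repeated localizations of one emitter merge into a
single spot whose mass cancels in the normalized correlations, so the
redundancy problem disappears by construction.

The package covers the full experimental pipeline for dual-color
acquisitions that include persistent fiducial markers (e.g. 40 nm
fluorescent nanodiamonds):

* **localization IO** — delimited localization tables with a
  column-mapping dialect (foreign headers, camera-pixel units, 1-based
  frames);
* **drift correction** — fiducials are detected by their persistence
  (they never blink), the per-frame stage drift is estimated from their
  tracks, subtracted, and fiducial neighbourhoods are excised;
* **rendering** — pixel-integrated Gaussian rendering on a shared
  two-channel grid (compiled hot loop);
* **ICCS** — FFT correlation with masked normalization (arbitrary ROIs,
  no periodic wrap-around), 2D Gaussian fits, and the derived
  quantities; sliding-window local maps (default 69 px window);
* **registration** — landmark (fiducial) based similarity/affine
  mapping of confocal images onto the SMLM frame, Otsu focus
  segmentation, mask transfer, and mask-restricted ICCS;
* **simulator** — seeded dual-color streams with planted colocalized
  fraction, pair distance, blinking redundancy, localization noise,
  drift, and fiducials, so every stage is testable without data.

## The statistic

With $\delta I = I - \langle I\rangle$ over the ROI, each channel pair
gives three correlation surfaces
$G_{ab}(\xi,\eta) = \langle \delta I_a(x,y)\,\delta I_b(x+\xi,y+\eta)\rangle
/ (\langle I_a\rangle\langle I_b\rangle)$, fitted with
$G_0 \exp\{-(\xi^2+\eta^2)/w^2\} + G_\infty$. Auto amplitudes scale as
$1/N$, so the amplitude ratios

$$M_1 = G_0^{\times}/G_0^{a2},\quad M_2 = G_0^{\times}/G_0^{a1},\quad
f_{\mathrm{ICCS}} = (M_1+M_2)/2$$

estimate the fraction of particles in each channel with a partner in
the other, and the cross-peak broadening gives the correlation distance
$d = \sqrt{\max(0,\, w_\times^2 - (w_{a1}^2+w_{a2}^2)/2)}$. See the
methods vignette (`vignettes/nanocoloc-methods.Rmd`) for conventions,
estimator bias, and design rationale.

## Worked example

A simulated 10 × 10 µm dual-color acquisition (15,000 frames, planted
colocalized fraction 0.5 at coincident positions, random-walk stage
drift, three fiducial markers), analysed end to end:

```r
library(nanocoloc)

cfg <- sim_config(f_true = 0.5, pair_distance = 0, n_fiducials = 3,
                  drift_model = "random_walk", drift_step_sd = 0.5,
                  fiducial_keyframe_interval = 1L, seed = 42)
sim <- simulate_dataset(cfg)

tracks <- detect_fiducials(sim$table, capture_radius = 100,
                           min_occupancy = 0.8, channel = "ch1")
tracks[, 1:5]
#> # A tibble: 3 × 5
#>      id  x_nm  y_nm occupancy n_localizations
#>   <int> <dbl> <dbl>     <dbl>           <int>
#> 1     1 4800. 5332.     0.970           14562
#> 2     2 4348. 5994.     0.971           14586
#> 3     3 6504. 2717.     0.969           14541

drift     <- estimate_drift(tracks, n_frames(sim$table), smoothing_window = 51)
corrected <- apply_drift_correction(sim$table, drift)
corrected <- exclude_fiducial_regions(corrected, tracks, 150)

ext  <- default_extent(corrected, 50)
img1 <- render_image(corrected, "ch1", pixel_size = 10, psf_width = 50, extent = ext)
img2 <- render_image(corrected, "ch2", pixel_size = 10, psf_width = 50, extent = ext)

res <- compute_iccs(img1, img2)
res
#> <iccs_result>
#>   f_ICCS = 0.483  (M1 = 0.484, M2 = 0.482)
#>   d = 25.9 nm
#>   ROI: 1072260 px; max lag 32 px @ 10.0 nm/px
tidy(res)
#> # A tibble: 3 × 7
#>   component    g0  w_nm  g_inf residual_rms converged n_points
#>   <chr>     <dbl> <dbl>  <dbl>        <dbl> <lgl>        <int>
#> 1 auto1     1.75   105. 0.0274       0.0152 TRUE          3209
#> 2 auto2     1.74   104. 0.0279       0.0177 TRUE          3209
#> 3 cross     0.841  108. 0.0175       0.0210 TRUE          3209
```

Reading the numbers: the three fiducials are recovered with ~97%
frame occupancy and ~14,500 events each — persistence is what separates
them from blinking molecules. The auto widths `w ≈ 104 nm` are the
expected `2 × sqrt(50² + 10²)` (rendering σ plus localization
precision); the cross amplitude is about half of each auto amplitude,
giving `f_ICCS = 0.483` for the planted 0.5 (the small deficit is the
Poisson-blinking damping quantified in the vignette); and `d = 26 nm`
is the estimator's floor for coincident partners, set by the rendering
width. `autoplot(res)` draws the radial correlation curves with their
fits, `local_iccs(img1, img2)` maps `f_ICCS` across the field, and
`glance(res)` returns the one-row summary. `run_pipeline()` executes
the same stages from a config (including confocal mask registration)
and writes a JSON/CSV/TIFF report; a thin CLI lives in
`inst/cli/nanocoloc.R`.

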
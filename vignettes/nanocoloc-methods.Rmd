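---
title: "Quantifying nanoscale colocalization in SMLM data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoscale colocalization in SMLM data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nanocoloc)
```

## The problem

Single-molecule localization microscopy (SMLM/dSTORM) reconstructs a
super-resolved view of a sample as a *list of coordinates*: over thousands
of camera frames, sparse subsets of photoswitching fluorophores are
localized with ~10–20 nm precision, and the events are pooled. Asking
whether two labelled molecular species occupy the same nanoscale
structures — colocalization — is awkward in this representation.
Object-based approaches (nearest neighbour, DBSCAN, Ripley's K) treat
every localization as a molecule, but a single antibody-borne fluorophore
reactivates many times, so localization counts over-represent targets
("redundancy" or "degeneracy"), and coordinate-level analyses scale
poorly with event counts.

`nanocoloc` implements the alternative: return to a pixel picture by
rendering each channel's coordinate list as a superposition of Gaussian
spots, and quantify colocalization by **image cross-correlation
spectroscopy (ICCS)** — the spatial analogue of fluorescence
cross-correlation spectroscopy. Because repeated localizations of one
emitter merge into a single rendered spot (only its mass changes, which
cancels in normalized correlations), the pixel route sidesteps redundancy
without any clustering step, and its cost scales with pixel count, not
event count.

## The ICCS model

For two rendered channel images $I_1$, $I_2$ on a shared grid, the
normalized spatial correlation over a region of interest (ROI) is

$$G_{ab}(\xi, \eta) \;=\;
\frac{\langle \delta I_a(x, y)\, \delta I_b(x + \xi, y + \eta)\rangle}
     {\langle I_a \rangle \langle I_b \rangle},
\qquad \delta I = I - \langle I \rangle ,$$

with means taken over ROI pixels. The two autocorrelations
($a = b$) and the cross-correlation are each fitted with an isotropic
Gaussian in lag space,

$$G(\xi, \eta) = G_0 \exp\!\left(-\frac{\xi^2 + \eta^2}{w^2}\right) + G_\infty ,$$

where $w$ is the $e^{-1}$ radius. For $N$ randomly placed particles the
auto amplitude scales as $G_0 \propto 1/N$ (verified as a property test:
log–log slope $-1$), so amplitude *ratios* count co-occurring particles:

$$M_1 = \frac{G_0^{\text{cross}}}{G_0^{\text{auto,2}}}, \qquad
  M_2 = \frac{G_0^{\text{cross}}}{G_0^{\text{auto,1}}}, \qquad
  f_{\mathrm{ICCS}} = \frac{M_1 + M_2}{2}.$$

$M_1$ estimates the fraction of channel-1 particles with a channel-2
partner and vice versa. Both are reported raw — noisy fits can stray
outside $[0,1]$ — with clamped convenience values alongside.

A nonzero separation $d$ between partners broadens the cross peak
relative to the autos; the estimator inverts that broadening by
quadrature,

$$\hat d = \sqrt{\max\!\left(0,\;
w_{\text{cross}}^2 - \tfrac{1}{2}\!\left(w_{\text{auto,1}}^2 +
w_{\text{auto,2}}^2\right)\right)} ,$$

clamped to zero (with a flag) when the cross peak is not broader —
negative broadening is noise, and the estimator must be total.

### What $\hat d$ measures, exactly

For partners at exact distance $D$ with uniformly random orientation, the
true cross-correlation is the PSF autocorrelation convolved with a ring
of radius $D$ — not a Gaussian. Fitting it with the Gaussian model and
applying the quadrature yields an expectation *above* $D$ (e.g. ≈96 nm
for $D = 80$ nm and ≈201 nm for $D = 120$ nm at a 51 nm effective
rendering width). The package therefore validates $\hat d$ against a
numerical ring-convolution oracle fitted with the same model, rather
than against the planted $D$ itself; recovered means agree with the
oracle to a few nm. Below the rendering width the estimator has a
positive floor (a planted $D = 0$ returns ~25–30 nm), comparable to the
distance reported for biological positive controls; the bias curve is
characterized by the oracle, not asserted away.

## Rendering

`render_image()` deposits a unit-integral isotropic Gaussian of standard
deviation `psf_width` at each localization, integrated analytically over
each pixel (separable normal-CDF differences, truncated at $5\sigma$,
omitted mass $<10^{-5}$; the hot loop is compiled). "Width" here always
means the Gaussian σ — conventions differ across software (σ, FWHM,
$e^{-1}$ radius), so the choice is stated wherever a width is reported.
It propagates directly into the correlation widths: a channel rendered
at σ gives $w_{\text{auto}} = 2\sigma$ (the autocorrelation of a
Gaussian of sd σ is a Gaussian of sd $\sigma\sqrt2$, and $w$ is the
$e^{-1}$ radius), which the test suite asserts within 5%.

Defaults: `pixel_size = 10` nm/pixel and `psf_width = 50` nm, the
analysis-grade rendering (a 20 µm field is then a 2000 × 2000 grid; a
10 nm width is available for display-grade rendering). The 50 nm width
is deliberately antibody-scale: one primary + secondary antibody complex
spans tens of nm, so a 50 nm spot absorbs both the labelling geometry
and the multiple emissions of its fluorophores into a single object.
Both channels are always rendered on one shared grid (the default
extent is the all-channel bounding box padded by $3\times$`psf_width`)
because cross-correlation requires pixel-aligned grids. Rendering is
unit-mass per event by default; photon weighting is available but
changes $f_{\mathrm{ICCS}}$ from a particle fraction toward an
intensity fraction, so it is off for quantification.

## Correlation computation and fitting

Correlations are computed by zero-padded FFT with **masked
normalization**: fluctuation images are zeroed outside the ROI and each
lag is divided by the number of overlapping ROI pixel pairs at that lag
(itself an FFT of the mask). This treats image boundaries and
arbitrarily shaped ROIs (nuclei, segmented foci) identically and avoids
the periodic wrap-around contamination of naive FFT correlation. The
implementation is checked against a direct per-lag evaluation of the
definition on random images, with and without random masks, to $10^{-8}$
relative error.

Fits minimize least squares over the full 2D disc of lags
$|(\xi,\eta)| \le$ `fit_radius` (default `max_lag` = 32 pixels ≈ 320 nm,
several times the expected correlation width) via Levenberg–Marquardt.
Starting values: $G_\infty$ = median of the rim lags, $G_0 = G(0,0) -
G_\infty$, $w = 2$ px, with progressively wider fallback starts because
a 2 px start on a broad peak can make the initial Jacobian numerically
singular. Non-convergence never raises: results carry a `converged`
flag, and `compute_iccs()` degrades gracefully (failed cross fit with
sound autos ⇒ $f_{\mathrm{ICCS}} = 0$, $d$ undefined, flagged). The
$(0,0)$ lag is kept in fits — smooth Gaussian renderings have no
shot-noise spike there — with an `include_zero_lag = FALSE` escape hatch
for histogram-mode images. Radial averages are computed for plotting
only; fits always use the full 2D data.

`local_iccs()` repeats the analysis on square subregions (default 69 px
window, stride half a window — the stride is not prescribed by the
method and is configurable), mapping $f_{\mathrm{ICCS}}$ and $d$ across
the field; cells with under 25% ROI coverage or failed fits are marked
invalid.

## Drift correction with persistent fiducials

Fiducial markers such as 40 nm fluorescent nanodiamonds never blink or
bleach: they produce a localization in essentially every frame at a
fixed true position, while dSTORM fluorophores are ON in far less than
1% of frames. `detect_fiducials()` therefore clusters the pooled
localizations (grid hash at the `capture_radius`, default 100 nm, with
centroid refinement) and keeps clusters whose *occupancy* — the fraction
of expected frames containing a member — reaches `min_occupancy`
(default 0.5, orders of magnitude above any blinking duty cycle). When
fiducials are observed only at keyframes (selective excitation every
1000 frames is a common scheme), occupancy is computed over keyframes
and the trajectory is interpolated piecewise-linearly between them.

`estimate_drift()` averages per-track displacements relative to frame 0
and optionally smooths with a centred moving average whose window
*shrinks* at the sequence ends: padding by edge replication would weight
the (noisy) first observation heavily and corrupt the frame-0 anchor,
which propagates as a constant offset over the whole trajectory. A
window of ~51 frames (≈1 s at 20 ms/frame) balances localization noise
suppression ($\sigma/\sqrt{nW}$) against trailing genuine stage motion;
with three fiducials at 10 nm precision it recovers a
0.5 nm/frame-step random walk over 15,000 frames with ≈3 nm RMSE. After
correction, re-estimated drift is compared to the per-frame noise floor
of the fiducial centroid ($\sigma_{\mathrm{loc}}/\sqrt{n_{\mathrm{fid}}}$)
as an RMS over frames: the *maximum* of a 15,000-frame smooth residual
process scales with its duration and is not the per-frame statistic the
floor describes.

Drift is estimated and applied per channel (this also absorbs static
chromatic offsets); fiducial neighbourhoods are then excised
(`exclude_fiducial_regions()`, default 150 nm — comfortably above the
40 nm marker plus the rendering width) so the bright non-molecular
spots cannot bias the correlations.

## Registration and mask-restricted analysis

Because fiducials are visible in both diffraction-limited and SMLM
modalities, matched fiducial coordinates define the mapping between a
confocal image and the rendered SMLM frame. `estimate_transform()`
offers translation, similarity (closed-form Procrustes/Umeyama — the
default, since confocal and widefield share the objective and shear is
not expected), and affine least squares. Foci in the confocal channel
are segmented by global Otsu threshold plus connected components with a
minimum area (default 20 confocal pixels at ~70 nm/pixel); this is the
simplest defensible method and is replaceable via a numeric threshold.
Global Otsu fails on images whose foreground occupies a negligible
fraction of pixels (it then splits the background noise); segmentation
is intended for fields where foci occupy a visible fraction of the
frame, as in nuclear imaging. Masks are transferred to the rendered
grid by nearest-neighbour pull-back of pixel centres through the
inverse transform, and `masked_iccs()` simply runs the same correlation
machinery with the mask as ROI — a full-frame mask reproduces the
unmasked analysis bit for bit.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates dual-color localization streams with
planted truth: channel-1 particles uniform in the field; a planted
fraction `f_true` receives channel-2 partners at *exactly*
`pair_distance` nm in uniformly random directions (the displacement is
exact so that distance-recovery oracles stay clean; localization noise
supplies all spread); remaining channel-2 particles are independent.
Each particle emits `max(1, Poisson(mean))` localizations in uniformly
random frames with isotropic Gaussian position error; a planted
per-frame drift (none / linear / random walk) shifts every event; and
non-blinking fiducials appear in both channels at every keyframe.

Defaults are chosen once as the study conditions and are not tuned:
10 × 10 µm field, 2000 particles per channel (≈20 particles/µm²,
a dense nuclear antigen), 15,000 frames, 10 nm localization precision,
and a mean of 20 localizations per particle — antibody-borne dSTORM
fluorophores commonly yield tens of reactivations over such
acquisitions, and this redundancy is precisely what the pixel-based
method must tolerate. The positive-control preset plants partners at
15 nm (secondary-antibody scale); the negative control plants
independent channels.

The blinking model is deliberately minimal: localizations land in
uniformly random frames with no ON-dwell structure or photon-count
statistics, because time-integrated rendered images are the analysis
input and frame-resolved photophysics would not change them. Poisson
event counts per particle do introduce the one second-order effect a
practitioner should know: amplitude ratios are damped by
$\mathbb{E}[m]^2 / \mathbb{E}[m^2]$ for random per-particle masses $m$,
about 5% at a mean of 20 events — visible as the recovered fractions
(≈0.48 for a planted 0.5) sitting just below the plant. Note also that
because per-channel blinking counts are drawn independently, coincident
pairs produce identical *emitter position sets*, not identical event
tables; the corresponding invariant is tested at the emitter level.
What passing tests show is that the estimators recover planted truth
under realistic noise, redundancy, and drift; they do not certify
behaviour under structured backgrounds, variable labelling efficiency,
camera artefacts, or 3D effects absent from the generator.

## Problem sizes and runtime

The default global analysis — two 1000 × 1000-pixel renderings plus
three correlation surfaces and fits — takes ~3 s on one CPU; a
2000 × 2000 field completes comfortably within a minute, consistent
with the method's pixel-bound cost. The test-suite and acceptance
simulations use the 10 × 10 µm defaults for recovery checks and
5–8 µm fields for property tests, sizes at which Monte-Carlo means over
5–10 seeds are stable to well within the asserted tolerances.

## Known limitations

* $f_{\mathrm{ICCS}}$ is a relative measure: without a calibration of
  fluorophores per antibody and antibodies per target, absolute
  stoichiometry is out of reach, and labelling-efficiency asymmetries
  bias $M_1$ and $M_2$ differently.
* $\hat d$ inherits the positive bias of the Gaussian-fit quadrature
  for non-Gaussian cross peaks and a floor near the rendering width;
  interpret it against the oracle expectation, not as a calibrated
  distance.
* Global Otsu segmentation assumes a visible foreground fraction.
* Drift correction is lateral only; axial drift is assumed to be
  handled by hardware focus lock.
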
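---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microqc)
```

This vignette documents the physical models behind each analysis, the
default parameters and why they were chosen, what the synthetic-fixture
generators do and do not emulate, and the numerical conventions the
implementation commits to.

## Coordinate and array conventions

2D images are matrices indexed `[y, x]`; z-stacks are `[y, x, z]`;
multichannel stacks `[y, x, z, channel]`; time-lapses `[y, x, z, t]`.
Pixel indices are 0-based in all reported coordinates, and pixel `i` has
its *centre* at `i * pixel_size` micrometres. All geometric formulas
(image centre, diagonal, centroids) therefore live in the pixel-centre
frame: the centre of an `nx x ny` image is `((nx-1)/2, (ny-1)/2)` and
its diagonal is `sqrt((nx-1)^2 + (ny-1)^2)` pixels. Wavelengths enter
the API in nanometres and are converted to micrometres internally; all
lengths are reported in micrometres unless a metric is conventionally
quoted in nanometres.

## Theoretical resolution

`theoretical_resolution()` returns the diffraction-limited FWHM of the
PSF for three modalities:

* wide-field (WF): lateral $0.51\,\lambda_{em}/NA$, axial
  $1.77\,n\,\lambda_{em}/NA^2$;
* laser-scanning confocal (LSCM): lateral $0.51\,\lambda_{ex}/NA$,
  axial $0.88\,\lambda_{ex}/(n - \sqrt{n^2 - NA^2})$, assuming a pinhole
  of at least 1 Airy unit;
* spinning-disk confocal (SDCM): lateral $0.51\,\lambda_{em}/NA$, axial
  $\lambda_{em}/(n - \sqrt{n^2 - NA^2})$, assuming a pinhole below
  1 Airy unit (no pinhole-size correction is applied).

The confocal axial formulas require $NA \le n$; metadata construction
rejects the imaginary-square-root domain up front. These are scalar
paraxial-style engineering formulas: no vectorial or depth-dependent
aberration model is attempted.

The Shannon–Nyquist pixel-size criterion is
$\lambda_{ex}/(8\,NA)$, relaxed by a factor 1.6 when a 1-Airy-unit
pinhole is used. `nyquist_pixel()` returns the exact value;
`nyquist_pixel_nm()` *truncates* to whole nanometres rather than
rounding, so the reported integer criterion never exceeds the exact
bound (for NA 1.4 at 488 nm: exact 43.57 nm, reported 43 nm). This is a
deliberate conservative convention: rounding up would license a pixel
size that violates the criterion.

## PSF measurement

Beads are detected as 8-neighbourhood local maxima on the
maximum-intensity z-projection, at least `prominence` ADU above the
projection median (a robust background estimate when beads are sparse).
Plateau ties closer than one lateral FWHM collapse to a single record.
Exclusion rules never silently drop a bead; each record carries a
status: `edge` (closer to the border than the ROI half-size),
`too_close` (both members of any pair closer than twice the ROI side —
their profiles would contaminate each other), `saturated` (any voxel at
the detector ceiling inside the ROI; clipped profiles bias Gaussian
widths down), or `central_zone_out` (outside the central 30% of the
field, where off-axis aberrations would inflate the statistics).

Each kept bead is fitted with three *one-dimensional* Gaussians (plus a
constant) through its brightest voxel along x, y and z — the standard
practical compromise: a full 3D Gaussian fit is slower and no more
informative for well-separated beads, while 1D profiles make the
per-axis goodness of fit ($R^2$, default floor 0.95) directly
interpretable. FWHM is $2\sqrt{2\ln 2}\,\sigma \approx 2.35\,\sigma$
(reported to one decimal as 2.4). The ROI half-size defaults to three
times the expected FWHM per axis, which contains essentially all of a
Gaussian spot while keeping neighbouring beads out.

Secondary metrics: the signal-to-background ratio (SBR) is the mean
intensity of the Otsu-segmented bead on its brightest plane over the
mean of a 1-µm-thick annulus around the segmentation; SNR is
$\sqrt{I_{max} \cdot 2^{12} / 2^{bit}}$, a square-root photon-noise
proxy normalized to a 12-bit scale so values are comparable across
detectors; the lateral asymmetry ratio is
$LAR = \min(FWHM_x, FWHM_y)/\max(FWHM_x, FWHM_y)$.

## Field illumination

The image is smoothed with a Gaussian blur of $\sigma = 2$ pixels to
de-weight hot pixels and dust before any extremum is taken; the blur
uses replicated edges rather than circular wrap-around, since
wrap-around would mix opposite corners of exactly the vignetted regions
the metric measures. Saturation is assessed *after* blurring.
Uniformity is $U = 100\,I_{min}/I_{max}$ of the blurred image.
Centering is $C = 100 - 100 \cdot 2 d / D$, with $d$ the distance from
the reference-zone centre (the mean position of pixels at 90–100% of
the normalized maximum — more robust than the single brightest pixel)
to the geometric centre, and $D$ the image diagonal. Both $d$ and $D$
are measured in the pixel-centre frame, which makes the formula exact
at its endpoints: $C = 100$ when the reference centre coincides with
the geometric centre and $C = 0$ when it sits on a corner pixel. The
10-step isointensity map is `floor(norm * 10) + 1`, capped at 10.

## Channel co-registration

Each bead's position per channel is its intensity-weighted centre of
mass inside a shared cubic ROI, after subtracting the median of the
ROI's border voxels (a local background estimate immune to the bead
itself) and clamping negatives. The experimental distance $r_{exp}$
between two channels' centres is compared with $r_{ref}$, the radius of
the resolution ellipsoid — semi-axes $(R_{lat}, R_{lat}, R_{ax})$ of
the pair's shorter-excitation-wavelength channel, the stricter of the
two — along the measured displacement direction:

$$ r_{ref} = \left[ (u_x^2+u_y^2)/R_{lat}^2 + u_z^2/R_{ax}^2
   \right]^{-1/2}. $$

A ratio $r_{exp}/r_{ref} \le 1$ means the two channel images of one
bead would be scored as colocalized; a purely lateral shift equal to
the lateral resolution gives a ratio of exactly 1. Channels saturated
at a bead are skipped for that bead's pairs and counted.

## Illumination power and camera noise

Power stability uses the min–max factor
$STAB = 100\,[1-(P_{max}-P_{min})/(P_{max}+P_{min})]$ and the standard
deviation of the max-normalized power; both are scale-invariant, so the
power-meter unit is irrelevant. Warm-up time is the earliest time after
which every sample stays within ±1% of the settled level, estimated as
the mean of the final 10-minute window.

Dark-frame analysis takes a short-exposure series (dark current assumed
negligible): the temporal mean image gives the offset (its mean, ADU)
and the DSNU (its SD times the conversion gain, electrons); the
per-pixel temporal SD times gain is the read-noise map, summarized by
both its RMS and median because vendors publish either. With finite
frame count $T$ the DSNU estimate is contaminated by temporal noise as
$\sigma/\sqrt{T}$, so the 100-frame protocol value slightly exceeds the
long-run value — a documented bias, not an error. VAR
($100\,N_{theor}/N_{exp}$, tolerance ≥ 90%) and the min–max noise
stability across sessions (≥ 97%) track the sensor against its
specification over time.

## Stage drift and repeatability

From a tracked bead's positions, the stabilization time $\tau_{stab}$
is the earliest frame such that every later frame stays within the
lateral resolution on x and y and the axial resolution on z of that
anchor frame. The last frame is never a valid anchor: stabilization
cannot be claimed without at least one later confirming frame. Mean 3D
velocities before ($V_b$) and after ($V_a$) stabilization are
classified independently (standard < 45 min / ≤ 120 min for
$\tau$; < 15 / ≤ 100 nm/min for $V_b$; < 15 / ≤ 50 nm/min for $V_a$),
and the overall class is the worst of the three. Lost frames are
flagged and excluded, never interpolated. Repeatability is the plain
sample SD of x and y over repeated returns to a reference position,
with a 0.2 µm tolerance.

## Tolerances

The default registry: FWHM ratio ≤ 1.5, uniformity ≥ 50%, centering
≥ 20%, co-registration ratio ≤ 1, power stability ≥ 97% with
normalized-power SD ≤ 0.02, repeatability ≤ 0.2 µm, camera VAR ≥ 90%
and noise stability ≥ 97%. Boundaries are inclusive on the passing
side. Every threshold can be overridden from a YAML file
(`registry_from_config()`); unknown keys are an error so typos cannot
silently keep a default.

## Synthetic fixtures: what they emulate and what they do not

Each generator emits data in exactly the format its analysis consumes,
plus a truth record, and is bit-identical under a fixed seed (the
caller's RNG stream is preserved). The defaults are study conditions,
not tuning knobs: 0.05 µm pixels, 0.15 µm z-steps, 16-bit ADU scales,
100-frame dark series.

* **Bead stacks** are sums of separable anisotropic 3D Gaussians on a
  constant background with optional Poisson shot noise, Gaussian read
  noise and quantization. Finite bead diameter is modelled by moment
  matching — the marginal variance of a solid sphere of diameter $d$,
  $(d/2)^2/5$ per axis, is added to the PSF variance — which preserves
  separability and reproduces size broadening qualitatively, but is not
  a true spherical convolution.
* **Flat fields** are Gaussian vignettes whose corner-to-peak ratio is
  set exactly, so the expected uniformity is `100 * edge_ratio` before
  smoothing.
* **Power traces, drift tracks, revisit tables and dark stacks** follow
  the minimal parametric models described above (step/ramp warm-up,
  exponential relaxation $p(t) = p_\infty + A e^{-t/\tau}$, Gaussian
  revisit jitter, static offset map plus temporal Gaussian noise).

Not emulated: realistic PSF models (Gibson–Lanni, vectorial), optical
aberrations beyond anisotropic Gaussians, sCMOS row noise beyond an
optional sinusoidal column pattern, detector nonlinearity and EM gain,
vibration spectra, or photobleaching.

## Problem sizes and runtimes

The validation suite runs entirely on synthetic data at modest sizes:
single-bead fits on 64×64×21–41 voxel stacks, a 20-bead recovery study
on a 256×256×41 stack, field images up to 256×256, dark series up to
32×32×6000. Everything completes in well under a minute on one CPU;
nothing in the package requires more memory than a few hundred
megabytes.

## Limitations

Metrics are only as meaningful as their inputs: sub-resolution beads
must actually be sub-resolution (larger beads inflate FWHM; the
generator's moment-matching broadening quantifies the trend, not the
exact physics), saturated data are excluded rather than corrected, and
the drift classifier assumes the track is long enough to confirm
stabilization. The resolution formulas are nominal design values —
measured-to-theoretical ratios above 1 are expected on real systems,
which is why the tolerance is 1.5, not 1.
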
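---
title: "Methods: vertical cell forces from photonic-crystal structural color"
author: "pccfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertical cell forces from photonic-crystal structural color}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pccfm)
```

# The measurement model

A photonic-crystal substrate (PCS) is a thin elastic film — here a
polyacrylamide hydrogel with periodically self-assembled silica
nanoparticles — whose (111) lattice planes reflect a narrow stop band. The
reflection peak sits at the Bragg wavelength

$$\lambda = 2 d_{111} \sqrt{n_{\mathrm{avg}}^2 - \sin^2\theta},$$

and because the lattice spacing scales with film thickness while
$n_{\mathrm{avg}}$ and $\theta$ stay fixed, the fractional peak shift equals
the fractional thickness change:

$$\frac{\Delta\lambda}{\lambda_0} = \frac{\Delta D}{D}.$$

A cell pulling the film up ($\Delta D > 0$) red-shifts the local color; a
push blue-shifts it. This sign convention is fixed package-wide.

With the film modeled as an isotropic, incompressible linear-elastic layer,
the out-of-plane surface traction follows from the Green–Lagrange strain
$e_{ij} = \tfrac12(\partial_i u_j + \partial_j u_i)$ and the constitutive
law $\sigma_{ij} = \frac{E}{1+\nu}\left(\frac{\nu}{1-2\nu}
e_{\alpha\alpha}\delta_{ij} + e_{ij}\right)$, which for incompressible
material simplifies to $\sigma_{ij} = \frac{E}{1+\nu} e_{ij}$. Taking the
surface normal $(0,0,1)$ and $e_{zz} = \Delta D / D$,

$$T_z = \frac{E}{1+\nu}\,\frac{\Delta D}{D}
      = \frac{E}{1+\nu}\,\frac{\Delta\lambda}{\lambda_0}.$$

Both the simplified vertical chain (`displacementMap()` →
`verticalStressMap()`) and the full tensor chain (`strainTensor()` →
`stressTensor()`) are implemented; the latter exists so the incompressible
shortcut can be checked against the general law, and errors at $\nu = 0.5$
under the full law are raised rather than silently regularized.

Default physical constants describe the study film: $D = 24$ µm,
$E = 20$ kPa, $\nu = 0.49$, $\lambda_0 = 550$ nm, pixel length 0.18 µm (×10
objective). With these, the stress prefactor is $E/(1+\nu) \approx
13{,}423$ Pa per unit strain, so benchmark deformations of 1.524, 0.27, 0.8
and 1.19 µm map to 852, 151, 447 and 666 Pa.

# Hue as the wavelength readout

Hyperspectral scanning measures the reflection peak directly but slowly;
the routine readout is the HSV hue of an ordinary color image. The package
keeps both branches:

- `peakWavelengthMap()` takes a hyperspectral cube, forms reflection
  spectra $R(\lambda) = I(\lambda)/I_{bg}(\lambda) - 1$, and locates the
  per-pixel peak as the argmax with optional three-point parabolic
  refinement (sub-sample accuracy well under 0.5 nm on the 1 nm
  acquisition grid of 420–730 nm). Parabolic refinement was chosen over a
  centroid because the stop band is locally even around its maximum and
  the parabola is exact to second order; pixels whose peak prominence
  (relative max–min excursion) falls below 5% of the maximum are marked
  invalid rather than reported. Optional running-mean spectral smoothing
  exists but is off by default — the synthetic spectra are smooth, and on
  real data smoothing belongs to the user's explicit choices.
- `computeHueMap()` + `lookupWavelength()` convert RGB to wavelength via a
  monotone lookup table. Hue is the standard hexagonal HSV angle scaled to
  $[0, 1)$ with red at 0; pixels whose chroma falls below a saturation
  floor (default 2% of full scale) have no meaningful hue and are
  invalidated.

The lookup table is built by `pairHueWavelength()` + `buildCalibration()`
from a gradient-deformed wedge imaged by both branches: co-valid pixels are
paired position by position, binned by hue (default bin width 0.002, on the
order of the film's intrinsic hue standard deviation of 0.0025), and
summarized by the per-bin median of both coordinates — medians, so a few
aberrant pairs cannot drag a knot, and so exactly collinear pairs produce
knots exactly on their line. Strict monotonicity is then enforced by
isotonic regression in the dominant direction, decided by the sign of the
Spearman correlation of the raw pairs rather than hard-coded: for a
green-to-yellow film the curve is *decreasing* (yellow hue < green hue at
longer wavelength). Only ties left by the isotonic fit are broken, by a
step of $10^{-10}$ of the wavelength scale, so strictly monotone input is
untouched. Lookup interpolates linearly between knots; out-of-range hue is
clamped to the boundary wavelength and flagged (default) or invalidated.
Interpolation rather than nearest-knot lookup was chosen because the knots
are dense and the difference is far below the camera noise floor.

# The camera model and synthetic scenes

Every stage is testable against ground truth because the forward optics is
implemented too. `renderRGB()` forms linear channel values

$$c = \frac{\int L(\lambda)\, R(\lambda)\, S_c(\lambda)\, d\lambda}
           {\int L(\lambda)\, S_c(\lambda)\, d\lambda}$$

by trapezoidal quadrature from the illuminant $L$ (Planck 3200 K,
tungsten-halogen), the Gaussian stop-band reflectance $R$ (peak height 1,
FWHM 30 nm, background 0.05) and the channel sensitivities $S_c$ — three
Gaussians at 600/540/460 nm with a common 55 nm width. The wide
sensitivities guarantee the spectral crosstalk that makes hue a one-to-one
function of a narrow reflection peak; the `CameraModel` validity method
rejects sensitivity sets without pairwise overlap on 510–570 nm. White
balance, exposure, seeded Gaussian read noise and 8/16-bit quantization
complete the model. With zero noise the render is seed-invariant and
idempotent. The rendered hue is strictly monotone in peak wavelength over
505–575 nm for the default camera (checked exhaustively on a 1 nm grid),
falling from ≈0.57 (green) to ≈0.20 (yellow).

The stop-band lineshape and width are modeling conveniences — only the peak
position carries mechanical information — and are exposed as parameters
(`peakHeight`, `fwhm`, `background`) rather than inferred.

Synthetic scenes are pure functions of (parameters, seed), with the
caller's RNG state preserved:

- `makeCellScene()`: each cell is a central Gaussian depression (body push,
  default 1.52 µm) with an annular Gaussian rim of elevation
  (focal-adhesion-like pull, default 1.19 µm); the raw two-Gaussian sum is
  rescaled so the field extremes equal the configured depths exactly when
  cells do not overlap. Cell centers are drawn by rejection sampling with a
  minimum separation of 3.2 footprint radii. The footprint shape is
  invented — real micrographs show such push-core/pull-rim patterns only
  qualitatively — so tests assert recovery of the *configured* field, not
  biological realism.
- `makeAggregateScene()`: a wide, shallow V-shaped depression (linear
  profile to the apex) with a raised rim, the pattern a 3-D cell aggregate
  compressing the film produces.
- `makeCalibrationWedge()`: a linear peak-wavelength ramp (endpoints
  attained exactly), rendered both as RGB and as a hyperspectral cube from
  the same truth. The default ramp spans the working band 510–570 nm; the
  CLI's `simulate --scene wedge` spans 505–585 nm so the resulting LUT
  covers the default cell scene's red-shifted pulls (up to ≈577 nm) without
  clamping.
- `makeBeatingSequence()`: $\Delta D(x,y,t) = b\,t + A(x,y)\max(0,
  \sin 2\pi f t)^p$ — rectified-sine half-wave pulses (default $p = 2$,
  sharpening the pulse the way a contraction twitch looks) on a linear
  baseline drift $b$. Only frequency and amplitude are asserted in tests;
  the pulse shape is invented. Default frame rate 19.06 fps matches the
  monolayer recordings this emulates; the generator refuses
  $fps \le 2f$.
- `makeHyperspectralStack()`: per-pixel intensity $I = I_{bg}(1 + R)$, so
  `reflectionSpectra()` inverts it exactly at zero noise.

What the generator does *not* emulate: nanoparticle-scale speckle,
illumination drift, chromatic aberration, defocus, and mechanistic cell
models. Passing tests therefore certify the *computational chain* —
optics-consistent inversion, calibration transfer, force integration,
beat detection — not robustness to every real-world artifact.

# Dynamics

`velocityMaps()` differences adjacent displacement frames and divides by
the frame interval; cumulative re-integration telescopes back to the
displacement difference exactly, which is asserted as an invariant.
`totalForceTrace()` integrates $|T_z|\ell^2$ (or the signed sum — the
choice is exposed because published total-force traces do not state which
is used) over the field or an ROI per frame.

`detectBeats()` finds local maxima by topographic prominence (default 20%
of the trace dynamic range, minimum separation 0.25 s) and reports
rate = beats × 60 / duration. Phase boundaries per beat use threshold
crossings at baseline + 10% of beat amplitude: onset→peak is systolic,
peak→return is diastolic, the rest of the inter-beat interval is static.
The 10% rule is a package choice; published beat-phase figures label the
phases without defining their boundaries. A 1.65 Hz synthetic sequence
sampled at 19.06 fps over 20 s yields 33 detected beats = 99 bpm.

`lowerEnvelope()` estimates the static-stress baseline as the linear
interpolation through the points where the trace attains its centered
running minimum, clipped by that running minimum so the envelope never
exceeds the trace. `classifyResponse()` calls a normalized per-cell force
series non-monotonic when any value exceeds the running minimum so far by
more than 5% (default) — a transient rise before decline; the grouping
threshold is exposed because the published grouping rule is unstated.
`amplitudeVelocityRegression()` and `forceAreaRegression()` are ordinary
least squares with intercept (degenerate inputs are flagged or rejected,
never silently fitted).

# Numerical and I/O choices

- **λ₀ estimation**: when the unstrained peak is not configured, it is
  estimated as the mode of the wavelength histogram over valid pixels
  (0.5 nm bins, mean within the modal bin) — the unstrained film dominates
  the field of view. With no valid background this is an explicit error.
- **Segmentation**: 8-connected components of $|\Delta D| >$ threshold
  (default 0.05 µm ≈ 3× the background displacement noise of a quantized
  noiseless render; exposed in config), dropping components under 20 px.
  The 4-connected labeling of the underlying image library is upgraded to
  8-connectivity by merging diagonally touching labels through a graph
  connected-components pass.
- **Float TIFF maps**: physical maps (µm, Pa, nm) need samples outside
  [0, 1], which the standard TIFF writer clamps, so maps are written by a
  built-in minimal uncompressed 32-bit-float TIFF writer (single precision
  on disk, NaN for invalid pixels) with a JSON sidecar carrying class,
  unit and pixel length; reading uses the standard reader, which handles
  unclamped float samples. RGB renders and hyperspectral cubes (values in
  [0, 1]) use the standard writer directly.
- **Precision of reports**: region tables round forces to 0.01 nN and
  stresses to 1 Pa; calibration CSV knots are written at full double
  precision (17 significant digits) and round-trip bit-exactly.
- **Frame interval**: taken from metadata/config, never re-derived from a
  nominal frame rate; where a recording's stated rate and interval
  disagree (19.06 fps vs 0.051 s), the metadata value wins.
- **Problem sizes**: tests and the acceptance script use 192×192-pixel
  scenes, 300-column wedges and 20 s sequences at 32×32 pixels — large
  enough that binning, segmentation and beat statistics are exercised,
  small enough to keep the full suite around ten seconds.

# Known limitations

In-plane tractions are out of scope: the method reads only the vertical
component, and no Boussinesq-type reconstruction is attempted. The
linear-elastic, incompressible, thin-film assumptions are inherited from
the measurement model; finite-thickness corrections and nonlinear
elasticity are not implemented. Calibration transfer across substrates,
illuminants or temperature drift is not modeled — a LUT is valid for the
camera/illuminant/film combination it was built on. ROIs in time-lapse
analysis are fixed; there is no cell tracking.
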
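---
title: "Kernel-superposition scatter correction for cone-beam CT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-superposition scatter correction for cone-beam CT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A flat-panel cone-beam CT (CBCT) scanner irradiates a large detector area
at once, so a substantial fraction of the photons it records did not
travel straight from the source: they were Compton- or Rayleigh-scattered
inside the object. Scatter adds a smooth, object-dependent haze to every
projection. After log conversion and reconstruction this haze becomes
depressed attenuation values at the object centre (the *cupping*
artifact), biased CT numbers, and reduced soft-tissue contrast — the
three failure modes that matter most when a portable head scanner is used
to look at soft tissue.

This package implements a projection-domain correction built from three
ingredients:

1. a **signal model**: the measured image is the primary image plus the
   primary image convolved with thickness-dependent scatter kernels,
2. a **thickness map**: each detector pixel is assigned an equivalent
   thickness of PMMA via Beer's law, and the projection is partitioned
   into thickness-group subprojections,
3. a **multiplicative (MLEM-type) deconvolution** that re-estimates the
   primary image from the measurement under that model.

A voxelized phantom simulator, a fan-beam/FDK filtered-backprojection
reconstructor, and the standard image-quality metrics (CT number,
contrast, CNR, percent cupping) close the loop so every stage can be
tested against known ground truth.

## Signal model

For a projection image with pixel coordinates $(x,y)$:

$$I_m = I_p + I_s, \qquad
  I_s = \sum_t \left(I_{p,t} ** K_t\right),$$

where $I_m$, $I_p$, $I_s$ are the measured, primary, and scatter images,
$**$ is 2-D convolution, $I_{p,t}$ is the primary image masked to pixels
whose equivalent thickness falls in group $t$, and $K_t$ is the kernel
for that group,

$$K_t = A_t \, \mathrm{SF}_t \, \mathrm{PSF}_t .$$

$\mathrm{PSF}_t$ is a unit-sum, radially symmetric point-spread function;
$\mathrm{SF}_t = a_1 t + a_2$ is the scatter fraction, linear in
thickness with defaults $a_1 = 0.0038\,\mathrm{mm}^{-1}$, $a_2 = 0.1$;
and $A_t$ is a piecewise-constant compensation amplitude
(1.0 up to 80 mm, 1.75 up to 160 mm, 2.0 beyond, with upper-inclusive
range edges). The kernel database holds kernels on a contiguous 1 mm
thickness grid; when kernels are produced at coarse nodes (emulating a
38 mm slab-ladder measurement) they are linearly interpolated per pixel
to the 1 mm grid and renormalized, while SF and A always come from their
own functions. Below the first coarse node the nearest node's PSF shape
is reused (a slab ladder provides no thinner measurements); above the
last node no extrapolation is allowed.

Two numerical guards on the SF line:

* the line crosses 1 near $t = (1-a_2)/a_1 \approx 237$ mm, which is
  unphysical; `sf_of_thickness()` clamps at 0.99 with a warning;
* the positive intercept $a_2$ would assign 10–18 % scatter emission to
  pixels with essentially **no** material. Physically, scatter vanishes
  with vanishing thickness, and the linear fit was calibrated on slabs
  of 38 mm and more. The package therefore treats pixels mapped below a
  **minimum emitting thickness** (`t_emit_min`, default 5 mm) as
  non-emitting, in both the simulator and the correction. This matters
  for stability: without it, any air pixel whose estimate dips below the
  flat field during iteration suddenly starts emitting a large scatter
  amount, and the large air region can latch collectively into a
  spurious self-consistent solution — the over-correction regime. A 5 mm
  chord lies within 0.04 mm of the rim of a 160 mm cylinder, so the
  excluded material is sub-pixel.

## Parametric PSF family

Monte-Carlo or measured kernels can be loaded from file; the built-in
parametric family is a narrow Gaussian core plus a broad exponential
tail,

$$\mathrm{PSF}(r) \propto (1-w)\,\frac{e^{-r^2/2\sigma^2}}{2\pi\sigma^2}
  + w\,\frac{e^{-r/\tau}}{2\pi\tau^2},$$

with widths affine in thickness: $\sigma(t) = 3 + 0.03\,t$ mm,
$\tau(t) = 40 + 0.5\,t$ mm, $w = 0.85$. Two properties of real
pencil-beam kernels drove these defaults. First, spread must grow with
thickness (multiple scatter), which the affine widths give and a test
verifies as a monotone radial second moment. Second — and less obvious —
the tails must be **comparable to the object size**. In this model the
scatter a pixel emits scales with its *transmitted* primary, so the
bright rim of a cylinder emits far more than its dim centre; narrow
kernels then pile scatter near the rim and the simulated artifact comes
out as *capping* (edges depressed) instead of cupping. Multi-centimetre
tails spread the rim emission across the whole field, the
scatter-to-primary ratio peaks behind the centre (about 1.4 for the
standard fixture), and the reconstruction cups — the behaviour real
scanners show. Kernels are truncated to their grid and renormalized to
unit sum; the truncated mass is reported at build time, and grids should
be chosen to hold the tails (the standard fixture uses 201 × 201 samples
at 1.2 mm pitch, i.e. ±120 mm).

## Thickness mapping and grouping

Under a monoenergetic Beer's law the primary signal behind $t$ mm of
PMMA is $I_p = I_{p,0} e^{-\mu_\mathrm{PMMA} t}$, so

$$t_\mathrm{PMMA} = \frac{1}{\mu_\mathrm{PMMA}}
  \log\frac{I_{p,0}}{I_p}.$$

`estimate_thickness()` implements this closed form (default
$\mu_\mathrm{PMMA} = 0.0229\,\mathrm{mm}^{-1}$, a PMMA value at an
effective energy of roughly 60 keV), or inverts a monotone log-signal
lookup table built from slab calibration samples. Pixels at or above the
flat field map to zero thickness; intensities below $10^{-6} I_{p,0}$
are floored before the log.

The default grouping is five 40 mm groups with the last group
open-ended: $(0,40], (40,80], (80,120], (120,160], (160,\infty)$. Each
group is represented by the kernel at its centre thickness (20, 60, 100,
140, 180 mm) — the least-biased simple choice when nothing more is
known about the within-group distribution. The subprojections are a
partition: disjoint masks whose union is the $t > 0$ support, so they
sum back to the primary image exactly.

One degenerate configuration is worth knowing about: if the object's
maximum equivalent thickness lands exactly **on** a group edge,
voxelization jitter splits those rays between two groups, and the
simulator (which maps thickness from the true primary) and the
correction (which maps it from the current iterate) can disagree
persistently, biasing the recovered centre rays. The standard fixture
uses a soft-tissue cylinder (max $t \approx 148$ mm, mid-group) rather
than a PMMA one (max $t = 160$ mm, exactly on the edge) for this reason.

## The MLEM update and its convergence monitor

With Poisson counting statistics, the multiplicative update

$$I_p^{n+1} = I_p^n \cdot
  \frac{I_m}{\,I_p^n + \sum_t (I_{p,t}^n ** K_t)\,}$$

drives the model-predicted total signal toward the measurement while
keeping the estimate positive. The estimate is initialized at the
measurement itself ($I_p^0 = I_m$), the standard choice, which also
keeps the first thickness map well defined. The thickness map and
grouping are refreshed from the current iterate before every update.
Views are corrected independently; no state is shared.

Convergence is monitored with the Poisson log-likelihood of the
measurement under the **model prediction**
$\lambda^n = I_p^n + \sum_t (I_{p,t}^n ** K_t)$:

$$L^n = \sum_{x,y} \left[ I_m \log \lambda^n - \lambda^n \right].$$

The likelihood of the *bare* estimate would be maximized trivially at
$I_p = I_m$, i.e. at the initialization, and necessarily decreases from
there — it cannot serve as an ascent monitor. $L^n$ as defined ascends
toward its maximum, which is attained exactly when the prediction
matches the measurement; in the simulator's inverse-crime setting the
true primary achieves it. Monotone ascent is *monitored*, not proven:
the kernel term depends on the current iterate through the thickness
partition, which takes the update outside classical Richardson–Lucy
theory. On the standard fixture the per-view sequences are
non-decreasing to within $10^{-9}$ relative slack.

Stopping: relative likelihood change below `tol` (default $10^{-4}$) or
`max_iter` iterations (default 5), whichever comes first. Five
iterations is deliberate: with the emission floor the iteration is
stable, but stopping early also guards against over-correction when the
model is imperfect. Non-convergence at `max_iter` is a warning and a
diagnostic flag, never an error.

Convolutions run in the frequency domain with zero padding to at least
image-plus-kernel extent, rounded up to 2·3·5-smooth FFT sizes (R's FFT
is several times faster there than at the next power of two).
Round-off negatives are clamped to zero; a test pins the FFT path to a
direct double-loop spatial convolution at $10^{-10}$.

## Simulator

`forward_project()` computes exact radiological paths (incremental
Siddon traversal: every ray accumulates attenuation times the exact
chord length through each voxel it crosses, with no interpolation) from
a source orbit of radius DSO = 500 mm to a flat detector at
DSD = 786 mm. The beam is monoenergetic; beam hardening is explicitly
out of scope. Poisson noise is available (`add_poisson_noise()`) and off
by default — the deterministic path makes exact identities testable.

`add_scatter()` generates the measured data with the *same* grouped
convolution model the correction assumes, thickness-mapped from the true
primary. This is a deliberate inverse crime, stated openly: it makes
"does the deconvolution recover the known primary?" a well-posed
question with an exact answer, which is the module's reason to exist.
Passing those tests says the estimator inverts its own forward model; it
does not say the forward model captures all of real scatter physics
(polychromatic spectra, detector glare and lag, asymmetric kernels and
off-axis effects are all absent).

The standard fixture: a 160 mm diameter, 160 mm tall soft-tissue
cylinder ($\mu = 0.0212\,\mathrm{mm}^{-1}$) voxelized at 1.25 mm; a
256 × 256 detector at 1.2 mm pitch (the physical detector's 0.388 mm
pitch scaled up so the full fan fits a desk-scale grid); 180 views over
a full rotation; flat field $10^4$ counts. On one CPU the simulation
takes ~25 s and ten correction iterations ~2 min.

## Reconstruction

Intensities are log-converted to line integrals and reconstructed by
flat-detector fan-beam FBP for the central slice: rescale to a virtual
detector through the isocenter, cosine-weight, convolve with the
windowed ramp, backproject with inverse-square distance weights and the
full-scan redundancy factor ½. The discrete band-limited ramp (spatial
samples $1/4d^2$ at lag 0, $-1/(\pi n d)^2$ at odd lags) is used for its
correct DC behaviour; reconstructed means of a uniform cylinder are
within a fraction of a percent of the true attenuation. "Cutoff 0.6"
is interpreted as window truncation at 0.6 × Nyquist — the filter
response is $|f|\,w(|f|/f_c)$ for $|f| \le f_c = 0.6 f_N$ and zero
above, with $w$ the half-period sinc (Shepp-Logan), the Hamming window,
or 1 (pure ramp). An FDK-weighted variant reconstructs off-centre
slices and is tested on small grids against the fan-beam path on the
central slice. Full angular coverage is required; gaps over 1.5× the
nominal spacing are an error.

At 180 views a 256-pixel reconstruction shows a deterministic angular
undersampling ripple of a few percent in single-pixel profiles; ROI
means average it away, which is why the metrics use circular ROIs.
Profile-flatness checks use 360 views.

## Metrics

CT numbers are calibrated as
$\mathrm{CT\#} = 1000\,(m_x - m_\mathrm{water})/m_\mathrm{water}$
against a scatter-free (or low-scatter benchmark) background ROI — the
package follows the practice of using the soft-tissue background as the
water surrogate when the spectrum cannot separate the two. Contrast is
the signed mean difference, CNR divides by the root-sum-square of the
two ROI standard deviations, and percent cupping is

$$\%\,\mathrm{cupping} =
  \frac{(\mathrm{CT\#}_{edge} - \mathrm{CT\#}_{center}) \times 100}
       {\mathrm{CT\#}_{edge} + 1000},$$

with $\mathrm{CT\#}_{edge}$ the mean of exactly four peripheral ROIs in
the uniform region. ROI positions and radii are configurable; defaults
are an 8 mm radius, a 55 mm ring for the edge ROIs.

The package ships the published benchmark tables for a QRM-type
multi-insert phantom (insert means and standard deviations across
correction conditions) as input data; tests and the acceptance script
verify that the contrast row and the HU-difference columns follow
exactly from those means. The corresponding published CNR row is *not*
reproducible from the same means and standard deviations (it was
evidently measured on different ROIs) and is deliberately not asserted;
likewise two of the three published low-contrast sections have
inconsistent uncorrected difference columns, so only the consistent
section is used.

## What the tests do and do not show

On the standard fixture the correction recovers the true primary to
about 0.02 % of the flat field in ten iterations, the likelihood ascends
monotonically, and percent cupping falls strictly over iterations 0→5
(from ~17 % to ~0.5 %, against a scatter-free benchmark at ~0 %). These
are statements about inverting the package's own forward model under
study conditions chosen once: they demonstrate correctness of the
estimator, the grouping, the convolution and the reconstruction
plumbing. They do not demonstrate that five iterations is optimal for
any real scanner, that the parametric PSFs match any particular
detector, or that the correction is robust to beam hardening, glare, or
kernel mismatch — none of which the simulator emulates. The kernel
loader exists precisely so that measured or Monte-Carlo kernels can
replace the parametric family without touching the rest of the
pipeline.
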
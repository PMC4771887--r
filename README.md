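# cbctscatter

Kernel-superposition X-ray scatter correction for cone-beam CT (CBCT)
projection images, with a digital-phantom simulator, fan-beam/FDK
filtered backprojection, and the image-quality metrics used to benchmark
soft-tissue CBCT against low-scatter fan-beam reference scans.

## Who this is for

Flat-panel CBCT irradiates a large detector area, so a big share of the
recorded photons were scattered inside the object. Scatter depresses
reconstructed attenuation at the object centre (*cupping*), biases CT
numbers, and washes out soft-tissue contrast. This package is for people
developing or studying projection-domain scatter corrections: it
provides the full model-based correction, a simulator that generates
ground-truth data from the same class of models, and the metrics to
quantify what the correction buys.

## The model

The measured projection is modelled as primary plus kernel-blurred
primary,

    I_m = I_p + Σ_t ( I_{p,t} ** K_t ),        K_t = A_t · SF_t · PSF_t

where `I_{p,t}` is the primary image restricted to pixels of
PMMA-equivalent thickness group `t` (default: five 40 mm groups, last
open-ended), `PSF_t` a unit-sum radial kernel, `SF_t = a1·t + a2` a
scatter fraction linear in thickness (defaults `a1 = 0.0038 /mm`,
`a2 = 0.1`), and `A_t` a piecewise-constant amplitude. Thickness comes
from Beer's law, `t = log(I_{p,0}/I_p)/μ_PMMA`. The primary is
recovered by the multiplicative (MLEM-type) update

    I_p^{n+1} = I_p^n · I_m / ( I_p^n + Σ_t I_{p,t}^n ** K_t )

initialized at the measurement, with the thickness map refreshed every
iteration and a Poisson log-likelihood convergence monitor. Corrected
projections are reconstructed with fan-beam FBP (Shepp-Logan or Hamming
windowed ramp, cutoff 0.6 × Nyquist by default) or an FDK-weighted
cone-beam variant. See the methods vignette
(`vignettes/scatter-correction-methods.Rmd`) for assumptions,
parameter choices, and numerical details.

## Worked example

A scaled-down end-to-end run (90 views, 128-pixel detector) takes a few
seconds:

```r
library(cbctscatter)
res <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "cbctscatter"), quiet = TRUE)
round(res$metrics$percent_cupping, 2)
#>   benchmark uncorrected   corrected 
#>       -0.05       16.83        2.63 
round(100 * res$metrics$primary_recovery_rmse_frac, 3)
#> [1] 0.097
```

Reading: the scatter-free benchmark reconstruction of the 160 mm
soft-tissue cylinder is flat (cupping ≈ 0). Adding model scatter
produces 16.8 % cupping; the correction (here stopped by the likelihood
tolerance after 3 iterations) brings it down to 2.6 %, and the corrected
projections sit within 0.1 % of the true primary relative to the flat
field.

The shipped benchmark tables for a QRM-type multi-insert phantom are
plain data:

```r
qrm_contrast_by_condition()
#>   fbct   none  iter2  iter4  iter6  iter8 iter10 
#>    752    338    496    650    707    729    735
```

i.e. bone/soft-tissue contrast collapses to 338 HU without correction
and recovers to 735 HU (FBCT benchmark: 752 HU) after ten iterations.

A command-line front end wrapping the same functions is installed at
`inst/cli/cbctscatter` with subcommands `simulate`, `build-kernels`,
`correct`, `reconstruct`, `evaluate`, and `run`.

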
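# elltct

Iterative reconstruction for multi-bin (photon-counting) spectral CT in R,
built around a locally linear transform that turns the structural
similarity of energy-channel images into gradient sparsity along the
spectral axis.

## The problem

A photon-counting detector bins each beam's photons into `C` energy windows,
yielding one sinogram `P_c` per bin and, after reconstruction, a stack of
channel images `F = (F_1, …, F_C)`. Splitting a fixed photon budget across
bins makes every channel image noisy, and that noise propagates into
image-domain material decomposition. The channel images are, however,
structurally redundant: same anatomy, different gray levels.

## The method

For a target channel `c`, every other channel `F_i` is fitted to `F_c`
patchwise with the guided-filter local linear model,

    min_{a,b} Σ_{x∈Ω(k)} [ (a F_i(x) + b − F_c(x))² + ε a² ],

and the per-patch coefficients are averaged over all patches covering each
pixel — with flat weights (LLT) or with a radial Gaussian weight
`exp(−‖x−k‖²/2σ²)` that preserves edges better (the refined transform,
ELLT). Applying the aggregated coefficients to every channel and stacking
the results gives the transformed volume `F^c`, which is nearly constant
along the spectral axis. Reconstruction solves

    min_F ‖P(F) − P‖² + Σ_c [ λ Φ(F^c) + τ ‖F^c − (ã^c F + b̃^c)‖² ],

alternating SART/POCS data sweeps with the proximal subproblem of the
chosen 3D sparsity measure `Φ`:

* `Φ1` — anisotropic gradient L1 (total variation), solved by dual
  projected gradient;
* `Φ0` — gradient support count, solved by half-quadratic splitting with
  exact support-candidate scoring;
* `Φ*` — trace norm of the `C × MN` mode-3 unfolding, solved by
  singular-value soft-thresholding.

The package also carries a parallel-beam Joseph projector with an exact
adjoint and FBP inversion, a polychromatic Beer–Lambert simulator (energy
windows, Poisson noise, analytic material curves, disk phantoms), per-pixel
material decomposition with optional exact nonnegativity, ROI statistics,
and a scripted pipeline, so the whole method is exercisable without scanner
data. See `vignette("spectral-ct-reconstruction")` for the model details
and every numerical choice.

## Worked example

The default synthetic study: a 128×128 water disk with bone/muscle inserts,
3 energy bins (30–60, 60–90, 90–120 keV), 180 views, 10⁴ photons per ray
per bin, Poisson noise, 20 outer iterations per method.

```r
library(elltct)
res <- run_pipeline(default_run_config(seed = 1), "study-out")
subset(res$evaluation, method %in% c("fbp", "ellt-l0"))
subset(res$roi_stats, material == "water")
```

```
  method channel         rmse
     fbp       1 0.0028816068
     fbp       2 0.0013857202
     fbp       3 0.0012713308
 ellt-l0       1 0.0026339594
 ellt-l0       2 0.0009646120
 ellt-l0       3 0.0008466354
    method material  mean    std n_pixels
       fbp    water 0.932 0.0893      613
   ellt-tv    water 0.969 0.0348      613
   ellt-l0    water 0.967 0.0425      613
 ellt-tvlr    water 0.967 0.0448      613
```

Reading the numbers: `rmse` is the per-channel root-mean-square error of
the reconstruction against the bin-effective ground-truth attenuation map
(units mm⁻¹; channel 1, the lowest-energy bin, carries the most noise and
beam-hardening bias). The refined-transform L0 method reduces the RMSE of
every channel relative to filtered backprojection. The ROI table scores the
decomposed water-fraction map over a pure-water region: an ideal
decomposition has mean 1 and spread 0, and the transform-based
reconstructions roughly halve the spread at a mean closer to 1. Artifacts
(sinogram/volume containers, fraction maps, `evaluation.csv`,
`roi_stats.csv`, `provenance.yaml`) land in `study-out/`.

A command-line front end with `simulate`, `reconstruct`, `decompose` and
`run` subcommands is installed at `inst/cli/elltct.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/elltct.R", package="elltct"))')" \
    run --seed 1 --out study-out
```

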
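# cmrmotus

Joint reconstruction of **motion fields and contrast-varying images** for
free-running dynamic cardiac MRI from undersampled multi-coil k-space —
an R implementation of the CMR-MOTUS approach for first-pass myocardial
perfusion and cine imaging, with a fully analytic perfusion phantom so the
whole method is testable without external data.

## The problem and the model

Free-running first-pass perfusion overlays four dynamics — cardiac motion,
respiration, bulk motion and contrast-agent inflow — while each frame is
sampled with only a handful of k-space readouts. The method disentangles
them into two individually compressible pieces:

* a contrast-varying **reference series** in one motion state,
  `Q = L + S`: low-rank `L` (static anatomy) plus sparse `S` (contrast
  enhancement, sparse under the temporal Fourier transform `T`);
* an explicit-rank **motion model** `D ≈ Φ Ψᵀ` on cubic B-spline control
  grids in space and (optionally) time.

The displayed cine is the mass-conserving warp of the reference,

```
h_t(r) = q_t(r + D_t(r)) · det(∇(r + D_t))
```

and the reconstruction alternates between

1. **image step** — FISTA-style proximal gradient on
   `Σ_t ‖F(q_t|D_t) − s_t‖² + λ_L‖L‖_* + λ_S‖T S‖₁` with motion fixed
   (hard rank truncation when an explicit rank is set), step size `1.3/γ`
   with `γ` from a power method on `F F*`;
2. **motion step** — L-BFGS on
   `Σ_t ‖F(D_t|q_t) − s_t‖² + λ_TV‖TV(D)‖₂,₁` over `(Φ, Ψ)` with exact
   analytic gradients,

with a mid-position adjustment (subtracting the temporal mean of `D`)
between the steps. Running with zero alternations gives the plain,
non-motion-corrected L+S baseline.

## Worked example

A small cine-like study: short-axis phantom, 64×64 matrix, 60 frames at
50 ms, 12 pseudo-random Cartesian readouts per frame, 8 coils.

```r
library(cmrmotus)

cfg <- phantomPreset("test1", nx = 64, ny = 64, frames = 60, seed = 7)
ds  <- simulatePerfusionDataset(cfg)
ds$kspace
#> DynamicKSpace: 60 frames, 8 coils, cartesian-lines sampling
#>   grid 64 x 64; 768-768 samples/frame (acceleration ~5.3)

rc  <- reconPreset("test1", ctrlX = 32, ctrlY = 32, alternations = 2,
                   seed = 7)
res <- runCmrMotus(ds$kspace, ds$coils, rc)

metrics <- evaluateRecon(res, ds$truth)
#> SSIM (myocardium): motion-corrected 0.9759 | baseline 0.7599
#> mean EPE: 0.13 voxels | warped-label DICE: 0.946
res$model
#> LowRankMotionModel: rank 1, 32 x 32 spatial control points, dense temporal coefficients
```

The motion-corrected cine is far sharper than the temporally blurred
baseline (SSIM 0.976 vs 0.760 against the noiseless truth), the rank-1
displacement field recovers the analytic cardiac contraction to 0.13
voxels mean end-point error, and warping the first-frame myocardium
segmentation through the estimated fields overlaps the true segmentations
with DICE 0.946.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/cmrmotus.R simulate --preset test1 --seed 7 -o data.h5
Rscript inst/cli/cmrmotus.R recon --method motus -i data.h5 -o out.h5
Rscript inst/cli/cmrmotus.R evaluate -i out.h5 --truth data.h5 -o metrics.json
```

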
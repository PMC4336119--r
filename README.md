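# thynseg

Segmentation of thyroid-nodule B-mode ultrasound by an enhanced recursive
normalized cut, for image-analysis researchers and tool builders working on
ultrasound-guided procedures (e.g. fine-needle aspiration planning).

Raw thyroid sonograms resist classical segmentation: multiplicative speckle,
blurred boundaries, and gray levels compressed into a narrow band defeat
edge detectors and histogram thresholds alike. `thynseg` conditions the
image with three enhancement stages and then partitions the pixel affinity
graph:

1. **Homomorphic filter** — a radial high-emphasis transfer
   `H(D) = (γH − γL)(1 − exp(−s·D²/D0²)) + γL` applied to `log(u + ε)` in
   the 2-D frequency domain compresses the brightness range and boosts
   reflectance detail.
2. **Edge-enhancing anisotropic diffusion** — explicit iterations of
   `u ← u + Δt·[f1·uMM + f2·uNN − f3·th(l·vMM)·|∇u|]` in the local
   gradient/tangent frame, with order-8 rational conductivities
   (`f1` the flux derivative, negative beyond the edge scale `a`, so edges
   re-steepen while speckle smooths) and a hyperbolic-tangent shock term
   gated by the smoothed image `v = Gσ∗u`.
3. **Fractional-differential gradient** — four directional
   Grünwald–Letnikov masks (order `v ∈ (0,1)`, nonzero coefficient sum)
   fused by per-pixel maximum and stacked back onto the image, boosting
   edges while retaining low-frequency texture.
4. **Recursive Ncut** — affinities
   `W_ij = exp(−(Fi−Fj)²/σI²)·exp(−‖Xi−Xj‖²/σX²)` for pixels within radius
   `r`; the generalized eigenproblem `(D−W)y = λDy` is solved per region
   (dense below 256 nodes, ARPACK above), thresholds are swept over the
   smallest eigenvectors, and the split of minimal exact
   `Ncut = cut/assoc(A) + cut/assoc(B)` is accepted while it stays below
   the 0.065 threshold.

Shipped defaults: `Δt = 0.1`, `n = 50`, `(a, b, c, l) =
(0.15, 1.4, 0.015, 0.015)`, `Ncut = 0.065`, `σX = 0.1`, `σI = 0.3`,
`r = 20` on 128 × 128 crops. A synthetic speckle-phantom generator with
ground-truth masks (background / hypoechoic nodule / tracheal ellipse,
L-look Gamma speckle, Gaussian point spread) makes everything testable
without clinical data; see the methods vignette
(`vignettes/methods.Rmd`) for the model details and design rationale.

## Worked example

```r
library(thynseg)

spec <- phantomSpec(seed = 0)   # default 128-px speckled phantom
out  <- runPipeline(spec)       # homomorphic -> diffusion -> fractional -> ncut

out$result
#> SegmentationResult: 4 region(s) on a 128 x 128 raster
#>   accepted split Ncuts: 0.0160, 0.0187, 0.0549

out$report
#>   label pixels mean_gray
#> 1     0   8633 0.6981531
#> 2     1    636 0.1714734
#> 3     2   5611 0.6962669
#> 4     3   1504 0.2644118

evaluateSegmentation(out$result, out$truth)
#>   truth_label pred_label truth_px pred_px overlap  dice
#> 1           0          0    14482    8633    8626 0.746
#> 3           2          1      547     636     541 0.915
#> 4          NA          2       NA    5611       0    NA
#> 2           1          3     1355    1504    1350 0.944
```

Every accepted split's Ncut is below the 0.065 threshold. Region matching
is by maximal overlap: the nodule (truth label 1) is recovered with Dice
0.944 and the trachea (truth label 2) with 0.915; the background was split
once more (an extra region, reported with `truth_label = NA`). Running the
same pipeline with all enhancement stages skipped finds only the trachea —
the enhancement is what makes the nodule separable.

A thin command-line wrapper lives at `inst/cli/thynseg.R`:

```sh
Rscript inst/cli/thynseg.R run scan.png --dump-intermediates --out results/
Rscript inst/cli/thynseg.R phantom spec.yaml --out phantom/
Rscript inst/cli/thynseg.R eval labels.png truth.png
```

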
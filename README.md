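# anchorreg

Anchor-point based non-rigid image registration for microscopy, in R.

Microscopy images of structured samples — atomic lattices in scanning-probe
microscopy (SPM), device outlines in optical microscopy — arrive misaligned
and distorted: camera pose varies between shots, and slow probe scans pick up
thermal drift and piezo creep. `anchorreg` registers such images against a
*structure model*: the known coordinates of structural features ("anchor
points" `P_m`, e.g. lattice sites or device corners) with their spacing `L`.
It is aimed at microscopists and image-analysis pipelines that need absolute-
scale comparisons across frames and per-site structural readout (which
lattice sites are occupied, which are defects).

## Method

Two stages, following the anchor-point workflow:

1. **Rough matching** — extract candidate points `P_e` from the image
   (difference-of-Gaussian dark-blob detection, or Otsu + minimum-area
   rectangle fit for device outlines); for periodic structures filter the
   cloud with a **vote rule** (each point scores +1 per neighbour at a
   distance in `[0.9L, 1.1L]`, −1 otherwise; negative scores are removed —
   a lattice-interior point scores +4, a typical spurious midpoint −2);
   place the model with an affine map `A = S·R·Sh·T` whose translation is
   found by brute-force grid search; pair `A⊗P_m` with `P_e` by gated
   nearest neighbours.
2. **Fine matching** — estimate the homography `H` with `P_e ≈ H ⊗ A ⊗ P_m`
   by **least median of squares** (normalised DLT on random 4-pair subsets,
   median-squared-residual scoring, inlier refit), then reconstruct
   `P_t = A⁻¹ ⊗ H⁻¹ ⊗ P_e` on the absolute model scale, rectify the image
   by the same inverse chain, and score accuracy by MAE and OKS
   (`mean exp(−d²/2s²κ²)`) with Recall@OKS>0.95 across samples.

A Monte-Carlo validation module (`run_noise_sweep`) quantifies estimation
accuracy under synthetic detection noise, and a fixture renderer
(`render_fixture`) produces images with exact ground truth so everything is
testable without instrument data.

## Worked example

Render a distorted lattice image with known ground truth, register it, and
rectify:

```r
library(anchorreg)

model <- make_lattice_model(4, 4)                 # 16 anchor points, L = 1
H_true <- transform_matrix(matrix(c(16, 0, 14,    # ~16 px per unit, offset 14 px,
                                    0, 16, 14,    # small projective distortion
                                    2e-4, -1.2e-4, 1), 3, 3, byrow = TRUE))
fx <- render_fixture(model, H_true, size = c(96, 96), noise_sd = 0.02, seed = 42)

res <- register(fx$image, model,
                fixed = affine_params(s_x = 16, s_y = 16),
                detection = detection_config(min_separation = 5),
                lmeds = lmeds_config(seed = 1))
res
#> <registration_result: status ok>
#>   pairs: 16   MAE: 0.001851   OKS: 1
round(res$H$m, 5)
#>          [,1]     [,2]    [,3]
#> [1,]  0.99831  0.00033 0.02056
#> [2,] -0.00001  0.99816 0.03343
#> [3,]  0.00000 -0.00002 1.00000

rect <- rectify(fx$image, res, pixels_per_unit = 18)  # anchors on an exact grid
```

All 16 sites were detected and paired; the reconstructed anchors sit 0.0019
unit lengths (about 0.03 px) from the model on average, and the residual
homography after the affine placement is within ~0.2% of the identity — the
planted projective distortion has been absorbed into `H` and removed by
`rectify()`. The vote rule on a perfect 3×3 lattice scores

```r
vote_filter(make_lattice_model(3, 3)$points, vote_config(1))$scores
#> [1] 2 3 2 3 4 3 2 3 2
```

(+4 at the interior point, nothing removed). See the methods vignette
(`vignettes/anchor-registration-methods.Rmd`) for the estimator details,
parameter meanings and validation design, and `cli_main()` /
`inst/cli/anchorreg` for the command-line interface
(`register`, `rectify`, `localize`, `diff`, `profile`, `sweep`, `fixture`).

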
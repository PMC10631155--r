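# jshape

Quantifies how elliptical segmented muscle cross-sections are, and how that
shape changes with limb positioning during MRI.

When the thigh is imaged supine, soft-tissue contact with the scanner table
deforms the posterior musculature, so the apparent cross-sectional shape of
a muscle depends on how the limb was positioned (for example on the level of
knee elevation). `jshape` implements the per-slice shape analysis used to
study this effect:

1. **Ellipse fit.** Each per-slice binary mask of a muscle is treated as a
   point cloud of foreground pixel centers. The fit's center is the centroid
   and its axes follow the eigen-decomposition of the 2×2 covariance matrix
   `Σ` of the cloud: with eigenvalues `λ₁ ≥ λ₂`, the semi-axes are
   `a = 2√λ₁`, `b = 2√λ₂` (exact for a uniformly filled elliptical lamina),
   the aspect ratio is `a/b` and the major-axis eigenvector gives the
   orientation.
2. **J index.** The fitted ellipse is rasterized back onto the mask's grid
   and the J index is the shared area divided by the non-shared area:
   `J = |A ∩ E| / |A Δ E|`, where `A` is the segmented region and `E` the
   fitted ellipse. `J` relates to the Jaccard index by
   `J = Jaccard / (1 − Jaccard)`; larger J means a more elliptical section.
3. **Study pipeline.** Per-slice J values are aggregated to per-muscle
   mean ± SD for every positioning condition, and each condition is compared
   with a reference condition by the percentage change in mean J,
   `|J̄_b − J̄_ref| / J̄_ref × 100`.
4. **Synthetic phantoms.** A seeded generator builds NIfTI label volumes of
   seven thigh muscles (quadriceps and hamstrings) with near-elliptical,
   smoothly tapering cross-sections, a one-sided "flattening" truncation
   whose strength varies by position and muscle group, and optional boundary
   noise — so the full analysis runs with no external data.

A small goniometer module computes the knee-elevation angle between a
femoral axis (two landmarks) and the imaging-plane normal.

Intended users: researchers in musculoskeletal imaging and biomechanics who
work with per-muscle segmentations (NIfTI label volumes, or per-slice
PNG/CSV masks) and want reproducible shape metrics across scan conditions.

## Worked example

Fit a 60 × 30 mm rectangle (a deliberately non-elliptical shape) and score
it, then run a full synthetic three-position study:

```r
library(jshape)

g <- matrix(FALSE, 80, 80); g[20:49, 11:70] <- TRUE
mask <- cross_section_mask(g, pixel_spacing_mm = c(1, 1))
fit  <- fit_mask_ellipse(mask)
fit
#> <ellipse_fit> center (40.00, 34.00) mm, a = 34.636, b = 17.311 mm, theta = 0.00 deg, a/b = 2.001
compute_j_index(mask, fit)
#> <j_index_result> J = 4.9762 (inter 1672.00 mm^2, sym diff 336.00 mm^2)
```

The fitted semi-major axis matches the analytic lamina moment of a rectangle
(`a = w/√3 ≈ 34.64` mm) and the aspect ratio its `w/h = 2`; a rectangle is
only moderately elliptical, hence `J ≈ 5` (for comparison, a rasterized disc
scores in the hundreds and a true ellipse is degenerate: nothing is
non-shared).

```r
spec  <- default_phantom_spec(seed = 42)
study <- generate_study(spec)
res   <- run_study(study_config(), study$volumes)
subset(res$comparisons, position_b == "high")
#>              muscle position_a position_b percent_change signed_change
#>      biceps_femoris       none       high         65.946       -65.946
#>     semimembranosus       none       high         64.845       -64.845
#>      semitendinosus       none       high         60.196       -60.196
#>      rectus_femoris       none       high          2.564         2.564
#>     vastus_medialis       none       high          1.906         1.906
#>    vastus_lateralis       none       high          1.647         1.647
#>  vastus_intermedius       none       high          0.555         0.555
```

In the default phantom the hamstring flattening grows across positions while
the quadriceps flattening is constant, so hamstring percentage changes
dominate the quadriceps ones — the qualitative signature of
positioning-sensitive posterior-thigh deformation. `run_study(...,
out_dir = ...)` writes `slices.csv`, `summaries.csv`, `comparisons.csv`
(and `angles.csv` when landmarks are supplied).

A thin command-line wrapper is installed at `inst/cli/jshape.R`
(subcommands `fit`, `jindex`, `angle`, `simulate`, `study`).

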
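# mmdect

Image-domain multi-material decomposition (MMD) for dual-energy CT in R.

## The problem

A single-energy CT image assigns every tissue one number, so materials
with similar attenuation — iodinated contrast in a vessel and a calcium
plaque on its wall, or fat and water-like soft tissue — can be
indistinguishable. Dual-energy CT (DECT) scans the object at two tube
voltages, giving each pixel a coordinate \((\mu_{low}, \mu_{high})\) in a
2-D attenuation plane where materials separate. Two measurements only pin
down two materials; to decompose **three**, a volume-conservation
constraint is added. Per pixel the method solves

    [ mu_1(E1)  mu_2(E1)  mu_3(E1) ] [ a1 ]   [ mu(E1) ]
    [ mu_1(E2)  mu_2(E2)  mu_3(E2) ] [ a2 ] = [ mu(E2) ]
    [    1         1         1     ] [ a3 ]   [   1    ]

whose solution \((\alpha_1,\alpha_2,\alpha_3)\) is the barycentric
coordinate of the pixel with respect to a *triangle* of three library
materials; only solutions with all \(\alpha_i \ge 0\) (pixel inside the
triangle) are physical volume fractions. The package automates the
triangle choice:

* the material library is **clustered locally** in attenuation space
  (Euclidean distance to a cluster agent), which shrinks the search
  domain and lets independent material groups decompose in parallel;
* a pixel's initial triangle comes from the three nearest cluster
  agents; if the pixel falls outside, a new containing triangle is
  selected by **bi-directional Hausdorff similarity** to the initial one;
* points outside the library's convex hull (e.g. metal) are clamped to
  the hull boundary and flagged, never silently mis-assigned;
* both energy images are denoised first with a **doubly local Wiener
  filter with directional windows** (two-pass wavelet-domain shrinkage
  with orientation-matched variance windows);
* volume fractions convert to **mass fractions** via
  \(m_i = \alpha_i\rho_i / \sum_j \alpha_j\rho_j\), the quantity
  concentration studies report.

Because scanner data cannot ship with a package, `mmdect` includes a
synthetic DECT simulator with pixel-level ground truth for three
evaluation objects: a 12-vial angiography phantom (iodine contrast and
KOH dilutions in water), a QA phantom (body section with
Water/Lexan/Acrylic/Teflon inserts; head section with 1–3 mm air
pinholes) and an abdominal slice (air/blood/fat/bone). It is aimed at
researchers prototyping DECT decomposition and quantification workflows.

## Worked example

Decompose the synthetic 12-vial angiography phantom at a realistic noise
level (10 HU), each contrast series as its own three-material group:

```r
library(mmdect)
ang <- demo_angiography(noise_sigma_hu = 10, seed = 0)
ang$vials[, c("solute", "concentration", "true_mass_fraction",
              "est_mass_fraction", "accuracy_pct")]
#>    solute       concentration true_mass_fraction est_mass_fraction accuracy_pct
#>  1 omnipaque350             1            0.00402           0.00424         94.7
#>  5 omnipaque350             5            0.0200            0.0205          97.5
#>  6 omnipaque350            10            0.0398            0.0407          97.9
#>  7 koh50                    5            0.1               0.112           87.6
#> 12 koh50                   50            1                 0.999           99.9
ang$fit
#>   solute       slope intercept r_squared     n
#> 1 omnipaque350 1.02   0.000210     1.000     6
#> 2 koh50        0.991  0.0200       0.999     6
```

Each vial's estimated stock mass fraction tracks the true one: the
iodine series is quantified to 94.7–97.9% accuracy (hardest at 1 mg/ml,
the weakest clinically realistic enhancement), the KOH series to
87.6–99.9%, and both concentration responses are linear (R² ≥ 0.999,
slope ≈ 1).

The abdominal demo reports region recovery and the effect of denoising:

```r
abd <- demo_abdomen(noise_sigma_hu = 10, seed = 0)
dplyr::summarise(dplyr::group_by(abd$report$roi, material),
                 mean_area_error_pct = mean(area_error_pct))
#>   material mean_area_error_pct
#> 1 blood                      0
#> 2 fat                        0
abd$report$noise
#>   energy sd_before sd_after reduction_pct
#> 1 low         10.7     1.20          88.7
#> 2 high        10.0     1.82          81.8
```

With denoising, every blood and fat ROI is recovered at exactly its true
area (0% area error at threshold 0.5), and the 10 HU image noise drops
to 1.2–1.8 HU. `autoplot(abd$vf)` shows the per-material fraction
images; `tidy(abd$vf)` gives them as a long tibble.

A thin CLI wraps the same functions:

```sh
exec/mmdect simulate --phantom abdomen --sigma 10 --out out/
exec/mmdect decompose --low out/low_hu.csv --high out/high_hu.csv \
    --materials air,blood,fat,bone --out out/maps
exec/mmdect demo --sigma 10 --seed 0 --out out/demo
```

## Package tour

| Area | Functions |
|---|---|
| Material library | `material_library()`, `default_material_library()`, `read_material_library()`, `hu_to_mu()` |
| Clustering | `cluster_materials()`, `assign_cluster()`, `update_subgroups()`, `build_histogram2d()` |
| Decomposition | `solve_barycentric()`, `decompose_pixel()`, `decompose_image()`, `volume_to_mass_fraction()` |
| Triangle optimization | `directed_hausdorff()`, `bidirectional_hausdorff()`, `select_triangle()` |
| Denoising | `dwt2()`, `estimate_noise_sigma()`, `local_wiener_pass()`, `dlwfdw_denoise()` |
| Simulation | `make_angio_phantom()`, `make_qa_body()`, `make_qa_head()`, `make_abdomen()`, `render_dect()` |
| Pipeline | `mmd_config()`, `run_pipeline()`, `roi_area_ratio()`, `concentration_fit()`, `demo_*()` |

See `vignettes/mmdect-methods.Rmd` for the model, the design decisions
and the limits of what the synthetic evaluation shows.
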
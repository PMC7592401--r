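---
title: "Multi-material DECT decomposition: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-material DECT decomposition: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdect)
```

## The model

Dual-energy CT measures each pixel twice, at a low and a high effective
energy, giving a coordinate $(\mu_{low}, \mu_{high})$ in a 2-D linear
attenuation plane. Within a pixel the attenuation is, to good
approximation, the volume-weighted sum of the attenuations of its
constituent materials, $\mu(E) = \sum_i \alpha_i \mu_i(E)$. With two
measurements and the volume-conservation constraint
$\sum_i \alpha_i = 1$, exactly three materials can be solved per pixel:

$$
\begin{pmatrix}
\mu_1(E_1) & \mu_2(E_1) & \mu_3(E_1)\\
\mu_1(E_2) & \mu_2(E_2) & \mu_3(E_2)\\
1 & 1 & 1
\end{pmatrix}
\begin{pmatrix}\alpha_1\\\alpha_2\\\alpha_3\end{pmatrix}
=
\begin{pmatrix}\mu(E_1)\\\mu(E_2)\\1\end{pmatrix}.
$$

Geometrically $\boldsymbol\alpha$ is the barycentric coordinate of the
pixel's attenuation point with respect to the triangle spanned by the
three materials; when the point lies inside, each $\alpha_i$ equals the
area of the sub-triangle opposite vertex $i$ divided by the total area,
and all fractions are non-negative — the physical admissibility
condition. (The test suite checks the solver against an independent
signed-area construction on 1000 random triangle/point pairs.)

With more than three candidate materials the choice of triangle is the
whole problem. The pipeline automates it in three tiers:

1. **Local clustering.** Library materials (and, via
   `update_subgroups()`, any stray histogram points) are grouped by
   greedy agglomeration: the closest pair of clusters merges as long as
   every member stays within an acceptance `radius` of the recomputed
   centroid ("agent"). A pixel's initial triangle is formed by its three
   nearest agents. Clusters inherit the library's `group` labels, and
   candidate enumeration is confined to the pixel's group, which is what
   makes groups decomposable independently (in parallel).
2. **Vertex refinement.** When the agent-triangle solve is admissible,
   each agent vertex is replaced by its cluster's member material
   nearest the pixel and the system is re-solved on the refined
   vertices. Solving directly against the agent coordinates and then
   attributing fractions to members would bias every multi-member
   cluster (the agent is not a material); refinement keeps the solve
   exact whenever the refined triangle contains the point, and falls
   through to tier 3 otherwise.
3. **Hausdorff re-selection.** For pixels outside their initial
   triangle, all 3-combinations of group materials plus all agent
   triplets are enumerated; among those containing the point, the one
   minimizing the bi-directional Hausdorff distance to the initial
   triangle's vertex set wins. Ties break lexicographically on vertex
   names, with material triangles preferred over agent triplets.

Two further rules make the per-pixel map total:

* **Exact sparse short-circuit.** A point numerically on a library
  vertex, or on the segment between two materials, has a unique sparsest
  composition, and the package assigns it directly (tolerance
  $10^{-9}$ of the library's attenuation-space diagonal). This matters
  because a noiseless two-material mixture can also be *exactly* inside
  some three-material triangle of other library entries — e.g. an
  air/blood partial-volume pixel is reproducible as an
  air + fat + bone mixture, and a dilute-iodine pixel as a weak
  KOH + air mixture; that is precisely the contrast/calcium ambiguity
  that motivates the method. The sparse rule resolves exact data to the
  parsimonious answer; the tolerance is nine orders of magnitude below
  any realistic noise, so noisy solves are untouched by it.
* **Convex-hull clamping.** A point no candidate triangle contains lies
  outside the library's convex hull (metal artifacts, extreme noise).
  It is orthogonally projected onto the nearest hull edge, decomposed
  between that edge's two materials, and flagged in the `out_of_hull`
  mask rather than erroring or silently extrapolating.

## Hausdorff distance: two conventions

The directed distance $h(A,B) = \max_{a\in A}\min_{b\in B}\|a-b\|$ is
computed with the classical randomized early-break scan (the inner loop
aborts as soon as a distance falls below the running maximum; a
broken-out point is skipped, so randomization changes the work done,
never the value — a property the tests assert). Points common to both
sets are excluded up front, so $h(A,B)=0$ exactly when $A\subseteq B$.
For the bi-directional combination the package exposes both
`"standard-max"` (the classical Hausdorff metric, the default) and
`"paper-min"` (the minimum of the two directed values, a laxer
similarity score found in some formulations). For triangle re-selection
on the packaged phantoms the two agree wherever it matters because
containment already filters the candidates.

## Denoising: doubly local Wiener filtering with directional windows

DECT spectra overlap, so decomposition is noise-sensitive; both energy
images are denoised before conversion to attenuation. The filter
operates in an orthogonal wavelet domain (sym4, 3 levels, periodized —
chosen over symmetric extension because periodization with orthonormal
8-tap filters reconstructs exactly, which the pyramid invariant demands;
image sides must be divisible by $2^{levels}$). Per detail band:

* **Pass 1** estimates each coefficient's signal variance as the local
  mean of squared coefficients minus the noise variance (floored at 0)
  over a window elongated along the band's orientation — 3×9 for
  horizontal-structure bands, 9×3 for vertical, 5×5 for diagonal — and
  applies the Wiener gain $\sigma_x^2/(\sigma_x^2+\sigma_n^2)$.
* **Pass 2** re-estimates the signal variance from the pass-1 denoised
  coefficients over a second, smaller directional window (3×5 / 5×3 /
  3×3) and shrinks the *original* coefficients with it. The first pass
  is only a pilot: variance estimated from denoised coefficients is far
  less contaminated around edges, which is the "doubly local" idea.

The noise level defaults to the median absolute deviation of the finest
diagonal band divided by 0.6745; a sigma at or below the numerical
precision of the image scale returns the input unchanged, so denoising
is exactly ablatable on clean data. Window sizes, wavelet, level count
and sigma are config-exposed. The noise model used throughout the
simulator is additive white Gaussian in HU, independent per energy;
correlated CT noise (streaks, reconstruction kernels) is out of scope.

## The synthetic phantoms and what they do (not) show

The three evaluation objects are forward-rendered with the same linear
mixing model the decomposition inverts, at effective energies 52 keV
(80 kVp) and 69 keV (140 kVp), with 4×4 supersampling so boundary pixels
carry genuine partial-volume mixtures:

* **Angiography phantom**: water-filled Plexiglas cylinder, twelve 12 mm
  vials on a ring; six iodine dilutions (1, 2, 3, 4, 5, 10 mg/ml,
  parameterized directly in mg iodine/ml of a 350 mg I/ml stock to avoid
  percent-conversion ambiguity; the 1 mg/ml floor is the weakest
  clinically realistic enhancement) and six KOH dilutions (5–50% w/w of
  a 50% stock, the calcium-plaque surrogate). 256×256 at 0.5 mm.
* **QA phantom**: body section with pure Water/Lexan/Acrylic/Teflon
  inserts and air holes (256×256 at 0.8 mm); head section with air
  pinholes of 1, 2, 3 mm in a uniform water body (192×192 at 0.5 mm) for
  the resolution test.
* **Abdominal slice**: elliptical body with subcutaneous fat ring,
  blood-equivalent soft tissue, visceral fat deposits, a bone "spine"
  and bowel gas, 256×256 at 1.5 mm. Region boundaries are kept disjoint
  so ground-truth pixels mix at most two materials; 8 blood and 8 fat
  evaluation ROIs sit strictly inside their regions (the ROI count is a
  documented stand-in — clinical ROI placement is operator-dependent).

The default noise levels used by the demos and the acceptance script —
10 HU on the abdomen and angiography phantom, 5 HU on the head section —
are typical CT image noise for abdominal and head protocols.

The **angiography phantom is decomposed per contrast group**: the iodine
series as {air, water, iodine stock} and the KOH series as {air, water,
KOH stock}, two independent three-material runs. This mirrors how the
QA body resolves into per-material component images and is the
practical use of grouping: with both stocks plus casing material in one
candidate set, a dilute-iodine pixel is *mathematically* inside several
triangles and no similarity rule can recover the true composition from a
single energy pair — the ambiguity is physics, not implementation. The
per-group round-trip checks therefore evaluate each run over the pixels
whose ground truth lies within that group's materials; the Plexiglas
casing is rendered but is not a decomposition target.

Because simulator and solver share the linear forward model, noiseless
round trips are exact to machine precision; this validates the
machinery, not the physics. What the synthetic evaluation does **not**
probe: beam hardening and scatter (effective-energy monochromatic
rendering), correlated noise, spectral drift between scans, registration
error between the two acquisitions, and real tissue heterogeneity. The
packaged attenuation table is derived from standard photon
cross-section tabulations at the two effective energies (generation
script in `inst/scripts/`); its absolute accuracy matters little for the
synthetic round trips but would matter on scanner data.

## Numerical choices

* Containment tolerance: $\alpha_i \ge -10^{-9}$ counts as inside
  (float noise on triangle edges); tolerated negatives are clamped to 0
  and rows renormalized, so every reported pixel satisfies
  $\alpha \in [0,1]$, $\sum\alpha = 1$, at most 3 non-zero.
* Degeneracy: a triangle is rejected when the determinant of its 3×3
  system falls below $10^{-12}$ times the squared coordinate scale.
* Cluster radius default: 5% of the library's attenuation-space
  bounding-box diagonal; configurable, and worth lowering for libraries
  whose diagonal is stretched by a contrast stock.
* Tie-breaks are deterministic everywhere: lowest library index for
  equidistant agents and equal merge distances, lexicographic vertex
  names for equal Hausdorff distances, material triangles over agent
  triplets.
* The concentration fit reports $R^2 = 0$ for a constant response
  (zero regression sum of squares) by convention.
* Mass-fraction accuracy is $100\,(1 - |\hat m - m|/m)$ on the
  vial-mean mass fraction, clamped to $[0, 100]$; vial means exclude a
  1 mm boundary rim so partial-volume pixels do not dilute the estimate.
* A pin counts as detected when the mean decomposed air fraction inside
  its true disk exceeds 0.5.
* Problem sizes for the packaged experiments (256×256 and 192×192
  single slices) keep every demo and the acceptance script in the
  seconds-to-tens-of-seconds range on one core while leaving >100
  pixels in the smallest evaluation structure.

## Known limitations

* Only 2-D slices; volumes decompose slice-by-slice.
* The library stores effective-energy coefficients; polychromatic
  spectra are not modelled, so no beam-hardening correction exists or
  is needed in simulation.
* Image input is NIfTI or delimited grids (no DICOM reader dependency);
  fraction maps are written as CSV or NIfTI.
* With more than three materials whose coordinates are not in convex
  position, noisy pixels near an interior material admit several
  admissible triangles; the Hausdorff rule is a heuristic there, and
  grouping (as in the angiography protocol) is the reliable answer.
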
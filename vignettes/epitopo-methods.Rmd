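---
title: "Methods: 3D cell-neighbour organisation in pseudostratified epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cell-neighbour organisation in pseudostratified epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitopo)
```

## Scope and model

A pseudostratified epithelium is a single-layered tissue whose elongated
cells all contact both the apical and the basal surface, while their
nuclei sit at different heights.  Although each cell spans the full
tissue thickness, its cross-sectional shape is not constant along the
apical–basal axis: the polygonal outline changes area and, crucially,
*neighbourhood* — a cell can gain and lose lateral contacts between the
apical and the basal side.  `epitopo` treats such a tissue as a stack of
planar polygonal tessellations:

* a **layer** (`polygonal_layer`) is one cross-section: per-cell areas,
  neighbour sets, and an interior mask;
* a **cell column** (`cell_column`) is one cell traced through all
  layers: its per-section area and neighbour set, indexed by the
  relative apical–basal position $z \in [0, 1]$ (0 = apical);
* a **tissue** bundles the layers, the columns, the nuclei, and
  (optionally) rasterised label stacks.

Input can be segmented label-image stacks (16-bit TIFF, one page per
section, via `read_label_stack()` + `build_layer()`) or a tidy
`cells.csv` table (`read_cells()`).

## Planar organisation laws

`layer_stats()` computes, per layer and over interior cells only:

* the mean neighbour number $\bar n$.  For a tessellation without
  boundary (a torus) Euler's polyhedron formula forces $\bar n = 6$
  exactly; bounded tissues approach 6 from below as the
  boundary-to-interior ratio shrinks;
* **Lewis' law**: the mean relative area of $n$-sided cells,
  $\bar A_n / \bar A = (n - 2)/4$ in the linear form
  (`lewis_linear()`), or the quadratic form
  $(n/6)\tan(\pi/6)/\tan(\pi/n)$ (`lewis_quadratic()`);
* the **Aboav–Weaire law**: the mean neighbour number $m(n)$ of the
  cells adjacent to an $n$-sided cell, $m(n) = 5 + 8/n$
  (`aw_prediction()`);
* the hexagon fraction, the polygon-class distribution, and the area
  coefficient of variation (sample standard deviation over the mean).

`predict_class_distribution()` inverts a Lewis-type law into an
expected polygon-class distribution: cell areas are modelled as a
truncated-normal family (parent $\mathcal N(1, \mathrm{cv})$ truncated
at 0 and rescaled to unit mean; a gamma family is available as an
alternative), the law maps polygon class $n$ to a relative-area band
with midpoint bin edges, and a self-consistency loop rescales so the
realised mean relative area is 1.  At $\mathrm{cv} = 0$ all mass is
hexagonal; increasing area dispersion spreads mass into other classes.

**Known limitation.**  The hexagon fraction predicted by this family
declines steeply up to $\mathrm{cv} \approx 0.5$ but is *not* globally
monotone: it attains a minimum ($\approx 0.097$ for the linear law near
$\mathrm{cv} = 0.51$) and then creeps upward by under 0.011 as
$\mathrm{cv} \to 1$, because the zero-truncation increasingly piles
probability of the unit-mean-rescaled density back into the central
band.  Treat the curves as quantitative only for
$\mathrm{cv} \lesssim 0.5$, which covers the range observed in
epithelia ($\mathrm{cv} \approx 0.2$–0.4).

## Lateral neighbour exchanges (T1L)

`detect_t1()` compares a column's neighbour *set* between adjacent
sections; any change (gain, loss, or an equal-count exchange — the
scutoid case, $\Delta n = 0$) at an interface is one lateral T1
transition.  `transition_stats()` aggregates counts over interior
columns and reports the mean per cell, the variance, the dispersion
index (variance/mean; 1 under a Poisson model), a $\chi^2$
goodness-of-fit test against the fitted Poisson distribution
(`poisson_gof()`, with both-tail merging to expected counts $\ge 5$ and
$\mathrm{dof} = \mathrm{bins} - 2$), and the mean relative
apical–basal position of the transitions with a normal-approximation
95% confidence interval.  `generate_poisson_columns()` produces
synthetic columns with a prescribed Poisson transition rate for
calibration.

## Curvature model

On a curved tube (e.g. a branching-organ trunk), apical and basal
cross-section perimeters differ; the basal-to-apical perimeter ratio
sets how much a cell's in-plane footprint is stretched.  Apical and
basal boundary outlines are fitted with direct least-squares ellipse
fits (`fit_ellipse()`, the Fitzgibbon constrained eigenvector method:
among all conics minimising the algebraic distance it enforces
$4AC - B^2 = 1$, guaranteeing an ellipse).  Semi-axes are recovered
from the general conic via the closed form
$\ell_{1,2}^2 = -2\,(AE^2 + CD^2 - BDE + (B^2-4AC)F)\,
\big((A+C) \pm \sqrt{(A-C)^2+B^2}\big) / (B^2-4AC)^2$.
`tube_geometry()` stores the two fitted ellipses; `local_radius(x,
geom)` interpolates an effective local radius linearly in the relative
depth $x$, and `predicted_fold(n)` gives the expected basal/apical
fold change of a cell that undergoes $n$ lateral transitions.
`event_fold_changes()` pairs each column's consecutive transitions and
reports the measured cross-section area fold between them.

## Nuclear morphometrics

`nuclear_stats()` measures labelled nuclei in a 3D stack: volume,
centroid depth, and ellipsoid shape from the voxel inertia tensor
(semi-axes $\sqrt{5\lambda_i}$ of the eigenvalues of the second-moment
matrix — exact for a solid ellipsoid), giving the ellipticity
$1 - c/a$.  `cell_nucleus_correlation()` correlates per-cell nuclear
size with the cell's cross-section area at the nuclear depth, and
`ellipticity_position_test()` runs a one-sided Welch $t$-test of
apical-third versus mid-tissue ellipticity, reflecting interkinetic
nuclear migration (IKNM): mitotic, apically located nuclei round up.

## Synthetic generator

`generate_tissue()` builds a fully labelled synthetic tissue from a
`simulation_config()`:

1. per-cell base areas are drawn from the truncated-normal family at
   `base_area_cv`; per-layer targets modulate each cell's area along
   $z$ with a smooth bulge centred on its (IKNM-sampled) nuclear depth,
   conserving total area per layer;
2. each section is tessellated with a **power diagram** (additively
   weighted Voronoi): seeds drift smoothly along $z$, and weights are
   fitted so realised areas match the targets;
3. nuclei are placed as prolate ellipsoids (aspect `nuclear_aspect`,
   default 2) at the sampled depths with volume
   `nuclear_volume_fraction` (default 0.55) of the cell volume, then
   rasterised and cleaned to one 6-connected component per nucleus.

Realism checks built into the test-suite: layer statistics reproduce
$\bar n \approx 6$, Lewis and Aboav–Weaire trends, and the configured
area CV; transition counts are near-Poisson; nuclear-to-cell size
correlation is strong; the bulge peak tracks the nuclear centre.

`generate_random_layer()` exposes a single bounded 400-cell layer, and
`generate_hex_layer()` a degenerate regular-hexagon control
($\bar n = 6$, hexagon fraction 1, area CV 0).

## Numerical choices

* **Weight fitting.**  The power-diagram weights are tuned by a damped
  fixed-point iteration on a pixel grid (area error feeds back into the
  weight through the isotropic-cell sensitivity $dA/dw \approx \pi/2$),
  with *per-cell* adaptive gains: a cell whose area error flips sign is
  oscillating between pixel configurations and has its gain halved
  (floor 0.02), while consistently moving cells recover their full
  step.  Convergence is declared when the mean absolute area error
  falls below 1% of the mean area; non-convergence is an error, never
  silently accepted.
* **Exact polygons.**  Final per-cell areas, adjacencies, and vertex
  polygons are *not* read off the raster: `power_diagram_cells()`
  clips each cell exactly by sequential half-plane intersection
  ($2(s_j - s_i)\cdot x \le |s_j|^2 - |s_i|^2 + w_i - w_j$, nearest
  periodic image), giving shoelace areas and edge-sharing adjacency
  free of raster bias.  Raster adjacency undercounts short edges and
  depresses $\bar n$ by $\approx 0.2$; the exact path measures
  $\bar n = 5.96$–5.97 on bounded 400-cell layers.
* **Raster adjacency convention.**  When building layers from label
  images, `build_layer()` counts two labels as neighbours when they
  share at least `min_contact` (default 2) 4-connected boundary pixel
  pairs, suppressing spurious single-pixel corner contacts.
* **Interior mask.**  Bounded layers exclude the boundary ring and
  (for `generate_random_layer()`) its first interior ring from the
  statistics, since clipped cells have truncated neighbourhoods.
* **Reproducibility.**  All stochastic entry points take an explicit
  seed and restore the caller's RNG state on exit.

## Limitations

* The curvature model assumes elliptic cross-sections and linear
  interpolation of the local radius in depth; strongly non-elliptic or
  saddle-shaped tissues are out of scope.
* The theory curves inherit the truncated-normal area family's
  non-monotonicity above $\mathrm{cv} \approx 0.5$ (see above).
* The generator drifts seeds smoothly, so it produces gradual neighbour
  exchanges; it does not model cell division, extrusion, or
  intercalation forced by external flows.
* Raster-derived areas and adjacency are resolution-limited; use
  `pixels_per_cell` $\ge$ 250 (default) for quantitative layer
  statistics when working from the label stacks rather than the exact
  polygon path.
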
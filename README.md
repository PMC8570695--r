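# epitopo

3D cell-neighbour organisation in pseudostratified epithelia.

Pseudostratified epithelia look stratified — nuclei sit at many heights
— but every cell touches both the apical and the basal surface. A
cell's polygonal cross-section is therefore not one shape but a whole
*profile* along the apical–basal axis: its area changes (a bulge travels
with the nucleus during interkinetic nuclear migration) and its set of
lateral neighbours changes too. A neighbour exchange between two
adjacent depths is a **lateral T1 transition**; cells exhibiting an
equal-count exchange are the 3D shapes known as scutoids.

`epitopo` quantifies this organisation from segmented cross-section
stacks (16-bit TIFF label images), tidy per-layer tables, or its own
synthetic generator:

* **Planar organisation laws per layer** — mean neighbour number
  (Euler: 6 on a boundary-free tessellation), Lewis' law
  (linear `(n − 2)/4` and quadratic forms), the Aboav–Weaire law
  `m(n) = 5 + 8/n`, polygon-class distributions, and hexagon fraction
  versus area coefficient of variation, with theory curves from a
  truncated-normal area model.
* **Lateral T1 detection and statistics** — per-interface neighbour-set
  comparison along each cell column, Poisson goodness-of-fit,
  dispersion index, and the apical–basal distribution of transitions.
* **Curvature model** — direct least-squares ellipse fits of apical and
  basal outlines, a local-radius tube model, and predicted versus
  measured cross-section fold changes between consecutive transitions.
* **Nuclear morphometrics** — inertia-tensor ellipsoid fits (volume,
  ellipticity, depth), nuclear-to-cell size correlation, and a Welch
  test of apical nuclear rounding (IKNM).
* **Synthetic generator** — a drifting-seed power-diagram tissue with
  prescribed area dispersion, nuclear volume fraction, and IKNM depth
  distribution, for fully reproducible end-to-end testing.
* **IO and pipeline** — TIFF label stacks, `cells.csv`/`nuclei.csv`
  tables, YAML/JSON configs, `run_pipeline()`, and a CLI at
  `inst/cli/epitopo.R`.

See the methods vignette (`vignettes/epitopo-methods.Rmd`) for the
model, numerical choices, and limitations.

## Worked example

```r
library(epitopo)

cfg <- simulation_config(n_cells = 140, n_layers = 30, seed = 1)
tissue <- generate_tissue(cfg)
tissue
#> <synthetic_tissue> 140 cells x 30 layers, 58.0 x 58.0 x 25.0 um (periodic)

# planar organisation of the mid-tissue section
layer_stats(tissue$layers[[15]])
#> <layer_stats> 140 interior cells: n_bar = 5.686, area CV = 0.521, hexagons 37.9%

# lateral T1 transitions along the apical-basal axis
transition_stats(tissue$columns)
#> <transition_stats> 140 cells, 1321 events: mean 9.44, dispersion 1.28, mean position 0.509

# curvature: circular apical tube section (R = 10) against an elliptic
# basal section whose minor-vertex radius is 22.1
geom <- tube_geometry(10, 10, 14, 14^2 / 22.1)
local_radius(1, geom) / local_radius(0, geom)
#> [1] 2.21

# nuclear size tracks the cell cross-section at the nuclear depth
corr <- cell_nucleus_correlation(tissue$columns, tissue$nuclei)
round(c(r_area = corr$r_area, r_volume = corr$r_volume), 3)
#>   r_area r_volume
#>    0.754    0.988

# degenerate control: a regular hexagonal lattice
layer_stats(generate_hex_layer())
#> <layer_stats> 100 interior cells: n_bar = 6.000, area CV = 0.000, hexagons 100.0%
```

Analysing real data follows the same path: read a segmented stack with
`read_label_stack()`, build layers with `build_layer()` (or a tidy
table with `read_cells()`), then apply `layer_stats()`,
`detect_t1_all()`, `transition_stats()`, `fit_tube_geometry()`,
and `nuclear_stats()`.

## Command line

```sh
Rscript inst/cli/epitopo.R pipeline --config config.yaml --seed 1 --out results/
Rscript inst/cli/epitopo.R t1 --cells results/cells.csv --out t1/
```

Subcommands: `simulate`, `layers`, `t1`, `curvature`, `nuclei`,
`theory`, `pipeline`. Logs go to stderr, artefacts to `--out`.

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .

# test suite (testthat 3e) against the installed package
Rscript -e 'testthat::test_dir("tests/testthat", package = "epitopo",
                               load_package = "installed")'

# headline quantities as a flat JSON file; all randomness from --seed
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Two acceptance assertions are expected to fail and are documented
rather than patched: the hexagon-fraction theory curve is not globally
monotone in the area CV — for the truncated-normal area family it
reaches a minimum near CV ≈ 0.5 and then rises by < 0.011 up to CV = 1
(see the vignette's limitations section). All other tests pass.

## Package layout

* `R/`, `src/` — analysis code; the pixel-assignment and
  weight-fitting inner loops are C++ (Rcpp).
* `tests/testthat/` — unit and oracle tests plus
  `test-acceptance.R` with the headline scientific assertions.
* `scripts/acceptance.R` — standalone reproduction script.
* `inst/cli/epitopo.R` — command-line interface.
* `vignettes/epitopo-methods.Rmd` — methods notes (source only).
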
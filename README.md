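# antspread

Spatiotemporal diffusion analysis for gridded invasive-ant surveillance.

Surveillance programs for the red imported fire ant (*Solenopsis
invicta*, RIFA) lay bait tubes on regular lattices and record, per tube
and survey year, whether any fire ants were caught. `antspread`
implements the full analysis chain that turns those tube tables — plus a
categorical land-use map — into actionable quantities for control
planning: how intense the infestation is where, how far it jumps between
years, which land-use types act as diffusion sources, and which areas
are entrenched hot spots versus active diffusion fronts. It is aimed at
spatial ecologists and plant-protection agencies working with
multi-density trap grids.

## The methods

**Density standardization.** Trap densities differ between years and
strata (1 tube per 100×100, 200×200 or 600×600 m²), so raw positive
counts are not comparable. Each positive tube is weighted by the lattice
cell it represents relative to the 200-m reference:

    w = (spacing / 200)²   →   0.25, 1, 9  for 100-, 200-, 600-m grids.

Negative tubes carry weight 0. Incidence rates (positives / all tubes
per group) deliberately use raw counts, since numerator and denominator
share a lattice.

**Intensity surfaces.** Standardized weights are interpolated by
ordinary kriging (Matheron empirical semivariogram, weighted
least-squares model fit, covariance-form system with a Lagrange
multiplier so prediction weights sum to one).

**Critical dispersal distance.** For each pair of consecutive years,
every year-t+1 positive tube contributes its distance to the nearest
year-t positive. The cumulative proportion curve of these distances is
summarized by a chord-residual turning-point estimator (the
extreme-distance estimator): the critical dispersal distance d* is the
distance of highest consecutive-year dispersal probability — not the
maximum dispersal distance. Yearly values are averaged into a
region-level d*.

**Land-use transition networks.** Tubes are joined to level-III
land-use codes; for each year pair, a directed weighted network on
codes attributes each new positive's weight to the in-range (≤ d*)
sources, split equally. Hub scores from the HITS algorithm identify
diffusion-source land uses; Louvain modularity communities identify
groups of land uses that exchange diffusion mass.

**Hotspot / diffusion mapping.** A bivariate local Moran's I,
I_i = z_x(i) · Σ_j w_ij z_y(j), relates source-land-use intensity in
year t (x) to neighborhood intensity in year t+1 (y) on a queen-
contiguity cell lattice, with conditional-permutation pseudo p-values.
Significant positive cells are hot spots; significant negative cells
are diffusion areas.

**Synthetic surveillance generator.** A seeded forward model (landscape
with road corridors, paddy patches and warehouse blocks; multi-density
tube lattices; yearly spreading with a mixture displacement kernel whose
P(D ≤ d0) = p_near exactly) provides ground truth for every estimator.

## Worked example

```r
library(antspread)

cfg <- simulation_config(seed = 42)        # 6x6 km, 4 survey years
sim <- simulate_surveillance(cfg)
tubes <- assign_landuse(standardize_tubes(sim$tubes), sim$map)
pos <- function(yr) tubes[tubes$year == yr & tubes$status == 1L, ]

# critical dispersal distances per year pair, and their mean
cds <- lapply(1:3, function(i) critical_distance(pos(2007 + i), pos(2008 + i)))
sapply(cds, `[[`, "d_star")
#> [1] 275 500 450
mean_critical_distance(sapply(cds, `[[`, "d_star"))
#> [1] 408.3333

# land-use transition network for the last year pair, thresholded at d*
net <- build_transition_network(pos(2010), pos(2011), d_star = 600)
net
#> transition_network: 6 nodes, 32 edges, total weight 126
head(score_nodes(net), 3)
#>     code   hub authority hub_rank community
#>   030101 0.679     0.506        1         3
#>   010102 0.498     0.574        2         2
#>   010101 0.384     0.483        3         1

# hotspot / diffusion map for the same pair (source: main roads, 030101)
lf <- lisa_field(tubes[tubes$year == 2010, ], tubes[tubes$year == 2011, ],
                 source_code = "030101", cell_size_m = 500,
                 extent = sim$map$extent, n_perm = 999, seed = 1)
table(lf$class)
#>      diffusion        hotspot nonsignificant
#>             17              8            119
```

The simulation seeds its initial foci on main-road polygons, and the
network analysis recovers exactly that: the main-road code (030101)
ranks first by hub score, i.e. it sends the most diffusion mass to
strong receivers. Per-pair d* estimates are noisy at a few dozen
samples (the 2008–2009 pair has 37); the kernel-recovery validation in
the test suite uses `kernel_validation_config()`, a fine 100-m lattice
whose estimates concentrate around the generator's true 600-m kernel
scale. Cells classed `diffusion` are where next year's intensity
significantly exceeds what the cell's own current intensity predicts —
the invasion front.

`run_pipeline(run_config(simulation = cfg, out_dir = "out"))` executes
all stages and writes every artifact (tube and curve CSVs, land-use
GeoJSON, ESRI-ASCII surfaces, edge-list CSV + GEXF networks, LISA
CSV/GeoJSON, manifest with seeds and input hashes). A thin CLI wrapper
lives at `inst/scripts/antspread.R`.

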
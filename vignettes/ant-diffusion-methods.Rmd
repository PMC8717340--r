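---
title: "Methods: surveillance standardization, dispersal curves, transition networks and bivariate LISA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveillance standardization, dispersal curves, transition networks and bivariate LISA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery
it implements: the assumptions each stage makes, the tunable parameters
and why their defaults are what they are, the numerical conventions, and
what validation on the synthetic generator does and does not establish
about real surveillance data.

## Data model

The unit of observation is the **tube record**: a bait trap at planar
metric coordinates, surveyed in one year, positive (caught at least one
fire ant) or negative, and tagged with the lattice spacing of its
sampling stratum (100, 200 or 600 m). All distances in the package are
Euclidean meters; geographic (degree) input is refused rather than
silently reprojected, because a unit error at this stage corrupts every
downstream distance. Years, not dates, are the temporal unit: every
analysis operates on pairs of consecutive survey years.

Land use enters as a polygon map carrying three-level hierarchical type
codes; analyses use the finest (level-III) code. Tubes outside any
polygon are *unclassified* — a valid state, since land-use products
rarely cover a full study region — and are excluded from land-use-based
stages only.

## Density standardization

A tube on a dense lattice is more likely to intercept a colony than one
on a sparse lattice, so surveys at different densities cannot be pooled
raw. Each positive tube receives the weight of the lattice cell it
represents relative to a reference density:

$$w = (\text{spacing} / \text{reference})^2,$$

giving 0.25, 1 and 9 for 100-, 200- and 600-m grids at the 200-m
reference. The reference is configurable (`reference_m`) because other
programs use other baselines. Negative tubes always carry weight zero:
the standardization scales *positive counts*, and inflating absences
9-fold has no defensible interpretation. Incidence rates, by contrast,
are computed from raw counts — numerator and denominator come from the
same lattice, so density cancels.

## Ordinary kriging of standardized intensity

The intensity surface interpolates standardized weights with ordinary
kriging. Conventions:

* **Empirical variogram**: Matheron estimator,
  $\gamma(h) = \sum (z_i - z_j)^2 / (2N(h))$, on equal-width lag bins
  (default 12 bins up to half the maximum pairwise distance).
* **Model fit**: nugget, partial sill and range of a spherical
  (default), exponential or Gaussian model, by weighted least squares
  with weights $N(h)/h^2$ — pair support discounted by squared lag, so
  short lags, which control the kriging weights, dominate the fit.
  Starting values are heuristic (sill at the empirical maximum, range at
  half the maximum lag); bounds keep all parameters non-negative. A flat
  zero variogram returns a flagged pure-nugget model with a warning
  rather than an error.
* **System**: covariance form with a Lagrange multiplier, so prediction
  weights sum to one by construction (checked to 1e-10 in tests).
  Duplicate coordinates are deduplicated by averaging, otherwise the
  system is singular. With nugget zero the predictor interpolates the
  data exactly and has zero variance there; predicted variances are
  clamped at zero against roundoff.
* **Neighborhood**: global (exact) up to 2,000 data points, the 16
  nearest points above — exact small-sample behavior where tests look,
  tractability at scale.
* **Zeros**: negative tubes enter as value-0 points by default
  (`include_negatives = FALSE` restricts to positives). Interpolating
  only positives would bias the surface upward in surveyed-but-clean
  areas; the zeros record where surveillance looked and found nothing.

## Dispersal curves and the critical distance

"How far does the infestation move between years?" is answered from
**nearest-source distances**: one sample per year-$t{+}1$ positive tube,
its distance to the nearest year-$t$ positive. This operationalizes the
circle-coverage idea — a radius $d$ around year-$t$ positives covers
exactly those year-$t{+}1$ positives whose sample is $\le d$. An
all-pairs variant would conflate dispersal with the spatial extent of
the infestation. Samples are weighted by standardized weights by default
(`weighted = FALSE` for raw counts), consistent with using standardized
counts everywhere downstream.

The samples are binned into a cumulative proportion curve with 50-m bins
— commensurate with the resolution at which critical distances are
conventionally reported (multiples of 50 m), and wide enough that
single tubes rarely occupy a bin alone.

The **turning point** of that curve is found by chord residuals: with
$L$ the chord joining the first and last curve points and
$s_k = p_k - L(b_k)$,

* both-signed residuals (sigmoid shape): $d^\* = (b_{\arg\max s} +
  b_{\arg\min s})/2$ — for a symmetric sigmoid this is exactly the
  inflection;
* one-signed residuals (pure convex/concave shape): the knee
  $d^\* = b_{\arg\max |s|}$ — for a ramp-saturation curve this is
  exactly the kink;
* $\max |s| \le$ `tol` (1e-9): the curve is indistinguishable from its
  chord and the estimator refuses rather than fabricating a point.

The estimator operates on the *binned* curve, so results come at bin
resolution; a terminal step yields the last pre-step bin. Yearly $d^\*$
values are combined by arithmetic mean into the region-level critical
distance used as the network attribution radius.

## Transition networks

For each year pair, a directed weighted network on level-III land-use
codes. Each year-$t{+}1$ positive with at least one year-$t$ positive
within $d^\*$ contributes its standardized weight, **split equally
among its in-range sources**, to the corresponding (source-code →
target-code) edges. Equal splitting is the key design choice: nothing
in the data says which candidate source actually seeded a new positive,
and splitting conserves target mass — total edge weight equals the
summed weight of attributed targets (a test invariant at 1e-12). A raw
pair-count mode (`mode = "count"`) is kept for sensitivity analysis.
Self-loops are retained: within-type spread is a real transition.
Attribution uses *all* sources within $d^\*$, not only the nearest —
the radius is the definition of "plausible source"; restricting to the
nearest would re-import the nearest-source assumption into a stage that
doesn't need it.

**HITS** hub/authority scores are computed by weighted power iteration
with Euclidean normalization each step (Kleinberg's formulation),
tolerance 1e-12, capped at 1,000 iterations (exceeding the cap is an
error, not a silent return). Hubs rank land uses by how strongly they
send diffusion mass to strong receivers — the "diffusion source" axis.
Ranks break ties by code order so they are a deterministic permutation.
Hub *values* depend on the normalization convention, so cross-tool
comparisons should be made at the rank level.

**Communities** come from Louvain modularity optimization (via igraph)
on the symmetrized graph — undirected weight is the sum of both
directed weights, self-loops kept — because modularity is defined for
undirected graphs. `network_modularity()` evaluates the partition
quality by the direct Newman–Girvan formula on the same symmetrized
matrix, and is cross-checked in tests against both an independently
coded oracle and igraph on loop-free graphs.

## Bivariate LISA

On a cell lattice (default 500 m, the block scale at which hotspot maps
are read), let $x_i$ be the summed standardized weight of year-$t$
positives of the *source* land use (by default the top-hub code) in
cell $i$, and $y_i$ the summed weight of all year-$t{+}1$ positives.
The statistic is

$$I_i = z_{x,i} \sum_j w_{ij}\, z_{y,j},$$

with population z-scores over non-isolated cells and row-standardized
queen-contiguity weights. The standard deviations *divide* (z-scoring):
a multiplicative reading would make the statistic scale-dependent,
contradicting the bivariate-LISA methodology the statistic comes from.
Constant $x$ or $y$ makes the statistic identically zero; the package
returns exactly that with a warning naming the degenerate variable
(`on_degenerate = "error"` restores a strict contract).

Significance uses **conditional permutation**: for each cell, its own
$z_x$ stays fixed while its neighbors' $z_y$ values are drawn without
replacement from all other cells; the two-sided pseudo p-value is
$(1 + \#\{|I^{perm}| \ge |I^{obs}|\})/(n_{perm}+1)$ with 999
permutations by default. Two-sided, because both signs are interpreted:
significant positive cells are **hot spots** (persistently intense
neighborhoods), significant negative cells are **diffusion areas**
(the neighborhood lights up next year relative to the cell's own
source intensity). No multiple-testing correction is applied by
default, mirroring standard LISA practice of reading the map as an
exploratory surface; the p-values are returned so any correction can be
applied downstream. Type-I calibration at $\alpha = 0.05$ on
independent noise is a test invariant (rejection rate in [0.03, 0.08]
on a 20×20 grid).

## The synthetic generator: what it emulates, and what not

The generator exists so every estimator above can be validated against
known truth. It emulates, with all randomness driven by one seed:

* a gap-free categorical landscape with main-road corridors, paddy and
  filler patches, and road-adjacent warehouse blocks. The mosaic is
  *rectilinear* (jittered grid cuts; roads and warehouses overwrite
  patches by exact rectangle subtraction) rather than a Voronoi
  tessellation: axis-aligned geometry makes the coverage and
  no-overlap invariants exact and the point-in-polygon tie-break rule
  trivially deterministic, at no cost to what downstream stages see.
  Patch types are allocated by largest-remaining-deficit so realized
  area shares track the configured proportions to within a cell.
* multi-density tube lattices (one tube per cell center; per-year zones
  of 100/200/600-m spacing);
* a yearly spreading process: active foci each produce
  Poisson($\lambda$) propagules; displacement is drawn from a
  two-component uniform mixture — $U(0, d_0)$ with probability
  $p_{near}$, else $U(d_0, d_{max})$ — at uniform angle, so
  $P(D \le d_0) = p_{near}$ *exactly*, a closed-form target for curve
  and turning-point recovery; establishment succeeds with the landing
  cell's land-use suitability; foci persist once established.
* deterministic detection: a tube is positive iff an active focus lies
  within `detection_radius_m`. Detection noise would test the
  observation model, not the estimators.

Defaults (6×6 km extent, 4 years, 200-m baseline schedule with 100- and
600-m strata in the middle years, 3 road corridors of 200-m width, 10
initial foci on main roads, $d_0 = 600$ m, $p_{near} = 0.75$,
$d_{max} = 3$ km, $\lambda = 3.5$, uniform suitability 0.7, 100-m
detection radius) are chosen once to emulate a multi-year campaign over
a compact mixed-use region with an actively growing infestation whose
source sits on the road network. Road corridors are deliberately wider
than the baseline trap spacing: a corridor narrower than the lattice
pitch contains almost no tubes, and a land-use type with no tubes is
invisible to every tube-based analysis.

**Observation grain and the critical distance.** A positive tube
localizes a focus only to trap-spacing-plus-detection-radius
precision, and nearest-source distances between *tubes* are shifted
systematically below nearest-source distances between *foci* (each end
of the measurement can sit up to a detection radius closer). The
kernel-recovery validation therefore runs on
`kernel_validation_config()`: a 9×9 km region with a uniform 100-m
lattice and a 70-m detection radius, keeping the total blur well under
the 600-m kernel scale while yielding several hundred consecutive-year
samples. This mirrors field practice, where the densest strata are
deployed precisely in the invaded areas that dominate the distance
samples. On the default 200-m-baseline configuration the same
estimator lands systematically a few bins low — a resolution effect
worth remembering when interpreting critical distances from sparse
lattices.

What the generator does **not** emulate: colony social forms, mound
budding versus nuptial flights, control interventions, flood- or
typhoon-assisted dispersal, detection error, and real geography.
Passing recovery tests therefore shows the estimators are correct
*given the observation model*, not that real surveillance data meet
that model's assumptions.

## Validation experiments and problem sizes

The test suite's heavier experiments, with sizes chosen to finish in
seconds to a couple of minutes on one CPU:

* kernel recovery: 10 seeded `kernel_validation_config()` surveys
  (≈ 8,100 tubes/year, ≥ 200 pooled distance samples each); every
  estimated $d^\*$ must fall in [450, 750] m and the 10-seed mean in
  [500, 700] m around the true 600 m.
* source recovery: 10 seeded default surveys; a run succeeds when the
  main-road code ranks in the top two hubs in at least 2 of its 3 year
  transitions (the majority rule is the package's own success
  definition), and at least 8 of 10 runs must succeed.
* permutation calibration: one 20×20 independent-noise grid, 999
  permutations per cell.
* oracle agreement: 100 random monotone curves (EDE), 20 random
  digraphs (HITS vs. eigen decomposition of $WW^\top$), random networks
  (modularity formula), brute-force pair loops (variogram, nearest
  distances), a hand-assembled 4×4 kriging system.

## Known limitations

* The EDE reports at bin resolution and is endpoint-sensitive: heavy
  right tails flatten the chord and can drag the knee rightward at
  small sample sizes.
* Mass splitting attributes diffusion equally among candidate sources; if true seeding is distance-dependent, hub values
  (though typically not top ranks) shift.
* The local-neighborhood kriging path (> 2,000 points) can produce
  small seams between neighborhoods, as any moving-neighborhood kriging
  does.
* Conditional permutation treats cells exchangeably under the null;
  strong global trend in $y$ inflates local significance, as with all
  LISA-type inference.
* The rejection of geographic coordinates is heuristic (all
  coordinates within lon/lat bounds *and* sub-degree span); planar data
  legitimately hugging the origin at < 10 m extent would be refused.
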
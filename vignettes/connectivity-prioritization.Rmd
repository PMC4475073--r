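---
title: "Two-scale habitat connectivity and conservation prioritization with hexconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scale habitat connectivity and conservation prioritization with hexconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexconn)
```

## The problem

Mobile organisms such as pollinating bees deliver ecosystem services by
moving through fragmented landscapes. How much service a region can sustain
depends jointly on *where* the habitat is (patch sizes and spatial
configuration), *how good* it is (climatic suitability for the species,
which shifts under climate change), and *how far* the organism disperses.
`hexconn` quantifies this with graph-theoretic habitat-availability
indices, compares them across climate periods, and turns the temporal
trends into a six-class conservation/restoration priority map.

## Habitat-availability indices

A landscape is a graph: habitat patches are nodes, and node $i$ carries an
attribute $a_i$. To fold habitat quality into the analysis, $a_i$ is the
*suitability-weighted area*: the sum of the habitat-suitability values (in
$[0,1]$, e.g. the output of a species distribution model) of all pixels in
the patch, after the suitability raster has been resampled to the habitat
grid. A large patch in a climatically favorable region scores high; a small
patch in a marginal region scores low.

The Probability of Connectivity (Saura & Pascual-Hortal 2007) is

$$PC = \frac{\sum_{i=1}^{n}\sum_{j=1}^{n} a_i\, a_j\, p^{*}_{ij}}{A_L^2},$$

where $p^{*}_{ij}$ is the maximum, over all paths between $i$ and $j$, of
the product of link probabilities, $p^{*}_{ii} = 1$ (the self-pairs are
part of the double sum — this is what makes the single-patch limit
$PC = a^2/A_L^2$ come out right), and $A_L$ is the landscape area in
attribute units. Link probabilities come from a negative exponential
dispersal kernel $p(d) = e^{-kd}$ calibrated through an anchor pair
$(p_0, d_0)$, i.e. $k = -\ln(p_0)/d_0$. The package default is
$p_0 = 0.10$ at $d_0 = 2\,\mathrm{km}$, a parameterization appropriate for
a stingless bee's flight range; `predict(dispersal_kernel(), 2000)`
returns exactly 0.10. $p^*$ is computed with Dijkstra's algorithm on
$-\log p$ edge weights (zero-probability links are dropped first; values in
$(1, 1+10^{-9}]$ are clipped to 1, anything larger is an error).

The Integral Index of Connectivity (Pascual-Hortal & Saura 2006) is the
binary counterpart:

$$IIC = \frac{\sum_{i=1}^{n}\sum_{j=1}^{n} a_i\, a_j / (1 + nl_{ij})}{A_L^2},$$

with $nl_{ij}$ the number of links on the topological shortest path
($nl_{ii}=0$; disconnected pairs contribute nothing).

The importance of a node is measured by removal: $\Delta I_k = 100\,(I -
I_{-k})/I$, with $A_L$ held fixed across removals — habitat loss is
simulated in the index, not in the extent of the study area. Because $A_L$
cancels in the ratio, $\Delta I_k$ does not depend on the normalization.

Both indices are checked in the test suite against brute-force oracles
(exhaustive simple-path enumeration for $p^*$, breadth-first pair
enumeration for $nl$) on hundreds of random graphs of up to 8 nodes.

## The two-scale procedure

**Local scale.** The study area is tessellated into equal-area regular
hexagons ("focal landscapes"), 5,000 ha each by default. The edge length
follows from the area, $s = \sqrt{2A/(3\sqrt3)} \approx 4{,}387$ m for
5,000 ha (this is often quoted rounded down as 4.3 km; the package uses the
exact closed form). Patches are clipped by cell edges and each fragment
becomes a node of that cell's local graph; fragment distances are
edge-to-edge (minimum boundary-pixel distance, measured center-to-center of
the nearest pixels), the convention used by Conefor-style tools. The
quantity stored per cell is the **PC numerator**, not PC itself: under
suitability weighting the maximum attainable attribute sum differs between
equal-area cells, and the unnormalized sum is what ranks cells jointly by
connectivity and suitability.

**Regional scale.** The cells themselves become nodes of a study-area
graph, with the local PC numerators as attributes. Only edge-sharing
hexagons are linked: with ~4.4 km edges, non-adjacent cells lie beyond the
dispersal capability of a 2-km-scale disperser, so a binary adjacency graph
is the appropriate model and IIC the appropriate index. Each cell's
regional importance is its removal importance $\Delta IIC$, computed per
climate period (e.g. current, 2030, 2050, 2080).

Two regional conventions are worth making explicit, because the index
definition does not fix them:

* **$A_L$.** The regional landscape area is set to (number of cells)
  $\times$ (pixels per cell), the ceiling of the total attribute, which
  makes $IIC \le 1$ and dimensionless. Since only $\Delta IIC$ (a ratio) is
  used downstream, the analysis is invariant to this choice — a property
  asserted in the tests rather than assumed.
* **Boundary cells.** Cells clipped by the study-area edge participate
  fully but are flagged (`interior = FALSE`) so users can exclude them. A
  cell merely tangent to the boundary is also flagged, which guarantees
  that every interior cell has exactly six neighbors.

## Temporal change and the strategy classes

For each transition between periods (consecutive pairs plus the overall
first-to-last trend), the change $\Delta\Delta IIC$ is the later minus the
earlier importance, in percentage points. Cells are then classified on two
axes: habitat availability (the *earlier* period's local PC numerator)
split at its median $M_a$, and $\Delta\Delta IIC$ split at zero and at
$M_d$, the median of the *strictly positive* changes — so restoration
effort targets only cells whose conditions genuinely improve:

| availability | change $\le 0$ | $0 <$ change $< M_d$ | change $\ge M_d$ |
|---|---|---|---|
| $\ge M_a$ | II short-term conservation | III low-priority restoration / long-term conservation | IV long-term conservation |
| $< M_a$  | I no action | V intermediate restoration | VI high-priority restoration |

Open edges of the rule needed a decision: median ties resolve upward
(deterministic, and it favors action over inaction), zero change groups
with decreases, and medians are computed per transition, not pooled. If no
cell has a positive change the restoration split is undefined; the
classifier warns and would route any increasing cell to class V.

## The synthetic landscape generator

Real inputs (a remnant-vegetation map and one SDM suitability raster per
period) are simply rasters, so the package ships a generator that emulates
them with known structure:

* **Habitat**: a Gaussian white-noise field smoothed by FFT convolution
  (the `aggregation` parameter in $[0,1]$ maps linearly to a smoothing
  length of 0–12 pixels) and thresholded at the quantile matching the
  requested `habitat_fraction`. Quantile thresholding keeps the realized
  fraction within a fraction of a percentage point of the request on
  256×256 grids; higher aggregation gives fewer, larger patches.
* **Suitability**: an anisotropic Gaussian bump (σ of 30% of the extent
  width and 20% of its height) plus a 10%-amplitude smooth noise field
  shared across periods, clamped to $[0,1]$. The bump center translates by
  `drift` meters per period, so zero drift yields bit-identical surfaces
  and a southward drift reproduces, at desk scale, the qualitative
  poleward/inland range shift that climate projections commonly show.

Everything is seeded: the same scenario always yields bit-identical
rasters. The packaged `demo_scenario()` is a 21 × 30 km landscape at 50 m
resolution, 30% habitat at aggregation 0.5, four periods with the
suitability peak drifting 8 km south per period. These sizes were chosen so
that a full four-period run (≈500,000 pixels, 18 focal landscapes)
completes in seconds while still containing ~100 patches and a 3-row
north–south gradient of cells.

What the generator does **not** emulate: the spatial autocorrelation
structure of real SDM output, topography-driven anisotropy in fragment
shapes, land-use change over time (habitat is held fixed across periods),
and realistic coastline geometry. Passing tests on synthetic landscapes
therefore demonstrate the correctness of the computations and the
qualitative behavior of the workflow, not biological conclusions about any
real landscape.

## Numerical and I/O choices

* Patch labeling uses 8-connectivity by default (diagonal forest pixels at
  50 m are functionally contiguous); 4-connectivity is available.
* Suitability resampling is nearest-neighbor by default, preserving the
  original SDM values so attribute sums are not smoothed; bilinear is
  offered and, being convex, also respects $[0,1]$.
* Inter-patch distances beyond the radius where the kernel drops below
  $10^{-4}$ (≈8 km at the default anchor) are not enumerated; their
  contribution to PC is negligible.
* Rasters are read/written as ESRI ASCII grids (plain text,
  self-georeferencing) or single-band TIFF with a JSON sidecar carrying
  origin, resolution and CRS; vector output is plain GeoJSON. Patch,
  distance, importance, change and strategy tables are CSV.
* The full pipeline writes a JSON manifest (configuration, package
  version, MD5 checksums of every output) and is byte-reproducible from
  the same configuration.

## Limitations

Distances are Euclidean edge-to-edge; there is no resistance-surface or
least-cost-path support, no flux/connector decomposition of the removal
importance, no non-adjacent regional links, and no budget-constrained
selection of how many cells to act on — the class thresholds are medians
and can be shifted by the user to match an available budget. Whether
edge-to-edge or centroid-to-centroid distances better represent a given
disperser is a genuinely open question; edge-to-edge is the package's
default because it matches common practice in connectivity software.
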
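---
title: "Bands, mosaics and transversal continuity depth: the coastband method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bands, mosaics and transversal continuity depth: the coastband method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastband)
```

## The band model

Coastal landscapes are usually analyzed longitudinally, along the shore, by
cutting fixed-width buffer strips. `coastband` takes the transversal view:
every land-cover patch is characterized by its *adjacency order* from the
coastline. A patch touching the coastline is in **band 1**; a patch touching
a band-1 patch (and no earlier band) is in **band 2**; and so on. Bands
follow the organic patch structure of the territory instead of imposing
metric strips, so one band may be tens of meters deep where patches are
small and kilometers deep where a single forest polygon runs far inland.

Formally, the map's patches plus one virtual `COAST` node form a contiguity
graph, and the band level is the breadth-first hop distance from `COAST`,
capped at `B` bands (default 10). Patches beyond the cap keep band 0
(unassigned) and stay in the partition so a rerun with a larger `B` can
reach them. The iterative select-and-erase formulation — select everything
adjacent to the previous band, assign, repeat — defines the same partition;
the test suite keeps it (plus an independent graph-distance computation) as
an oracle against the production breadth-first sweep.

## Contiguity: rook by default

Two patches are *rook*-contiguous when their boundaries share a stretch of
positive length, and *queen*-contiguous when they touch at all, corner
points included. GIS "select by location" tools default to the queen-like
intersect predicate, but a corner contact is no ecological corridor, so
`build_adjacency()` defaults to rook with `min_shared_boundary = 0` (any
positive shared length). Both knobs are exposed: `mode = "queen"` replicates
intersect-style selections, and a positive `min_shared_boundary` (e.g. 25 m)
suppresses sliver contacts common in real CORINE exports. Queen edge sets
always contain rook edge sets; the suite checks this as a property.

## Natural surfaces and mosaic extraction

Stage 2 keeps only *natural* patches: CORINE Level-3 classes
523, 522, 521, 422, 421, 411, 333, 331, 324, 323, 321, 313, 312, 311.
Artificial (1xx) and agricultural (2xx) classes are excluded. In
Mediterranean contexts olive groves (223) and agro-forestry (244) function
ecologically as natural cover; `nature_scheme(mediterranean_extras = TRUE)`
promotes exactly those two.

A natural patch belongs to a **transversally connected natural landscape
mosaic (TCNLM)** when it is linked to the coastline by a chain of
band-adjacent natural patches: band-1 naturals seed the set, and a band-k
natural joins when it touches a member of band k−1. Two readings of the
original workflow differ on whether a same-band (lateral) contact may also
propagate membership; the stage sequences only ever test band k against
band k−1, so lateral propagation is **off** by default and available as
`lateral_merge = TRUE` for the broader reading. Members are grouped into
mosaics — connected components of the member-induced subgraph (computed with
igraph) — labeled in ascending order of each component's smallest patch id,
which makes labels reproducible across runs and platforms.

## Transversal continuity depth

The **TCD** of a member is the deepest band it provides transversal
connectivity for: the maximum band reachable from it through a strictly
band-ascending chain of members. The production algorithm is the descending
reclassification: all unlabeled members of band B get TCD = B and the label
propagates coastward one band per step; the sweep repeats for B−1, …, 1.
The two formulations are provably identical — the descending sweep labels a
patch with t exactly when an ascending chain from it reaches band t and none
reaches deeper — and the suite verifies the equivalence against an
exhaustive memoized chain search on random maps. Useful consequences, all
tested as invariants: band(p) ≤ TCD(p) ≤ B; each mosaic's maximum TCD
equals its maximum band; patches outside the mosaic never influence a
member's TCD.

## Interpretation: hinges and barriers

Stage 4A cross-tabulates band level against TCD (the lower triangle is
structurally empty). Members combining a low band (default ≤ 4) with a high
TCD (default ≥ 7) are *crucial*: close to the sea yet carrying deep inland
continuity. Among them, `find_endangered()` flags the **singular hinges** —
patches whose artificialization would strand deeper mosaic patches. The
criterion is operational, not heuristic: membership is recomputed with the
candidate treated as artificial, and the members that drop out form its
dependent set; an empty dependent set means redundant links exist and the
candidate is not flagged. "Only patch of its band within its mosaic" is
reported as an auxiliary flag rather than used as the criterion, since band
uniqueness neither implies nor follows from being a cut patch. Both
thresholds are parameters: hinges can also sit in middle bands, so the
screen is a lens, not a definition.

Stage 4B inverts the filter: coast-adjacent *artificial* patches seed the
same propagation, ascending through natural patches. A seed fronting at
least one natural band-2 patch reached this way is a **barrier** — restoring
it would reconnect that mosaic to the coastline — and `unlocked_depth`
records the deepest band behind it. With `exclude_already_connected = TRUE`
band-2 patches that already reach the coast through a natural band-1 link
are ignored, isolating seeds that are the sole separation.

## The synthetic generator

Real CORINE coastal strips cannot ship with the package, so
`generate_landscape()` builds deterministic surrogates: a rows × cols grid
of square patches (default edge 100 m, a realistic lower bound for CORINE
minimum mapping units) whose seaward edge is the coastline. Under rook
contiguity each patch's band equals its row index — a closed-form ground
truth the tests exploit. Class codes are drawn independently per cell; the
default mixture is 60 % natural, 25 % agricultural, 15 % artificial, spread
over common coastal classes (311–313, 321/323, 331; 211/222; 112/121).
Motifs stamp structures after the draw: `corridor()` a transversal natural
column, `hinge()` a column whose lateral neighbors at one row are forced
artificial (making that patch the singular link), `barrier()` an artificial
waterfront cell fronting a natural column. The generator reproduces class
proportions and planted topology but none of the statistical texture of
real land cover — patch-size distributions, spatial autocorrelation,
irregular boundaries — so green tests demonstrate algorithmic correctness
on clean topology, not robustness to degraded real-world geometry (that is
what the repair and `min_shared_boundary` machinery addresses).

`worked_example_chain(from, to)` is the minimal fixture for the method's
printed examples: a single natural column spanning bands 1..`to`, on which
every member's TCD equals `to`.

## Numerical and I/O choices

* **Geometry kernel.** Adjacency needs only boundary predicates, so the
  package carries a small planar kernel: collinear segment-overlap for
  shared-border length, segment distance for queen contact, crossing-point
  insertion plus loop decomposition for repairing self-intersecting rings
  (a bow-tie becomes its two lobes; features with no positive-area simple
  lobe are rejected and reported). The coincidence tolerance is 1e-7 m —
  far below any meaningful shared border, above double-precision noise at
  projected-coordinate magnitudes. No custom snapping is applied.
* **Formats.** Vector I/O is GeoJSON (read and write), with CSV for the
  cross-tab and JSON for the run summary. Output attribute names are fixed:
  `band`, `tcnlm`, `mosaic_id`, `tcd`, `endangered`, `barrier`.
* **CRS.** A projected CRS is required — shared-boundary thresholds are
  metric. A GeoJSON layer without a legacy `crs` member is WGS84 by
  specification and is refused unless `allow_geographic = TRUE`.
* **Sea patches.** The coastline is the dissolved sea/land shared boundary;
  the sea-class patches themselves (e.g. 523, which also appears in the
  natural list) are excluded from banding by default, since banding offshore
  water as band 1 would let mosaics run through the sea. `keep_sea_patches`
  restores the literal reading.
* **Determinism.** The generator seeds R's RNG locally and restores the
  caller's stream; pipeline outputs carry no timestamps, so identical seeds
  and configurations give byte-identical files.

## Problem sizes in the test suite

Property suites run on randomized grids of 9–100 patches: 200 maps for the
oracle-equivalence checks (bands ≡ graph distance, membership ≡ exhaustive
descending-chain search, TCD ≡ exhaustive ascending-chain maximum), 15 for
the structural invariants with full removal re-validation, and a
10,000-patch draw for the class-mixture calibration. These sizes keep each
oracle exhaustive while the whole suite runs in well under a minute.

## Limitations

* Connectivity is purely topological: no area weighting, no dispersal
  distances, no probability-of-connectivity indices.
* Band depth is in adjacency steps, not meters; the two coincide only on
  regular tessellations.
* The repair handles self-crossing rings; overlapping *between* patches is
  assumed away (CORINE topology) and only guarded by the non-overlap
  invariant on generated data.
* Shapefile and GeoPackage containers are not read; convert to GeoJSON
  first (e.g. `ogr2ogr -f GeoJSON`).
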
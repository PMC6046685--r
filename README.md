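# coastband

Transversal continuity analysis of natural landscapes in the coastal zone.

Coastal land cover is usually analyzed *along* the shore with fixed-width
buffer strips. `coastband` works *across* it: every land-cover patch is
classified by its **band level** — its adjacency order from the coastline
(band 1 touches the coast; band k touches band k−1), an organic alternative
to metric buffers that follows the actual patch structure. On top of the
bands the package

* extracts **TCNLM** (transversally connected natural landscape mosaics):
  natural patches linked to the coastline by a chain of band-adjacent
  natural patches;
* assigns each mosaic patch its **TCD** (transversal continuity depth), the
  deepest band it provides connectivity for — formally
  `TCD(p) = max { band(q) : q reachable from p by a strictly band-ascending
  chain of mosaic members }`, computed by a descending band-by-band
  reclassification;
* flags **endangered hinge patches** (low band, high TCD, whose
  artificialization would strand deeper mosaic patches — verified by
  recomputing membership without the candidate) and **barrier patches**
  (artificial waterfront patches separating the coastline from a mosaic
  that starts at band 2, i.e. restoration candidates).

It targets landscape ecologists and coastal-zone planners (ICZM /
sustainable coastal tourism assessments) who want the analysis scriptable
and reproducible outside proprietary GIS. Input is a CORINE-style polygon
layer (GeoJSON, projected CRS, 3-digit Level-3 class codes); natural
surfaces default to classes 523, 522, 521, 422, 421, 411, 333, 331, 324,
323, 321, 313, 312, 311, with an option to add olive groves (223) and
agro-forestry (244) in Mediterranean contexts.

## Worked example

```r
library(coastband)

# an 8x6 synthetic coastal grid: a natural corridor down column 3 reaching
# band 8, and an artificial waterfront patch blocking a natural column 5
g <- generate_landscape(synth_spec(rows = 8, cols = 6, seed = 5,
                                   motifs = list(corridor(3, 8),
                                                 barrier(5, 4))))
res <- run_pipeline(g$map, coast = g$coast, out_dir = "out")

res$crosstab
#> <crosstab> band x TCD member counts (total 10)
#>         tcd
#> band     tcd1 tcd2 tcd3 tcd4 tcd5 tcd6 tcd7 tcd8 tcd9 tcd10
#>   band1     2    0    0    0    0    0    0    1    0     0
#>   band2     0    0    0    0    0    0    0    1    0     0
#>   ...
res$endangered[, c("id", "band", "tcd", "mosaic_id", "n_dependents")]
#>      id band tcd mosaic_id n_dependents
#> 1 r1_c3    1   8         2            7
#> 2 r2_c3    2   8         2            6
#> 3 r3_c3    3   8         2            5
#> 4 r4_c3    4   8         2            4
res$barriers[, c("id", "clc_code", "unlocked_depth", "n_unlocked")]
#>      id clc_code unlocked_depth n_unlocked
#> 1 r1_c5      112              4          3
```

Reading the output: the corridor produces one mosaic whose members all
carry TCD 8 (each column-3 patch up to band 8 provides continuity to
band 8); its band 1–4 patches are flagged endangered because removing any
one of them strands everything deeper (`n_dependents`). Two isolated
natural band-1 patches elsewhere carry TCD 1. The artificial patch
`r1_c5` is a barrier: restoring it would reconnect 3 natural patches down
to band 4 (`unlocked_depth`).

`out/` receives the banded, TCNLM, TCD, endangered and barrier GeoJSON
layers (attributes `band`, `tcnlm`, `mosaic_id`, `tcd`, `endangered`,
`barrier`), `crosstab.csv` and a JSON run summary.

For real data: `read_lulc("clc.geojson", code_field = "CODE_18")`, then
either pass a coastline layer or let `derive_coastline()` dissolve the
sea/land shared boundary from the sea class (523). A command-line wrapper
with the same parameters lives in `inst/cli/coastband.R`
(subcommands `synth`, `derive-coastline`, `bands`, `tcnlm`, `tcd`,
`interpret`, `run`).

See `vignettes/coastband-methods.Rmd` for the method, its assumptions and
the design choices.

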
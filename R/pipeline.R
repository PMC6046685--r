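#' Pipeline configuration
#'
#' One flat set of parameters covering every stage, with the defaults each
#' stage documents.  Validated before any stage runs.
#'
#' @param code_field land-cover code attribute name (default `"CODE_18"`).
#' @param sea_codes sea class codes used to derive the coastline (default
#'   `"523"`); ignored when a coastline layer is supplied.
#' @param B number of bands (default 10).
#' @param mode contiguity rule, `"rook"` or `"queen"`.
#' @param min_shared_boundary meters, see [build_adjacency()].
#' @param mediterranean_extras count olive groves (223) and agro-forestry
#'   (244) as natural.
#' @param lateral_merge same-band membership propagation, see
#'   [extract_tcnlm()].
#' @param band_max,tcd_min endangered-patch screen, see [find_endangered()].
#' @param exclude_already_connected see [find_barriers()].
#' @param keep_sea_patches keep sea patches available for banding.
#' @param allow_geographic accept a geographic CRS on input.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(code_field = "CODE_18", sea_codes = "523",
                            B = 10L, mode = "rook",
                            min_shared_boundary = 0,
                            mediterranean_extras = FALSE,
                            lateral_merge = FALSE,
                            band_max = 4L, tcd_min = 7L,
                            exclude_already_connected = FALSE,
                            keep_sea_patches = FALSE,
                            allow_geographic = FALSE) {
  stopifnot(B >= 1, min_shared_boundary >= 0, band_max >= 1, tcd_min >= 1,
            mode %in% c("rook", "queen"))
  structure(list(code_field = code_field, sea_codes = as.character(sea_codes),
                 B = as.integer(B), mode = mode,
                 min_shared_boundary = min_shared_boundary,
                 mediterranean_extras = isTRUE(mediterranean_extras),
                 lateral_merge = isTRUE(lateral_merge),
                 band_max = as.integer(band_max),
                 tcd_min = as.integer(tcd_min),
                 exclude_already_connected = isTRUE(exclude_already_connected),
                 keep_sea_patches = isTRUE(keep_sea_patches),
                 allow_geographic = isTRUE(allow_geographic)),
            class = "pipeline_config")
}

#' Run the full coastal-banding pipeline (Stages 0-4)
#'
#' Executes coastline derivation, band assignment, TCNLM extraction, TCD
#' assignment, the band x TCD cross-tabulation with endangered-patch
#' screening, and the barrier analysis, each stage consuming the previous
#' stage's output.  When `out_dir` is given, writes `banded.geojson`,
#' `tcnlm.geojson`, `tcd.geojson`, `endangered.geojson`,
#' `barriers.geojson` (all patches, carrying the attributes `band`, `tcnlm`,
#' `mosaic_id`, `tcd`, `endangered`, `barrier`), `coastline.geojson`,
#' `crosstab.csv`, and `summary.json`.
#'
#' @param input a [landcover] object, or a path readable by [read_lulc()].
#' @param out_dir output directory (created), or `NULL` for no files.
#' @param config a [pipeline_config()].
#' @param coast a [coastline] object or GeoJSON path; when `NULL` the
#'   coastline is derived from `config$sea_codes`.
#' @return Invisibly, a result bundle: `map`, `coast`, `graph`, `bands`,
#'   `mosaics`, `tcd`, `crosstab`, `endangered`, `barriers`, `table`
#'   (the per-patch attribute data frame), `summary`.
#' @export
run_pipeline <- function(input, out_dir = NULL, config = pipeline_config(),
                         coast = NULL) {
  map <- if (inherits(input, "landcover")) input
         else read_lulc(input, config$code_field,
                        allow_geographic = config$allow_geographic)
  # Stage 0
  if (is.null(coast)) {
    coast <- derive_coastline(map, sea_codes = config$sea_codes,
                              keep_sea_patches = config$keep_sea_patches)
  } else if (is.character(coast)) {
    coast <- read_coastline(coast, allow_geographic = config$allow_geographic)
  }
  # Stage 1
  graph <- build_adjacency(map, coast, mode = config$mode,
                           min_shared_boundary = config$min_shared_boundary)
  bands <- assign_bands(graph, B = config$B)
  # Stage 2
  scheme <- nature_scheme(mediterranean_extras = config$mediterranean_extras)
  mosaics <- extract_tcnlm(bands, graph, map, scheme,
                           lateral_merge = config$lateral_merge)
  # Stage 3
  tcd <- assign_tcd(mosaics, bands, graph)
  # Stage 4
  ct <- cross_tabulate(bands, tcd, map)
  endangered <- find_endangered(mosaics, bands, graph, tcd,
                                band_max = config$band_max,
                                tcd_min = config$tcd_min)
  barriers <- find_barriers(map, bands, graph, scheme,
                            exclude_already_connected =
                              config$exclude_already_connected)
  ids <- graph$ids
  table <- data.frame(
    id = ids,
    band = as.integer(bands[ids]),
    tcnlm = as.integer(mosaics$member[ids]),
    mosaic_id = mosaics$mosaic_id[ids],
    tcd = tcd[ids],
    endangered = as.integer(ids %in% endangered$id),
    barrier = as.integer(ids %in% barriers$id),
    stringsAsFactors = FALSE)
  band_counts <- as.list(table(factor(bands[ids], levels = 0:config$B)))
  names(band_counts) <- paste0("band", names(band_counts))
  summary <- list(
    n_patches = length(map$ids),
    n_banded = sum(bands[ids] > 0L),
    band_counts = band_counts,
    coastline_length_m = coast$length,
    n_members = sum(mosaics$member[ids]),
    n_mosaics = length(unique(stats::na.omit(mosaics$mosaic_id[ids]))),
    max_tcd = if (any(!is.na(tcd[ids]))) max(tcd[ids], na.rm = TRUE) else 0L,
    n_endangered = nrow(endangered),
    n_barriers = nrow(barriers),
    parameters = unclass(config),
    version = as.character(utils::packageVersion("coastband")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_outputs(map, table, file.path(out_dir, "banded.geojson"))
    members <- table[table$tcnlm == 1L, , drop = FALSE]
    write_outputs(.subset_map(map, members$id), members,
                  file.path(out_dir, "tcnlm.geojson"))
    write_outputs(.subset_map(map, members$id), members,
                  file.path(out_dir, "tcd.geojson"))
    write_outputs(.subset_map(map, endangered$id),
                  table[table$endangered == 1L, , drop = FALSE],
                  file.path(out_dir, "endangered.geojson"))
    write_outputs(.subset_map(map, barriers$id),
                  table[table$barrier == 1L, , drop = FALSE],
                  file.path(out_dir, "barriers.geojson"))
    write_coastline(coast, file.path(out_dir, "coastline.geojson"))
    write_crosstab(ct, file.path(out_dir, "crosstab.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(map = map, coast = coast, graph = graph, bands = bands,
                 mosaics = mosaics, tcd = tcd, crosstab = ct,
                 endangered = endangered, barriers = barriers,
                 table = table, summary = summary))
}

# Subset a landcover to the given ids (empty subsets allowed for writing
# empty report layers).
.subset_map <- function(map, ids) {
  ix <- match(ids, map$ids)
  out <- map
  out$ids <- map$ids[ix]
  out$codes <- map$codes[ix]
  out$geoms <- map$geoms[ix]
  out$areas <- map$areas[ix]
  out
}
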
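#' Motifs for synthetic coastal landscapes
#'
#' Structures planted deterministically on the synthetic grid after the
#' random class draw:
#' * `corridor(col, depth)` — natural patches down column `col` from the
#'   coast to row `depth` (a transversal natural corridor);
#' * `hinge(col, band)` — a natural corridor down column `col` to the full
#'   grid depth whose lateral neighbors at row `band` are forced artificial,
#'   making the row-`band` patch the singular coastward link of everything
#'   deeper in that column;
#' * `barrier(col, depth)` — an artificial patch at row 1 of column `col`
#'   fronting a natural corridor in rows 2..`depth`.
#'
#' @param col grid column (1-based, alongshore position).
#' @param depth,band grid row (1-based, 1 = seaward).
#' @return A `synth_motif` list.
#' @name motifs
NULL

#' @rdname motifs
#' @export
corridor <- function(col, depth) {
  structure(list(kind = "corridor", col = col, depth = depth),
            class = "synth_motif")
}

#' @rdname motifs
#' @export
hinge <- function(col, band) {
  structure(list(kind = "hinge", col = col, band = band),
            class = "synth_motif")
}

#' @rdname motifs
#' @export
barrier <- function(col, depth) {
  structure(list(kind = "barrier", col = col, depth = depth),
            class = "synth_motif")
}

# Default class mixture of the generator: 60% natural, 25% agricultural,
# 15% artificial, spread over common CORINE Level-3 classes of a coastal
# strip (forests 311-313, scrub 323/321, beaches 331, arable/permanent
# crops, urban fabric and industrial units).
default_class_weights <- function() {
  c("311" = 0.15, "312" = 0.15, "313" = 0.10, "323" = 0.10, "321" = 0.05,
    "331" = 0.05, "211" = 0.15, "222" = 0.10, "112" = 0.10, "121" = 0.05)
}

#' Specification of a synthetic coastal landscape
#'
#' Describes a `rows` x `cols` grid of square patches: row 1 lines the
#' coast, higher rows lie further inland, so with rook adjacency the band
#' level of every patch is simply its row index (the closed-form ground
#' truth used in tests).  Class codes are drawn independently per cell from
#' `class_weights` by a seeded RNG; `motifs` are stamped afterwards.
#'
#' @param rows patch rows inland (depth), >= 1.
#' @param cols patches alongshore, >= 1.
#' @param cell_size patch edge length in meters (default 100).
#' @param class_weights named probability vector, names are 3-digit codes.
#' @param seed RNG seed for the class draw.
#' @param motifs list of [motifs] objects.
#' @return A `synth_spec` object for [generate_landscape()].
#' @export
synth_spec <- function(rows, cols, cell_size = 100,
                       class_weights = default_class_weights(),
                       seed = 1L, motifs = list()) {
  stopifnot(rows >= 1, cols >= 1, cell_size > 0)
  if (abs(sum(class_weights) - 1) > 1e-9)
    stop("class_weights must sum to 1")
  if (is.null(names(class_weights)) ||
      !all(grepl("^[1-5][0-9][0-9]$", names(class_weights))))
    stop("class_weights must be named by 3-digit class codes")
  for (m in motifs) {
    if (m$col < 1 || m$col > cols)
      stop("motif column ", m$col, " outside the grid")
    d <- if (m$kind == "hinge") m$band else m$depth
    if (d < 1 || d > rows)
      stop("motif depth/band ", d, " outside the grid")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size, class_weights = class_weights,
                 seed = as.integer(seed), motifs = motifs),
            class = "synth_spec")
}

#' Generate a synthetic coastal landscape
#'
#' Builds the grid described by a [synth_spec()]: square patches with ids
#' `r<row>_c<col>`, codes drawn from the class weights with the spec's seed
#' (R's default Mersenne-Twister; the caller's RNG state is restored), then
#' motifs stamped deterministically.  The coastline is the grid's seaward
#' edge (y = 0).  Two calls with the same spec give identical output.
#'
#' @param spec a [synth_spec()].
#' @return A list with elements `map` (a [landcover]) and `coast`
#'   (a [coastline]).
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  rows <- spec$rows; cols <- spec$cols; cs <- spec$cell_size
  n <- rows * cols
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  codes <- sample(names(spec$class_weights), n, replace = TRUE,
                  prob = spec$class_weights)
  code_at <- function(r, c) codes[(r - 1L) * cols + c]
  set_at <- function(r, c, v) codes[(r - 1L) * cols + c] <<- v
  # stamp motifs, tracking claims to detect collisions
  claimed <- list()   # key "r,c" -> list(motif index, code)
  stamp <- function(mi, r, c, v) {
    key <- paste0(r, ",", c)
    prev <- claimed[[key]]
    if (!is.null(prev) && prev$code != v)
      stop("motif collision at row ", r, ", col ", c, ": motifs ",
           prev$mi, " and ", mi, " stamp different codes")
    claimed[[key]] <<- list(mi = mi, code = v)
    set_at(r, c, v)
  }
  for (mi in seq_along(spec$motifs)) {
    m <- spec$motifs[[mi]]
    if (m$kind == "corridor") {
      for (r in seq_len(m$depth)) stamp(mi, r, m$col, "311")
    } else if (m$kind == "hinge") {
      for (r in seq_len(rows)) stamp(mi, r, m$col, "311")
      if (m$col > 1L) stamp(mi, m$band, m$col - 1L, "112")
      if (m$col < cols) stamp(mi, m$band, m$col + 1L, "112")
    } else if (m$kind == "barrier") {
      stamp(mi, 1L, m$col, "112")
      if (m$depth >= 2L) for (r in 2:m$depth) stamp(mi, r, m$col, "311")
    } else stop("unknown motif kind: ", m$kind)
  }
  ids <- character(n); geoms <- vector("list", n)
  for (r in seq_len(rows)) {
    y0 <- (r - 1L) * cs; y1 <- r * cs
    for (c in seq_len(cols)) {
      i <- (r - 1L) * cols + c
      x0 <- (c - 1L) * cs; x1 <- c * cs
      ids[i] <- paste0("r", r, "_c", c)
      geoms[[i]] <- list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1),
                                ncol = 2L, byrow = TRUE))
    }
  }
  map <- landcover(ids, codes, geoms, crs = "EPSG:3035",
                   code_field = "CODE_18")
  coast <- coastline(matrix(c(0, 0, cols * cs, 0), ncol = 4L),
                     crs = "EPSG:3035")
  list(map = map, coast = coast)
}

#' Minimal single-chain fixture for the worked TCD examples
#'
#' A one-column grid of `depth_to` natural patches whose seaward edge is the
#' coastline: running Stages 1-3 on it yields one TCNLM occupying bands
#' 1..`depth_to`, every member with TCD = `depth_to`.  `depth_from` names
#' the band whose patch the worked example inspects (validated, not used in
#' construction).
#'
#' @param depth_from band of the inspected patch, `1 <= depth_from <=
#'   depth_to`.
#' @param depth_to deepest band of the chain, `<= B`.
#' @param B band cap the fixture must fit (default 10).
#' @return A list with `map` and `coast`, as [generate_landscape()].
#' @export
worked_example_chain <- function(depth_from, depth_to, B = 10L) {
  stopifnot(1 <= depth_from, depth_from <= depth_to, depth_to <= B)
  generate_landscape(synth_spec(rows = depth_to, cols = 1L,
                                class_weights = c("311" = 1),
                                seed = 0L))
}
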
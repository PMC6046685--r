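# Fixture builders and independent oracles shared across the test files.

square_poly <- function(x0, y0, s = 1) {
  list(matrix(c(x0, y0, x0 + s, y0, x0 + s, y0 + s, x0, y0 + s),
              ncol = 2L, byrow = TRUE))
}

rect_poly <- function(x0, y0, x1, y1) {
  list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2L, byrow = TRUE))
}

make_map <- function(geoms, codes, ids = NULL, crs = "EPSG:3035") {
  if (is.null(ids)) ids <- paste0("p", seq_along(geoms))
  landcover(ids, codes, geoms, crs = crs)
}

# a straight coastline along y = 0 from x = 0 to x = len
flat_coast <- function(len, crs = "EPSG:3035") {
  coastline(matrix(c(0, 0, len, 0), ncol = 4L), crs = crs)
}

# random synthetic landscape of at most ~100 patches, seeded
random_landscape <- function(seed, max_side = 10L) {
  set.seed(seed)
  rows <- sample(3:max_side, 1L)
  cols <- sample(3:max_side, 1L)
  generate_landscape(synth_spec(rows, cols, seed = seed))
}

run_stage123 <- function(map, coast, B = 10L, scheme = nature_scheme(),
                         mode = "rook") {
  graph <- build_adjacency(map, coast, mode = mode)
  bands <- assign_bands(graph, B = B)
  mosaics <- extract_tcnlm(bands, graph, map, scheme)
  tcd <- assign_tcd(mosaics, bands, graph)
  list(graph = graph, bands = bands, mosaics = mosaics, tcd = tcd)
}

# ---- independent oracles ----------------------------------------------------

# Band oracle A: hop distance from a virtual coast vertex, via igraph.
oracle_bands_igraph <- function(graph, B) {
  ids <- graph$ids
  edges <- rbind(
    data.frame(src = graph$coast$id, dst = "COAST", stringsAsFactors = FALSE),
    graph$edges[, c("src", "dst")])
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(ids, "COAST")))
  d <- as.vector(igraph::distances(g, v = "COAST", to = ids))
  d[!is.finite(d) | d > B] <- 0
  stats::setNames(as.integer(d), ids)
}

# Band oracle B: the iterative select-and-erase formulation — select all
# unassigned patches adjacent to the previous band, assign, repeat B times.
oracle_bands_select_erase <- function(graph, B) {
  ids <- graph$ids
  adj <- list()
  for (r in seq_len(nrow(graph$edges))) {
    s <- graph$edges$src[r]; d <- graph$edges$dst[r]
    adj[[s]] <- c(adj[[s]], d); adj[[d]] <- c(adj[[d]], s)
  }
  band <- stats::setNames(rep(0L, length(ids)), ids)
  prev <- graph$coast$id
  band[prev] <- 1L
  for (k in seq_len(B)[-1L]) {
    sel <- character(0)
    for (p in ids) {
      if (band[[p]] != 0L) next
      if (any(prev %in% adj[[p]])) sel <- c(sel, p)
    }
    if (!length(sel)) break
    band[sel] <- k
    prev <- sel
  }
  band
}

# TCNLM oracle: exhaustive memoized search for a band-descending chain of
# natural patches ending at a coast-adjacent natural band-1 patch.
oracle_membership <- function(natural, bands, graph) {
  ids <- graph$ids
  adj <- list()
  for (r in seq_len(nrow(graph$edges))) {
    s <- graph$edges$src[r]; d <- graph$edges$dst[r]
    adj[[s]] <- c(adj[[s]], d); adj[[d]] <- c(adj[[d]], s)
  }
  memo <- new.env(parent = emptyenv())
  connected <- function(p) {
    if (!is.null(memo[[p]])) return(memo[[p]])
    if (!natural[[p]] || bands[[p]] == 0L) { memo[[p]] <- FALSE; return(FALSE) }
    if (bands[[p]] == 1L) { memo[[p]] <- TRUE; return(TRUE) }
    memo[[p]] <- FALSE    # breaks (impossible) cycles during recursion
    below <- adj[[p]][vapply(adj[[p]], function(q) bands[[q]] == bands[[p]] - 1L, TRUE)]
    res <- any(vapply(below, connected, TRUE))
    memo[[p]] <- res
    res
  }
  stats::setNames(vapply(ids, connected, TRUE), ids)
}

# TCD oracle: maximum band over all strictly band-ascending member chains.
oracle_tcd <- function(member, bands, graph) {
  ids <- graph$ids
  adj <- list()
  for (r in seq_len(nrow(graph$edges))) {
    s <- graph$edges$src[r]; d <- graph$edges$dst[r]
    adj[[s]] <- c(adj[[s]], d); adj[[d]] <- c(adj[[d]], s)
  }
  memo <- new.env(parent = emptyenv())
  deepest <- function(p) {
    if (!is.null(memo[[p]])) return(memo[[p]])
    up <- adj[[p]][vapply(adj[[p]],
      function(q) member[[q]] && bands[[q]] == bands[[p]] + 1L, TRUE)]
    res <- if (!length(up)) bands[[p]] else max(vapply(up, deepest, 0L))
    memo[[p]] <- res
    res
  }
  out <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (p in ids[member[ids]]) out[[p]] <- deepest(p)
  out
}

# Evaluate a tiny shapely (Python) snippet that prints one number; the
# independent geometry oracle.
shapely_eval <- function(code) {
  out <- suppressWarnings(
    system2("python", "-", input = code, stdout = TRUE, stderr = TRUE))
  as.numeric(out[length(out)])
}
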
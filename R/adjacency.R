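#' Build the patch contiguity graph with a virtual coast node
#'
#' Every later stage's "select by location" step reduces to this graph.  Two
#' patches are neighbors under `rook` contiguity when their boundaries share
#' a stretch of positive length (strictly greater than
#' `min_shared_boundary`), and under `queen` contiguity when their boundaries
#' touch at all (a corner point counts).  A patch is coast-adjacent when the
#' same predicate holds between its boundary and the coastline.  Only
#' bounding-box candidate pairs are tested.
#'
#' Patches listed in `coast$excluded_ids` (sea patches from
#' [derive_coastline()]) are left out of the graph entirely.
#'
#' @param map a [landcover] object.
#' @param coast a [coastline] object in the same CRS.
#' @param mode `"rook"` (shared border of positive length, the default) or
#'   `"queen"` (any boundary contact).
#' @param min_shared_boundary meters; rook edges require a shared border
#'   strictly longer than this (default 0; raise to e.g. 25 to suppress
#'   sliver contacts in real CLC data).
#' @return An `adjacency_graph`: list with `ids`, `edges` (data frame
#'   `src`, `dst`, `shared_len`), `coast` (data frame `id`, `shared_len`),
#'   `mode`, `min_shared_boundary`.
#' @export
build_adjacency <- function(map, coast, mode = c("rook", "queen"),
                            min_shared_boundary = 0) {
  mode <- match.arg(mode)
  if (min_shared_boundary < 0)
    stop("min_shared_boundary must be >= 0")
  if (!is.na(map$crs) && !is.na(coast$crs) && !identical(map$crs, coast$crs))
    stop("CRS mismatch: map is ", map$crs, ", coastline is ", coast$crs)
  keep <- !(map$ids %in% coast$excluded_ids)
  ids <- map$ids[keep]
  geoms <- map$geoms[keep]
  n <- length(ids)
  segsets <- lapply(geoms, poly_segments)
  bbs <- t(vapply(geoms, poly_bbox, numeric(4L)))
  src <- character(0); dst <- character(0); slen <- numeric(0)
  pairs <- if (n >= 2L) bbox_candidate_pairs(bbs) else matrix(integer(0), ncol = 2L)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    sl <- shared_boundary_length(segsets[[i]], segsets[[j]])
    edge <- if (mode == "rook") sl > min_shared_boundary
            else sl > 0 || segments_touch(segsets[[i]], segsets[[j]])
    if (edge) {
      src <- c(src, ids[i]); dst <- c(dst, ids[j]); slen <- c(slen, sl)
    }
  }
  cseg <- coast$segments
  cbb <- c(min(cseg[, c(1L, 3L)]), min(cseg[, c(2L, 4L)]),
           max(cseg[, c(1L, 3L)]), max(cseg[, c(2L, 4L)]))
  cid <- character(0); cslen <- numeric(0)
  for (i in seq_len(n)) {
    if (!.bbox_overlaps(bbs[i, ], cbb)) next
    sl <- shared_boundary_length(segsets[[i]], cseg)
    edge <- if (mode == "rook") sl > min_shared_boundary
            else sl > 0 || segments_touch(segsets[[i]], cseg)
    if (edge) { cid <- c(cid, ids[i]); cslen <- c(cslen, sl) }
  }
  structure(list(
    ids = ids,
    edges = data.frame(src = src, dst = dst, shared_len = slen,
                       stringsAsFactors = FALSE),
    coast = data.frame(id = cid, shared_len = cslen, stringsAsFactors = FALSE),
    mode = mode, min_shared_boundary = min_shared_boundary),
    class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph> ", length(x$ids), " patches, ",
      nrow(x$edges), " edges, ", nrow(x$coast), " coast-adjacent (",
      x$mode, ")\n", sep = "")
  invisible(x)
}

# Named list: patch id -> character vector of neighbor ids.
adjacency_list <- function(graph) {
  adj <- stats::setNames(vector("list", length(graph$ids)), graph$ids)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    adj[[e$src[r]]] <- c(adj[[e$src[r]]], e$dst[r])
    adj[[e$dst[r]]] <- c(adj[[e$dst[r]]], e$src[r])
  }
  adj
}

#' Export the adjacency graph as an edge-list data frame
#'
#' Patch-patch edges as `src,dst,shared_len` rows plus one `COAST,dst` row
#' per coast-adjacent patch; suitable for writing to CSV.
#'
#' @param graph an `adjacency_graph`.
#' @return A data frame with columns `src`, `dst`, `shared_len`.
#' @export
edge_list <- function(graph) {
  rbind(
    data.frame(src = "COAST", dst = graph$coast$id,
               shared_len = graph$coast$shared_len, stringsAsFactors = FALSE),
    graph$edges)
}
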
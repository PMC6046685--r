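#' Assign band levels (Stage 1)
#'
#' The band level of a patch is its adjacency order from the coastline:
#' band 1 patches touch the coastline, band k patches touch a band k-1 patch
#' without belonging to any earlier band.  This is the hop distance from the
#' virtual coast node in the contiguity graph, computed by frontier
#' propagation (breadth-first search) and capped at `B` bands.  Patches
#' farther than `B` steps, or unreachable, keep band 0 (unassigned) — they
#' stay in the partition so a rerun with a larger `B` can reach them.
#'
#' @param graph an `adjacency_graph` from [build_adjacency()].
#' @param B number of bands (default 10).
#' @return A named integer vector over all graph patch ids: band level in
#'   `1..B`, or `0` for unassigned; attribute `"B"` records the cap.
#' @export
assign_bands <- function(graph, B = 10L) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  band <- stats::setNames(rep(0L, length(graph$ids)), graph$ids)
  frontier <- graph$coast$id
  if (!length(frontier)) {
    warning("no coast-adjacent patch: band 1 is empty, all patches unassigned")
    attr(band, "B") <- B
    return(band)
  }
  adj <- adjacency_list(graph)
  band[frontier] <- 1L
  k <- 1L
  while (k < B && length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[band[nxt] == 0L]
    if (!length(nxt)) break
    band[nxt] <- k + 1L
    frontier <- nxt
    k <- k + 1L
  }
  attr(band, "B") <- B
  band
}
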
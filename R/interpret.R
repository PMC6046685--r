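#' Cross-tabulate band level against TCD (Stage 4A)
#'
#' Counts the TCNLM members in every (band, TCD) cell.  TCD can never fall
#' below the band level, so the lower triangle (TCD < band) is structurally
#' zero; the table total equals the member count.  With a map, per-cell area
#' totals (square meters) are attached as well.
#'
#' @param bands band vector from [assign_bands()].
#' @param tcd TCD vector from [assign_tcd()].
#' @param map optional [landcover] object for per-cell area totals.
#' @return A `crosstab`: list with `counts` (B x B matrix, rows = band,
#'   columns = TCD) and optionally `areas`.
#' @export
cross_tabulate <- function(bands, tcd, map = NULL) {
  B <- attr(bands, "B")
  counts <- matrix(0L, nrow = B, ncol = B,
                   dimnames = list(band = paste0("band", seq_len(B)),
                                   tcd = paste0("tcd", seq_len(B))))
  areas <- if (!is.null(map)) {
    a <- counts; storage.mode(a) <- "double"; a
  }
  mids <- names(tcd)[!is.na(tcd)]
  for (p in mids) {
    b <- bands[[p]]; t <- tcd[[p]]
    counts[b, t] <- counts[b, t] + 1L
    if (!is.null(areas))
      areas[b, t] <- areas[b, t] + map$areas[match(p, map$ids)]
  }
  structure(list(counts = counts, areas = areas), class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("<crosstab> band x TCD member counts (total ",
      sum(x$counts), ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Write a cross-tabulation as CSV
#'
#' @param ct a `crosstab` from [cross_tabulate()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_crosstab <- function(ct, path) {
  df <- as.data.frame(ct$counts)
  df <- cbind(band = rownames(ct$counts), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Find endangered hinge patches (Stage 4A)
#'
#' Screens the TCNLM members combining a low band level (coast proximity)
#' with a high TCD (deep inland continuity) — by default band 1..4 and
#' TCD 7..10 — and flags those that act as singular hinges: if the patch
#' were artificialized, deeper mosaic patches would lose their transversal
#' connection to the coastline (landscape fragmentation).  The test is
#' direct: membership is recomputed with the candidate treated as
#' artificial, and the members that drop out (beyond the candidate itself)
#' form its dependent set; a candidate with an empty dependent set is
#' redundant and not flagged.  Whether the patch is the only member of its
#' band within its mosaic is reported as an auxiliary flag.
#'
#' @param mosaics a `mosaic_set` from [extract_tcnlm()].
#' @param bands band vector.
#' @param graph the `adjacency_graph`.
#' @param tcd TCD vector from [assign_tcd()].
#' @param band_max highest band level screened (default 4).
#' @param tcd_min lowest TCD screened (default 7).
#' @return A data frame with one row per flagged patch: `id`, `band`,
#'   `tcd`, `mosaic_id`, `unique_in_band_within_mosaic`, `n_dependents`,
#'   and list-column `dependent_patch_ids`.
#' @export
find_endangered <- function(mosaics, bands, graph, tcd,
                            band_max = 4L, tcd_min = 7L) {
  if (band_max >= tcd_min)
    warning("band_max >= tcd_min: the band/TCD screen is not selective")
  ids <- graph$ids
  member <- mosaics$member
  cands <- ids[member[ids] & bands[ids] <= band_max & !is.na(tcd[ids]) &
               tcd[ids] >= tcd_min]
  rows <- list()
  for (p in cands) {
    # re-run the membership propagation with p artificialized; extraction is
    # monotone in the natural set, so restricting to the original members
    # minus p is exactly the full Stage-2 re-run
    nat2 <- member; nat2[p] <- FALSE
    member2 <- tcnlm_membership(nat2, bands, graph)
    dependents <- ids[member[ids] & !member2[ids]]
    dependents <- setdiff(dependents, p)
    if (!length(dependents)) next
    mid <- mosaics$mosaic_id[[p]]
    same_band <- ids[member[ids] & mosaics$mosaic_id[ids] == mid &
                     bands[ids] == bands[[p]]]
    rows[[length(rows) + 1L]] <- data.frame(
      id = p, band = bands[[p]], tcd = tcd[[p]], mosaic_id = mid,
      unique_in_band_within_mosaic = length(same_band) == 1L,
      n_dependents = length(dependents), stringsAsFactors = FALSE)
    rows[[length(rows)]]$dependent_patch_ids <- list(dependents)
  }
  if (!length(rows))
    return(data.frame(id = character(0), band = integer(0), tcd = integer(0),
                      mosaic_id = integer(0),
                      unique_in_band_within_mosaic = logical(0),
                      n_dependents = integer(0),
                      dependent_patch_ids = I(list())))
  do.call(rbind, rows)
}

#' Find restorable artificial barrier patches (Stage 4B)
#'
#' Reruns the Stage-2 propagation with the band-1 seed set replaced by the
#' coast-adjacent artificial patches: from each such seed the chain ascends
#' through natural patches exactly as in [extract_tcnlm()].  A seed is
#' flagged as a barrier when it fronts at least one natural band-2 patch
#' reached this way — restoring the seed to a natural state would reconnect
#' that mosaic to the coastline.  `unlocked_depth` is the deepest band among
#' the natural patches reached behind the seed.  With
#' `exclude_already_connected`, band-2 patches that are already TCNLM
#' members through a natural band-1 link are ignored, isolating seeds that
#' are the sole separation.
#'
#' @param map the [landcover] object.
#' @param bands band vector.
#' @param graph the `adjacency_graph`.
#' @param scheme a [nature_scheme()].
#' @param exclude_already_connected see above (default off).
#' @return A data frame with one row per barrier: `id`, `clc_code`,
#'   `unlocked_depth`, `n_unlocked`, list-column `unlocked_member_ids`.
#' @export
find_barriers <- function(map, bands, graph, scheme = nature_scheme(),
                          exclude_already_connected = FALSE) {
  ids <- graph$ids
  codes <- map$codes[match(ids, map$ids)]
  cls <- classify_code(codes, scheme)
  natural <- stats::setNames(cls == "natural", ids)
  artificial <- stats::setNames(cls == "artificial", ids)
  seeds <- ids[artificial[ids] & bands[ids] == 1L]
  already <- if (exclude_already_connected)
    tcnlm_membership(natural, bands, graph) else NULL
  adj <- adjacency_list(graph)
  B <- attr(bands, "B")
  rows <- list()
  for (s in seeds) {
    nb <- adj[[s]]
    start <- nb[natural[nb] & bands[nb] == 2L]
    if (!is.null(already)) start <- start[!already[start]]
    if (!length(start)) next
    reached <- stats::setNames(rep(FALSE, length(ids)), ids)
    reached[start] <- TRUE
    frontier <- start
    k <- 2L
    while (k < B && length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[natural[nxt] & bands[nxt] == k + 1L & !reached[nxt]]
      if (!length(nxt)) break
      reached[nxt] <- TRUE
      frontier <- nxt
      k <- k + 1L
    }
    unlocked <- ids[reached[ids]]
    rows[[length(rows) + 1L]] <- data.frame(
      id = s, clc_code = codes[match(s, ids)],
      unlocked_depth = max(bands[unlocked]),
      n_unlocked = length(unlocked), stringsAsFactors = FALSE)
    rows[[length(rows)]]$unlocked_member_ids <- list(unlocked)
  }
  if (!length(rows))
    return(data.frame(id = character(0), clc_code = character(0),
                      unlocked_depth = integer(0), n_unlocked = integer(0),
                      unlocked_member_ids = I(list())))
  do.call(rbind, rows)
}
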
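#' Natural land-cover classification scheme
#'
#' The default natural set is the 14 CORINE Level-3 classes treated as
#' natural surfaces: 523, 522, 521 (marine waters), 422, 421, 411
#' (wetlands), 333, 331, 324, 323, 321, 313, 312, 311 (forest and
#' semi-natural land).  In Mediterranean contexts olive groves (223) and
#' agro-forestry areas (244) can be counted as part of the natural
#' environment via `mediterranean_extras`.
#'
#' @param mediterranean_extras add classes 223 and 244 to the natural set.
#' @param natural_codes override the base natural set.
#' @return A `nature_scheme` object.
#' @export
nature_scheme <- function(mediterranean_extras = FALSE,
                          natural_codes = c("523", "522", "521", "422",
                                            "421", "411", "333", "331",
                                            "324", "323", "321", "313",
                                            "312", "311")) {
  extras <- if (mediterranean_extras) c("223", "244") else character(0)
  structure(list(natural_codes = as.character(natural_codes),
                 mediterranean_extras = mediterranean_extras,
                 extras = extras),
            class = "nature_scheme")
}

#' Classify a land-cover code as natural, artificial, agricultural or other
#'
#' Natural means membership in the scheme's natural set (plus the
#' Mediterranean extras when enabled); artificial is any 1xx code;
#' agricultural any 2xx code not promoted by an enabled extra; everything
#' else is other.
#'
#' @param code character vector of 3-digit class codes.
#' @param scheme a [nature_scheme()].
#' @return Character vector in `natural`, `artificial`, `agricultural`,
#'   `other`.
#' @export
classify_code <- function(code, scheme = nature_scheme()) {
  code <- as.character(code)
  bad <- !grepl("^[1-5][0-9][0-9]$", code)
  if (any(bad))
    stop("malformed class code(s): ", paste(unique(code[bad]), collapse = ", "))
  out <- rep("other", length(code))
  out[startsWith(code, "1")] <- "artificial"
  out[startsWith(code, "2")] <- "agricultural"
  out[code %in% c(scheme$natural_codes, scheme$extras)] <- "natural"
  out
}

#' Extract transversally connected natural landscape mosaics (Stage 2)
#'
#' A patch is a TCNLM member when it is natural and either lies in band 1
#' (touching the coastline) or touches a member of the immediately preceding
#' band — i.e. it is linked to the coastline by a chain of band-adjacent
#' natural patches.  Membership is computed by ascending the bands 1..B;
#' natural patches of band k with no member neighbor in band k-1 drop out.
#' Members are then grouped into mosaics: the connected components of the
#' member-induced contiguity subgraph, labeled 1, 2, ... in ascending order
#' of each component's smallest patch id.
#'
#' With `lateral_merge`, same-band contact between natural patches also
#' propagates membership (a band-k natural patch touching a band-k member
#' joins), computed to a fixed point.
#'
#' @param bands band vector from [assign_bands()].
#' @param graph the `adjacency_graph` the bands were computed on.
#' @param map the [landcover] object.
#' @param scheme a [nature_scheme()].
#' @param lateral_merge allow same-band membership propagation (default off).
#' @return A `mosaic_set`: list with `member` (named logical) and
#'   `mosaic_id` (named integer, `NA` for non-members).
#' @export
extract_tcnlm <- function(bands, graph, map, scheme = nature_scheme(),
                          lateral_merge = FALSE) {
  ids <- graph$ids
  codes <- map$codes[match(ids, map$ids)]
  natural <- classify_code(codes, scheme) == "natural"
  names(natural) <- ids
  member <- tcnlm_membership(natural, bands, graph, lateral_merge)
  structure(list(member = member,
                 mosaic_id = label_mosaics(member, graph)),
            class = "mosaic_set")
}

# Core membership propagation over an arbitrary "natural" indicator; also
# the engine behind the barrier analysis (with an artificial band-1 seed
# set) and the endangered-patch removal test.
tcnlm_membership <- function(natural, bands, graph, lateral_merge = FALSE,
                             seed_ids = NULL) {
  ids <- graph$ids
  B <- attr(bands, "B")
  adj <- adjacency_list(graph)
  member <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (is.null(seed_ids))
    seed_ids <- ids[natural[ids] & bands[ids] == 1L]
  member[seed_ids] <- TRUE
  if (lateral_merge) {
    repeat {
      grew <- FALSE
      for (k in seq_len(B)) {
        repeat {
          cand <- ids[!member[ids] & natural[ids] & bands[ids] == k]
          add <- cand[vapply(cand, function(p) {
            nb <- adj[[p]]
            any(member[nb] & (bands[nb] == k - 1L | bands[nb] == k))
          }, TRUE)]
          if (!length(add)) break
          member[add] <- TRUE; grew <- TRUE
        }
      }
      if (!grew) break
    }
  } else {
    for (k in seq_len(B)[-1L]) {
      cand <- ids[natural[ids] & bands[ids] == k]
      add <- cand[vapply(cand, function(p) {
        nb <- adj[[p]]
        any(member[nb] & bands[nb] == k - 1L)
      }, TRUE)]
      member[add] <- TRUE
    }
  }
  member
}

# Connected components of the member-induced subgraph, labeled in ascending
# order of each component's smallest patch id (lexicographic, C locale).
label_mosaics <- function(member, graph) {
  ids <- graph$ids
  mosaic <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  mids <- ids[member[ids]]
  if (!length(mids)) return(mosaic)
  e <- graph$edges
  keep <- e$src %in% mids & e$dst %in% mids
  g <- igraph::graph_from_data_frame(
    e[keep, c("src", "dst"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = mids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  smallest <- vapply(split(names(comp), comp),
                     function(v) sort(v, method = "radix")[1L], "")
  relabel <- order(order(smallest, method = "radix"))
  mosaic[names(comp)] <- relabel[comp]
  mosaic
}

#' Assign Transversal Continuity Depth (Stage 3)
#'
#' The TCD of a TCNLM patch is the maximum band level it provides transversal
#' connectivity for: the deepest band reachable inland from it through a
#' strictly band-ascending chain of mosaic members.  Computed by the
#' descending reclassification: all still-unlabeled members of band B get
#' TCD = B, the label then propagates coastward band by band (a band-k
#' member touching a labeled band-(k+1) member inherits the label); the
#' sweep repeats for B-1, B-2, ... 1 over the patches still unlabeled.  A
#' natural band-1 patch connected to no band-2 member ends with TCD 1.
#'
#' @param mosaics a `mosaic_set` from [extract_tcnlm()].
#' @param bands band vector from [assign_bands()].
#' @param graph the same `adjacency_graph`.
#' @return Named integer vector over graph ids: TCD for members, `NA`
#'   otherwise.
#' @export
assign_tcd <- function(mosaics, bands, graph) {
  ids <- graph$ids
  B <- attr(bands, "B")
  member <- mosaics$member
  if (any(member[ids] & bands[ids] == 0L))
    stop("internal inconsistency: TCNLM member without a band level")
  adj <- adjacency_list(graph)
  tcd <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (t in rev(seq_len(B))) {
    seeds <- ids[member[ids] & bands[ids] == t & is.na(tcd[ids])]
    if (!length(seeds)) next
    tcd[seeds] <- t
    frontier <- seeds
    k <- t - 1L
    while (k >= 1L && length(frontier)) {
      nxt <- ids[member[ids] & bands[ids] == k & is.na(tcd[ids])]
      nxt <- nxt[vapply(nxt, function(p) {
        nb <- adj[[p]]
        any(!is.na(tcd[nb]) & tcd[nb] == t & bands[nb] == k + 1L)
      }, TRUE)]
      if (!length(nxt)) break
      tcd[nxt] <- t
      frontier <- nxt
      k <- k - 1L
    }
  }
  tcd
}
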
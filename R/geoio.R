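#' Land-cover map objects
#'
#' A `landcover` object holds the patches of a land-use/land-cover polygon
#' layer: one simple polygon per patch, a stable string id, and a 3-digit
#' CORINE-style class code.  All geometry is in the planar units of one
#' projected CRS (meters).
#'
#' @param ids character vector of unique patch ids.
#' @param codes character vector of 3-digit class codes (`[1-5][0-9][0-9]`).
#' @param geoms list of polygons; a polygon is a list of rings, a ring an
#'   n x 2 coordinate matrix (exterior first, holes after, stored open).
#' @param crs CRS descriptor string (e.g. `"EPSG:3035"`), or `NA`.
#' @param code_field name of the source attribute the codes came from.
#' @return A `landcover` object.
#' @export
landcover <- function(ids, codes, geoms, crs = NA_character_,
                      code_field = "CODE_18") {
  ids <- as.character(ids); codes <- as.character(codes)
  stopifnot(length(ids) == length(codes), length(ids) == length(geoms))
  if (anyDuplicated(ids))
    stop("duplicate patch ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !grepl("^[1-5][0-9][0-9]$", codes)
  if (any(bad))
    stop("malformed class code(s) for patch(es): ",
         paste(ids[bad], collapse = ", "))
  areas <- vapply(geoms, poly_area, 0)
  if (any(areas <= 0))
    stop("non-positive area for patch(es): ", paste(ids[areas <= 0], collapse = ", "))
  structure(list(ids = ids, codes = codes, geoms = geoms,
                 areas = areas, crs = crs, code_field = code_field),
            class = "landcover")
}

#' @export
print.landcover <- function(x, ...) {
  cat("<landcover> ", length(x$ids), " patches, CRS ",
      if (is.na(x$crs)) "<none>" else x$crs,
      ", codes: ", paste(utils::head(sort(unique(x$codes)), 8L), collapse = " "),
      if (length(unique(x$codes)) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.landcover <- function(x, ...) {
  data.frame(id = x$ids, clc_code = x$codes, area = x$areas,
             stringsAsFactors = FALSE)
}

#' @export
length.landcover <- function(x) length(x$ids)

#' Coastline objects
#'
#' A polyline (possibly multi-part) in the same planar CRS as the land-cover
#' map, stored as loose segments.  `excluded_ids` lists sea patches that must
#' not take part in banding.
#'
#' @param segments m x 4 matrix of segments (`x1,y1,x2,y2`).
#' @param crs CRS descriptor.
#' @param excluded_ids ids of sea patches excluded from banding.
#' @return A `coastline` object with a `length` field in meters.
#' @export
coastline <- function(segments, crs = NA_character_,
                      excluded_ids = character(0)) {
  segments <- matrix(as.numeric(segments), ncol = 4L)
  len <- if (nrow(segments)) sum(seg_length(segments)) else 0
  if (len <= 0) stop("coastline has zero length")
  structure(list(segments = segments, length = len, crs = crs,
                 excluded_ids = excluded_ids),
            class = "coastline")
}

#' @export
print.coastline <- function(x, ...) {
  cat("<coastline> ", nrow(x$segments), " segments, length ",
      format(x$length), " m\n", sep = "")
  invisible(x)
}

# ---- GeoJSON reading --------------------------------------------------------

.gj_ring <- function(coords) {
  m <- matrix(unlist(lapply(coords, function(p) c(p[[1L]], p[[2L]]))),
              ncol = 2L, byrow = TRUE)
  ring_normalize(m)
}

.gj_polygons <- function(geom) {
  # returns list of polygons (each a list of rings)
  if (is.null(geom) || is.null(geom$type)) return(list())
  switch(geom$type,
    Polygon = list(lapply(geom$coordinates, .gj_ring)),
    MultiPolygon = lapply(geom$coordinates, function(pg) lapply(pg, .gj_ring)),
    list())
}

.gj_crs <- function(obj) {
  nm <- tryCatch(obj$crs$properties$name, error = function(e) NULL)
  if (is.null(nm)) NA_character_ else as.character(nm)
}

.crs_is_geographic <- function(crs) {
  if (is.na(crs)) return(TRUE)   # RFC 7946: no crs member means WGS84
  grepl("4326|CRS84|WGS *84", crs, ignore.case = TRUE)
}

#' Read a land-use/land-cover polygon layer
#'
#' Reads a GeoJSON FeatureCollection of polygonal features carrying a 3-digit
#' class code attribute.  Multi-part features are split into single-part
#' patches (ids suffixed `_0`, `_1`, ...).  Self-intersecting rings are
#' repaired by splitting at their crossing points; features for which no
#' positive-area simple ring survives are dropped with a warning and listed
#' in `attr(map, "rejected")`.
#'
#' @param path path to a GeoJSON file.
#' @param code_field name of the feature property holding the class code.
#' @param explode_multiparts split multi-part features (default `TRUE`).
#' @param allow_geographic accept a geographic (degree-unit) CRS.  Off by
#'   default: band analysis relies on metric shared-boundary lengths.
#' @return A [landcover] object.
#' @export
read_lulc <- function(path, code_field, explode_multiparts = TRUE,
                      allow_geographic = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.(geo)?json$", path, ignore.case = TRUE))
    stop("unsupported vector format for '", path,
         "': only GeoJSON (.geojson/.json) layers are supported")
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- obj$features
  if (!length(feats)) stop("empty layer: ", path)
  crs <- .gj_crs(obj)
  if (.crs_is_geographic(crs) && !allow_geographic)
    stop("layer CRS (", if (is.na(crs)) "implicit WGS84" else crs,
         ") is geographic; band analysis needs a projected CRS ",
         "(set allow_geographic = TRUE to override)")
  ids <- character(0); codes <- character(0); geoms <- list()
  rejected <- character(0); repaired <- character(0)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties
    if (is.null(props) || !code_field %in% names(props))
      stop("attribute '", code_field, "' missing; available fields: ",
           paste(names(props), collapse = ", "))
    fid <- if (!is.null(f$id)) as.character(f$id)
           else if (!is.null(props$id)) as.character(props$id)
           else paste0("f", i - 1L)
    polys <- .gj_polygons(f$geometry)
    if (!length(polys)) { rejected <- c(rejected, fid); next }
    if (!explode_multiparts && length(polys) > 1L) {
      # keep as the largest part plus the rest merged is not meaningful for
      # banding; un-exploded multiparts keep part 0's shell list flattened
      polys <- list(do.call(c, polys))
    }
    multi <- length(polys) > 1L
    for (k in seq_along(polys)) {
      poly <- polys[[k]]
      pid <- if (multi) paste0(fid, "_", k - 1L) else fid
      ext <- repair_ring(poly[[1L]])
      if (!length(ext)) { rejected <- c(rejected, pid); next }
      if (length(ext) > 1L || !isTRUE(all.equal(ext[[1L]], ring_normalize(poly[[1L]]))))
        repaired <- c(repaired, pid)
      holes <- poly[-1L]
      if (length(ext) == 1L) {
        ids <- c(ids, pid); geoms[[length(geoms) + 1L]] <- c(ext[1L], holes)
        codes <- c(codes, as.character(props[[code_field]]))
      } else {
        for (e in seq_along(ext)) {
          ids <- c(ids, paste0(pid, "_r", e - 1L))
          geoms[[length(geoms) + 1L]] <- ext[e]
          codes <- c(codes, as.character(props[[code_field]]))
        }
      }
    }
  }
  if (length(rejected))
    warning("rejected irreparable feature(s): ", paste(rejected, collapse = ", "))
  if (!length(ids)) stop("no valid polygonal features in ", path)
  map <- landcover(ids, codes, geoms, crs = crs, code_field = code_field)
  attr(map, "rejected") <- rejected
  attr(map, "repaired") <- repaired
  map
}

# ---- coastline derivation (Stage 0) -----------------------------------------

# Boundary of the union of the map's patches, as loose segments: every piece
# of a patch boundary not shared with any other patch.
union_boundary_segments <- function(map, tol = .cb_tol) {
  n <- length(map$ids)
  bbs <- t(vapply(map$geoms, poly_bbox, numeric(4L)))
  pairs <- bbox_candidate_pairs(bbs, tol)
  nbr <- vector("list", n)
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    nbr[[pairs[r, 1L]]] <- c(nbr[[pairs[r, 1L]]], pairs[r, 2L])
    nbr[[pairs[r, 2L]]] <- c(nbr[[pairs[r, 2L]]], pairs[r, 1L])
  }
  segsets <- lapply(map$geoms, poly_segments)
  out <- list()
  for (i in seq_len(n)) {
    segs <- segsets[[i]]
    other <- if (length(nbr[[i]])) do.call(rbind, segsets[nbr[[i]]]) else NULL
    for (s in seq_len(nrow(segs))) {
      a <- segs[s, ]
      la <- seg_length(matrix(a, ncol = 4L))
      ivs <- list()
      if (!is.null(other)) for (o in seq_len(nrow(other))) {
        b <- other[o, ]
        if (.seg_bbox_disjoint(a, b, tol)) next
        iv <- seg_overlap_interval(a, b, tol)
        if (!is.null(iv)) ivs[[length(ivs) + 1L]] <- iv
      }
      keep <- .interval_complement(ivs, la, tol)
      for (k in seq_len(nrow(keep))) {
        p0 <- seg_point_at(a, keep[k, 1L]); p1 <- seg_point_at(a, keep[k, 2L])
        out[[length(out) + 1L]] <- c(p0, p1)
      }
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 4L))
  do.call(rbind, out)
}

# Complement of merged intervals within [0, len]; returns a 2-col matrix.
.interval_complement <- function(ivs, len, tol) {
  if (!length(ivs)) return(matrix(c(0, len), ncol = 2L))
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1L]), , drop = FALSE]
  merged <- m[1L, , drop = FALSE]
  for (r in seq_len(nrow(m))[-1L]) {
    last <- nrow(merged)
    if (m[r, 1L] <= merged[last, 2L] + tol)
      merged[last, 2L] <- max(merged[last, 2L], m[r, 2L])
    else merged <- rbind(merged, m[r, ])
  }
  out <- list(); cur <- 0
  for (r in seq_len(nrow(merged))) {
    if (merged[r, 1L] - cur > tol) out[[length(out) + 1L]] <- c(cur, merged[r, 1L])
    cur <- max(cur, merged[r, 2L])
  }
  if (len - cur > tol) out[[length(out) + 1L]] <- c(cur, len)
  if (!length(out)) return(matrix(numeric(0), ncol = 2L))
  do.call(rbind, out)
}

#' Derive the coastline from a land-cover map (Stage 0)
#'
#' Two modes.  Sea mode: the coastline is the dissolved shared boundary
#' between the union of sea-class patches and the union of everything else;
#' sea patches are marked excluded from all later banding (unless
#' `keep_sea_patches`).  Split-point mode: all patches are dissolved to one
#' polygon, its boundary is traversed, and the boundary path between the two
#' boundary points nearest the given coordinates is returned; `direction`
#' picks which of the two arcs (following the counter-clockwise boundary
#' orientation, or against it).
#'
#' @param map a [landcover] object.
#' @param sea_codes character vector of sea class codes (e.g. `"523"`).
#' @param split_points a list/matrix of two (x, y) coordinates.
#' @param direction `"ccw"` or `"cw"` arc selection in split-point mode.
#' @param keep_sea_patches keep sea patches available for banding.
#' @return A [coastline] object.
#' @export
derive_coastline <- function(map, sea_codes = NULL, split_points = NULL,
                             direction = c("ccw", "cw"),
                             keep_sea_patches = FALSE) {
  direction <- match.arg(direction)
  if (is.null(sea_codes) && is.null(split_points))
    stop("either sea_codes or split_points must be given")
  if (!is.null(sea_codes)) {
    sea <- map$codes %in% as.character(sea_codes)
    if (!any(sea)) stop("no patch carries a sea code (",
                        paste(sea_codes, collapse = ", "), ")")
    sea_segs <- lapply(map$geoms[sea], poly_segments)
    land_segs <- lapply(map$geoms[!sea], poly_segments)
    sea_bb <- t(vapply(map$geoms[sea], poly_bbox, numeric(4L)))
    land_bb <- t(vapply(map$geoms[!sea], poly_bbox, numeric(4L)))
    out <- list()
    for (i in seq_along(sea_segs)) {
      for (j in seq_along(land_segs)) {
        if (!.bbox_overlaps(sea_bb[i, ], land_bb[j, ])) next
        sh <- shared_boundary_segments(sea_segs[[i]], land_segs[[j]])
        if (nrow(sh)) out[[length(out) + 1L]] <- sh
      }
    }
    if (!length(out))
      stop("sea and land patches share no boundary: empty coastline")
    segs <- do.call(rbind, out)
    return(coastline(segs, crs = map$crs,
                     excluded_ids = if (keep_sea_patches) character(0)
                                    else map$ids[sea]))
  }
  # split-point mode
  sp <- if (is.matrix(split_points)) split_points
        else do.call(rbind, lapply(split_points, as.numeric))
  if (nrow(sp) != 2L) stop("split_points must give exactly two coordinates")
  bsegs <- union_boundary_segments(map)
  chains <- assemble_chains(bsegs)
  closed <- Filter(function(ch) isTRUE(attr(ch, "closed")), chains)
  if (!length(closed)) stop("dissolved boundary is not a closed ring")
  # outer shell: the closed chain with the largest enclosed area
  areas <- vapply(closed, function(ch) abs(ring_signed_area(ch)), 0)
  ring <- closed[[which.max(areas)]]
  if (ring_signed_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
  path <- .boundary_arc(ring, sp[1L, ], sp[2L, ], direction)
  n <- nrow(path)
  segs <- cbind(path[-n, 1L], path[-n, 2L], path[-1L, 1L], path[-1L, 2L])
  coastline(segs, crs = map$crs)
}

# Nearest boundary point to pt; returns list(seg = index, t = arclen, xy).
.nearest_on_ring <- function(ring, pt) {
  segs <- ring_segments(ring)
  best <- NULL
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, ]
    dx <- a[3L] - a[1L]; dy <- a[4L] - a[2L]
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) 0 else
      min(1, max(0, ((pt[1L] - a[1L]) * dx + (pt[2L] - a[2L]) * dy) / l2))
    q <- c(a[1L] + t * dx, a[2L] + t * dy)
    d <- sqrt(sum((q - pt)^2))
    if (is.null(best) || d < best$d)
      best <- list(seg = i, t = t * sqrt(l2), xy = q, d = d)
  }
  best
}

# Boundary arc of a CCW ring from the point nearest p1 to the point nearest
# p2, walking in ring order ("ccw") or reversed ("cw").  Positions are
# arc-length parameters along the closed boundary.
.boundary_arc <- function(ring, p1, p2, direction) {
  if (direction == "cw") {
    cw <- .boundary_arc(ring, p2, p1, "ccw")
    return(cw[rev(seq_len(nrow(cw))), , drop = FALSE])
  }
  segs <- ring_segments(ring)
  lens <- seg_length(segs)
  cum <- c(0, cumsum(lens))           # cum[i] = arclen at start of segment i
  total <- cum[length(cum)]
  a <- .nearest_on_ring(ring, p1)
  b <- .nearest_on_ring(ring, p2)
  sa <- cum[a$seg] + a$t
  sb <- cum[b$seg] + b$t
  span <- (sb - sa) %% total
  # vertices strictly inside (sa, sa + span) in ring order
  vstart <- cum[seq_len(nrow(segs))]  # arclen of each ring vertex
  rel <- (vstart - sa) %% total
  inside <- which(rel > .cb_tol & rel < span - .cb_tol)
  inside <- inside[order(rel[inside])]
  pts <- rbind(a$xy, ring[inside, , drop = FALSE], b$xy)
  ring_normalize(pts)
}

# ---- writing ----------------------------------------------------------------

.gj_crs_member <- function(crs) {
  if (is.na(crs)) NULL
  else list(type = "name", properties = list(name = crs))
}

.poly_to_gj <- function(poly) {
  list(type = "Polygon",
       coordinates = lapply(poly, function(r) {
         rc <- close_ring(r)
         lapply(seq_len(nrow(rc)), function(i) c(rc[i, 1L], rc[i, 2L]))
       }))
}

#' Write a land-cover layer with per-patch result attributes
#'
#' Writes a GeoJSON FeatureCollection in which every feature carries the
#' patch id, its class code (under the map's `code_field`), and the columns
#' of `attributes` matched by patch id (standard names: `band`, `tcnlm`,
#' `mosaic_id`, `tcd`, `endangered`, `barrier`).
#'
#' @param map a [landcover] object.
#' @param attributes data frame keyed by an `id` column (may be `NULL`).
#' @param path output file path.
#' @param format output format; only `"geojson"` is supported.
#' @return The path, invisibly.
#' @export
write_outputs <- function(map, attributes = NULL, path, format = "geojson") {
  if (!identical(tolower(format), "geojson"))
    stop("unknown output format '", format, "': supported format is geojson")
  if (!is.null(attributes)) {
    if (!"id" %in% names(attributes)) stop("attributes must have an 'id' column")
    ix <- match(map$ids, attributes$id)
  }
  feats <- lapply(seq_along(map$ids), function(i) {
    props <- list(id = map$ids[i])
    props[[map$code_field]] <- map$codes[i]
    if (!is.null(attributes) && !is.na(ix[i])) {
      for (col in setdiff(names(attributes), "id")) {
        v <- attributes[[col]][ix[i]]
        props[[col]] <- if (is.logical(v)) as.integer(v) else v
      }
    }
    list(type = "Feature", id = map$ids[i], properties = props,
         geometry = .poly_to_gj(map$geoms[[i]]))
  })
  obj <- list(type = "FeatureCollection")
  crsm <- .gj_crs_member(map$crs)
  if (!is.null(crsm)) obj$crs <- crsm
  obj$features <- feats
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10L,
                              null = "null"), path)
  invisible(path)
}

#' Write a coastline as a GeoJSON MultiLineString
#'
#' @param coast a [coastline] object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_coastline <- function(coast, path) {
  chains <- assemble_chains(coast$segments)
  lines <- lapply(chains, function(ch) {
    if (isTRUE(attr(ch, "closed"))) ch <- close_ring(ch)
    lapply(seq_len(nrow(ch)), function(i) c(ch[i, 1L], ch[i, 2L]))
  })
  obj <- list(type = "FeatureCollection")
  crsm <- .gj_crs_member(coast$crs)
  if (!is.null(crsm)) obj$crs <- crsm
  obj$features <- list(list(
    type = "Feature",
    properties = list(length_m = coast$length),
    geometry = list(type = "MultiLineString", coordinates = lines)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10L,
                              null = "null"), path)
  invisible(path)
}

#' Read a coastline written by [write_coastline()] (or any GeoJSON layer of
#' LineString/MultiLineString features)
#'
#' @param path GeoJSON file path.
#' @param allow_geographic accept a geographic CRS.
#' @return A [coastline] object.
#' @export
read_coastline <- function(path, allow_geographic = FALSE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crs <- .gj_crs(obj)
  if (.crs_is_geographic(crs) && !allow_geographic)
    stop("coastline CRS is geographic; a projected CRS is required")
  segs <- list()
  add_line <- function(coords) {
    m <- .gj_ring(coords)
    if (nrow(m) >= 2L)
      segs[[length(segs) + 1L]] <<- cbind(m[-nrow(m), 1L], m[-nrow(m), 2L],
                                          m[-1L, 1L], m[-1L, 2L])
  }
  for (f in obj$features) {
    g <- f$geometry
    if (is.null(g$type)) next
    if (g$type == "LineString") add_line(g$coordinates)
    if (g$type == "MultiLineString") for (ln in g$coordinates) add_line(ln)
  }
  if (!length(segs)) stop("no line features in ", path)
  coastline(do.call(rbind, segs), crs = crs)
}
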
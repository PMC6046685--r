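# Internal planar geometry kernel.
#
# A polygon is a list of rings; a ring is an n x 2 numeric matrix of vertices
# stored open (last vertex != first).  Ring 1 is the exterior shell, further
# rings are holes.  Coordinates are planar map units (meters).  Segments are
# stored as m x 4 matrices with columns x1, y1, x2, y2.
#
# Tolerances: .cb_tol is the geometric coincidence tolerance in map units
# (1e-7 m); coordinates that differ by less are the same point.  It is far
# below any real shared-boundary length and above double-precision noise for
# coordinates up to ~1e7 m (the range of projected CRS).

.cb_tol <- 1e-7

close_ring <- function(m) rbind(m, m[1L, , drop = FALSE])

ring_signed_area <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

poly_area <- function(poly) {
  a <- abs(ring_signed_area(poly[[1L]]))
  if (length(poly) > 1L)
    a <- a - sum(vapply(poly[-1L], function(r) abs(ring_signed_area(r)), 0))
  a
}

ring_segments <- function(m) {
  n <- nrow(m)
  cbind(m[, 1L], m[, 2L], m[c(2:n, 1L), 1L], m[c(2:n, 1L), 2L])
}

poly_segments <- function(poly) {
  do.call(rbind, lapply(poly, ring_segments))
}

poly_bbox <- function(poly) {
  xs <- unlist(lapply(poly, function(r) r[, 1L]))
  ys <- unlist(lapply(poly, function(r) r[, 2L]))
  c(min(xs), min(ys), max(xs), max(ys))
}

seg_length <- function(segs) {
  sqrt((segs[, 3L] - segs[, 1L])^2 + (segs[, 4L] - segs[, 2L])^2)
}

# Distance from point (px, py) to segment (x1,y1)-(x2,y2).
point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / l2
  t <- min(1, max(0, t))
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

# Minimum distance between two segments a and b (each length-4 numeric).
seg_seg_dist <- function(a, b) {
  # proper crossing => distance 0
  d1 <- .orient(a[1L], a[2L], a[3L], a[4L], b[1L], b[2L])
  d2 <- .orient(a[1L], a[2L], a[3L], a[4L], b[3L], b[4L])
  d3 <- .orient(b[1L], b[2L], b[3L], b[4L], a[1L], a[2L])
  d4 <- .orient(b[1L], b[2L], b[3L], b[4L], a[3L], a[4L])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(point_seg_dist(b[1L], b[2L], a[1L], a[2L], a[3L], a[4L]),
      point_seg_dist(b[3L], b[4L], a[1L], a[2L], a[3L], a[4L]),
      point_seg_dist(a[1L], a[2L], b[1L], b[2L], b[3L], b[4L]),
      point_seg_dist(a[3L], a[4L], b[1L], b[2L], b[3L], b[4L]))
}

.orient <- function(ax, ay, bx, by, px, py) {
  (bx - ax) * (py - ay) - (by - ay) * (px - ax)
}

# Collinear overlap of segment b on segment a.  Returns NULL when the
# segments are not collinear or do not overlap by more than tol; otherwise
# c(t0, t1): the overlap interval as arc-length parameters along a.
seg_overlap_interval <- function(a, b, tol = .cb_tol) {
  dx <- a[3L] - a[1L]; dy <- a[4L] - a[2L]
  la <- sqrt(dx * dx + dy * dy)
  if (la <= tol) return(NULL)
  ux <- dx / la; uy <- dy / la
  # both endpoints of b must lie on the supporting line of a
  c1 <- abs(ux * (b[2L] - a[2L]) - uy * (b[1L] - a[1L]))
  c2 <- abs(ux * (b[4L] - a[2L]) - uy * (b[3L] - a[1L]))
  if (c1 > tol || c2 > tol) return(NULL)
  t1 <- (b[1L] - a[1L]) * ux + (b[2L] - a[2L]) * uy
  t2 <- (b[3L] - a[1L]) * ux + (b[4L] - a[2L]) * uy
  lo <- max(0, min(t1, t2)); hi <- min(la, max(t1, t2))
  if (hi - lo <= tol) return(NULL)
  c(lo, hi)
}

seg_point_at <- function(a, t) {
  dx <- a[3L] - a[1L]; dy <- a[4L] - a[2L]
  la <- sqrt(dx * dx + dy * dy)
  c(a[1L] + dx * t / la, a[2L] + dy * t / la)
}

.seg_bbox_disjoint <- function(a, b, tol) {
  max(a[1L], a[3L]) < min(b[1L], b[3L]) - tol ||
  min(a[1L], a[3L]) > max(b[1L], b[3L]) + tol ||
  max(a[2L], a[4L]) < min(b[2L], b[4L]) - tol ||
  min(a[2L], a[4L]) > max(b[2L], b[4L]) + tol
}

# Total length of the shared (collinear, overlapping) boundary between two
# segment sets.  Sub-segments within one valid polygon boundary are disjoint
# along any supporting line, so summing pairwise overlaps never double counts.
shared_boundary_length <- function(segsA, segsB, tol = .cb_tol) {
  total <- 0
  for (i in seq_len(nrow(segsA))) {
    a <- segsA[i, ]
    for (j in seq_len(nrow(segsB))) {
      b <- segsB[j, ]
      if (.seg_bbox_disjoint(a, b, tol)) next
      iv <- seg_overlap_interval(a, b, tol)
      if (!is.null(iv)) total <- total + (iv[2L] - iv[1L])
    }
  }
  total
}

# The shared sub-segments themselves (m x 4 matrix), for coastline derivation.
shared_boundary_segments <- function(segsA, segsB, tol = .cb_tol) {
  out <- list()
  for (i in seq_len(nrow(segsA))) {
    a <- segsA[i, ]
    for (j in seq_len(nrow(segsB))) {
      b <- segsB[j, ]
      if (.seg_bbox_disjoint(a, b, tol)) next
      iv <- seg_overlap_interval(a, b, tol)
      if (!is.null(iv)) {
        p0 <- seg_point_at(a, iv[1L]); p1 <- seg_point_at(a, iv[2L])
        out[[length(out) + 1L]] <- c(p0, p1)
      }
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 4L))
  do.call(rbind, out)
}

# TRUE when the two segment sets touch anywhere (shared point counts).
segments_touch <- function(segsA, segsB, tol = .cb_tol) {
  for (i in seq_len(nrow(segsA))) {
    a <- segsA[i, ]
    for (j in seq_len(nrow(segsB))) {
      b <- segsB[j, ]
      if (.seg_bbox_disjoint(a, b, tol)) next
      if (seg_seg_dist(a, b) <= tol) return(TRUE)
    }
  }
  FALSE
}

# Drop consecutive duplicate vertices and a duplicated closing vertex.
ring_normalize <- function(m, tol = .cb_tol) {
  if (nrow(m) >= 2L) {
    keep <- c(TRUE, sqrt(diff(m[, 1L])^2 + diff(m[, 2L])^2) > tol)
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m)
  if (n >= 2L && sqrt((m[1L, 1L] - m[n, 1L])^2 + (m[1L, 2L] - m[n, 2L])^2) <= tol)
    m <- m[-n, , drop = FALSE]
  m
}

# A ring is simple when no two non-adjacent boundary segments come within
# tol of each other and adjacent segments meet only at their shared vertex.
ring_is_simple <- function(m, tol = .cb_tol) {
  n <- nrow(m)
  if (n < 3L) return(FALSE)
  segs <- ring_segments(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      a <- segs[i, ]; b <- segs[j, ]
      if (adjacent) {
        iv <- seg_overlap_interval(a, b, tol)
        if (!is.null(iv)) return(FALSE)       # spike: segments double back
      } else {
        if (.seg_bbox_disjoint(a, b, tol)) next
        if (seg_seg_dist(a, b) <= tol) return(FALSE)
      }
    }
  }
  TRUE
}

# Crossing point of two non-parallel segments, or NULL when they do not
# cross within their extents (tol-expanded).
.seg_crossing <- function(a, b, tol = .cb_tol) {
  rx <- a[3L] - a[1L]; ry <- a[4L] - a[2L]
  sx <- b[3L] - b[1L]; sy <- b[4L] - b[2L]
  denom <- rx * sy - ry * sx
  la <- sqrt(rx^2 + ry^2); lb <- sqrt(sx^2 + sy^2)
  if (abs(denom) <= tol * la * lb) return(NULL)   # parallel or collinear
  qpx <- b[1L] - a[1L]; qpy <- b[2L] - a[2L]
  t <- (qpx * sy - qpy * sx) / denom
  u <- (qpx * ry - qpy * rx) / denom
  if (t < -tol / la || t > 1 + tol / la) return(NULL)
  if (u < -tol / lb || u > 1 + tol / lb) return(NULL)
  c(a[1L] + t * rx, a[2L] + t * ry, t * la)       # x, y, arclen on a
}

# Repair a (possibly self-intersecting) ring into a list of simple,
# positive-area rings: insert all self-crossing points as vertices, then
# decompose the closed boundary walk into loops at repeated vertices.  A
# bow-tie becomes its two lobes.  Returns an empty list when nothing with
# positive area survives.
repair_ring <- function(m, tol = .cb_tol) {
  m <- ring_normalize(m, tol)
  if (nrow(m) < 3L) return(list())
  if (ring_is_simple(m, tol) && abs(ring_signed_area(m)) > tol^2)
    return(list(m))
  segs <- ring_segments(m)
  n <- nrow(segs)
  extra <- vector("list", n)   # per segment: arclen positions of crossings
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- segs[i, ]; b <- segs[j, ]
      if (.seg_bbox_disjoint(a, b, tol)) next
      p <- .seg_crossing(a, b, tol)
      if (!is.null(p)) {
        extra[[i]] <- rbind(extra[[i]], p)
        # recompute arclen of the same point on segment j
        dxj <- b[3L] - b[1L]; dyj <- b[4L] - b[2L]
        lj <- sqrt(dxj^2 + dyj^2)
        tj <- ((p[1L] - b[1L]) * dxj + (p[2L] - b[2L]) * dyj) / lj
        extra[[j]] <- rbind(extra[[j]], c(p[1L], p[2L], tj))
      }
    }
  }
  verts <- list()
  for (i in seq_len(n)) {
    verts[[length(verts) + 1L]] <- segs[i, 1:2]
    ex <- extra[[i]]
    if (!is.null(ex)) {
      ex <- ex[order(ex[, 3L]), , drop = FALSE]
      for (k in seq_len(nrow(ex)))
        verts[[length(verts) + 1L]] <- ex[k, 1:2]
    }
  }
  vm <- ring_normalize(do.call(rbind, verts), tol)
  # walk the closed sequence, splitting off a loop whenever a vertex repeats
  rings <- list()
  path <- matrix(numeric(0), ncol = 2L)
  walk <- rbind(vm, vm[1L, ])
  for (i in seq_len(nrow(walk))) {
    v <- walk[i, ]
    hit <- 0L
    if (nrow(path) > 0L) {
      d <- sqrt((path[, 1L] - v[1L])^2 + (path[, 2L] - v[2L])^2)
      w <- which(d <= tol)
      if (length(w)) hit <- w[1L]
    }
    if (hit > 0L) {
      loop <- path[hit:nrow(path), , drop = FALSE]
      if (nrow(loop) >= 3L && abs(ring_signed_area(loop)) > tol^2)
        rings[[length(rings) + 1L]] <- loop
      path <- path[seq_len(hit), , drop = FALSE]
    } else {
      path <- rbind(path, v)
    }
  }
  Filter(function(r) ring_is_simple(r, tol), rings)
}

# ---- bounding-box candidate search (the spatial index) ----------------------

# Sweep over xmin-sorted boxes; returns a 2-column matrix of index pairs
# (i < j) whose boxes overlap after tol expansion.
bbox_candidate_pairs <- function(bboxes, tol = .cb_tol) {
  n <- nrow(bboxes)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  ord <- order(bboxes[, 1L])
  out <- list()
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    xmax_i <- bboxes[i, 3L] + tol
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (bboxes[j, 1L] > xmax_i) break
      if (bboxes[i, 2L] <= bboxes[j, 4L] + tol &&
          bboxes[j, 2L] <= bboxes[i, 4L] + tol)
        out[[length(out) + 1L]] <- c(min(i, j), max(i, j))
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, out)
}

.bbox_overlaps <- function(a, b, tol = .cb_tol) {
  a[1L] <= b[3L] + tol && b[1L] <= a[3L] + tol &&
  a[2L] <= b[4L] + tol && b[2L] <= a[4L] + tol
}

# ---- chain assembly ---------------------------------------------------------

.pt_key <- function(x, y, tol) paste(round(x / tol) * tol, round(y / tol) * tol)

# Merge loose segments into polylines (chains) joined at shared endpoints.
# Returns a list of k x 2 vertex matrices; closed chains repeat no vertex
# but have attr "closed" = TRUE.
assemble_chains <- function(segs, tol = 1e-6) {
  m <- nrow(segs)
  if (m == 0L) return(list())
  keys <- cbind(.pt_key(segs[, 1L], segs[, 2L], tol),
                .pt_key(segs[, 3L], segs[, 4L], tol))
  # endpoint -> list of (segment, end) incidences
  inc <- new.env(parent = emptyenv())
  for (i in seq_len(m)) {
    for (e in 1:2) {
      k <- keys[i, e]
      inc[[k]] <- rbind(if (!is.null(inc[[k]])) inc[[k]], c(i, e))
    }
  }
  used <- logical(m)
  chains <- list()
  for (start in seq_len(m)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- rbind(segs[start, 1:2], segs[start, 3:4])
    kf <- keys[start, 2L]; kb <- keys[start, 1L]
    # extend forward then backward
    repeat {
      nxt <- inc[[kf]]
      nxt <- nxt[!used[nxt[, 1L]], , drop = FALSE]
      if (is.null(nxt) || nrow(nxt) == 0L) break
      i <- nxt[1L, 1L]; e <- nxt[1L, 2L]
      used[i] <- TRUE
      other <- if (e == 1L) 2L else 1L
      pts <- rbind(pts, segs[i, if (other == 1L) 1:2 else 3:4])
      kf <- keys[i, other]
    }
    repeat {
      nxt <- inc[[kb]]
      nxt <- nxt[!used[nxt[, 1L]], , drop = FALSE]
      if (is.null(nxt) || nrow(nxt) == 0L) break
      i <- nxt[1L, 1L]; e <- nxt[1L, 2L]
      used[i] <- TRUE
      other <- if (e == 1L) 2L else 1L
      pts <- rbind(segs[i, if (other == 1L) 1:2 else 3:4], pts)
      kb <- keys[i, other]
    }
    closed <- FALSE
    np <- nrow(pts)
    if (np > 2L &&
        sqrt((pts[1L, 1L] - pts[np, 1L])^2 + (pts[1L, 2L] - pts[np, 2L])^2) <= tol) {
      pts <- pts[-np, , drop = FALSE]
      closed <- TRUE
    }
    attr(pts, "closed") <- closed
    chains[[length(chains) + 1L]] <- pts
  }
  chains
}
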
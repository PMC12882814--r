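# Low-level 2-D polygon primitives.
#
# Polygons are numeric n x 2 matrices of vertices in order (open ring: the
# closing edge last->first is implicit). All coordinates are physical microns.
# These primitives back the border-to-border and overlap-area operations; no
# installed package in this stack provides 2-D polygon boolean areas, so the
# (convex-decomposition + clipping) machinery lives here and is validated
# against rasterization oracles in the test suite.

.AREA_EPS <- 1e-9

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p)) {
    stop("a polygon must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  }
  # drop an explicit closing vertex
  n <- nrow(p)
  if (all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  unname(p)
}

polygon_signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

polygon_area_mat <- function(p) abs(polygon_signed_area(p))

polygon_centroid_mat <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .AREA_EPS) return(colMeans(p))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

ensure_ccw <- function(p) {
  if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

polygon_edges <- function(p) {
  n <- nrow(p)
  cbind(p, p[c(2:n, 1L), , drop = FALSE]) # x1 y1 x2 y2
}

polygon_circumradius <- function(p, centroid = polygon_centroid_mat(p)) {
  sqrt(max((p[, 1L] - centroid[1L])^2 + (p[, 2L] - centroid[2L])^2))
}

# Distance from every point (rows of pts, n x 2) to every segment
# (rows of segs, m x 4 as x1,y1,x2,y2); returns an n x m matrix.
point_seg_dist <- function(pts, segs) {
  n <- nrow(pts); m <- nrow(segs)
  px <- matrix(pts[, 1L], n, m); py <- matrix(pts[, 2L], n, m)
  ax <- matrix(segs[, 1L], n, m, byrow = TRUE)
  ay <- matrix(segs[, 2L], n, m, byrow = TRUE)
  vx <- matrix(segs[, 3L] - segs[, 1L], n, m, byrow = TRUE)
  vy <- matrix(segs[, 4L] - segs[, 2L], n, m, byrow = TRUE)
  len2 <- vx * vx + vy * vy
  len2[len2 == 0] <- 1
  tt <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  dx <- px - (ax + tt * vx); dy <- py - (ay + tt * vy)
  sqrt(dx * dx + dy * dy)
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
# Points exactly on the boundary are resolved by callers via a distance test.
point_in_polygon_mat <- function(pts, poly) {
  n <- nrow(poly)
  x <- pts[, 1L]; y <- pts[, 2L]
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from points to the polygon region: 0 inside or on the boundary,
# otherwise the distance to the boundary.
points_region_distance <- function(pts, poly, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  d <- apply(point_seg_dist(pts, polygon_edges(poly)), 1L, min)
  inside <- point_in_polygon_mat(pts, poly)
  d[inside | d <= tol] <- 0
  d
}

# TRUE when any edge of polygon a properly crosses any edge of polygon b.
polygons_edges_cross <- function(a, b) {
  ea <- polygon_edges(a); eb <- polygon_edges(b)
  p <- nrow(ea); q <- nrow(eb)
  a1x <- matrix(ea[, 1L], p, q); a1y <- matrix(ea[, 2L], p, q)
  a2x <- matrix(ea[, 3L], p, q); a2y <- matrix(ea[, 4L], p, q)
  b1x <- matrix(eb[, 1L], p, q, byrow = TRUE); b1y <- matrix(eb[, 2L], p, q, byrow = TRUE)
  b2x <- matrix(eb[, 3L], p, q, byrow = TRUE); b2y <- matrix(eb[, 4L], p, q, byrow = TRUE)
  o <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- o(b1x, b1y, b2x, b2y, a1x, a1y)
  d2 <- o(b1x, b1y, b2x, b2y, a2x, a2y)
  d3 <- o(a1x, a1y, a2x, a2y, b1x, b1y)
  d4 <- o(a1x, a1y, a2x, a2y, b2x, b2y)
  any(((d1 > 0) != (d2 > 0)) & ((d3 > 0) != (d4 > 0)))
}

is_convex_polygon <- function(p, tol = 1e-9) {
  n <- nrow(p)
  nxt <- c(2:n, 1L); nx2 <- c(3:n, 1L, 2L)
  cr <- (p[nxt, 1L] - p[, 1L]) * (p[nx2, 2L] - p[nxt, 2L]) -
        (p[nxt, 2L] - p[, 2L]) * (p[nx2, 1L] - p[nxt, 1L])
  all(cr >= -tol) || all(cr <= tol)
}

# Sutherland-Hodgman clip of an arbitrary subject polygon by a convex CCW
# clip polygon. Returns the clipped polygon matrix or NULL when empty.
clip_convex <- function(subject, clip) {
  out <- subject
  n_c <- nrow(clip)
  for (i in seq_len(n_c)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    c1 <- clip[i, ]; c2 <- clip[if (i == n_c) 1L else i + 1L, ]
    ex <- c2[1L] - c1[1L]; ey <- c2[2L] - c1[2L]
    side <- ex * (out[, 2L] - c1[2L]) - ey * (out[, 1L] - c1[1L])
    keep <- side >= 0
    if (all(keep)) next
    if (!any(keep)) return(NULL)
    m <- nrow(out)
    res_x <- numeric(0); res_y <- numeric(0)
    for (k in seq_len(m)) {
      k2 <- if (k == m) 1L else k + 1L
      s_in <- keep[k]; e_in <- keep[k2]
      if (s_in) { res_x <- c(res_x, out[k, 1L]); res_y <- c(res_y, out[k, 2L]) }
      if (s_in != e_in) {
        denom <- side[k] - side[k2]
        t <- if (denom == 0) 0.5 else side[k] / denom
        res_x <- c(res_x, out[k, 1L] + t * (out[k2, 1L] - out[k, 1L]))
        res_y <- c(res_y, out[k, 2L] + t * (out[k2, 2L] - out[k, 2L]))
      }
    }
    if (length(res_x) < 3L) return(NULL)
    out <- cbind(res_x, res_y)
  }
  if (polygon_area_mat(out) < .AREA_EPS) NULL else unname(out)
}

# Ear-clipping triangulation of a simple polygon; returns a list of CCW
# triangles (3 x 2 matrices).
triangulate_polygon <- function(p) {
  p <- ensure_ccw(as_polygon(p))
  n <- nrow(p)
  if (n == 3L) return(list(p))
  idx <- seq_len(n)
  tris <- vector("list", n - 2L)
  nt <- 0L
  cross_z <- function(a, b, c) {
    (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  }
  in_tri <- function(q, a, b, c) {
    d1 <- cross_z(a, b, q); d2 <- cross_z(b, c, q); d3 <- cross_z(c, a, q)
    (d1 > 1e-12 & d2 > 1e-12 & d3 > 1e-12)
  }
  guard <- 0L
  while (length(idx) > 3L && guard < n * n) {
    guard <- guard + 1L
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      ip <- idx[if (k == 1L) m else k - 1L]
      ic <- idx[k]
      inx <- idx[if (k == m) 1L else k + 1L]
      a <- p[ip, ]; b <- p[ic, ]; c <- p[inx, ]
      if (cross_z(a, b, c) <= 1e-12) next
      others <- setdiff(idx, c(ip, ic, inx))
      blocked <- FALSE
      for (q in others) {
        if (in_tri(p[q, ], a, b, c)) { blocked <- TRUE; break }
      }
      if (blocked) next
      nt <- nt + 1L
      tris[[nt]] <- rbind(a, b, c)
      idx <- idx[-k]
      clipped <- TRUE
      break
    }
    if (!clipped) break # numerically degenerate remainder; fan it below
  }
  if (length(idx) >= 3L) {
    base <- idx[1L]
    for (k in 2:(length(idx) - 1L)) {
      tri <- p[c(base, idx[k], idx[k + 1L]), , drop = FALSE]
      if (polygon_area_mat(tri) > .AREA_EPS) {
        nt <- nt + 1L
        tris[[nt]] <- ensure_ccw(tri)
      }
    }
  }
  tris[seq_len(nt)]
}

# Decompose a simple polygon into convex CCW pieces with disjoint interiors.
convex_pieces <- function(p) {
  p <- as_polygon(p)
  if (is_convex_polygon(p)) list(ensure_ccw(p)) else triangulate_polygon(p)
}

pieces_area <- function(pieces) {
  if (length(pieces) == 0L) return(0)
  sum(vapply(pieces, polygon_area_mat, numeric(1L)))
}

# Pairwise convex intersection of two piece sets; pieces within a set have
# disjoint interiors, so the result does too.
intersect_piece_sets <- function(P, Q) {
  out <- list()
  for (a in P) {
    for (b in Q) {
      cl <- clip_convex(a, b)
      if (!is.null(cl)) out[[length(out) + 1L]] <- cl
    }
  }
  out
}

# Exact area of the union of piece sets:
# area(U A_i) = sum_i [ area(A_i) - area(A_i inter U_{j<i} A_j) ].
union_area_piece_sets <- function(sets) {
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (length(sets) == 0L) return(0)
  tot <- 0
  for (i in seq_along(sets)) {
    a_i <- pieces_area(sets[[i]])
    if (i > 1L) {
      inter <- list()
      for (j in seq_len(i - 1L)) {
        pij <- intersect_piece_sets(sets[[i]], sets[[j]])
        if (length(pij) > 0L) inter[[length(inter) + 1L]] <- pij
      }
      if (length(inter) > 0L) a_i <- a_i - union_area_piece_sets(inter)
    }
    tot <- tot + a_i
  }
  tot
}

#' Regular-polygon approximation of a disk
#'
#' @param center numeric length-2 center (μm).
#' @param area target disk area (μm²); the polygon is inscribed in the circle
#'   of radius `sqrt(area / pi)`.
#' @param n number of vertices.
#' @return an `n` x 2 polygon matrix.
#' @export
disk_polygon <- function(center, area, n = 24L) {
  stop_if_not_scalar_number(area, "area", min = 0, strict_min = TRUE)
  r <- sqrt(area / pi)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

#' Capsule polygon (segment buffered by a radius)
#'
#' Rasterizes the set of points within `radius` of the segment `p1`--`p2`
#' into a convex polygon; used to emulate elongated vessel cross-sections.
#'
#' @param p1,p2 segment endpoints (μm).
#' @param radius buffer radius (μm).
#' @param n_arc vertices per end cap.
#' @return polygon matrix.
#' @export
capsule_polygon <- function(p1, p2, radius, n_arc = 16L) {
  stop_if_not_scalar_number(radius, "radius", min = 0, strict_min = TRUE)
  d <- c(p2[1L] - p1[1L], p2[2L] - p1[2L])
  len <- sqrt(sum(d^2))
  if (len < 1e-12) return(disk_polygon(p1, pi * radius^2, 2L * n_arc))
  ang <- atan2(d[2L], d[1L])
  th1 <- seq(ang + pi / 2, ang + 3 * pi / 2, length.out = n_arc)
  th2 <- seq(ang - pi / 2, ang + pi / 2, length.out = n_arc)
  rbind(
    cbind(p1[1L] + radius * cos(th1), p1[2L] + radius * sin(th1)),
    cbind(p2[1L] + radius * cos(th2), p2[2L] + radius * sin(th2))
  )
}

# Distance from points to the segment p1-p2 (used for capsule placement).
point_segment_distance <- function(pts, p1, p2) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  point_seg_dist(pts, matrix(c(p1, p2), 1L, 4L))[, 1L]
}
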
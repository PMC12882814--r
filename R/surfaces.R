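# SurfaceSet: segmented 2-D marker objects (polygons) with class, area and
# centroid. Stored as a data.frame with a `boundary` list column of n x 2
# vertex matrices, mirroring how segmentation exports carry object outlines.

#' Build a surface set from polygon boundaries
#'
#' @param boundaries list of polygon matrices (n x 2, μm), one per surface.
#' @param marker_class character vector (recycled) naming the marker each
#'   surface was segmented from (e.g. `"FSCN1"`, `"CD31"`, `"LYVE1"`).
#' @param surface_id optional ids; defaults to `s1, s2, ...`.
#' @return a `surface_set`: data.frame with columns `surface_id`,
#'   `marker_class`, `area_um2`, `centroid_x`, `centroid_y` and a `boundary`
#'   list column. Areas are computed from the polygons (shoelace formula).
#' @export
surface_set <- function(boundaries, marker_class = "object", surface_id = NULL) {
  if (!is.list(boundaries)) boundaries <- list(boundaries)
  boundaries <- lapply(boundaries, as_polygon)
  n <- length(boundaries)
  areas <- vapply(boundaries, polygon_area_mat, numeric(1L))
  if (any(areas <= .AREA_EPS)) {
    stop("degenerate polygon with zero area in surface set", call. = FALSE)
  }
  cents <- t(vapply(boundaries, polygon_centroid_mat, numeric(2L)))
  if (is.null(surface_id)) surface_id <- paste0("s", seq_len(n))
  if (anyDuplicated(surface_id)) {
    stop("duplicated surface_id", call. = FALSE)
  }
  out <- data.frame(
    surface_id = as.character(surface_id),
    marker_class = rep_len(as.character(marker_class), n),
    area_um2 = areas,
    centroid_x = cents[, 1L],
    centroid_y = cents[, 2L],
    stringsAsFactors = FALSE
  )
  out$boundary <- boundaries
  class(out) <- c("surface_set", "data.frame")
  out
}

empty_surface_set <- function() {
  out <- data.frame(
    surface_id = character(0), marker_class = character(0),
    area_um2 = numeric(0), centroid_x = numeric(0), centroid_y = numeric(0),
    stringsAsFactors = FALSE
  )
  out$boundary <- list()
  class(out) <- c("surface_set", "data.frame")
  out
}

is_surface_set <- function(x) inherits(x, "surface_set") ||
  (is.data.frame(x) && "boundary" %in% names(x))

validate_surfaces <- function(x, what = "surface set") {
  if (!is_surface_set(x)) {
    stop(sprintf("%s must be a surface_set (see surface_set())", what),
         call. = FALSE)
  }
  invisible(x)
}

# subset rows of a surface_set, keeping the class
surface_subset <- function(x, i) {
  out <- x[i, , drop = FALSE]
  class(out) <- class(x)
  rownames(out) <- NULL
  out
}

#' Border-to-border distance between two surfaces
#'
#' Minimum Euclidean distance between the two polygon boundaries; zero when
#' the polygons overlap or touch. This is the distance the perivascular
#' association rules are phrased in.
#'
#' @param a,b polygon matrices, or single-row `surface_set`s.
#' @return distance in μm (>= 0), symmetric in its arguments.
#' @export
border_distance <- function(a, b) {
  a <- extract_polygon(a); b <- extract_polygon(b)
  poly_pair_distance(a, b)
}

extract_polygon <- function(x) {
  if (is_surface_set(x)) {
    if (nrow(x) != 1L) {
      stop("expected a single surface; subset the surface_set first",
           call. = FALSE)
    }
    return(x$boundary[[1L]])
  }
  as_polygon(x)
}

# Internal pairwise polygon distance with overlap detection.
poly_pair_distance <- function(a, b, tol = 1e-9) {
  d <- min(point_seg_dist(a, polygon_edges(b)),
           point_seg_dist(b, polygon_edges(a)))
  if (d <= tol) return(0)
  ca <- polygon_centroid_mat(a); cb <- polygon_centroid_mat(b)
  ra <- polygon_circumradius(a, ca); rb <- polygon_circumradius(b, cb)
  if (sqrt(sum((ca - cb)^2)) <= ra + rb) {
    if (any(point_in_polygon_mat(a, b)) || any(point_in_polygon_mat(b, a)) ||
        polygons_edges_cross(a, b)) {
      return(0)
    }
  }
  d
}

# Distance from every surface in `a_set` to every surface in `b_set`
# (dense n x m matrix). Used by the small-scale oracles.
surface_distance_matrix <- function(a_set, b_set) {
  n <- nrow(a_set); m <- nrow(b_set)
  out <- matrix(0, n, m, dimnames = list(a_set$surface_id, b_set$surface_id))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- poly_pair_distance(a_set$boundary[[i]], b_set$boundary[[j]])
    }
  }
  out
}

# Per-surface distance to the nearest member of `b_set`, with pruning by
# centroid/circumradius bounds so that only candidate pairs are evaluated
# exactly. Returns list(dist, which).
nearest_surface_distance <- function(a_set, b_set) {
  n <- nrow(a_set); m <- nrow(b_set)
  if (m == 0L) return(list(dist = rep(Inf, n), which = rep(NA_integer_, n)))
  ra <- vapply(seq_len(n), function(i) {
    polygon_circumradius(a_set$boundary[[i]],
                         c(a_set$centroid_x[i], a_set$centroid_y[i]))
  }, numeric(1L))
  rb <- vapply(seq_len(m), function(j) {
    polygon_circumradius(b_set$boundary[[j]],
                         c(b_set$centroid_x[j], b_set$centroid_y[j]))
  }, numeric(1L))
  dist <- rep(Inf, n); whichj <- rep(NA_integer_, n)
  cax <- a_set$centroid_x; cay <- a_set$centroid_y
  cbx <- b_set$centroid_x; cby <- b_set$centroid_y
  for (i in seq_len(n)) {
    dc <- sqrt((cax[i] - cbx)^2 + (cay[i] - cby)^2)
    lb <- pmax(0, dc - ra[i] - rb)    # lower bound on border distance
    ub <- dc                          # centroid distance is an upper bound
    best_ub <- min(ub)
    ord <- order(lb)
    best <- Inf; bj <- NA_integer_
    for (j in ord) {
      if (lb[j] >= best || lb[j] > best_ub) break
      d <- poly_pair_distance(a_set$boundary[[i]], b_set$boundary[[j]])
      if (d < best) { best <- d; bj <- j }
      if (best == 0) break
    }
    dist[i] <- best; whichj[i] <- bj
  }
  list(dist = dist, which = whichj)
}

#' Overlap-area ratio of a surface against a set of surfaces
#'
#' Fraction of the area of `a` covered by the union of `b_set`; the statistic
#' behind the vessel-typing rule (blood vs lymphatic by LYVE-1 overlap) and
#' the Ccl19-coverage rule.
#'
#' @param a polygon matrix or single-row `surface_set`.
#' @param b_set a `surface_set` (possibly empty) or list of polygons.
#' @return fraction in `[0, 1]`.
#' @export
overlap_ratio <- function(a, b_set) {
  a <- extract_polygon(a)
  a_area <- polygon_area_mat(a)
  if (a_area <= .AREA_EPS) stop("degenerate polygon", call. = FALSE)
  polys <- if (is_surface_set(b_set)) b_set$boundary else {
    if (!is.list(b_set)) list(b_set) else b_set
  }
  if (length(polys) == 0L) return(0)
  a_pieces <- convex_pieces(a)
  ca <- polygon_centroid_mat(a)
  rr <- polygon_circumradius(a, ca)
  sets <- list()
  for (b in polys) {
    b <- as_polygon(b)
    cb <- polygon_centroid_mat(b)
    if (sqrt(sum((ca - cb)^2)) > rr + polygon_circumradius(b, cb)) next
    ab <- intersect_piece_sets(a_pieces, convex_pieces(b))
    if (length(ab) > 0L) sets[[length(sets) + 1L]] <- ab
  }
  ratio <- union_area_piece_sets(sets) / a_area
  min(max(ratio, 0), 1)
}
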
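# Detection of dendritic-cell clusters from segmented detections.
#
# Primary rule (2-D whole-section imaging): Delaunay triangulation on
# detection centroids with a 22.5 μm edge cut, followed by a transitive
# border-to-border merge (< 20 μm) and a 500 μm² minimum total-area filter.
# Secondary rule (3-D volumetric imaging): fixed-radius neighbor graph
# (<= 20 μm), minimum 5 members, maximum 100 μm cluster diameter enforced by
# iterative longest-link removal.

#' Filter detections by minimum area
#'
#' Detections with an area smaller than `min_area` are excluded (the boundary
#' value itself is kept: "smaller than" excludes strictly).
#'
#' @param detections a `surface_set`.
#' @param min_area minimum area in μm² (default 5).
#' @return the filtered `surface_set`.
#' @export
filter_detections <- function(detections, min_area = 5) {
  validate_surfaces(detections, "detections")
  stop_if_not_scalar_number(min_area, "min_area", min = 0)
  surface_subset(detections, detections$area_um2 >= min_area)
}

#' Delaunay-graph clustering of DC detections
#'
#' Builds the Delaunay triangulation of detection centroids, keeps edges of
#' length `<= edge_len`, takes connected components as initial clusters,
#' transitively merges clusters containing detections whose border-to-border
#' distance is `< merge_dist`, and finally drops clusters whose total member
#' area is below `min_total_area`.
#'
#' @param detections a pre-filtered `surface_set` (see [filter_detections()]).
#' @param edge_len Delaunay edge cut in μm (default 22.5).
#' @param merge_dist border-to-border merge distance in μm (default 20,
#'   strict `<`).
#' @param min_total_area minimum total cluster area in μm² (default 500;
#'   clusters with area `>= min_total_area` are kept).
#' @return a `cluster_set`: data.frame with `cluster_id`, `n_members`,
#'   `total_area_um2`, `centroid_x`, `centroid_y`, `association` (initially
#'   `"unassigned"`) and a `members` list column of detection ids.
#' @export
delaunay_cluster <- function(detections, edge_len = 22.5, merge_dist = 20,
                             min_total_area = 500) {
  validate_surfaces(detections, "detections")
  stop_if_not_scalar_number(edge_len, "edge_len", min = 0)
  stop_if_not_scalar_number(merge_dist, "merge_dist", min = 0)
  stop_if_not_scalar_number(min_total_area, "min_total_area", min = 0)
  n <- nrow(detections)
  if (n < 2L) {
    if (n == 1L && detections$area_um2[1L] < min_total_area) {
      warning("single detection below min_total_area; no clusters possible")
    }
    return(empty_cluster_set())
  }

  memb <- {
    cents <- data.frame(cell_id = detections$surface_id,
                        x_um = detections$centroid_x,
                        y_um = detections$centroid_y)
    g <- delaunay_graph(cents)
    len <- igraph::edge_attr(g, "length")
    g <- igraph::delete_edges(g, which(len > edge_len))

    # transitive border-to-border merge: add an edge for every detection pair
    # closer than merge_dist (bounding-circle prefilter, exact check after)
    radii <- vapply(seq_len(n), function(i) {
      polygon_circumradius(detections$boundary[[i]],
                           c(detections$centroid_x[i], detections$centroid_y[i]))
    }, numeric(1L))
    extra <- merge_candidate_pairs(detections, radii, merge_dist)
    if (nrow(extra) > 0L) g <- igraph::add_edges(g, as.vector(t(extra)))
    igraph::components(g)$membership
  }

  build_cluster_set(detections, memb, min_total_area)
}

# all detection pairs with border-to-border distance strictly below `cut`
merge_candidate_pairs <- function(detections, radii, cut) {
  n <- nrow(detections)
  cx <- detections$centroid_x; cy <- detections$centroid_y
  out <- matrix(integer(0), 0L, 2L)
  if (n < 2L) return(out)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    dc <- sqrt((cx[i] - cx[js])^2 + (cy[i] - cy[js])^2)
    cand <- js[dc - radii[i] - radii[js] < cut]
    for (j in cand) {
      if (poly_pair_distance(detections$boundary[[i]],
                             detections$boundary[[j]]) < cut) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(pairs) > 0L) out <- do.call(rbind, pairs)
  out
}

empty_cluster_set <- function() {
  out <- data.frame(cluster_id = character(0), n_members = integer(0),
                    total_area_um2 = numeric(0), centroid_x = numeric(0),
                    centroid_y = numeric(0), association = character(0),
                    stringsAsFactors = FALSE)
  out$members <- list()
  class(out) <- c("cluster_set", "data.frame")
  out
}

build_cluster_set <- function(detections, membership, min_total_area) {
  comp_ids <- sort(unique(membership))
  rows <- list()
  for (cid in comp_ids) {
    idx <- which(membership == cid)
    total <- sum(detections$area_um2[idx])
    if (total < min_total_area) next
    w <- detections$area_um2[idx]
    rows[[length(rows) + 1L]] <- list(
      members = detections$surface_id[idx],
      n = length(idx), area = total,
      cx = sum(detections$centroid_x[idx] * w) / sum(w),
      cy = sum(detections$centroid_y[idx] * w) / sum(w)
    )
  }
  if (length(rows) == 0L) return(empty_cluster_set())
  out <- data.frame(
    cluster_id = paste0("cl", seq_along(rows)),
    n_members = vapply(rows, function(r) r$n, integer(1L)),
    total_area_um2 = vapply(rows, function(r) r$area, numeric(1L)),
    centroid_x = vapply(rows, function(r) r$cx, numeric(1L)),
    centroid_y = vapply(rows, function(r) r$cy, numeric(1L)),
    association = "unassigned",
    stringsAsFactors = FALSE
  )
  out$members <- lapply(rows, function(r) r$members)
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Fixed-radius 3-D clustering of DC centroids
#'
#' Links points at mutual distance `<= neighbor_dist`, keeps connected
#' components with at least `min_size` members, and enforces a maximum
#' cluster diameter by repeatedly deleting the longest remaining link inside
#' any oversized component until all diameters comply (a deterministic,
#' order-independent stand-in for manual splitting of merged clusters in
#' DC-rich regions).
#'
#' @param points matrix or data.frame of centroids with 2 or 3 coordinate
#'   columns (μm).
#' @param min_size minimum cluster size (default 5).
#' @param neighbor_dist linkage distance in μm (default 20, `<=`).
#' @param max_diameter maximum allowed cluster diameter in μm (default 100).
#' @return a `cluster_set` (member ids are row indices as character, or
#'   rownames when present).
#' @export
knn_cluster_3d <- function(points, min_size = 5, neighbor_dist = 20,
                           max_diameter = 100) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || !(ncol(pts) %in% c(2L, 3L))) {
    stop("`points` must have 2 or 3 numeric coordinate columns", call. = FALSE)
  }
  ids <- rownames(pts)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(pts)))
  n <- nrow(pts)
  if (n == 0L) return(empty_cluster_set())
  dmat <- as.matrix(stats::dist(pts))
  adj <- dmat <= neighbor_dist & upper.tri(dmat)
  ee <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(ee) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(ee)))
    g <- igraph::set_edge_attr(g, "length", value = dmat[ee])
  }

  repeat {
    comp <- igraph::components(g)$membership
    # diameter = max pairwise member distance (not graph distance)
    oversized <- NULL
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      if (length(idx) < 2L) next
      if (max(dmat[idx, idx]) > max_diameter) { oversized <- c(oversized, cid) }
    }
    if (is.null(oversized)) break
    # delete the single longest edge inside any oversized component
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el) == 0L) break
    lens <- igraph::edge_attr(g, "length")
    in_bad <- comp[el[, 1L]] %in% oversized
    if (!any(in_bad)) break
    cand <- which(in_bad)
    # deterministic tie-break: longest, then smallest endpoint indices
    ord <- cand[order(-lens[cand], el[cand, 1L], el[cand, 2L])]
    g <- igraph::delete_edges(g, ord[1L])
  }

  comp <- igraph::components(g)$membership
  rows <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) < min_size) next
    rows[[length(rows) + 1L]] <- idx
  }
  if (length(rows) == 0L) return(empty_cluster_set())
  out <- data.frame(
    cluster_id = paste0("cl", seq_along(rows)),
    n_members = vapply(rows, length, integer(1L)),
    total_area_um2 = NA_real_,
    centroid_x = vapply(rows, function(i) mean(pts[i, 1L]), numeric(1L)),
    centroid_y = vapply(rows, function(i) mean(pts[i, 2L]), numeric(1L)),
    association = "unassigned",
    stringsAsFactors = FALSE
  )
  out$members <- lapply(rows, function(i) ids[i])
  class(out) <- c("cluster_set", "data.frame")
  out
}
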
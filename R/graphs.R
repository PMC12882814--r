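# Spatial graphs on cell coordinates: Delaunay construction, percentile edge
# pruning, and k-layer ("cell layer") graph neighborhoods.

#' Delaunay graph of a cell map
#'
#' Builds the Delaunay triangulation of the cell centroids and returns it as
#' an undirected [igraph::igraph] whose vertices are named by `cell_id` and
#' whose edges carry their Euclidean `length` in μm. Degenerate inputs are
#' handled explicitly: fewer than 3 points (or all points collinear) yield
#' the complete graph (a chain along the line when all points are collinear),
#' and exactly coincident coordinates are de-duplicated stably -- the first
#' occurrence acts as the representative, the duplicates are attached to it
#' by zero-length edges, and the mapping is kept in the graph attribute
#' `duplicate_map`.
#'
#' @param cells data.frame with `cell_id`, `x_um`, `y_um` columns, or a
#'   two-column coordinate matrix.
#' @return igraph object with vertex attribute `name` and edge attribute
#'   `length`.
#' @export
delaunay_graph <- function(cells) {
  if (is.matrix(cells)) {
    cells <- data.frame(cell_id = paste0("c", seq_len(nrow(cells))),
                        x_um = cells[, 1L], y_um = cells[, 2L])
  }
  check_columns(cells, c("cell_id", "x_um", "y_um"), "cell table")
  ids <- as.character(cells$cell_id)
  if (anyDuplicated(ids)) stop("duplicated cell_id", call. = FALSE)
  x <- as.numeric(cells$x_um); y <- as.numeric(cells$y_um)
  n <- length(x)

  key <- paste(x, y)
  first <- !duplicated(key)
  rep_idx <- match(key, key[first]) # index into unique set per cell
  ux <- x[first]; uy <- y[first]
  uid <- ids[first]
  nu <- length(ux)

  edges_u <- matrix(integer(0), 0L, 2L)
  if (nu == 2L) {
    edges_u <- matrix(c(1L, 2L), 1L, 2L)
  } else if (nu >= 3L) {
    # collinearity check on the unique points
    v1 <- c(ux[2L] - ux[1L], uy[2L] - uy[1L])
    cross <- (ux - ux[1L]) * v1[2L] - (uy - uy[1L]) * v1[1L]
    scale <- max(abs(c(ux - ux[1L], uy - uy[1L], 1e-12)))
    if (all(abs(cross) < 1e-9 * scale^2 + 1e-12)) {
      # all collinear: chain along the line
      proj <- (ux - ux[1L]) * v1[1L] + (uy - uy[1L]) * v1[2L]
      ord <- order(proj)
      edges_u <- cbind(ord[-nu], ord[-1L])
    } else {
      tri <- .delaunay_triangles(ux, uy)
      e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
      e <- t(apply(e, 1L, sort))
      edges_u <- unique(e)
    }
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  ew <- numeric(0)
  eu <- matrix(integer(0), 0L, 2L)
  if (nrow(edges_u) > 0L) {
    # map unique-point indices back to original row indices of the firsts
    firsts <- which(first)
    eu <- cbind(firsts[edges_u[, 1L]], firsts[edges_u[, 2L]])
    ew <- sqrt((x[eu[, 1L]] - x[eu[, 2L]])^2 + (y[eu[, 1L]] - y[eu[, 2L]])^2)
  }
  dup_map <- NULL
  dups <- which(!first)
  if (length(dups) > 0L) {
    reps <- which(first)[rep_idx[dups]]
    eu <- rbind(eu, cbind(dups, reps))
    ew <- c(ew, rep(0, length(dups)))
    dup_map <- data.frame(cell_id = ids[dups],
                          representative_id = ids[reps],
                          stringsAsFactors = FALSE)
  }
  if (nrow(eu) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(eu)))
    g <- igraph::set_edge_attr(g, "length", value = ew)
  }
  g <- igraph::set_graph_attr(g, "duplicate_map", dup_map)
  g
}

#' Prune long graph edges at a length percentile
#'
#' Removes every edge whose length is strictly greater than the given
#' percentile (linear-interpolation convention, as in [stats::quantile()]
#' type 7) of all edge lengths; the node set is unchanged. Pruning at the
#' 99th percentile is the standard cleanup applied to Delaunay graphs before
#' neighborhood statistics, since triangulation edges spanning tissue gaps
#' otherwise connect cells that are not neighbors in any biological sense.
#'
#' @param graph igraph with edge attribute `length`.
#' @param percentile percentile in `[0, 100]` (default 99).
#' @return the pruned igraph.
#' @export
prune_percentile <- function(graph, percentile = 99) {
  stop_if_not_scalar_number(percentile, "percentile", min = 0)
  if (percentile > 100) stop("`percentile` must be <= 100", call. = FALSE)
  len <- igraph::edge_attr(graph, "length")
  if (length(len) == 0L) {
    warning("graph has no edges; returned unchanged")
    return(graph)
  }
  cutoff <- stats::quantile(len, percentile / 100, type = 7, names = FALSE)
  igraph::delete_edges(graph, which(len > cutoff))
}

#' k-layer graph neighborhood of a seed set
#'
#' Returns the ids of all cells within graph distance `k` (hops, "cell
#' layers") of any seed, excluding the seeds themselves. `k = 0` gives the
#' empty set.
#'
#' @param graph igraph with named vertices.
#' @param seeds character vector of seed cell ids (must exist in the graph).
#' @param k number of layers (hops), `>= 0`.
#' @return character vector of cell ids.
#' @export
k_layer_neighborhood <- function(graph, seeds, k) {
  stop_if_not_scalar_number(k, "k", min = 0)
  seeds <- as.character(seeds)
  vn <- igraph::V(graph)$name
  unknown <- setdiff(seeds, vn)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown seed id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (k == 0 || length(seeds) == 0L) return(character(0))
  reach <- igraph::ego(graph, order = k, nodes = seeds, mode = "all",
                       mindist = 0)
  ids <- unique(unlist(lapply(reach, function(v) v$name), use.names = FALSE))
  setdiff(ids, seeds)
}
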
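# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain BFS, the O(n^4) empty-circumcircle
# definition of Delaunay edges, boundary sampling for border distances,
# pixel counting for overlap areas, and a direct union-find clustering
# pipeline.

# ---- BFS neighborhood ------------------------------------------------------
# edges: 2-column integer matrix, n nodes; returns indices within k hops of
# any seed, excluding seeds.
oracle_bfs <- function(edges, n, seeds, k) {
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- rep(Inf, n)
  dist[seeds] <- 0
  frontier <- seeds
  d <- 0
  while (length(frontier) > 0L && d < k) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (dist[w] > d + 1) { dist[w] <- d + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  setdiff(which(dist <= k), seeds)
}

# ---- Delaunay edges by the empty-circumcircle definition -------------------
# A triple forms a Delaunay triangle iff its circumcircle contains no other
# point; the Delaunay edge set is the union of such triangles' edges.
oracle_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3L)
  x <- pts[, 1L]; y <- pts[, 2L]
  trip <- t(utils::combn(n, 3L))
  ax <- x[trip[, 1L]]; ay <- y[trip[, 1L]]
  bx <- x[trip[, 2L]]; by <- y[trip[, 2L]]
  cx <- x[trip[, 3L]]; cy <- y[trip[, 3L]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-12
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  edges <- matrix(integer(0), 0L, 2L)
  for (t in which(ok)) {
    others <- setdiff(seq_len(n), trip[t, ])
    dd <- (x[others] - ux[t])^2 + (y[others] - uy[t])^2
    if (all(dd > r2[t] * (1 - 1e-9))) {
      e <- rbind(trip[t, c(1L, 2L)], trip[t, c(2L, 3L)], trip[t, c(1L, 3L)])
      edges <- rbind(edges, e)
    }
  }
  unique(t(apply(edges, 1L, sort)))
}

# extract the package graph's edge set as a sorted 2-column index matrix
graph_edge_indices <- function(g, ids) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) return(matrix(integer(0), 0L, 2L))
  m <- cbind(match(el[, 1L], ids), match(el[, 2L], ids))
  unique(t(apply(m, 1L, sort)))
}

edge_sets_equal <- function(a, b) {
  key <- function(m) sort(paste(m[, 1L], m[, 2L]))
  identical(key(a), key(b))
}

# ---- border distance by dense boundary sampling ----------------------------
oracle_border_distance <- function(a, b, n_samp = 10000L) {
  samp <- function(p) {
    p2 <- rbind(p, p[1L, ])
    seg_len <- sqrt(rowSums((p2[-1L, , drop = FALSE] - p2[-nrow(p2), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg_len))
    tt <- seq(0, cum[length(cum)], length.out = n_samp)
    i <- findInterval(tt, cum, rightmost.closed = TRUE)
    i[i > nrow(p)] <- nrow(p)
    frac <- (tt - cum[i]) / pmax(seg_len[i], 1e-12)
    p2[i, , drop = FALSE] + (p2[i + 1L, , drop = FALSE] - p2[i, , drop = FALSE]) * frac
  }
  pa <- samp(a); pb <- samp(b)
  # chunked min pairwise distance
  best <- Inf
  chunk <- 500L
  for (s in seq(1L, nrow(pa), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pa))
    d2 <- outer(pa[s:e, 1L], pb[, 1L], "-")^2 + outer(pa[s:e, 2L], pb[, 2L], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# ---- overlap ratio by pixel counting ---------------------------------------
oracle_overlap_raster <- function(a, b_list, res = 400L) {
  xr <- range(a[, 1L]); yr <- range(a[, 2L])
  gx <- seq(xr[1L], xr[2L], length.out = res)
  gy <- seq(yr[1L], yr[2L], length.out = res)
  pts <- cbind(rep(gx, times = res), rep(gy, each = res))
  pip <- function(poly, pts) {
    n <- nrow(poly); inside <- rep(FALSE, nrow(pts)); j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1L]; yi <- poly[i, 2L]; xj <- poly[j, 1L]; yj <- poly[j, 2L]
      inside <- xor(inside, ((yi > pts[, 2L]) != (yj > pts[, 2L])) &
                      (pts[, 1L] < (xj - xi) * (pts[, 2L] - yi) / (yj - yi) + xi))
      j <- i
    }
    inside
  }
  in_a <- pip(a, pts)
  if (!any(in_a)) return(0)
  in_b <- rep(FALSE, sum(in_a))
  sub <- pts[in_a, , drop = FALSE]
  for (b in b_list) in_b <- in_b | pip(b, sub)
  mean(in_b)
}

# ---- brute-force clustering pipeline ---------------------------------------
# Simple union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, a, b) { p[uf_find(p, a)] <- uf_find(p, b); p }

# independent polygon border distance: vertex-to-segment both directions
oracle_poly_dist <- function(a, b) {
  seg_d <- function(pts, poly) {
    p2 <- rbind(poly, poly[1L, ])
    best <- rep(Inf, nrow(pts))
    for (k in seq_len(nrow(poly))) {
      a1 <- p2[k, ]; a2 <- p2[k + 1L, ]
      v <- a2 - a1
      l2 <- sum(v^2)
      tt <- pmin(1, pmax(0, ((pts[, 1L] - a1[1L]) * v[1L] +
                               (pts[, 2L] - a1[2L]) * v[2L]) / l2))
      dx <- pts[, 1L] - (a1[1L] + tt * v[1L])
      dy <- pts[, 2L] - (a1[2L] + tt * v[2L])
      best <- pmin(best, sqrt(dx^2 + dy^2))
    }
    best
  }
  min(seg_d(a, b), seg_d(b, a))
}

# detections: surface_set; returns list of sorted member-id character vectors
oracle_cluster_partition <- function(detections, delaunay_edges_idx,
                                     edge_len = 22.5, merge_dist = 20,
                                     min_total_area = 500) {
  n <- nrow(detections)
  cx <- detections$centroid_x; cy <- detections$centroid_y
  p <- uf_new(n)
  if (nrow(delaunay_edges_idx) > 0L) {
    for (r in seq_len(nrow(delaunay_edges_idx))) {
      i <- delaunay_edges_idx[r, 1L]; j <- delaunay_edges_idx[r, 2L]
      if (sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2) <= edge_len) {
        p <- uf_union(p, i, j)
      }
    }
  }
  rmax <- max(vapply(seq_len(n), function(i) {
    max(sqrt((detections$boundary[[i]][, 1L] - cx[i])^2 +
               (detections$boundary[[i]][, 2L] - cy[i])^2))
  }, numeric(1L)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dc <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
      if (dc - 2 * rmax >= merge_dist) next
      if (oracle_poly_dist(detections$boundary[[i]],
                           detections$boundary[[j]]) < merge_dist) {
        p <- uf_union(p, i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(p, i), integer(1L))
  out <- list()
  for (rt in unique(roots)) {
    idx <- which(roots == rt)
    if (sum(detections$area_um2[idx]) < min_total_area) next
    out[[length(out) + 1L]] <- sort(detections$surface_id[idx])
  }
  out[order(vapply(out, `[`, character(1L), 1L))]
}

partition_from_cluster_set <- function(cl) {
  out <- lapply(cl$members, sort)
  out[order(vapply(out, `[`, character(1L), 1L))]
}

# random simple (convex) polygon helper
random_convex_polygon <- function(center, radius, n = 10L) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.4 * radius, radius)
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# square polygon with exact area
square_polygon <- function(center, area) {
  s <- sqrt(area) / 2
  cbind(center[1L] + c(-s, s, s, -s), center[2L] + c(-s, -s, s, s))
}

# random episode schedule for track tests: per-Treg non-overlapping episodes
# with >= 2 idle frames between them, random DC partners
random_episode_schedule <- function(n_episodes, n_dc, n_treg, n_frames,
                                    max_len = 6L) {
  eps <- list()
  next_free <- rep(0L, n_treg)
  g <- 0L
  while (length(eps) < n_episodes) {
    g <- g %% n_treg + 1L
    if (next_free[g] >= n_frames - 2L) {
      if (all(next_free >= n_frames - 2L)) break
      next
    }
    start <- next_free[g] + sample(0:2, 1L)
    len <- sample(seq_len(max_len), 1L)
    end <- min(start + len - 1L, n_frames - 1L)
    if (start > n_frames - 1L) { next_free[g] <- n_frames; next }
    eps[[length(eps) + 1L]] <- data.frame(
      dc_id = paste0("dc", sample(n_dc, 1L)),
      treg_id = paste0("treg", g),
      start_frame = start, end_frame = end, stringsAsFactors = FALSE
    )
    next_free[g] <- end + 2L
  }
  do.call(rbind, eps)
}
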
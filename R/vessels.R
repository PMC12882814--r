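# Vessel classification and perivascular niche assignment.
#
# Blood vs lymphatic vessels are distinguished on CD31+ surfaces by their
# overlap-area ratio to LYVE-1+ surfaces (0.01% rule); DCs and DC clusters
# are assigned to the nearer vessel class within an association cutoff
# (20 μm border-to-border in mouse sections; 50 μm border / 100 μm centroid
# dialects for the human imaging platforms).

#' Association rule configuration
#'
#' @param vessel_cutoff association cutoff in μm; cells farther than this
#'   from every vessel are non-vessel-associated. Default 20.
#' @param cluster_area_fraction minimum fraction of a cluster's member area
#'   that must lie within the cutoff of a vessel class for the cluster to be
#'   associated (default 0.5).
#' @param mode `"border"` (border-to-border) or `"centroid"`
#'   (centroid-to-centroid) distances.
#' @param preset one of `"mouse"` (20 μm border), `"human_fast"` (50 μm
#'   border), `"human_multispectral"` (100 μm centroid); overrides
#'   `vessel_cutoff`/`mode`.
#' @return an `association_config` list.
#' @export
association_config <- function(vessel_cutoff = 20, cluster_area_fraction = 0.5,
                               mode = c("border", "centroid"), preset = NULL) {
  mode <- match.arg(mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("mouse", "human_fast", "human_multispectral"))
    if (preset == "mouse") { vessel_cutoff <- 20; mode <- "border" }
    if (preset == "human_fast") { vessel_cutoff <- 50; mode <- "border" }
    if (preset == "human_multispectral") { vessel_cutoff <- 100; mode <- "centroid" }
  }
  stop_if_not_scalar_number(vessel_cutoff, "vessel_cutoff", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(cluster_area_fraction, "cluster_area_fraction",
                            min = 0, strict_min = TRUE)
  if (cluster_area_fraction > 1) {
    stop("`cluster_area_fraction` must be <= 1", call. = FALSE)
  }
  structure(list(vessel_cutoff = vessel_cutoff,
                 cluster_area_fraction = cluster_area_fraction,
                 mode = mode),
            class = "association_config")
}

#' Classify CD31+ surfaces as blood or lymphatic vessels
#'
#' A CD31+ surface is lymphatic (LV) when its overlap-area ratio to the
#' union of LYVE-1+ surfaces is at least `ratio_cutoff` (default 0.01%),
#' blood (BV) otherwise.
#'
#' @param cd31 `surface_set` of CD31+ vessel surfaces.
#' @param lyve1 `surface_set` of LYVE-1+ surfaces (may be empty).
#' @param ratio_cutoff overlap-ratio threshold (default `1e-4`, i.e. 0.01%);
#'   a ratio exactly at the cutoff classifies as LV.
#' @return a `vessel_set`: the `cd31` surfaces with added `class`
#'   (`"BV"`/`"LV"`), `lyve1_overlap_ratio`, and `ccl19_covered` (`NA` until
#'   [ccl19_coverage()] is run).
#' @export
classify_vessels <- function(cd31, lyve1, ratio_cutoff = 1e-4) {
  validate_surfaces(cd31, "cd31")
  validate_surfaces(lyve1, "lyve1")
  n <- nrow(cd31)
  ratios <- vapply(seq_len(n), function(i) {
    overlap_ratio(surface_subset(cd31, i), lyve1)
  }, numeric(1L))
  out <- cd31
  out$class <- ifelse(ratios >= ratio_cutoff, "LV", "BV")
  out$lyve1_overlap_ratio <- ratios
  out$ccl19_covered <- NA
  class(out) <- unique(c("vessel_set", class(out)))
  out
}

#' Assign DCs to blood-vessel, lymphatic, or non-vessel niches
#'
#' A DC farther than the cutoff from every vessel is non-vessel-associated
#' (`"none"`). Otherwise it takes the class of the nearer of (closest BV,
#' closest LV); an exact tie within the cutoff is resolved to BV
#' deterministically. When one vessel class is entirely absent the remaining
#' class wins by default and this is flagged in the `missing_class`
#' attribute of the result.
#'
#' @param dcs `surface_set` of DC detections (border mode) -- in centroid
#'   mode only centroids are used, so a cell table with `x_um`/`y_um` is also
#'   accepted.
#' @param vessels a `vessel_set` (see [classify_vessels()]).
#' @param cfg an [association_config()].
#' @return data.frame with `surface_id`, `d_bv`, `d_lv` (μm; `Inf` when the
#'   class is absent) and `label` in `{"BV", "LV", "none"}`.
#' @export
associate_cells <- function(dcs, vessels, cfg = association_config()) {
  validate_surfaces(vessels, "vessels")
  if (!"class" %in% names(vessels)) {
    stop("`vessels` must carry a class column (see classify_vessels())",
         call. = FALSE)
  }
  bv <- surface_subset(vessels, vessels$class == "BV")
  lv <- surface_subset(vessels, vessels$class == "LV")
  missing_class <- c(if (nrow(bv) == 0L) "BV", if (nrow(lv) == 0L) "LV")

  if (cfg$mode == "centroid") {
    if (is_surface_set(dcs)) {
      pts <- cbind(dcs$centroid_x, dcs$centroid_y)
      ids <- dcs$surface_id
    } else {
      check_columns(dcs, c("x_um", "y_um"), "dcs")
      pts <- cbind(dcs$x_um, dcs$y_um)
      ids <- if ("cell_id" %in% names(dcs)) dcs$cell_id else
        if ("surface_id" %in% names(dcs)) dcs$surface_id else
          paste0("c", seq_len(nrow(pts)))
    }
    cdist <- function(vs) {
      if (nrow(vs) == 0L) return(rep(Inf, nrow(pts)))
      apply(cbind(outer(pts[, 1L], vs$centroid_x, "-")^2 +
                    outer(pts[, 2L], vs$centroid_y, "-")^2), 1L,
            function(r) sqrt(min(r)))
    }
    d_bv <- cdist(bv); d_lv <- cdist(lv)
  } else {
    validate_surfaces(dcs, "dcs")
    ids <- dcs$surface_id
    d_bv <- if (nrow(bv) > 0L) nearest_surface_distance(dcs, bv)$dist else
      rep(Inf, nrow(dcs))
    d_lv <- if (nrow(lv) > 0L) nearest_surface_distance(dcs, lv)$dist else
      rep(Inf, nrow(dcs))
  }

  nearest <- pmin(d_bv, d_lv)
  label <- ifelse(nearest > cfg$vessel_cutoff, "none",
                  ifelse(d_bv <= d_lv, "BV", "LV"))
  label[!is.finite(nearest)] <- "none"
  out <- data.frame(surface_id = ids, d_bv = d_bv, d_lv = d_lv,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "missing_class") <- missing_class
  out
}

#' Assign DC clusters to vessel classes by proximal area
#'
#' For each cluster, the fraction of member area lying within the cutoff of
#' each vessel class is computed; the cluster is associated with a class
#' reaching at least `cluster_area_fraction` of its area. When both classes
#' qualify, the class with the larger proximal area wins (exact ties go to
#' BV).
#'
#' @param clusters a `cluster_set` (see [delaunay_cluster()]).
#' @param detections the `surface_set` the clusters were built from.
#' @param vessels a `vessel_set`.
#' @param cfg an [association_config()].
#' @return the `cluster_set` with `association` filled in
#'   (`"BV"`/`"LV"`/`"none"`) plus `bv_area_fraction`, `lv_area_fraction`.
#' @export
associate_clusters <- function(clusters, detections, vessels,
                               cfg = association_config()) {
  validate_surfaces(detections, "detections")
  assoc <- associate_cells(detections, vessels, cfg)
  near_bv <- assoc$d_bv <= cfg$vessel_cutoff
  near_lv <- assoc$d_lv <= cfg$vessel_cutoff
  idx <- match(assoc$surface_id, detections$surface_id)
  area <- detections$area_um2[idx]
  key <- stats::setNames(seq_len(nrow(assoc)), assoc$surface_id)

  bv_frac <- numeric(nrow(clusters)); lv_frac <- numeric(nrow(clusters))
  label <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    rows <- key[clusters$members[[i]]]
    tot <- sum(area[rows])
    bf <- sum(area[rows][near_bv[rows]]) / tot
    lf <- sum(area[rows][near_lv[rows]]) / tot
    bv_frac[i] <- bf; lv_frac[i] <- lf
    qual_bv <- bf >= cfg$cluster_area_fraction
    qual_lv <- lf >= cfg$cluster_area_fraction
    label[i] <- if (qual_bv && qual_lv) {
      if (bf >= lf) "BV" else "LV"
    } else if (qual_bv) "BV" else if (qual_lv) "LV" else "none"
  }
  clusters$association <- label
  clusters$bv_area_fraction <- bv_frac
  clusters$lv_area_fraction <- lv_frac
  clusters
}

#' Flag Ccl19-covered vessels
#'
#' A vessel is Ccl19-covered when its overlap-area ratio to Ccl19+ surfaces
#' is strictly greater than zero. Also returns the covered / non-covered
#' area fractions among blood vessels (normalized to total BV area).
#'
#' @param vessels a `vessel_set`.
#' @param ccl19 `surface_set` of Ccl19+ surfaces.
#' @return the `vessel_set` with `ccl19_covered` and `ccl19_overlap_ratio`
#'   filled in; attribute `bv_area_fractions` holds
#'   `c(covered = ..., non_covered = ...)` (they sum to 1 when BVs exist).
#' @export
ccl19_coverage <- function(vessels, ccl19) {
  validate_surfaces(vessels, "vessels")
  validate_surfaces(ccl19, "ccl19")
  n <- nrow(vessels)
  ratios <- vapply(seq_len(n), function(i) {
    overlap_ratio(surface_subset(vessels, i), ccl19)
  }, numeric(1L))
  vessels$ccl19_overlap_ratio <- ratios
  vessels$ccl19_covered <- ratios > 0
  bv <- vessels$class == "BV"
  tot <- sum(vessels$area_um2[bv])
  fr <- if (tot > 0) {
    cov <- sum(vessels$area_um2[bv & vessels$ccl19_covered]) / tot
    c(covered = cov, non_covered = 1 - cov)
  } else c(covered = NA_real_, non_covered = NA_real_)
  attr(vessels, "bv_area_fractions") <- fr
  vessels
}

#' Cluster membership in CCL21+ regions
#'
#' A cluster lies within a CCL21+ region when at least one of its member
#' detections has a centroid-to-border distance of zero to some region,
#' i.e. its centroid is inside or on the region polygon.
#'
#' @param clusters a `cluster_set`.
#' @param detections the member `surface_set`.
#' @param regions `surface_set` of CCL21+ region polygons.
#' @return logical vector, one entry per cluster.
#' @export
ccl21_membership <- function(clusters, detections, regions) {
  validate_surfaces(detections, "detections")
  validate_surfaces(regions, "regions")
  pts <- cbind(detections$centroid_x, detections$centroid_y)
  inside <- rep(FALSE, nrow(detections))
  for (j in seq_len(nrow(regions))) {
    d <- points_region_distance(pts, regions$boundary[[j]])
    inside <- inside | (d == 0)
  }
  key <- stats::setNames(inside, detections$surface_id)
  vapply(clusters$members, function(m) any(key[m]), logical(1L))
}

#' Total proximal DC area per vessel
#'
#' Sums the areas of DC surfaces whose border-to-border distance to the
#' vessel is at most `cutoff` and labels the vessel "cluster-associated"
#' when that total reaches `cluster_area`.
#'
#' @param vessels a `vessel_set` (or any `surface_set`).
#' @param dcs DC `surface_set`.
#' @param cutoff proximity cutoff in μm (default 20).
#' @param cluster_area area threshold in μm² (default 500, `>=`).
#' @return data.frame with `vessel_id`, `dc_area_um2`, `cluster_associated`.
#' @export
vessel_dc_load <- function(vessels, dcs, cutoff = 20, cluster_area = 500) {
  validate_surfaces(vessels, "vessels")
  validate_surfaces(dcs, "dcs")
  n <- nrow(vessels); m <- nrow(dcs)
  total <- numeric(n)
  if (m > 0L) {
    r_dc <- vapply(seq_len(m), function(i) {
      polygon_circumradius(dcs$boundary[[i]],
                           c(dcs$centroid_x[i], dcs$centroid_y[i]))
    }, numeric(1L))
    for (i in seq_len(n)) {
      vb <- vessels$boundary[[i]]
      cv <- c(vessels$centroid_x[i], vessels$centroid_y[i])
      rv <- polygon_circumradius(vb, cv)
      dc_cent <- sqrt((dcs$centroid_x - cv[1L])^2 + (dcs$centroid_y - cv[2L])^2)
      lb <- dc_cent - r_dc - rv
      cand <- which(lb <= cutoff)
      keep <- logical(length(cand))
      for (k in seq_along(cand)) {
        j <- cand[k]
        keep[k] <- if (dc_cent[j] <= cutoff) TRUE else
          poly_pair_distance(dcs$boundary[[j]], vb) <= cutoff
      }
      total[i] <- sum(dcs$area_um2[cand[keep]])
    }
  }
  data.frame(vessel_id = vessels$surface_id, dc_area_um2 = total,
             cluster_associated = total >= cluster_area,
             stringsAsFactors = FALSE)
}
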
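# Synthetic tissue scenes with planted ground truth.
#
# The generator emulates the structures the static pipeline quantifies:
# elongated vessel cross-sections (capsules) classified blood/lymphatic,
# Ccl19 shells around a subset of blood vessels, dendritic-cell detections
# (disks) planted either perivascularly -- within the association cutoff of
# an anchor vessel -- or away from all vessels, plus unconstrained T-cell and
# background populations. Because placement is constraint-based (rejection
# sampling with explicit clearances), the planted association labels are
# geometrically consistent and downstream estimators can be validated
# against them exactly.

#' Configuration for a synthetic tissue scene
#'
#' @param field_width,field_height field size in μm.
#' @param n_vessels_bv,n_vessels_lv number of blood / lymphatic vessels.
#' @param vessel_radius_range length-2 range of vessel radii (μm).
#' @param vessel_length_range length-2 range of vessel segment lengths (μm).
#' @param n_dc,n_treg,n_other population sizes.
#' @param perivascular_fraction fraction of DCs planted within
#'   `vessel_cutoff` (border-to-border) of an anchor blood vessel.
#' @param lv_fraction fraction of DCs planted against lymphatic vessels
#'   (default 0); `perivascular_fraction + lv_fraction <= 1`, the remainder
#'   is placed more than `vessel_cutoff + nonvessel_margin` from any vessel.
#' @param cluster_dispersion Gaussian spread (μm) of planted DCs along their
#'   anchor vessel axis; small values give tight perivascular clusters.
#' @param ccl19_cover_fraction fraction of blood vessels wrapped by a Ccl19
#'   shell surface.
#' @param dc_area_range length-2 range of DC detection areas (μm²).
#' @param vessel_cutoff association cutoff used for planting (μm).
#' @param nonvessel_margin extra clearance (μm) enforced for non-associated
#'   DCs beyond the cutoff.
#' @param sample_id sample label written into the cell table.
#' @param seed integer seed; fixed seed gives byte-identical scenes.
#' @return a `scene_config` list.
#' @export
scene_config <- function(field_width = 1000, field_height = 1000,
                         n_vessels_bv = 8, n_vessels_lv = 5,
                         vessel_radius_range = c(5, 12),
                         vessel_length_range = c(40, 120),
                         n_dc = 300, n_treg = 150, n_other = 600,
                         perivascular_fraction = 0.4, lv_fraction = 0,
                         cluster_dispersion = 10,
                         ccl19_cover_fraction = 0.5,
                         dc_area_range = c(20, 60),
                         vessel_cutoff = 20, nonvessel_margin = 10,
                         sample_id = "scene1", seed = 1L) {
  stop_if_not_scalar_number(field_width, "field_width", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(field_height, "field_height", min = 0, strict_min = TRUE)
  for (nm in c("n_vessels_bv", "n_vessels_lv", "n_dc", "n_treg", "n_other")) {
    v <- get(nm)
    stop_if_not_scalar_number(v, nm, min = 0)
    if (v != round(v)) stop(sprintf("`%s` must be an integer count", nm), call. = FALSE)
  }
  for (nm in c("perivascular_fraction", "lv_fraction", "ccl19_cover_fraction")) {
    v <- get(nm)
    stop_if_not_scalar_number(v, nm, min = 0)
    if (v > 1) stop(sprintf("`%s` must be <= 1", nm), call. = FALSE)
  }
  if (perivascular_fraction + lv_fraction > 1) {
    stop("perivascular_fraction + lv_fraction must be <= 1", call. = FALSE)
  }
  stop_if_not_scalar_number(vessel_cutoff, "vessel_cutoff", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(cluster_dispersion, "cluster_dispersion", min = 0)
  cfg <- list(
    field_width = field_width, field_height = field_height,
    n_vessels_bv = as.integer(n_vessels_bv), n_vessels_lv = as.integer(n_vessels_lv),
    vessel_radius_range = as.numeric(vessel_radius_range),
    vessel_length_range = as.numeric(vessel_length_range),
    n_dc = as.integer(n_dc), n_treg = as.integer(n_treg),
    n_other = as.integer(n_other),
    perivascular_fraction = perivascular_fraction, lv_fraction = lv_fraction,
    cluster_dispersion = cluster_dispersion,
    ccl19_cover_fraction = ccl19_cover_fraction,
    dc_area_range = as.numeric(dc_area_range),
    vessel_cutoff = vessel_cutoff, nonvessel_margin = nonvessel_margin,
    sample_id = sample_id, seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  cfg
}

# minimum distance between two segments (p1-p2, q1-q2)
segment_segment_distance <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2); d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
  if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(0)
  min(point_segment_distance(rbind(p1, p2), q1, q2),
      point_segment_distance(rbind(q1, q2), p1, p2))
}

#' Generate a synthetic tissue scene
#'
#' @param config a [scene_config()].
#' @return a list of class `dc_scene` with elements
#'   `cells` (cell table: DCs, Tregs, background cells),
#'   `detections` (DC `surface_set`, marker `FSCN1`),
#'   `surfaces` (list of raw marker `surface_set`s: `cd31`, `lyve1`, `ccl19`),
#'   `vessels` (ground-truth vessel set with `class` and `ccl19_covered`),
#'   `truth` (planted per-DC association labels and anchors), and `config`.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) {
    stop("`config` must be created with scene_config()", call. = FALSE)
  }
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  W <- cfg$field_width; H <- cfg$field_height
  cutoff <- cfg$vessel_cutoff
  n_v <- cfg$n_vessels_bv + cfg$n_vessels_lv
  # clearance between vessel surfaces so that a DC planted against one vessel
  # is unambiguously closer to it than to any other vessel
  clearance <- 2 * cutoff + 2 * sqrt(max(cfg$dc_area_range) / pi) + 10
  pad <- max(cfg$vessel_radius_range) + cutoff + 8

  axes <- vector("list", n_v)
  radii <- numeric(n_v)
  for (i in seq_len(n_v)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      len <- runif(1, cfg$vessel_length_range[1L], cfg$vessel_length_range[2L])
      r <- runif(1, cfg$vessel_radius_range[1L], cfg$vessel_radius_range[2L])
      ang <- runif(1, 0, pi)
      cx <- runif(1, pad + len / 2, W - pad - len / 2)
      cy <- runif(1, pad + len / 2, H - pad - len / 2)
      p1 <- c(cx - cos(ang) * len / 2, cy - sin(ang) * len / 2)
      p2 <- c(cx + cos(ang) * len / 2, cy + sin(ang) * len / 2)
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          d <- segment_segment_distance(p1, p2, axes[[j]]$p1, axes[[j]]$p2) -
            r - radii[j]
          if (d < clearance) { ok <- FALSE; break }
        }
      }
      if (ok) {
        axes[[i]] <- list(p1 = p1, p2 = p2)
        radii[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place vessels with the required clearance; ",
           "reduce vessel counts or enlarge the field", call. = FALSE)
    }
  }

  vclass <- c(rep("BV", cfg$n_vessels_bv), rep("LV", cfg$n_vessels_lv))
  vid <- paste0("v", seq_len(n_v))
  cd31_polys <- lapply(seq_len(n_v), function(i) {
    capsule_polygon(axes[[i]]$p1, axes[[i]]$p2, radii[i])
  })
  cd31 <- if (n_v > 0L) {
    surface_set(cd31_polys, marker_class = "CD31", surface_id = vid)
  } else empty_surface_set()

  lv_idx <- which(vclass == "LV")
  lyve1 <- if (length(lv_idx) > 0L) {
    surface_set(lapply(lv_idx, function(i) {
      capsule_polygon(axes[[i]]$p1, axes[[i]]$p2, radii[i] * 0.8)
    }), marker_class = "LYVE1", surface_id = paste0("ly", seq_along(lv_idx)))
  } else empty_surface_set()

  bv_idx <- which(vclass == "BV")
  n_cov <- round(cfg$ccl19_cover_fraction * length(bv_idx))
  cov_idx <- if (n_cov > 0L) sort(sample(bv_idx, n_cov)) else integer(0)
  ccl19 <- if (length(cov_idx) > 0L) {
    surface_set(lapply(cov_idx, function(i) {
      capsule_polygon(axes[[i]]$p1, axes[[i]]$p2, radii[i] + 3)
    }), marker_class = "Ccl19", surface_id = paste0("cc", seq_along(cov_idx)))
  } else empty_surface_set()

  vessels <- if (n_v > 0L) {
    v <- cd31
    v$class <- vclass
    v$ccl19_covered <- seq_len(n_v) %in% cov_idx
    class(v) <- c("vessel_set", class(v))
    v
  } else {
    v <- empty_surface_set()
    v$class <- character(0); v$ccl19_covered <- logical(0)
    class(v) <- c("vessel_set", class(v))
    v
  }

  # ---- dendritic cells -------------------------------------------------
  n_pv <- round(cfg$perivascular_fraction * cfg$n_dc)
  n_lv <- round(cfg$lv_fraction * cfg$n_dc)
  n_none <- cfg$n_dc - n_pv - n_lv
  if (n_pv > 0L && length(bv_idx) == 0L) {
    stop("perivascular_fraction > 0 requires at least one blood vessel", call. = FALSE)
  }
  if (n_lv > 0L && length(lv_idx) == 0L) {
    stop("lv_fraction > 0 requires at least one lymphatic vessel", call. = FALSE)
  }

  anchor_t <- runif(n_v, 0.25, 0.75) # cluster anchor position along each axis

  place_anchored <- function(k, pool) {
    anchors <- pool[1L + (seq_len(k) - 1L) %% length(pool)]
    out <- matrix(0, k, 2L)
    areas <- runif(k, cfg$dc_area_range[1L], cfg$dc_area_range[2L])
    for (m in seq_len(k)) {
      i <- anchors[m]
      ax <- axes[[i]]
      v <- ax$p2 - ax$p1
      len <- sqrt(sum(v^2)); u <- v / len
      nrm <- c(-u[2L], u[1L])
      tpos <- min(max(rnorm(1, anchor_t[i] * len, cfg$cluster_dispersion), 0), len)
      side <- sample(c(-1, 1), 1L)
      gap <- runif(1, 0.05, 0.9) * cutoff
      r_dc <- sqrt(areas[m] / pi)
      p <- ax$p1 + u * tpos + nrm * side * (radii[i] + r_dc + gap)
      out[m, ] <- p
    }
    list(xy = out, areas = areas, anchor = vid[anchors])
  }

  dc_xy <- matrix(numeric(0), 0L, 2L)
  dc_area <- numeric(0)
  dc_label <- character(0)
  dc_anchor <- character(0)
  if (n_pv > 0L) {
    g <- place_anchored(n_pv, bv_idx)
    dc_xy <- rbind(dc_xy, g$xy); dc_area <- c(dc_area, g$areas)
    dc_label <- c(dc_label, rep("BV", n_pv)); dc_anchor <- c(dc_anchor, g$anchor)
  }
  if (n_lv > 0L) {
    g <- place_anchored(n_lv, lv_idx)
    dc_xy <- rbind(dc_xy, g$xy); dc_area <- c(dc_area, g$areas)
    dc_label <- c(dc_label, rep("LV", n_lv)); dc_anchor <- c(dc_anchor, g$anchor)
  }
  if (n_none > 0L) {
    far <- cutoff + cfg$nonvessel_margin
    xs <- numeric(n_none); ys <- numeric(n_none)
    areas <- runif(n_none, cfg$dc_area_range[1L], cfg$dc_area_range[2L])
    for (m in seq_len(n_none)) {
      r_dc <- sqrt(areas[m] / pi)
      ok <- FALSE
      for (try in seq_len(10000L)) {
        p <- c(runif(1, r_dc, W - r_dc), runif(1, r_dc, H - r_dc))
        good <- TRUE
        for (i in seq_len(n_v)) {
          d <- point_segment_distance(p, axes[[i]]$p1, axes[[i]]$p2) -
            radii[i] - r_dc
          if (d <= far) { good <- FALSE; break }
        }
        if (good) { xs[m] <- p[1L]; ys[m] <- p[2L]; ok <- TRUE; break }
      }
      if (!ok) stop("field too crowded to place non-vessel DCs", call. = FALSE)
    }
    dc_xy <- rbind(dc_xy, cbind(xs, ys)); dc_area <- c(dc_area, areas)
    dc_label <- c(dc_label, rep("none", n_none))
    dc_anchor <- c(dc_anchor, rep(NA_character_, n_none))
  }

  detections <- if (cfg$n_dc > 0L) {
    surface_set(lapply(seq_len(cfg$n_dc), function(m) {
      disk_polygon(dc_xy[m, ], dc_area[m])
    }), marker_class = "FSCN1", surface_id = paste0("dc", seq_len(cfg$n_dc)))
  } else empty_surface_set()

  n_cells <- cfg$n_dc + cfg$n_treg + cfg$n_other
  other_xy <- cbind(runif(cfg$n_treg + cfg$n_other, 0, W),
                    runif(cfg$n_treg + cfg$n_other, 0, H))
  cells <- data.frame(
    cell_id = c(if (cfg$n_dc > 0L) detections$surface_id else character(0),
                if (cfg$n_treg > 0L) paste0("tr", seq_len(cfg$n_treg)) else character(0),
                if (cfg$n_other > 0L) paste0("ot", seq_len(cfg$n_other)) else character(0)),
    sample_id = rep(cfg$sample_id, n_cells),
    x_um = c(dc_xy[, 1L], other_xy[, 1L]),
    y_um = c(dc_xy[, 2L], other_xy[, 2L]),
    cell_type = c(rep("DC", cfg$n_dc), rep("Treg", cfg$n_treg),
                  rep("other", cfg$n_other)),
    stringsAsFactors = FALSE
  )

  truth <- list(
    dc_association = data.frame(
      surface_id = if (cfg$n_dc > 0L) detections$surface_id else character(0),
      label = dc_label, anchor_vessel = dc_anchor, stringsAsFactors = FALSE
    ),
    vessel_class = data.frame(vessel_id = vid, class = vclass,
                              stringsAsFactors = FALSE),
    ccl19_covered = data.frame(vessel_id = vid,
                               covered = seq_len(n_v) %in% cov_idx,
                               stringsAsFactors = FALSE),
    planted_fractions = c(BV = if (cfg$n_dc > 0) n_pv / cfg$n_dc else NA_real_,
                          LV = if (cfg$n_dc > 0) n_lv / cfg$n_dc else NA_real_,
                          none = if (cfg$n_dc > 0) n_none / cfg$n_dc else NA_real_)
  )

  structure(list(cells = cells, detections = detections,
                 surfaces = list(cd31 = cd31, lyve1 = lyve1, ccl19 = ccl19),
                 vessels = vessels, truth = truth, config = cfg),
            class = "dc_scene")
}
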
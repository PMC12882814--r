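# Nearest-distance proximity statistics between cell classes and
# niche-composition summaries (Treg proximity to DC niches, contact-site
# distribution over vessel classes).

#' Nearest distance from each source cell to each target type
#'
#' Computes, per source cell, the minimum distance (and the id attaining it)
#' to every requested target type; squared distances are minimized
#' internally with a final square root. A cell is never its own nearest
#' target when source and target types coincide.
#'
#' @param cells cell table (`cell_id`, `x_um`, `y_um`, `cell_type`).
#' @param source_type the source cell type.
#' @param target_types character vector of target types.
#' @param mode `"centroid"` (point distances, default) or `"border"`
#'   (border-to-border between surfaces; requires `surfaces`).
#' @param surfaces optional `surface_set` carrying boundaries for all
#'   involved cells (matched by `surface_id` = `cell_id`) for border mode.
#' @return data.frame with one row per source cell: `cell_id`, and per
#'   target type `T` columns `dist_T` (μm; `NA` when the type is absent) and
#'   `nearest_T` (id).
#' @export
nearest_by_type <- function(cells, source_type, target_types,
                            mode = c("centroid", "border"), surfaces = NULL) {
  mode <- match.arg(mode)
  validate_cells(cells)
  src <- cells[cells$cell_type == source_type, , drop = FALSE]
  if (nrow(src) == 0L) stop(sprintf("no cells of source type '%s'", source_type),
                            call. = FALSE)
  out <- data.frame(cell_id = src$cell_id, stringsAsFactors = FALSE)
  for (tt in target_types) {
    tgt <- cells[cells$cell_type == tt, , drop = FALSE]
    dcol <- paste0("dist_", tt); icol <- paste0("nearest_", tt)
    if (nrow(tgt) == 0L) {
      out[[dcol]] <- NA_real_
      out[[icol]] <- NA_character_
      next
    }
    if (mode == "centroid") {
      d2 <- outer(src$x_um, tgt$x_um, "-")^2 + outer(src$y_um, tgt$y_um, "-")^2
      # exclude self-pairs when the types coincide
      self <- outer(src$cell_id, tgt$cell_id, "==")
      d2[self] <- Inf
      j <- apply(d2, 1L, which.min)
      dmin <- sqrt(d2[cbind(seq_len(nrow(src)), j)])
      dmin[!is.finite(dmin)] <- NA_real_
      out[[dcol]] <- dmin
      out[[icol]] <- ifelse(is.na(dmin), NA_character_, tgt$cell_id[j])
    } else {
      if (is.null(surfaces)) stop("border mode requires `surfaces`", call. = FALSE)
      s_idx <- match(src$cell_id, surfaces$surface_id)
      t_idx <- match(tgt$cell_id, surfaces$surface_id)
      if (anyNA(s_idx) || anyNA(t_idx)) {
        stop("border mode: missing boundaries for some cells", call. = FALSE)
      }
      dmin <- rep(NA_real_, nrow(src)); jid <- rep(NA_character_, nrow(src))
      for (i in seq_len(nrow(src))) {
        best <- Inf; bj <- NA_character_
        for (k in seq_len(nrow(tgt))) {
          if (src$cell_id[i] == tgt$cell_id[k]) next
          d <- poly_pair_distance(surfaces$boundary[[s_idx[i]]],
                                  surfaces$boundary[[t_idx[k]]])
          if (d < best) { best <- d; bj <- tgt$cell_id[k] }
        }
        if (is.finite(best)) { dmin[i] <- best; jid[i] <- bj }
      }
      out[[dcol]] <- dmin
      out[[icol]] <- jid
    }
  }
  out
}

#' Fraction of source cells with a nearby target cell
#'
#' Fraction of `source_type` cells whose nearest `target_type` cell lies
#' strictly within `radius` (the "at least one nearby (< 50 μm) Treg"
#' statistic).
#'
#' @inheritParams nearest_by_type
#' @param target_type single target type.
#' @param radius distance threshold in μm (default 50, strict `<`).
#' @return single fraction; `NA` with a warning when there are no source
#'   cells.
#' @export
fraction_with_neighbor <- function(cells, source_type, target_type,
                                   radius = 50) {
  stop_if_not_scalar_number(radius, "radius", min = 0, strict_min = TRUE)
  validate_cells(cells)
  if (!any(cells$cell_type == source_type)) {
    warning(sprintf("no source cells of type '%s'; fraction undefined", source_type))
    return(NA_real_)
  }
  nn <- nearest_by_type(cells, source_type, target_type)
  d <- nn[[paste0("dist_", target_type)]]
  if (all(is.na(d))) {
    warning("target type absent; fraction undefined")
    return(NA_real_)
  }
  mean(d < radius, na.rm = FALSE)
}

#' Treg proximity status of DC-CD8 niches
#'
#' A niche is a DC with at least one CD8 cell within `contact`; each niche
#' is Treg-proximal when at least one Treg lies within `treg_radius` of the
#' DC. Returns the niche counts and the two frequencies (which sum to 1 over
#' niches).
#'
#' @param cells cell table.
#' @param dc_type,cd8_type,treg_type the three cell-type labels.
#' @param contact DC-CD8 contact threshold in μm (strict `<`).
#' @param treg_radius Treg proximity radius in μm (default 100, strict `<`).
#' @return list with `n_niches`, `n_with_treg`, `n_without_treg`,
#'   `freq_with_treg`, `freq_without_treg` (frequencies `NA` with a warning
#'   when there are no niches).
#' @export
niche_treg_status <- function(cells, dc_type, cd8_type, treg_type,
                              contact, treg_radius = 100) {
  stop_if_not_scalar_number(contact, "contact", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(treg_radius, "treg_radius", min = 0, strict_min = TRUE)
  validate_cells(cells)
  dcs <- cells[cells$cell_type == dc_type, , drop = FALSE]
  cd8 <- cells[cells$cell_type == cd8_type, , drop = FALSE]
  tregs <- cells[cells$cell_type == treg_type, , drop = FALSE]
  nearest_d <- function(src, tgt) {
    if (nrow(tgt) == 0L) return(rep(Inf, nrow(src)))
    d2 <- outer(src$x_um, tgt$x_um, "-")^2 + outer(src$y_um, tgt$y_um, "-")^2
    sqrt(apply(d2, 1L, min))
  }
  is_niche <- nearest_d(dcs, cd8) < contact
  n_niches <- sum(is_niche)
  if (n_niches == 0L) {
    warning("no DC-CD8 niches found; frequencies undefined")
    return(list(n_niches = 0L, n_with_treg = 0L, n_without_treg = 0L,
                freq_with_treg = NA_real_, freq_without_treg = NA_real_))
  }
  with_treg <- nearest_d(dcs[is_niche, , drop = FALSE], tregs) < treg_radius
  list(n_niches = n_niches,
       n_with_treg = sum(with_treg),
       n_without_treg = sum(!with_treg),
       freq_with_treg = mean(with_treg),
       freq_without_treg = mean(!with_treg))
}

#' Vessel-class distribution of DC-Treg contact sites
#'
#' Restricts to DCs with a Treg within the contact threshold and reports the
#' distribution of their vessel-association labels (BV / LV / none; the
#' fractions sum to 1 whenever any contacting DC exists).
#'
#' @param dcs DC `surface_set`.
#' @param tregs Treg positions: a cell table with `x_um`/`y_um` (distances
#'   are then measured from the DC border to the Treg centroid) or a
#'   `surface_set` (border-to-border).
#' @param vessels a `vessel_set`.
#' @param contact contact threshold in μm (default 5, `<=` per the static
#'   surface-distance rule).
#' @param cfg an [association_config()].
#' @return list with `fractions` (named BV/LV/none, summing to 1 or all `NA`),
#'   `n_contacting`, and the per-DC association table as `association`.
#' @export
contact_by_vessel_class <- function(dcs, tregs, vessels, contact = 5,
                                    cfg = association_config()) {
  stop_if_not_scalar_number(contact, "contact", min = 0)
  validate_surfaces(dcs, "dcs")
  assoc <- associate_cells(dcs, vessels, cfg)
  n <- nrow(dcs)
  treg_d <- rep(Inf, n)
  if (is_surface_set(tregs)) {
    if (nrow(tregs) > 0L) treg_d <- nearest_surface_distance(dcs, tregs)$dist
  } else {
    check_columns(tregs, c("x_um", "y_um"), "tregs")
    if (nrow(tregs) > 0L) {
      pts <- cbind(tregs$x_um, tregs$y_um)
      for (i in seq_len(n)) {
        treg_d[i] <- min(points_region_distance(pts, dcs$boundary[[i]]))
      }
    }
  }
  contacting <- treg_d <= contact
  if (!any(contacting)) {
    warning("no contacting DCs; fractions undefined")
    fr <- c(BV = NA_real_, LV = NA_real_, none = NA_real_)
  } else {
    lab <- factor(assoc$label[contacting], levels = c("BV", "LV", "none"))
    fr <- as.vector(table(lab)) / sum(contacting)
    names(fr) <- c("BV", "LV", "none")
  }
  list(fractions = fr, n_contacting = sum(contacting), association = assoc)
}
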
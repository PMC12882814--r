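# Readers and writers for the exchange formats: cell tables and tracks as
# CSV, surfaces as GeoJSON FeatureCollections, ground truth as JSON.

#' Write / read a cell table (CSV)
#'
#' Schema: `cell_id, sample_id, x_um, y_um, cell_type[, gene_*]`.
#'
#' @param cells cell table.
#' @param path file path.
#' @return `read_cells` returns the validated data.frame.
#' @export
write_cells <- function(cells, path) {
  validate_cells(cells)
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "sample_id", "x_um", "y_um", "cell_type"),
                sprintf("cell table '%s'", path))
  for (col in c("x_um", "y_um")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s at row(s): %s", col,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  df$cell_id <- as.character(df$cell_id)
  validate_cells(df)
  df
}

#' Write / read a surface set (GeoJSON)
#'
#' Surfaces are stored as a GeoJSON `FeatureCollection` of `Polygon`
#' features with properties `surface_id`, `marker_class`, `area_um2`
#' (coordinates in μm, not geographic).
#'
#' @param surfaces a `surface_set`.
#' @param path file path.
#' @return `read_surfaces` returns the `surface_set` (areas recomputed from
#'   the polygons and checked against the stored property at 1% tolerance).
#' @export
write_surfaces <- function(surfaces, path) {
  validate_surfaces(surfaces)
  feats <- lapply(seq_len(nrow(surfaces)), function(i) {
    b <- surfaces$boundary[[i]]
    ring <- rbind(b, b[1L, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(surface_id = surfaces$surface_id[i],
                        marker_class = surfaces$marker_class[i],
                        area_um2 = surfaces$area_um2[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)), function(k) {
                        c(ring[k, 1L], ring[k, 2L])
                      })))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$type) || js$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- js$features
  if (length(feats) == 0L) return(empty_surface_set())
  bnds <- vector("list", length(feats))
  ids <- character(length(feats)); mk <- character(length(feats))
  stored_area <- numeric(length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (is.null(f$geometry) || f$geometry$type != "Polygon") {
      stop(sprintf("feature %d is not a Polygon", i), call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    bnds[[i]] <- as_polygon(m)
    ids[i] <- as.character(f$properties$surface_id)
    mk[i] <- as.character(f$properties$marker_class)
    stored_area[i] <- as.numeric(f$properties$area_um2)
  }
  out <- surface_set(bnds, marker_class = mk, surface_id = ids)
  bad <- which(is.finite(stored_area) &
                 abs(out$area_um2 - stored_area) > 0.01 * pmax(stored_area, 1e-9))
  if (length(bad) > 0L) {
    stop(sprintf("stored area inconsistent with polygon for surface(s): %s",
                 paste(ids[utils::head(bad, 5L)], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Write / read object tracks (CSV)
#'
#' Schema: `object_id, class, frame, t_s, x_um, y_um, z_um, radius_um`.
#'
#' @param tracks a [track_set()].
#' @param path file path.
#' @return `read_tracks` returns the validated [track_set()].
#' @export
write_tracks <- function(tracks, path) {
  check_columns(tracks, c("object_id", "class", "frame", "t_s",
                          "x_um", "y_um", "z_um", "radius_um"), "track table")
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  track_set(df)
}

#' Write / read ground truth (JSON)
#'
#' @param truth the `truth` element of a [generate_scene()] result (or any
#'   list of data.frames / vectors).
#' @param path file path.
#' @return `read_ground_truth` returns the list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
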
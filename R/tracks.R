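# Time-lapse statistics from object tracks: DC-Treg contact episodes and
# durations, cumulative interaction counts, and track speeds.
#
# Tracked objects are approximated as spheres (centroid + equivalent
# radius); the surface distance at a frame is
# max(0, centroid distance - r1 - r2), and a contact episode is a maximal
# run of consecutive co-observed frames with surface distance strictly
# below the threshold ("below 5 μm ... without being interrupted").

#' Validate and build a track set
#'
#' @param tracks data.frame with columns `object_id`, `class` (`"DC"` /
#'   `"Treg"`), `frame` (integer, 0-based), `t_s` (timestamp, seconds),
#'   `x_um`, `y_um`, `z_um`, `radius_um`.
#' @return the validated data.frame with class `track_set`, ordered by
#'   object and frame.
#' @export
track_set <- function(tracks) {
  check_columns(tracks, c("object_id", "class", "frame", "t_s",
                          "x_um", "y_um", "z_um", "radius_um"), "track table")
  if (any(tracks$radius_um < 0)) stop("radius_um must be >= 0", call. = FALSE)
  tracks <- tracks[order(tracks$object_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  for (id in unique(tracks$object_id)) {
    ts <- tracks$t_s[tracks$object_id == id]
    if (is.unsorted(ts, strictly = TRUE)) {
      stop(sprintf("timestamps not strictly increasing for object '%s'", id),
           call. = FALSE)
    }
  }
  class(tracks) <- c("track_set", "data.frame")
  tracks
}

# frames-indexed position/radius table for one object
object_frames <- function(tracks, id) {
  tr <- tracks[tracks$object_id == id, , drop = FALSE]
  tr[order(tr$frame), , drop = FALSE]
}

#' Detect DC-Treg contact episodes
#'
#' For every (DC, Treg) pair with co-observed frames, computes the per-frame
#' surface distance and extracts maximal runs of consecutive frames with
#' distance strictly below `threshold`. An episode of `n` frames counts
#' `n x` the local frame interval as its duration (reported in minutes).
#'
#' @param tracks a [track_set()].
#' @param threshold contact threshold in μm (default 5, strict `<`).
#' @param gap_tolerance number of above-threshold (or missing) frames
#'   allowed inside an episode without breaking it (default 0: any
#'   interruption ends the episode).
#' @return `contact_table` data.frame: `dc_id`, `treg_id`, `start_frame`,
#'   `end_frame`, `n_frames`, `duration_min`. Pairs with no common frames
#'   are skipped and listed in the `skipped_pairs` attribute.
#' @export
detect_contacts <- function(tracks, threshold = 5, gap_tolerance = 0) {
  stop_if_not_scalar_number(threshold, "threshold", min = 0)
  stop_if_not_scalar_number(gap_tolerance, "gap_tolerance", min = 0)
  dc_ids <- unique(tracks$object_id[tracks$class == "DC"])
  treg_ids <- unique(tracks$object_id[tracks$class == "Treg"])
  rows <- list()
  skipped <- list()
  for (d in dc_ids) {
    td <- object_frames(tracks, d)
    for (g in treg_ids) {
      tg <- object_frames(tracks, g)
      common <- intersect(td$frame, tg$frame)
      if (length(common) == 0L) {
        skipped[[length(skipped) + 1L]] <- c(dc_id = d, treg_id = g)
        next
      }
      common <- sort(common)
      i1 <- match(common, td$frame); i2 <- match(common, tg$frame)
      cd <- sqrt((td$x_um[i1] - tg$x_um[i2])^2 +
                 (td$y_um[i1] - tg$y_um[i2])^2 +
                 (td$z_um[i1] - tg$z_um[i2])^2)
      sd_ <- pmax(0, cd - td$radius_um[i1] - tg$radius_um[i2])
      below <- sd_ < threshold
      t_s <- td$t_s[i1]
      runs <- contact_runs(common, below, gap_tolerance)
      for (r in runs) {
        fr <- common >= r[1L] & common <= r[2L]
        n_fr <- sum(fr & below)
        dt <- local_interval(t_s, common, r)
        rows[[length(rows) + 1L]] <- data.frame(
          dc_id = d, treg_id = g, start_frame = r[1L], end_frame = r[2L],
          n_frames = n_fr, duration_min = n_fr * dt / 60,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(dc_id = character(0), treg_id = character(0),
               start_frame = integer(0), end_frame = integer(0),
               n_frames = integer(0), duration_min = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  attr(out, "skipped_pairs") <- skipped
  attr(out, "threshold") <- threshold
  out
}

# maximal runs of TRUE over observed frames; frames must be sorted.
# Consecutive means adjacent in the co-observed frame sequence AND adjacent
# in frame number (a missed detection breaks the episode unless bridged by
# gap_tolerance frames).
contact_runs <- function(frames, below, gap_tolerance) {
  runs <- list()
  i <- 1L
  n <- length(frames)
  while (i <= n) {
    if (!below[i]) { i <- i + 1L; next }
    start <- frames[i]
    end <- frames[i]
    j <- i + 1L
    gap <- 0
    while (j <= n) {
      step <- frames[j] - frames[j - 1L]
      if (below[j] && (frames[j] - end) <= gap_tolerance + 1 && step >= 1) {
        end <- frames[j]
        j <- j + 1L
      } else if (!below[j] && gap_tolerance > 0 &&
                 (frames[j] - end) <= gap_tolerance) {
        j <- j + 1L # bridged interruption; episode may continue
      } else break
    }
    runs[[length(runs) + 1L]] <- c(start, end)
    # advance past the run
    while (i <= n && frames[i] <= end) i <- i + 1L
  }
  runs
}

# mean frame interval local to the run (falls back to the global mean)
local_interval <- function(t_s, frames, run) {
  if (length(t_s) < 2L) return(NA_real_)
  sel <- which(frames >= run[1L] & frames <= run[2L])
  if (length(sel) >= 2L) {
    mean(diff(t_s[sel]) / diff(frames[sel]))
  } else {
    mean(diff(t_s) / diff(frames))
  }
}

#' Per-DC interaction counts and cumulative interactions over time
#'
#' At every frame, counts Tregs whose centroid-to-centroid distance to the
#' DC is strictly below `radius`; the cumulative curve counts how many
#' Treg-interaction episodes (maximal below-radius runs per Treg) have
#' started up to each frame. Both the per-frame counts and the cumulative
#' episode curve are returned (episodes are the headline statistic; the
#' per-frame counts let a Treg-frame convention be derived if wanted).
#'
#' @param tracks a [track_set()].
#' @param radius interaction radius in μm (default 20, strict `<`).
#' @return data.frame with `dc_id`, `frame`, `t_s`, `n_interacting`
#'   (Tregs currently below the radius) and `cumulative_episodes`.
#' @export
cumulative_interactions <- function(tracks, radius = 20) {
  stop_if_not_scalar_number(radius, "radius", min = 0, strict_min = TRUE)
  dc_ids <- unique(tracks$object_id[tracks$class == "DC"])
  treg_ids <- unique(tracks$object_id[tracks$class == "Treg"])
  rows <- list()
  for (d in dc_ids) {
    td <- object_frames(tracks, d)
    frames <- td$frame
    counts <- integer(length(frames))
    new_starts <- integer(length(frames))
    for (g in treg_ids) {
      tg <- object_frames(tracks, g)
      i2 <- match(frames, tg$frame)
      ok <- !is.na(i2)
      cd <- rep(Inf, length(frames))
      cd[ok] <- sqrt((td$x_um[ok] - tg$x_um[i2[ok]])^2 +
                     (td$y_um[ok] - tg$y_um[i2[ok]])^2 +
                     (td$z_um[ok] - tg$z_um[i2[ok]])^2)
      below <- cd < radius
      counts <- counts + below
      starts <- below & !c(FALSE, below[-length(below)])
      new_starts <- new_starts + starts
    }
    rows[[length(rows) + 1L]] <- data.frame(
      dc_id = d, frame = frames, t_s = td$t_s,
      n_interacting = counts,
      cumulative_episodes = cumsum(new_starts),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(dc_id = character(0), frame = integer(0), t_s = numeric(0),
               n_interacting = integer(0), cumulative_episodes = integer(0))
  rownames(out) <- NULL
  out
}

#' Mean track speed per object
#'
#' Total path length divided by total elapsed time, in μm/s. Single-frame
#' tracks have undefined speed and are reported as `NA`.
#'
#' @param tracks a [track_set()].
#' @return data.frame with `object_id`, `class`, `n_frames`, `speed_um_s`.
#' @export
track_speed <- function(tracks) {
  ids <- unique(tracks$object_id)
  out <- data.frame(object_id = ids,
                    class = tracks$class[match(ids, tracks$object_id)],
                    n_frames = NA_integer_, speed_um_s = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    tr <- object_frames(tracks, ids[i])
    out$n_frames[i] <- nrow(tr)
    if (nrow(tr) < 2L) next
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 + diff(tr$z_um)^2)
    out$speed_um_s[i] <- sum(steps) / (tr$t_s[nrow(tr)] - tr$t_s[1L])
  }
  out
}
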
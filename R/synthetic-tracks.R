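# Synthetic DC/Treg time-lapse tracks with planted contact episodes.
#
# DCs random-walk inside disjoint territories on a grid; Tregs random-walk
# freely but are (a) pinned to their partner DC during planted episodes, at
# a surface distance of half the contact threshold, and (b) pushed away from
# every DC outside episodes so that their surface distance always exceeds
# threshold + margin. Contact detection therefore recovers the planted
# episode set exactly, which is the property the track statistics are
# validated against.

#' Configuration for synthetic tracks
#'
#' @param n_dc_tracks,n_treg_tracks numbers of DC and Treg objects.
#' @param n_frames number of frames (frames are 0-based: `0 .. n_frames-1`).
#' @param frame_interval seconds between frames (default 90).
#' @param planted_episodes data.frame with `dc_id`, `treg_id`,
#'   `start_frame`, `end_frame` (inclusive, within `[0, n_frames)`).
#'   Object ids are `dc1..` / `treg1..`. Overlapping or adjacent episodes of
#'   the same pair are merged with a warning; overlapping episodes of one
#'   Treg with two different DCs are rejected.
#' @param motility_sd random-walk step standard deviation (μm per frame).
#' @param object_radius equivalent sphere radius (μm) for both classes.
#' @param contact_threshold contact threshold the episodes are planted
#'   against (μm, default 5).
#' @param margin outside episodes the DC-Treg surface distance is kept
#'   strictly above `contact_threshold + margin` (μm, default 10).
#' @param seed integer seed.
#' @return a `track_config` list.
#' @export
track_config <- function(n_dc_tracks = 6, n_treg_tracks = 10, n_frames = 40,
                         frame_interval = 90,
                         planted_episodes = NULL,
                         motility_sd = 2, object_radius = 4,
                         contact_threshold = 5, margin = 10, seed = 1L) {
  stop_if_not_scalar_number(n_dc_tracks, "n_dc_tracks", min = 0)
  stop_if_not_scalar_number(n_treg_tracks, "n_treg_tracks", min = 0)
  stop_if_not_scalar_number(n_frames, "n_frames", min = 1)
  stop_if_not_scalar_number(frame_interval, "frame_interval", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(motility_sd, "motility_sd", min = 0)
  stop_if_not_scalar_number(object_radius, "object_radius", min = 0)
  stop_if_not_scalar_number(margin, "margin", min = 0, strict_min = TRUE)
  if (!is.null(planted_episodes)) {
    check_columns(planted_episodes, c("dc_id", "treg_id", "start_frame",
                                      "end_frame"), "planted_episodes")
    if (any(planted_episodes$start_frame < 0) ||
        any(planted_episodes$end_frame >= n_frames) ||
        any(planted_episodes$end_frame < planted_episodes$start_frame)) {
      stop("planted episodes must lie within [0, n_frames) with start <= end",
           call. = FALSE)
    }
  }
  structure(list(n_dc_tracks = as.integer(n_dc_tracks),
                 n_treg_tracks = as.integer(n_treg_tracks),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 planted_episodes = planted_episodes,
                 motility_sd = motility_sd, object_radius = object_radius,
                 contact_threshold = contact_threshold, margin = margin,
                 seed = as.integer(seed)),
            class = "track_config")
}

# merge overlapping or adjacent episodes of the same pair
normalize_episodes <- function(ep, n_frames) {
  if (is.null(ep) || nrow(ep) == 0L) {
    return(data.frame(dc_id = character(0), treg_id = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  merged_any <- FALSE
  for (key in unique(paste(ep$dc_id, ep$treg_id))) {
    sub <- ep[paste(ep$dc_id, ep$treg_id) == key, , drop = FALSE]
    sub <- sub[order(sub$start_frame), , drop = FALSE]
    cur <- sub[1L, ]
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        if (sub$start_frame[i] <= cur$end_frame + 1L) {
          cur$end_frame <- max(cur$end_frame, sub$end_frame[i])
          merged_any <- TRUE
        } else {
          out[[length(out) + 1L]] <- cur
          cur <- sub[i, ]
        }
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  out <- do.call(rbind, out)
  if (merged_any) warning("overlapping planted episodes for a pair were merged")
  # a Treg cannot contact two DCs at the same frame
  for (g in unique(out$treg_id)) {
    sub <- out[out$treg_id == g, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$start_frame), , drop = FALSE]
    if (any(sub$start_frame[-1L] <= sub$end_frame[-nrow(sub)])) {
      stop(sprintf("treg '%s' has overlapping episodes with different DCs", g),
           call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

#' Generate synthetic DC/Treg tracks
#'
#' @param config a [track_config()].
#' @return a [track_set()] with attributes `planted_episodes` (the merged,
#'   validated episode table) and `config`.
#' @export
generate_tracks <- function(config) {
  if (!inherits(config, "track_config")) {
    stop("`config` must be created with track_config()", call. = FALSE)
  }
  ep <- normalize_episodes(config$planted_episodes, config$n_frames)
  with_seed(config$seed, generate_tracks_impl(config, ep))
}

generate_tracks_impl <- function(cfg, ep) {
  n_f <- cfg$n_frames
  r <- cfg$object_radius
  thr <- cfg$contact_threshold
  safe <- 2 * r + thr + cfg$margin # minimum safe centroid distance
  # DC territories: grid with cells wide enough that a Treg pushed to the
  # safe distance from one DC cannot violate the margin at another
  cell <- max(3 * safe, 60)
  box <- 6 # DC random walk confined to +/- box around its territory center
  n_side <- max(1L, ceiling(sqrt(max(cfg$n_dc_tracks, 1L))))
  field <- n_side * cell

  dc_ids <- if (cfg$n_dc_tracks > 0L) paste0("dc", seq_len(cfg$n_dc_tracks)) else character(0)
  treg_ids <- if (cfg$n_treg_tracks > 0L) paste0("treg", seq_len(cfg$n_treg_tracks)) else character(0)
  bad_dc <- setdiff(ep$dc_id, dc_ids)
  bad_tr <- setdiff(ep$treg_id, treg_ids)
  if (length(bad_dc) || length(bad_tr)) {
    stop("planted episodes reference unknown object ids", call. = FALSE)
  }

  reflect <- function(x, lo, hi) {
    # reflect a coordinate into [lo, hi]
    rng <- hi - lo
    y <- (x - lo) %% (2 * rng)
    lo + ifelse(y > rng, 2 * rng - y, y)
  }

  # DC positions: confined random walks
  dc_pos <- array(0, c(cfg$n_dc_tracks, n_f, 3L))
  for (i in seq_len(cfg$n_dc_tracks)) {
    cx <- ((i - 1L) %% n_side + 0.5) * cell
    cy <- ((i - 1L) %/% n_side + 0.5) * cell
    p <- c(cx + runif(1, -box, box), cy + runif(1, -box, box), runif(1, 0, 10))
    for (f in seq_len(n_f)) {
      if (f > 1L) {
        p <- p + rnorm(3L, 0, cfg$motility_sd)
        p[1L] <- reflect(p[1L], cx - box, cx + box)
        p[2L] <- reflect(p[2L], cy - box, cy + box)
        p[3L] <- reflect(p[3L], 0, 10)
      }
      dc_pos[i, f, ] <- p
    }
  }

  # episode lookup: for treg j at frame f (0-based), which DC (index) if any
  ep_dc <- matrix(NA_integer_, max(cfg$n_treg_tracks, 1L), n_f)
  if (nrow(ep) > 0L) {
    for (k in seq_len(nrow(ep))) {
      j <- match(ep$treg_id[k], treg_ids)
      i <- match(ep$dc_id[k], dc_ids)
      ep_dc[j, (ep$start_frame[k]:ep$end_frame[k]) + 1L] <- i
    }
  }

  treg_pos <- array(0, c(cfg$n_treg_tracks, n_f, 3L))
  for (j in seq_len(cfg$n_treg_tracks)) {
    p <- c(runif(1, 0, field), runif(1, 0, field), runif(1, 0, 10))
    # a stable approach direction per treg, used during episodes
    dirs <- rnorm(3L); dirs <- dirs / sqrt(sum(dirs^2))
    for (f in seq_len(n_f)) {
      i <- ep_dc[j, f]
      if (!is.na(i)) {
        # pinned to the partner DC at half the contact threshold
        p <- dc_pos[i, f, ] + dirs * (2 * r + thr / 2)
      } else {
        if (f > 1L) p <- p + rnorm(3L, 0, cfg$motility_sd)
        p[1L] <- reflect(p[1L], 0, field)
        p[2L] <- reflect(p[2L], 0, field)
        p[3L] <- reflect(p[3L], 0, 10)
        # push away from any DC violating the safety margin
        if (cfg$n_dc_tracks > 0L) {
          for (pass in 1:3) {
            d2 <- (dc_pos[, f, 1L] - p[1L])^2 + (dc_pos[, f, 2L] - p[2L])^2 +
              (dc_pos[, f, 3L] - p[3L])^2
            w <- which.min(d2)
            if (sqrt(d2[w]) > safe) break
            v <- p - dc_pos[w, f, ]
            nv <- sqrt(sum(v^2))
            v <- if (nv < 1e-9) c(1, 0, 0) else v / nv
            p <- dc_pos[w, f, ] + v * (safe + 0.5)
          }
        }
      }
      treg_pos[j, f, ] <- p
    }
  }

  frames <- rep(0:(n_f - 1L), cfg$n_dc_tracks + cfg$n_treg_tracks)
  build <- function(ids, pos, cls) {
    if (length(ids) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(object_id = ids[i], class = cls, frame = 0:(n_f - 1L),
                 t_s = (0:(n_f - 1L)) * cfg$frame_interval,
                 x_um = pos[i, , 1L], y_um = pos[i, , 2L], z_um = pos[i, , 3L],
                 radius_um = r, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(build(dc_ids, dc_pos, "DC"), build(treg_ids, treg_pos, "Treg"))
  out <- track_set(out)
  attr(out, "planted_episodes") <- ep
  attr(out, "config") <- cfg
  out
}
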
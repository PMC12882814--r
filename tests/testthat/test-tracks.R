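# Track dynamics: contact episodes and durations, cumulative interactions,
# track speeds.

# a stationary DC at the origin and a Treg moving along x, radii zero so
# the surface distance equals the centroid distance
linear_tracks <- function(treg_x, interval = 90, radius = 0) {
  n <- length(treg_x)
  track_set(rbind(
    data.frame(object_id = "dc1", class = "DC", frame = 0:(n - 1),
               t_s = (0:(n - 1)) * interval, x_um = 0, y_um = 0, z_um = 0,
               radius_um = radius),
    data.frame(object_id = "treg1", class = "Treg", frame = 0:(n - 1),
               t_s = (0:(n - 1)) * interval, x_um = treg_x, y_um = 0, z_um = 0,
               radius_um = radius)
  ))
}

test_that("a below-threshold run of n frames lasts n frame intervals", {
  ct <- detect_contacts(linear_tracks(c(6, 4, 4, 6)), threshold = 5)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_frames, 2)
  expect_equal(ct$duration_min, 2 * 90 / 60) # 3.0 min
  expect_equal(c(ct$start_frame, ct$end_frame), c(1, 2))
  # never below threshold: no episodes
  expect_equal(nrow(detect_contacts(linear_tracks(c(6, 7, 8, 9)))), 0)
  # boundary: distance exactly at the threshold is not a contact
  expect_equal(nrow(detect_contacts(linear_tracks(c(5, 5, 5)))), 0)
  # two separate episodes
  ct2 <- detect_contacts(linear_tracks(c(4, 9, 9, 4, 4, 9)))
  expect_equal(nrow(ct2), 2)
  expect_equal(ct2$n_frames, c(1, 2))
})

test_that("equivalent radii shift the surface distance; threshold 0 means overlap only", {
  # centroid distance 12, radii 4+4 -> surface distance 4 < 5
  ct <- detect_contacts(linear_tracks(c(12, 12), radius = 4), threshold = 5)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_frames, 2)
  # threshold 0 with positive radii: only overlapping spheres count
  expect_equal(nrow(detect_contacts(linear_tracks(c(12, 12), radius = 4),
                                    threshold = 0)), 0)
  ct0 <- detect_contacts(linear_tracks(c(7, 12), radius = 4), threshold = 1e-9)
  expect_equal(nrow(ct0), 1)
  expect_equal(ct0$n_frames, 1)
})

test_that("missed detections break episodes unless a gap tolerance bridges them", {
  n <- 8
  dc <- data.frame(object_id = "dc1", class = "DC", frame = 0:(n - 1),
                   t_s = (0:(n - 1)) * 90, x_um = 0, y_um = 0, z_um = 0,
                   radius_um = 0)
  tr <- data.frame(object_id = "treg1", class = "Treg",
                   frame = c(0, 1, 2, 4, 5), t_s = c(0, 1, 2, 4, 5) * 90,
                   x_um = c(4, 4, 4, 4, 4), y_um = 0, z_um = 0, radius_um = 0)
  tt <- track_set(rbind(dc, tr))
  ct <- detect_contacts(tt)
  expect_equal(nrow(ct), 2) # frame 3 missing splits the run
  ct_b <- detect_contacts(tt, gap_tolerance = 1)
  expect_equal(nrow(ct_b), 1)
  expect_equal(c(ct_b$start_frame, ct_b$end_frame), c(0, 5))
})

test_that("episode durations shift with time translation and scale with the interval", {
  ct1 <- detect_contacts(linear_tracks(c(6, 4, 4, 6), interval = 90))
  tt <- linear_tracks(c(6, 4, 4, 6), interval = 90)
  tt$t_s <- tt$t_s + 1000 # uniform translation
  ct2 <- detect_contacts(tt)
  expect_equal(ct1$duration_min, ct2$duration_min)
  ct3 <- detect_contacts(linear_tracks(c(6, 4, 4, 6), interval = 180))
  expect_equal(ct3$duration_min, 2 * ct1$duration_min)
})

test_that("500 planted episodes are recovered exactly with no false positives", {
  set.seed(2024)
  ep <- random_episode_schedule(60, n_dc = 6, n_treg = 12, n_frames = 60)
  cfg <- track_config(n_dc_tracks = 6, n_treg_tracks = 12, n_frames = 60,
                      planted_episodes = ep, seed = 10)
  tr <- generate_tracks(cfg)
  ct <- detect_contacts(tr, threshold = cfg$contact_threshold)
  planted <- attr(tr, "planted_episodes")
  key <- function(d) {
    sort(paste(d$dc_id, d$treg_id, d$start_frame, d$end_frame))
  }
  expect_identical(key(ct), key(planted))
  expect_equal(ct$duration_min[order(paste(ct$dc_id, ct$treg_id, ct$start_frame))],
               (planted$end_frame - planted$start_frame + 1)[order(paste(
                 planted$dc_id, planted$treg_id, planted$start_frame))] *
                 cfg$frame_interval / 60)
  # no planted episodes and a wide margin: zero contacts
  cfg0 <- track_config(n_dc_tracks = 4, n_treg_tracks = 8, n_frames = 30,
                       margin = 30, seed = 3)
  expect_equal(nrow(detect_contacts(generate_tracks(cfg0))), 0)
})

test_that("median recovered duration matches the planted distribution", {
  set.seed(5)
  ep <- random_episode_schedule(40, n_dc = 5, n_treg = 10, n_frames = 80,
                                max_len = 9L)
  cfg <- track_config(n_dc_tracks = 5, n_treg_tracks = 10, n_frames = 80,
                      planted_episodes = ep, seed = 6)
  tr <- generate_tracks(cfg)
  ct <- detect_contacts(tr)
  planted <- attr(tr, "planted_episodes")
  med_planted <- median((planted$end_frame - planted$start_frame + 1) * 90 / 60)
  expect_lte(abs(median(ct$duration_min) - med_planted), 90 / 60)
})

test_that("cumulative interactions count per-frame partners and episode starts", {
  # one Treg inside the radius the whole time
  tt <- linear_tracks(rep(10, 5))
  cum <- cumulative_interactions(tt, radius = 20)
  expect_equal(cum$n_interacting, rep(1L, 5))
  expect_equal(cum$cumulative_episodes, rep(1L, 5))
  # oscillating in and out k = 3 times
  tt2 <- linear_tracks(c(10, 30, 10, 30, 10, 30))
  cum2 <- cumulative_interactions(tt2, radius = 20)
  expect_equal(max(cum2$cumulative_episodes), 3)
  expect_equal(cum2$n_interacting, rep(c(1L, 0L), 3))
  # random walks match a per-frame exhaustive scan
  set.seed(8)
  cfg <- track_config(n_dc_tracks = 3, n_treg_tracks = 6, n_frames = 25, seed = 9)
  tr <- generate_tracks(cfg)
  cum3 <- cumulative_interactions(tr, radius = 40)
  for (d in unique(cum3$dc_id)) {
    td <- tr[tr$object_id == d, ]
    for (f in sample(td$frame, 5L)) {
      tg <- tr[tr$class == "Treg" & tr$frame == f, ]
      row <- td[td$frame == f, ]
      ref <- sum(sqrt((tg$x_um - row$x_um)^2 + (tg$y_um - row$y_um)^2 +
                        (tg$z_um - row$z_um)^2) < 40)
      expect_equal(cum3$n_interacting[cum3$dc_id == d & cum3$frame == f], ref)
    }
  }
})

test_that("track_speed is path length over elapsed time", {
  tt <- track_set(data.frame(object_id = "o1", class = "DC", frame = 0:1,
                             t_s = c(0, 90), x_um = c(0, 90), y_um = 0,
                             z_um = 0, radius_um = 1))
  expect_equal(track_speed(tt)$speed_um_s, 1)
  # stationary object
  st <- track_set(data.frame(object_id = "o1", class = "DC", frame = 0:3,
                             t_s = (0:3) * 90, x_um = 5, y_um = 5, z_um = 0,
                             radius_um = 1))
  expect_equal(track_speed(st)$speed_um_s, 0)
  # single frame: undefined
  single <- track_set(data.frame(object_id = "o1", class = "DC", frame = 0,
                                 t_s = 0, x_um = 0, y_um = 0, z_um = 0,
                                 radius_um = 1))
  expect_true(is.na(track_speed(single)$speed_um_s))
  # random walk equals the direct stepwise sum
  set.seed(3)
  xyz <- matrix(cumsum(rnorm(30)), 10L, 3L)
  rw <- track_set(data.frame(object_id = "o1", class = "Treg", frame = 0:9,
                             t_s = (0:9) * 90, x_um = xyz[, 1], y_um = xyz[, 2],
                             z_um = xyz[, 3], radius_um = 2))
  ref <- sum(sqrt(rowSums(diff(xyz)^2))) / (9 * 90)
  expect_equal(track_speed(rw)$speed_um_s, ref)
})

test_that("track_set rejects non-monotone timestamps", {
  bad <- data.frame(object_id = "o1", class = "DC", frame = c(0, 1),
                    t_s = c(90, 0), x_um = 0, y_um = 0, z_um = 0, radius_um = 1)
  expect_error(track_set(bad), "strictly increasing")
})
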
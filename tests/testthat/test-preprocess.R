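cycle_cfg <- cycle_config(cycle_length = 4, pixel_size = 160,
                          photon_min = 1000, merge_radius = 50)

# place an event sequence at a given camera pixel: frames are absolute
event_tab <- function(frames, px = 0, py = 0, pixel = 160) {
  n <- length(frames)
  localization_table(x = rep((px + 0.5) * pixel, n),
                     y = rep((py + 0.5) * pixel, n),
                     frame = frames, photons = 1500)
}

test_that("cycle filter keeps frame-1-only events and removes persistent
           ones", {
  # imaging frame 1 of cycle 0 is absolute frame 1 (activation frame 0)
  expect_equal(nrow(storm_cycle_filter(event_tab(1), cycle_cfg)), 1)
  # present in imaging frames 1, 2, 3 -> removed
  expect_equal(nrow(storm_cycle_filter(event_tab(c(1, 2, 3)), cycle_cfg)), 0)
  # presence in imaging frame 2 is tolerated for the frame-1 event
  out <- storm_cycle_filter(event_tab(c(1, 2)), cycle_cfg)
  expect_equal(out$frame, 1)
  # events not in imaging frame 1 are never kept
  expect_equal(nrow(storm_cycle_filter(event_tab(2), cycle_cfg)), 0)
  expect_equal(nrow(storm_cycle_filter(event_tab(3), cycle_cfg)), 0)
})

test_that("repeats in the consecutive cycle are removed, later occurrence
           first", {
  # frame-1-only events in cycles 0 and 1 at the same pixel
  tab <- event_tab(c(1, 5))
  out <- storm_cycle_filter(tab, cycle_cfg)
  expect_equal(out$frame, 1)
  # +/- 1 pixel in both axes also counts as a repeat
  tab2 <- localization_table(x = c(80, 240), y = c(80, 240),
                             frame = c(1, 5), photons = 1500)
  expect_equal(storm_cycle_filter(tab2, cycle_cfg)$frame, 1)
  # two pixels apart is not a repeat
  tab3 <- localization_table(x = c(80, 400), y = c(80, 80),
                             frame = c(1, 5), photons = 1500)
  expect_equal(nrow(storm_cycle_filter(tab3, cycle_cfg)), 2)
})

test_that("cycle filter matches the rule oracle on an adversarial fixture", {
  set.seed(101)
  n <- 600
  px <- sample(0:4, n, replace = TRUE)
  py <- sample(0:4, n, replace = TRUE)
  frame <- sample(0:39, n, replace = TRUE)   # 10 cycles of 4
  tab <- localization_table(x = (px + runif(n)) * 160,
                            y = (py + runif(n)) * 160,
                            frame = frame, photons = 1500)
  keep <- oracle_cycle_filter_keep(tab$frame, floor(tab$x / 160),
                                   floor(tab$y / 160))
  out <- storm_cycle_filter(tab, cycle_cfg)
  expect_equal(as.data.frame(out),
               as.data.frame(tab[keep, ]), ignore_attr = TRUE)
})

test_that("cycle filter is idempotent and never invents coordinates", {
  set.seed(102)
  tab <- localization_table(x = runif(400, 0, 800), y = runif(400, 0, 800),
                            frame = sample(0:39, 400, TRUE), photons = 1500)
  once <- storm_cycle_filter(tab, cycle_cfg)
  twice <- storm_cycle_filter(once, cycle_cfg)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_true(all(paste(once$x, once$y) %in% paste(tab$x, tab$y)))
})

test_that("consecutive-frame chains merge to one photon-weighted event", {
  tab <- localization_table(x = c(100, 104, 98), y = c(200, 200, 200),
                            frame = c(5, 6, 7),
                            photons = c(1000, 2000, 1000))
  out <- merge_consecutive_detections(tab, cycle_cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$frame, 5)
  expect_equal(out$photons, 4000)
  expect_equal(out$x, (100 * 1000 + 104 * 2000 + 98 * 1000) / 4000)

  # a frame gap breaks the chain
  gap <- localization_table(x = c(100, 100), y = c(0, 0),
                            frame = c(5, 7), photons = 1500)
  expect_equal(nrow(merge_consecutive_detections(gap, cycle_cfg)), 2)

  # beyond merge_radius stays separate
  far <- localization_table(x = c(100, 200), y = c(0, 0),
                            frame = c(5, 6), photons = 1500)
  expect_equal(nrow(merge_consecutive_detections(far, cycle_cfg)), 2)
})

test_that("merging recovers the constructed chain structure exactly", {
  set.seed(103)
  # 40 chains at well-separated sites (>> 2 * merge_radius apart)
  n_chain <- 40
  site <- expand.grid(x = seq(0, 6 * 500, by = 500),
                      y = seq(0, 6 * 500, by = 500))[seq_len(n_chain), ]
  lens <- sample(1:5, n_chain, replace = TRUE)
  starts <- sample(0:50, n_chain, replace = TRUE)
  rows <- do.call(rbind, lapply(seq_len(n_chain), function(i) {
    k <- lens[i]
    data.frame(x = site$x[i] + runif(k, -20, 20),
               y = site$y[i] + runif(k, -20, 20),
               frame = starts[i] + seq_len(k) - 1L)
  }))
  tab <- localization_table(rows$x, rows$y, rows$frame, photons = 1500)
  out <- merge_consecutive_detections(tab, cycle_cfg)
  expect_equal(nrow(out), n_chain)
  expect_setequal(out$frame, starts)
  # idempotent on separated chains
  expect_equal(as.data.frame(merge_consecutive_detections(out, cycle_cfg)),
               as.data.frame(out), ignore_attr = TRUE)
  # merged positions stay inside the input bounding box
  expect_true(all(out$x >= min(tab$x) & out$x <= max(tab$x)))
  expect_true(all(out$y >= min(tab$y) & out$y <= max(tab$y)))
})

test_that("photon quality filter applies the threshold at the boundary", {
  tab <- localization_table(x = 1:3, y = 1:3, frame = 0:2,
                            photons = c(150, 200, 1000))
  out <- quality_filter(tab, cycle_config(photon_min = 200))
  expect_equal(out$photons, c(200, 1000))
  expect_equal(attr(out, "n_removed"), 1)

  expect_equal(nrow(quality_filter(tab, cycle_config(photon_min = 0))), 3)

  palm <- localization_table(x = 1:5, y = 1:5, frame = 0:4,
                             photons = c(200, 400, 600, 800, 999))
  expect_warning(out2 <- quality_filter(palm,
                                        cycle_config(photon_min = 1000)),
                 "removed every")
  expect_equal(nrow(out2), 0)

  # idempotent
  once <- quality_filter(tab, cycle_config(photon_min = 200))
  expect_equal(as.data.frame(quality_filter(once,
                                            cycle_config(photon_min = 200))),
               as.data.frame(once), ignore_attr = TRUE)
})

test_that("fiducial drift correction cancels known drift", {
  # zero drift: identity
  tab <- localization_table(x = c(100, 200), y = c(50, 60),
                            frame = c(0, 10), photons = 1500)
  still <- data.frame(frame = 0:10, x = 500, y = 500)
  out <- drift_correct_fiducials(tab, still)
  expect_equal(out$x, tab$x)
  expect_equal(out$y, tab$y)

  # constant drift, noiseless fiducial: exact cancellation
  cfg <- simulation_config(n_emitters = 100, n_fiducials = 1,
                           fiducial_jitter = 0, n_frames = 200,
                           drift_velocity = c(1, 0), jitter_sigma = 0,
                           blink_mean = 1, seed = 11,
                           roi_width = 3000, roi_height = 3000)
  truth <- sample_emitter_positions(cfg)
  r <- render_localizations(truth, cfg)
  corr <- drift_correct_fiducials(r$table, r$truth$fiducial_tracks)
  emitters_only <- !is.na(r$truth$links$emitter)
  em <- truth$emitters[r$truth$links$emitter[emitters_only], ]
  expect_equal(corr$x[emitters_only], em$x, tolerance = 1e-12)
  expect_equal(corr$y[emitters_only], em$y, tolerance = 1e-12)
})

test_that("smoothed drift estimate suppresses fiducial localization noise", {
  cfg <- simulation_config(n_emitters = 200, n_fiducials = 3,
                           fiducial_jitter = 5, n_frames = 1000,
                           drift_velocity = c(0.05, -0.03),
                           jitter_sigma = 0, blink_mean = 2, seed = 12,
                           roi_width = 5000, roi_height = 5000)
  truth <- sample_emitter_positions(cfg)
  r <- render_localizations(truth, cfg)
  corr <- drift_correct_fiducials(r$table, r$truth$fiducial_tracks,
                                  window = 50)
  emitters_only <- !is.na(r$truth$links$emitter)
  em <- truth$emitters[r$truth$links$emitter[emitters_only], ]
  residual <- sqrt(mean((corr$x[emitters_only] - em$x)^2 +
                          (corr$y[emitters_only] - em$y)^2))
  expect_lt(residual, 2)
})

test_that("missing fiducial tracks advise skipping the correction", {
  tab <- localization_table(1, 1, 0)
  expect_error(drift_correct_fiducials(tab, list()), "skip")
})
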
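test_that("same config and seed give bitwise-identical datasets", {
  cfg <- simulation_config(n_emitters = 300, seed = 42,
                           roi_width = 3000, roi_height = 3000,
                           n_domains = 10)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$truth$emitters, d2$truth$emitters)
})

test_that("clustered_fraction_true controls domain membership exactly", {
  cfg0 <- simulation_config(n_emitters = 100, clustered_fraction_true = 0,
                            n_domains = 0, seed = 1)
  t0 <- sample_emitter_positions(cfg0)
  expect_equal(nrow(t0$emitters), 100)
  expect_true(all(is.na(t0$emitters$domain)))

  cfg1 <- simulation_config(n_emitters = 200, clustered_fraction_true = 1,
                            n_domains = 1, domain_diameter_log_mu = log(70),
                            domain_diameter_log_sigma = 0, seed = 2)
  t1 <- sample_emitter_positions(cfg1)
  d <- sqrt((t1$emitters$x - t1$domains$x)^2 +
              (t1$emitters$y - t1$domains$y)^2)
  expect_true(all(d <= 35 + 1e-9))

  cfg5 <- simulation_config(n_emitters = 10000,
                            clustered_fraction_true = 0.5,
                            n_domains = 100, seed = 3)
  t5 <- sample_emitter_positions(cfg5)
  expect_equal(sum(!is.na(t5$emitters$domain)), 5000)
})

test_that("domain diameters exceeding the ROI are a config error", {
  cfg <- simulation_config(roi_width = 50, roi_height = 50,
                           n_emitters = 10, n_domains = 1,
                           domain_diameter_log_mu = log(500),
                           domain_diameter_log_sigma = 0, seed = 1)
  expect_error(sample_emitter_positions(cfg), "exceeds ROI")
})

test_that("degenerate rendering puts localizations on emitter positions", {
  cfg <- simulation_config(n_emitters = 50, blink_mean = 1,
                           jitter_sigma = 0, clustered_fraction_true = 0,
                           n_domains = 0, seed = 4,
                           roi_width = 2000, roi_height = 2000)
  truth <- sample_emitter_positions(cfg)
  r <- render_localizations(truth, cfg)
  expect_equal(nrow(r$table), 50)
  em <- r$truth$emitters[r$truth$links$emitter, ]
  expect_equal(r$table$x, em$x)
  expect_equal(r$table$y, em$y)
})

test_that("localization count follows the geometric blink law", {
  cfg <- simulation_config(n_emitters = 10000, blink_mean = 4,
                           clustered_fraction_true = 0, n_domains = 0,
                           seed = 5)
  r <- render_localizations(sample_emitter_positions(cfg), cfg)
  rate <- nrow(r$table) / 10000
  # geometric (k >= 1) with mean 4: sd = sqrt(mean*(mean-1)) per emitter
  se <- sqrt(4 * 3 / 10000)
  expect_lt(abs(rate - 4), 3 * se)
})

test_that("every localization links to exactly one emitter or fiducial", {
  cfg <- simulation_config(n_emitters = 200, n_fiducials = 2,
                           n_frames = 400, seed = 6,
                           roi_width = 3000, roi_height = 3000)
  r <- render_localizations(sample_emitter_positions(cfg), cfg)
  one_source <- xor(is.na(r$truth$links$emitter),
                    is.na(r$truth$links$fiducial))
  expect_true(all(one_source))
  expect_equal(sum(!is.na(r$truth$links$fiducial)), 2 * 400)
})

test_that("fiducials trace the configured drift exactly when noiseless", {
  cfg <- simulation_config(n_emitters = 10, n_fiducials = 1,
                           fiducial_jitter = 0, n_frames = 100,
                           drift_velocity = c(1, 0), seed = 7,
                           roi_width = 2000, roi_height = 2000)
  r <- render_localizations(sample_emitter_positions(cfg), cfg)
  tr <- r$truth$fiducial_tracks[[1]]
  expect_equal(tr$x - tr$x[tr$frame == 0], tr$frame * 1)
  expect_equal(tr$y, rep(tr$y[1], nrow(tr)))
})

test_that("frames fall on imaging positions of the activation cycle", {
  cfg <- simulation_config(n_emitters = 500, cycle_length = 4,
                           n_frames = 4000, seed = 8)
  r <- render_localizations(sample_emitter_positions(cfg), cfg)
  pos <- r$table$frame %% 4
  expect_true(all(pos %in% 1:3))
})

test_that("two-channel modes share, resample or translate the emitters", {
  cfg <- simulation_config(n_emitters = 100, seed = 9,
                           roi_width = 3000, roi_height = 3000)
  di <- generate_dataset(cfg, channel_mode = "identical")
  expect_identical(di$truth$emitters[, c("x", "y")],
                   di$truth1$emitters[, c("x", "y")])
  expect_setequal(unique(di$table$channel), c(0, 1))
  # identical structures, but blinks and jitter differ between channels
  ch0 <- di$table[di$table$channel == 0, ]
  ch1 <- di$table[di$table$channel == 1, ]
  expect_gt(nrow(ch0), 0)
  expect_gt(nrow(ch1), 0)
  expect_false(identical(sort(ch0$x), sort(ch1$x)))

  doff <- generate_dataset(cfg, channel_mode = "offset", offset = c(500, 0))
  expect_equal(doff$truth1$emitters$x, doff$truth$emitters$x + 500)
  expect_equal(doff$truth1$emitters$y, doff$truth$emitters$y)

  dind <- generate_dataset(cfg, channel_mode = "independent")
  expect_false(isTRUE(all.equal(dind$truth1$emitters$x,
                                dind$truth$emitters$x)))
})

test_that("datasets round-trip through the on-disk layout", {
  cfg <- simulation_config(n_emitters = 50, seed = 10,
                           roi_width = 2000, roi_height = 2000)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir, "sim")
  expect_true(all(file.exists(paths)))
  back <- read_localizations(paths[["localizations"]])
  expect_equal(as.data.frame(back), as.data.frame(ds$table))
  cfg_back <- jsonlite::read_json(paths[["config"]])
  expect_equal(cfg_back$n_emitters, 50)
})
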
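test_that("the random-reference curve is evaluated exactly", {
  eta <- seq(0, 1, by = 0.05)
  expect_equal(expected_random_density(eta) - 1, 1.4 * eta^4)
  expect_equal(expected_random_density(0), 1)
  expect_equal(expected_random_density(0.5), 1.0875)
  expect_equal(expected_random_density(1), 2.4)
  expect_error(expected_random_density(1.2), ">= 0")
})

test_that("a uniform dense grid gives an empty mask under mean
           normalization", {
  g <- expand.grid(x = seq(5, 1995, by = 10), y = seq(5, 1995, by = 10))
  tab <- localization_table(g$x, g$y, frame = 0)
  p <- mask_params(threshold_unit = "mean", roi = c(0, 2000, 0, 2000))
  m <- build_cluster_mask(tab, p)
  s <- mask_statistics(tab, m)
  expect_equal(s$eta, 0)
  expect_true(is.na(s$normalized_density))
  expect_true(is.na(s$deviation))
  expect_equal(s$expected_random, 1)
})

test_that("a single tight blob yields a mask confined to its vicinity", {
  set.seed(401)
  tab <- localization_table(2500 + rnorm(1000, 0, 20),
                            2500 + rnorm(1000, 0, 20), frame = 0)
  m <- build_cluster_mask(tab, mask_params(roi = c(0, 5000, 0, 5000)))
  expect_gt(sum(m$mask), 0)
  idx <- which(m$mask, arr.ind = TRUE)
  px <- m$x0 + (idx[, 1] - 0.5) * m$spacing
  py <- m$y0 + (idx[, 2] - 0.5) * m$spacing
  expect_true(all(sqrt((px - 2500)^2 + (py - 2500)^2) < 150))
  s <- mask_statistics(tab, m)
  expect_gt(s$normalized_density, s$expected_random)
})

test_that("mask area is stable under grid refinement", {
  set.seed(402)
  cfg <- simulation_config(n_emitters = 4000, clustered_fraction_true = 0,
                           n_domains = 0, jitter_sigma = 15, seed = 402,
                           roi_width = 4000, roi_height = 4000)
  ds <- generate_dataset(cfg)
  chk <- check_grid_sensitivity(ds$table,
                                mask_params(roi = c(0, 4000, 0, 4000)))
  expect_lt(chk$relative_change, 0.05)
})

test_that("mask statistics are invariant under rigid motion of data and
           ROI together", {
  set.seed(403)
  cfg <- simulation_config(n_emitters = 2000, clustered_fraction_true = 0.5,
                           n_domains = 50, seed = 403,
                           roi_width = 4000, roi_height = 4000)
  ds <- generate_dataset(cfg)
  box <- rbind(c(0, 0), c(4000, 0), c(4000, 4000), c(0, 4000))
  s0 <- mask_statistics(ds$table,
                        build_cluster_mask(ds$table, mask_params(roi = box)))
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(1234, -567)
  xy <- cbind(ds$table$x, ds$table$y) %*% R
  moved <- localization_table(xy[, 1] + shift[1], xy[, 2] + shift[2],
                              frame = ds$table$frame)
  roi_m <- sweep(box %*% R, 2, shift, "+")
  s1 <- mask_statistics(moved,
                        build_cluster_mask(moved, mask_params(roi = roi_m)))
  # raster re-alignment perturbs the statistic only slightly
  expect_equal(s1$eta, s0$eta, tolerance = 0.05)
  expect_equal(s1$normalized_density, s0$normalized_density,
               tolerance = 0.05)
})

test_that("neighbor counts match the trivial cases and the all-pairs
           oracle", {
  close2 <- localization_table(c(0, 20), c(0, 0), frame = 0:1)
  expect_equal(neighbor_counts(close2, 30)$count, c(1, 1))
  far2 <- localization_table(c(0, 40), c(0, 0), frame = 0:1)
  expect_equal(neighbor_counts(far2, 30)$count, c(0, 0))
  expect_equal(nrow(neighbor_counts(localization_table(), 30)), 0)

  set.seed(404)
  tab <- csr_table(300, 1000, 1000, seed = 404)
  expect_equal(neighbor_counts(tab, 30)$count,
               oracle_neighbor_counts(tab$x, tab$y, 30))
  # symmetry: total neighbor degree is even
  expect_equal(sum(neighbor_counts(tab, 50)$count) %% 2, 0)
  # permutation invariance
  perm <- sample(nrow(tab))
  expect_equal(neighbor_counts(tab[perm, ], 30)$count,
               neighbor_counts(tab, 30)$count[perm])
})

test_that("counts rise toward domain centers on true-cluster fixtures", {
  cfg <- simulation_config(n_emitters = 800, clustered_fraction_true = 1,
                           n_domains = 50, domain_diameter_log_sigma = 0,
                           jitter_sigma = 5, seed = 405)
  ds <- generate_dataset(cfg)
  nc <- neighbor_counts(ds$table, 30)
  em <- ds$truth$emitters[ds$truth$links$emitter, ]
  dom <- ds$truth$domains[em$domain, ]
  r <- sqrt((nc$x - dom$x)^2 + (nc$y - dom$y)^2)
  inner <- r < 17.5
  outer <- r >= 17.5 & r < 35
  expect_gt(mean(nc$count[inner]), mean(nc$count[outer]))
})

test_that("verification separates clustered data from CSR blinking and
           flags degenerate ranges", {
  roi <- c(0, 5000, 0, 5000)
  p <- mask_params(roi = roi)
  csr <- lapply(seq(0, 4), function(i)
    generate_dataset(simulation_config(
      n_emitters = round(25 * 2^i * 0.25 * 100), # 25..400 per um^2 on 25 um^2
      clustered_fraction_true = 0, n_domains = 0, jitter_sigma = 15,
      seed = 410 + i, roi_width = 5000, roi_height = 5000))$table)
  v_csr <- verify_clustering(csr, p)
  expect_false(v_csr$degenerate_range)

  clustered <- lapply(seq(0, 4), function(i)
    generate_dataset(simulation_config(
      n_emitters = round(25 * 2^i * 0.25 * 100),
      clustered_fraction_true = 0.8,
      n_domains = max(5, round(0.8 * 25 * 2^i * 0.25 * 100 / 16)),
      jitter_sigma = 15, seed = 420 + i,
      roi_width = 5000, roi_height = 5000))$table)
  v_cl <- verify_clustering(clustered, p)
  expect_equal(v_cl$verdict, "clustered")
  expect_true(all(v_cl$stats$deviation > 0))
  expect_gt(v_cl$c, v_csr$c)

  expect_error(verify_clustering(csr[1:3], p), ">= 5")
  same <- rep(csr[2], 5)
  v_same <- verify_clustering(same, p)
  expect_true(v_same$degenerate_range)
})
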
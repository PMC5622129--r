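#' Configuration for the synthetic localization-data generator
#'
#' Encodes the acquisition and biology the generator emulates: a membrane
#' region containing disk-shaped nanodomains with lognormal diameters
#' (median ~70 nm by default), a clustered fraction of emitters placed
#' inside those domains, per-fluorophore multi-blinking (geometric blink
#' counts), isotropic localization jitter, a 4-frame activation/imaging
#' cycle, lognormal photon counts, and optional linear stage drift with
#' fiducial tracks.
#'
#' @param roi_width,roi_height region size in nm.
#' @param n_emitters number of emitters.
#' @param clustered_fraction_true fraction of emitters placed inside
#'   domains, in `[0, 1]`; 0 gives pure complete spatial randomness (CSR).
#' @param n_domains number of domains.
#' @param domain_diameter_log_mu,domain_diameter_log_sigma lognormal
#'   parameters of the domain diameter (nm); defaults give a 70 nm median.
#' @param blink_mean mean localizations per emitter (`>= 1`); blink counts
#'   are geometric on support `k >= 1`.
#' @param jitter_sigma isotropic localization noise s.d. in nm.
#' @param n_frames number of acquisition frames.
#' @param cycle_length frames per activation cycle (one activation frame
#'   followed by imaging frames).
#' @param photon_log_mu,photon_log_sigma lognormal photon-count model.
#' @param drift_velocity `NULL` or a 2-vector, nm/frame.
#' @param n_fiducials number of continuously emitting fiducial particles.
#' @param fiducial_jitter localization noise s.d. of the fiducial tracks
#'   (nm); 0 gives noiseless tracks.
#' @param seed RNG seed (integer, `< 2^30`); identical config and seed give
#'   bitwise-identical output.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(roi_width = 10000, roi_height = 10000,
                              n_emitters = 3000,
                              clustered_fraction_true = 0.5,
                              n_domains = 150,
                              domain_diameter_log_mu = log(70),
                              domain_diameter_log_sigma = 0.2,
                              blink_mean = 4,
                              jitter_sigma = 10,
                              n_frames = 40000,
                              cycle_length = 4,
                              photon_log_mu = log(2000),
                              photon_log_sigma = 0.5,
                              drift_velocity = NULL,
                              n_fiducials = 0,
                              fiducial_jitter = 0,
                              seed = 1L) {
  stopifnot(roi_width > 0, roi_height > 0, n_emitters >= 0,
            clustered_fraction_true >= 0, clustered_fraction_true <= 1,
            n_domains >= 0, blink_mean >= 1, jitter_sigma >= 0,
            n_frames >= 1, cycle_length >= 2,
            n_fiducials >= 0, fiducial_jitter >= 0,
            is.numeric(seed), seed == round(seed), abs(seed) < 2^30)
  if (!is.null(drift_velocity)) stopifnot(length(drift_velocity) == 2)
  structure(as.list(environment()), class = "simulation_config")
}

runif_disk <- function(n, cx, cy, radius) {
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(a), y = cy + r * sin(a))
}

#' Sample ground-truth emitter positions
#'
#' Places `n_domains` disk-shaped domains with lognormal diameters
#' uniformly in the ROI (overlaps allowed), puts
#' `round(clustered_fraction_true * n_emitters)` emitters uniformly inside
#' randomly chosen domains and the remainder uniformly in the ROI.
#'
#' @param config a [simulation_config()].
#' @return A list of class `"ground_truth"` with elements `emitters`
#'   (data frame: `id`, `x`, `y`, `domain`; `domain` is `NA` for CSR
#'   emitters), `domains` (data frame: `id`, `x`, `y`, `diameter`) and
#'   `config`.
#' @export
sample_emitter_positions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  with(config, {
    diam <- if (n_domains > 0) {
      stats::rlnorm(n_domains, domain_diameter_log_mu,
                    domain_diameter_log_sigma)
    } else {
      numeric()
    }
    if (length(diam) && max(diam) > min(roi_width, roi_height)) {
      stop("config error: domain diameter ", round(max(diam), 1),
           " nm exceeds ROI")
    }
    domains <- data.frame(
      id = seq_len(n_domains),
      x = stats::runif(n_domains, 0, roi_width),
      y = stats::runif(n_domains, 0, roi_height),
      diameter = diam
    )
    n_clustered <- round(clustered_fraction_true * n_emitters)
    if (n_clustered > 0 && n_domains == 0) {
      stop("config error: clustered_fraction_true > 0 requires n_domains > 0")
    }
    dom_of <- if (n_clustered > 0) {
      sample.int(n_domains, n_clustered, replace = TRUE)
    } else {
      integer()
    }
    pos_c <- if (n_clustered > 0) {
      runif_disk(n_clustered, domains$x[dom_of], domains$y[dom_of],
                 domains$diameter[dom_of] / 2)
    } else {
      cbind(x = numeric(), y = numeric())
    }
    n_csr <- n_emitters - n_clustered
    emitters <- data.frame(
      id = seq_len(n_emitters),
      x = c(pos_c[, "x"], stats::runif(n_csr, 0, roi_width)),
      y = c(pos_c[, "y"], stats::runif(n_csr, 0, roi_height)),
      domain = c(dom_of, rep(NA_integer_, n_csr))
    )
    structure(list(emitters = emitters, domains = domains, config = config),
              class = "ground_truth")
  })
}

rgeom1 <- function(n, mean) {
  # blink counts: geometric on support k >= 1 with the given mean
  if (mean <= 1) return(rep(1L, n))
  stats::rgeom(n, 1 / mean) + 1L
}

#' Render localizations from ground-truth emitters
#'
#' Per emitter draws a geometric blink count (support `k >= 1`, mean
#' `blink_mean`); each blink becomes one localization at the emitter
#' position plus isotropic normal jitter, is assigned a uniformly chosen
#' imaging frame of a random activation cycle, and draws a lognormal photon
#' count.  Linear drift (if configured) adds `drift_velocity * frame` to
#' every localization.  Fiducials emit one localization every frame and are
#' tracked separately in the returned ground truth.
#'
#' @param truth a `"ground_truth"` from [sample_emitter_positions()].
#' @param config the same [simulation_config()].
#' @param channel channel id written into the table.
#' @return A list: `table` (a [localization_table()] including fiducial
#'   localizations), `truth` (the input extended with `links`, a data frame
#'   mapping each table row to its `emitter` or `fiducial` id, and
#'   `fiducial_tracks`, a list of per-frame `frame`/`x`/`y` data frames).
#' @export
render_localizations <- function(truth, config, channel = 0L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  em <- truth$emitters
  n_cycles <- config$n_frames %/% config$cycle_length
  stopifnot(n_cycles >= 1)
  k <- rgeom1(nrow(em), config$blink_mean)
  n_loc <- sum(k)
  ex <- rep(em$x, k)
  ey <- rep(em$y, k)
  x <- ex + stats::rnorm(n_loc, 0, config$jitter_sigma)
  y <- ey + stats::rnorm(n_loc, 0, config$jitter_sigma)
  cyc <- sample.int(n_cycles, n_loc, replace = TRUE) - 1L
  # imaging frames are the cycle positions after the activation frame
  img <- sample.int(config$cycle_length - 1L, n_loc, replace = TRUE)
  frame <- cyc * config$cycle_length + img
  photons <- stats::rlnorm(n_loc, config$photon_log_mu,
                           config$photon_log_sigma)
  emitter_id <- rep(em$id, k)
  fid_id <- rep(NA_integer_, n_loc)

  # fiducials: one localization per frame, continuously bright
  if (config$n_fiducials > 0) {
    fx <- stats::runif(config$n_fiducials, 0, config$roi_width)
    fy <- stats::runif(config$n_fiducials, 0, config$roi_height)
    frames <- seq_len(config$n_frames) - 1L
    for (i in seq_len(config$n_fiducials)) {
      jx <- stats::rnorm(config$n_frames, 0, config$fiducial_jitter)
      jy <- stats::rnorm(config$n_frames, 0, config$fiducial_jitter)
      x <- c(x, fx[i] + jx)
      y <- c(y, fy[i] + jy)
      frame <- c(frame, frames)
      photons <- c(photons, rep(10 * exp(config$photon_log_mu),
                                config$n_frames))
      emitter_id <- c(emitter_id, rep(NA_integer_, config$n_frames))
      fid_id <- c(fid_id, rep(i, config$n_frames))
    }
  }

  if (!is.null(config$drift_velocity)) {
    x <- x + config$drift_velocity[1] * frame
    y <- y + config$drift_velocity[2] * frame
  }

  ord <- order(frame, seq_along(frame))
  tab <- localization_table(x = x[ord], y = y[ord], frame = frame[ord],
                            photons = photons[ord], channel = channel)
  truth$links <- data.frame(emitter = emitter_id[ord], fiducial = fid_id[ord])
  truth$fiducial_tracks <- if (config$n_fiducials > 0) {
    lapply(seq_len(config$n_fiducials), function(i) {
      sel <- which(truth$links$fiducial == i)
      data.frame(frame = tab$frame[sel], x = tab$x[sel], y = tab$y[sel])
    })
  } else {
    list()
  }
  list(table = tab, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Composes [sample_emitter_positions()] and [render_localizations()].
#' Two-channel modes support colocalization tests: channel 1 can share the
#' channel-0 emitters (`"identical"`, independent blinks and jitter), use an
#' independently resampled emitter set (`"independent"`), or use the
#' channel-0 emitters rigidly translated (`"offset"`).
#'
#' @param config a [simulation_config()].
#' @param channel_mode `"single"`, `"identical"`, `"independent"` or
#'   `"offset"`.
#' @param offset 2-vector translation in nm for `channel_mode = "offset"`.
#' @return A list `table` (all channels), `truth` (channel 0) and, in
#'   two-channel modes, `truth1` (channel 1).
#' @export
generate_dataset <- function(config,
                             channel_mode = c("single", "identical",
                                              "independent", "offset"),
                             offset = c(500, 0)) {
  channel_mode <- match.arg(channel_mode)
  truth0 <- sample_emitter_positions(config)
  r0 <- render_localizations(truth0, config, channel = 0L)
  if (channel_mode == "single") {
    return(list(table = r0$table, truth = r0$truth))
  }
  cfg1 <- config
  cfg1$seed <- config$seed + 2L
  truth1 <- switch(channel_mode,
    identical = {
      t1 <- truth0
      t1$config <- cfg1
      t1
    },
    independent = sample_emitter_positions(cfg1),
    offset = {
      t1 <- truth0
      t1$emitters$x <- t1$emitters$x + offset[1]
      t1$emitters$y <- t1$emitters$y + offset[2]
      t1$config <- cfg1
      t1
    })
  r1 <- render_localizations(truth1, cfg1, channel = 1L)
  tab <- rbind(r0$table, r1$table)
  tab <- localization_table(x = tab$x, y = tab$y, frame = tab$frame,
                            photons = tab$photons, channel = tab$channel,
                            precision = tab$precision)
  list(table = tab, truth = r0$truth, truth1 = r1$truth)
}

#' Write a dataset (localizations, ground truth, config snapshot) to disk
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory, created if needed.
#' @param stem file-name stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir, stem = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    localizations = file.path(dir, paste0(stem, "_localizations.csv")),
    ground_truth = file.path(dir, paste0(stem, "_ground_truth.csv")),
    config = file.path(dir, paste0(stem, "_config.json"))
  )
  write_localizations(dataset$table, paths[["localizations"]])
  utils::write.csv(dataset$truth$emitters, paths[["ground_truth"]],
                   row.names = FALSE)
  cfg <- dataset$truth$config
  cfg$drift_velocity <- if (is.null(cfg$drift_velocity)) NULL else
    as.numeric(cfg$drift_velocity)
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
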
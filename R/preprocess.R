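#' Acquisition-cycle configuration for blink correction
#'
#' Parameters of the STORM acquisition scheme the duplicate-event
#' corrections operate on: cycles of `cycle_length` frames, one activation
#' frame (position `activation_frame_index`) followed by imaging frames,
#' the camera pixel size used for the +/- 1 pixel repeat rule, the photon
#' quality threshold (200 for Dronpa/PALM, 1000 for STORM dyes), and the
#' spatial tolerance for consecutive-frame merging.
#'
#' @param cycle_length frames per cycle, `>= 2` (4 for STORM).
#' @param activation_frame_index position of the activation frame within
#'   the cycle, 0-based.
#' @param pixel_size camera pixel size in nm, `> 0`.  The pixel grid
#'   origin is fixed at the ROI origin (`floor(position / pixel_size)`).
#' @param photon_min photon threshold, `>= 0`.
#' @param merge_radius spatial tolerance in nm for consecutive-frame
#'   merging.
#' @return A list of class `"cycle_config"`.
#' @export
cycle_config <- function(cycle_length = 4, activation_frame_index = 0,
                         pixel_size = 160, photon_min = 1000,
                         merge_radius = 50) {
  stopifnot(cycle_length >= 2, pixel_size > 0, photon_min >= 0,
            merge_radius > 0,
            activation_frame_index >= 0,
            activation_frame_index < cycle_length)
  structure(list(cycle_length = as.integer(cycle_length),
                 activation_frame_index = as.integer(activation_frame_index),
                 pixel_size = pixel_size, photon_min = photon_min,
                 merge_radius = merge_radius),
            class = "cycle_config")
}

# imaging-frame number within the cycle (1-based), NA for the activation
# frame
imaging_frame_no <- function(frame, cfg) {
  pos <- frame %% cfg$cycle_length
  no <- pos - cfg$activation_frame_index
  no[no <= 0L] <- NA_integer_
  no
}

#' Activation-cycle duplicate filter for quantitative STORM
#'
#' Implements the 4-frame-cycle single-event rule: within each cycle and
#' camera-pixel bin, an event is kept only when it appears in imaging
#' frame 1 of the cycle and the same bin shows no event in imaging
#' frame 3 ("gone by the third imaging frame"; presence in imaging frame 2
#' is tolerated, and those frame-2/3 detections of the same particle are
#' not counted again).  A kept event is then removed when its pixel bin,
#' +/- 1 pixel in both axes, also produced a kept event in the
#' immediately preceding cycle (the later occurrence of a repeat is
#' removed; repeats are judged against the set kept by the first rule).
#'
#' The rule is defined per cycle and pixel bin, so tables spanning any
#' frame range (including a single partial cycle, as arises when the
#' filter is re-applied to its own output) are processed consistently;
#' this makes the filter idempotent.
#'
#' @param table a [localization_table()].
#' @param cfg a [cycle_config()]; `cycle_length` must match the
#'   acquisition that produced the table.
#' @return The filtered table, in the original row order of the survivors,
#'   with attribute `n_removed`.
#' @export
storm_cycle_filter <- function(table, cfg = cycle_config()) {
  assert_localization_table(table)
  n <- nrow(table)
  if (n == 0L) return(table)
  cyc <- table$frame %/% cfg$cycle_length
  img <- imaging_frame_no(table$frame, cfg)
  px <- floor(table$x / cfg$pixel_size)
  py <- floor(table$y / cfg$pixel_size)
  bin <- paste(px, py)
  key <- paste(cyc, bin)
  frame3_bins <- unique(key[!is.na(img) & img == 3L])
  keep <- !is.na(img) & img == 1L & !(key %in% frame3_bins)

  # repeat removal against the kept set of the previous cycle
  kept_idx <- which(keep)
  if (length(kept_idx)) {
    prev_keys <- character()
    for (di in -1:1) {
      for (dj in -1:1) {
        prev_keys <- c(prev_keys, paste(cyc[kept_idx] + 1L,
                                        px[kept_idx] + di,
                                        py[kept_idx] + dj))
      }
    }
    repeat_of_prev <- paste(cyc[kept_idx], px[kept_idx], py[kept_idx]) %in%
      prev_keys
    keep[kept_idx[repeat_of_prev]] <- FALSE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - nrow(out)
  class(out) <- class(table)
  out
}

#' Merge detections persisting over consecutive frames
#'
#' Chains of localizations in strictly consecutive frames, each within
#' `merge_radius` of the previous chain member, are collapsed to a single
#' localization at the photon-weighted mean position of the chain, with
#' the frame of the first member and the summed photon count.  Chains are
#' built greedily in frame order: each localization extends the nearest
#' unclaimed chain that ended in the previous frame (ties by smallest
#' distance, then lowest input row index), or starts a new chain.
#'
#' @param table a [localization_table()].
#' @param cfg a [cycle_config()]; only `merge_radius` is used.
#' @return The merged table (one row per chain, ordered by first frame then
#'   first input row), with attribute `n_merged` (input rows absorbed).
#' @export
merge_consecutive_detections <- function(table, cfg = cycle_config()) {
  assert_localization_table(table)
  n <- nrow(table)
  if (n == 0L) return(table)
  ord <- order(table$frame, seq_len(n))
  chain_of <- integer(n)            # chain id per input row (in ord space)
  n_chain <- 0L
  chain_first <- integer()          # first input row of each chain
  tail_x <- tail_y <- numeric()     # last member position per chain
  tail_frame <- integer()
  members <- list()
  r2 <- cfg$merge_radius^2
  frames <- table$frame[ord]
  for (pos in seq_len(n)) {
    i <- ord[pos]
    f <- frames[pos]
    active <- which(tail_frame == f - 1L)
    best <- 0L
    if (length(active)) {
      d2 <- (tail_x[active] - table$x[i])^2 + (tail_y[active] - table$y[i])^2
      ok <- d2 <= r2
      if (any(ok)) {
        cand <- active[ok]
        d2 <- d2[ok]
        # smallest distance, then lowest first-row index of the chain
        best <- cand[order(d2, chain_first[cand])][1L]
      }
    }
    if (best > 0L) {
      members[[best]] <- c(members[[best]], i)
      tail_x[best] <- table$x[i]
      tail_y[best] <- table$y[i]
      tail_frame[best] <- f
    } else {
      n_chain <- n_chain + 1L
      chain_first[n_chain] <- i
      members[[n_chain]] <- i
      tail_x[n_chain] <- table$x[i]
      tail_y[n_chain] <- table$y[i]
      tail_frame[n_chain] <- f
    }
  }
  collapse <- function(idx) {
    w <- table$photons[idx]
    if (anyNA(w) || all(w == 0)) w <- rep(1, length(idx))
    data.frame(
      x = sum(table$x[idx] * w) / sum(w),
      y = sum(table$y[idx] * w) / sum(w),
      frame = min(table$frame[idx]),
      photons = if (anyNA(table$photons[idx])) NA_real_ else
        sum(table$photons[idx]),
      channel = table$channel[idx[1L]],
      precision = table$precision[idx[1L]]
    )
  }
  rows <- do.call(rbind, lapply(members[seq_len(n_chain)], collapse))
  ord_out <- order(rows$frame, chain_first[seq_len(n_chain)])
  rows <- rows[ord_out, , drop = FALSE]
  out <- localization_table(rows$x, rows$y, rows$frame, rows$photons,
                            rows$channel, rows$precision)
  attr(out, "n_merged") <- n - nrow(out)
  out
}

#' Photon-count quality filter
#'
#' Removes localizations with fewer than `photon_min` photons (threshold
#' kept at the boundary).  Localizations with missing photon counts are
#' removed when `photon_min > 0`, since their quality cannot be certified.
#'
#' @param table a [localization_table()].
#' @param cfg a [cycle_config()]; only `photon_min` is used.
#' @return The filtered table with attribute `n_removed`.
#' @export
quality_filter <- function(table, cfg = cycle_config()) {
  assert_localization_table(table)
  if (!"photons" %in% names(table)) stop("schema error: no photons column")
  if (cfg$photon_min <= 0) {
    attr(table, "n_removed") <- 0L
    return(table)
  }
  keep <- !is.na(table$photons) & table$photons >= cfg$photon_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L && nrow(table) > 0L) {
    warning("quality_filter removed every localization (photon_min = ",
            cfg$photon_min, ")")
  }
  attr(out, "n_removed") <- nrow(table) - nrow(out)
  class(out) <- class(table)
  out
}

#' Fiducial-based drift correction
#'
#' Estimates per-frame stage drift from one or more continuously bright
#' fiducial particles: each track is linearly interpolated over the full
#' frame range of the table (edge frames extend the nearest observation),
#' its displacement from its first-frame position is taken, displacements
#' are averaged over fiducials and smoothed by a centered moving average,
#' and the resulting drift is subtracted from every localization according
#' to its frame.  The drift model is translation-only.
#'
#' @param table a [localization_table()].
#' @param fiducial_tracks a data frame with columns `frame`, `x`, `y`, or a
#'   list of such data frames (one per fiducial).  Each fiducial should be
#'   localized in at least 90% of the frames; sparser tracks trigger a
#'   warning.
#' @param window moving-average window in frames (default 50); 1 disables
#'   smoothing.
#' @return The drift-corrected table; attribute `drift` holds the per-frame
#'   drift table (`frame`, `dx`, `dy`).
#' @export
drift_correct_fiducials <- function(table, fiducial_tracks, window = 50) {
  assert_localization_table(table)
  if (is.data.frame(fiducial_tracks)) {
    fiducial_tracks <- list(fiducial_tracks)
  }
  if (!length(fiducial_tracks)) {
    stop("no fiducial track supplied; skip drift correction instead")
  }
  if (nrow(table) == 0L) return(table)
  frames <- seq(min(table$frame), max(table$frame))
  n_f <- length(frames)
  dx <- dy <- matrix(0, n_f, length(fiducial_tracks))
  for (i in seq_along(fiducial_tracks)) {
    tr <- fiducial_tracks[[i]]
    stopifnot(all(c("frame", "x", "y") %in% names(tr)), nrow(tr) >= 1)
    if (nrow(tr) < 0.9 * n_f) {
      warning("fiducial ", i, " localized in ",
              round(100 * nrow(tr) / n_f), "% of frames (< 90%)")
    }
    ix <- stats::approx(tr$frame, tr$x, xout = frames, rule = 2)$y
    iy <- stats::approx(tr$frame, tr$y, xout = frames, rule = 2)$y
    if (window > 1) {
      ix <- moving_average(ix, window)
      iy <- moving_average(iy, window)
    }
    dx[, i] <- ix - ix[1L]
    dy[, i] <- iy - iy[1L]
  }
  mdx <- rowMeans(dx)
  mdy <- rowMeans(dy)
  # re-anchor at the first frame with a linear fit over the first window:
  # anchoring to the raw first observation would bake its localization
  # noise into every frame, while this is exact for linear drift
  w <- min(max(2L * window, 2L), n_f)
  if (w >= 2L) {
    h <- floor(window / 2)
    eff <- 2L * pmin(h, seq_len(w) - 1L, n_f - seq_len(w)) + 1L
    mdx <- mdx - anchor_intercept(frames[seq_len(w)], mdx[seq_len(w)],
                                  frames[1L], eff)
    mdy <- mdy - anchor_intercept(frames[seq_len(w)], mdy[seq_len(w)],
                                  frames[1L], eff)
  }
  at <- match(table$frame, frames)
  out <- table
  out$x <- table$x - mdx[at]
  out$y <- table$y - mdy[at]
  attr(out, "drift") <- data.frame(frame = frames, dx = mdx, dy = mdy)
  out
}

# value of the least-squares line through (f, v) at f0, with weights
# proportional to the effective smoothing window of each value (the edge
# values of a shrinking-window moving average are nearly raw and must not
# dominate the anchor)
anchor_intercept <- function(f, v, f0, w = rep(1, length(f))) {
  w <- w / sum(w)
  fm <- sum(w * f)
  vm <- sum(w * v)
  b <- sum(w * (f - fm) * (v - vm)) / sum(w * (f - fm)^2)
  vm + b * (f0 - fm)
}

# centered moving average; the half-width shrinks symmetrically at the
# edges, so linear trends are preserved exactly everywhere
moving_average <- function(v, window) {
  h <- floor(window / 2)
  n <- length(v)
  cs <- cumsum(c(0, v))
  hs <- pmin(h, seq_len(n) - 1L, n - seq_len(n))
  lo <- seq_len(n) - hs
  hi <- seq_len(n) + hs
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
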
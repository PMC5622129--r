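# Exact fixed-radius neighbor queries via a uniform grid index.
# Contract: exact Euclidean neighbor sets (no approximation); the grid only
# prunes candidates.

grid_cells <- function(x, y, cell) {
  paste(floor(x / cell), floor(y / cell))
}

#' Exact fixed-radius neighbor query
#'
#' For each query point returns the indices of (and distances to) all
#' reference points within `radius`, using a uniform grid with cell size
#' `radius` to prune candidates.  With `exclude_same_index = TRUE` the
#' reference point with the same index as the query is skipped (self-query
#' on one point set).
#'
#' @param qx,qy query coordinates (nm).
#' @param rx,ry reference coordinates (nm).
#' @param radius search radius (nm).
#' @param exclude_same_index skip reference index `i` for query `i`.
#' @return List with one element per query point, each a list with integer
#'   `idx` and numeric `dist` sorted by index.
#' @keywords internal
fr_query <- function(qx, qy, rx, ry, radius, exclude_same_index = FALSE) {
  stopifnot(radius > 0)
  nq <- length(qx)
  out <- vector("list", nq)
  if (nq == 0L) return(out)
  if (length(rx) == 0L) {
    empty <- list(idx = integer(), dist = numeric())
    for (i in seq_len(nq)) out[[i]] <- empty
    return(out)
  }
  cells <- split(seq_along(rx), grid_cells(rx, ry, radius))
  env <- list2env(cells, hash = TRUE, size = max(16L, length(cells)))
  qi <- floor(qx / radius)
  qj <- floor(qy / radius)
  r2 <- radius^2
  for (i in seq_len(nq)) {
    cand <- integer()
    for (di in -1:1) {
      ii <- qi[i] + di
      for (dj in -1:1) {
        hit <- get0(paste(ii, qj[i] + dj), envir = env, inherits = FALSE)
        if (!is.null(hit)) cand <- c(cand, hit)
      }
    }
    if (exclude_same_index) cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (rx[cand] - qx[i])^2 + (ry[cand] - qy[i])^2
      keep <- d2 <= r2
      cand <- cand[keep]
      ord <- order(cand)
      out[[i]] <- list(idx = cand[ord], dist = sqrt(d2[keep])[ord])
    } else {
      out[[i]] <- list(idx = integer(), dist = numeric())
    }
  }
  out
}
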
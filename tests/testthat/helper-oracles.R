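# Independent brute-force oracles.  These deliberately avoid the package's
# grid index and incremental algorithms: all-pairs distance matrices,
# explicit neighbor graphs, half-plane tests, fan triangulation.

# DBSCAN via explicit neighbor graph + connected components, with the same
# published conventions (self-inclusive counting, clusters numbered by
# first core point, border ties to the lowest cluster id)
oracle_dbscan <- function(x, y, eps, minpts) {
  n <- length(x)
  if (n == 0L) return(integer())
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- d <= eps
  core <- rowSums(adj) >= minpts           # self included on the diagonal
  label <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || label[i] != -1L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & label == -1L &
                      colSums(adj[comp, , drop = FALSE]) > 0)
      grow <- setdiff(grow, comp)
      label[comp] <- cl
      if (!length(grow)) break
      comp <- grow
    }
  }
  for (i in which(!core)) {
    lbl <- label[adj[i, ] & core]
    if (length(lbl)) label[i] <- min(lbl)
  }
  label
}

# hull vertex set by the all-pairs half-plane test: a directed edge (i, j)
# is on the hull iff every other point lies strictly to its left
oracle_hull_vertices <- function(pts) {
  n <- nrow(pts)
  if (n <= 2L) return(unique(pts))
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
      if (all(cr[-c(i, j)] > 0)) {
        on_hull[c(i, j)] <- TRUE
      }
    }
  }
  unique(pts[on_hull, , drop = FALSE])
}

# polygon area by fan triangulation from the first vertex
oracle_fan_area <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  tri <- function(a, b, c) {
    ((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  }
  abs(sum(vapply(2:(n - 1), function(k) tri(v[1, ], v[k, ], v[k + 1, ]),
                 numeric(1))))
}

# all-pairs fixed-radius neighbor counts (self excluded)
oracle_neighbor_counts <- function(x, y, r) {
  if (!length(x)) return(integer())
  d <- as.matrix(stats::dist(cbind(x, y)))
  as.integer(rowSums(d <= r) - 1L)
}

# activation-cycle filter by direct restatement of the rule on event lists
oracle_cycle_filter_keep <- function(frame, px, py, cycle_length = 4L,
                                     activation = 0L) {
  cyc <- frame %/% cycle_length
  img <- frame %% cycle_length - activation
  img[img <= 0L] <- NA_integer_
  keep <- logical(length(frame))
  for (i in seq_along(frame)) {
    if (is.na(img[i]) || img[i] != 1L) next
    same_bin_cycle <- cyc == cyc[i] & px == px[i] & py == py[i]
    keep[i] <- !any(same_bin_cycle & !is.na(img) & img == 3L)
  }
  kept <- which(keep)
  for (i in kept) {
    prev <- kept[cyc[kept] == cyc[i] - 1L &
                   abs(px[kept] - px[i]) <= 1L &
                   abs(py[kept] - py[i]) <= 1L]
    if (length(prev)) keep[i] <- FALSE
  }
  keep
}
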
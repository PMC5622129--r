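# Programmatic fixtures

# tight Gaussian blobs on a jittered grid, far enough apart not to merge
make_blob_table <- function(n_blobs, n_per, spread = 8, spacing = 2000,
                            seed = 1) {
  set.seed(seed)
  side <- ceiling(sqrt(n_blobs))
  cx <- (((seq_len(n_blobs) - 1L) %% side) + 0.5) * spacing
  cy <- (((seq_len(n_blobs) - 1L) %/% side) + 0.5) * spacing
  x <- rep(cx, each = n_per) + rnorm(n_blobs * n_per, 0, spread)
  y <- rep(cy, each = n_per) + rnorm(n_blobs * n_per, 0, spread)
  tab <- localization_table(x, y, frame = seq_along(x) - 1L,
                            photons = 1500)
  attr(tab, "blob") <- rep(seq_len(n_blobs), each = n_per)
  tab
}

csr_table <- function(n, width = 10000, height = 10000, seed = 1) {
  set.seed(seed)
  localization_table(runif(n, 0, width), runif(n, 0, height),
                     frame = seq_len(n) - 1L, photons = 1500)
}

# canonical partition form: labels renumbered by first occurrence among
# clustered points, noise kept at -1 (for comparisons up to relabeling)
canonical_labels <- function(label) {
  out <- label
  ids <- unique(label[label >= 0L])
  out[label >= 0L] <- match(label[label >= 0L], ids)
  out
}
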
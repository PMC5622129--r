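#' DBSCAN parameters
#'
#' The two DBSCAN inputs: the search radius epsilon (nm) and the minimum
#' point count MinPts.  Defaults are the cluster-stage values used for
#' STORM data (`epsilon = 30`, `min_pts = 20`); the monomer-filter stage
#' uses [monomer_params()] (`epsilon = 60`, `min_pts = 10`).  PALM (Dronpa)
#' data are typically clustered with `min_pts = 5` (or 3 under sparse
#' labeling); MinPts is strictly configuration.
#'
#' @param epsilon search radius in nm, `> 0`.
#' @param min_pts minimum number of points (self included) within
#'   `epsilon` for a core point, integer `>= 1`.
#' @return A list of class `"cluster_params"`.
#' @export
cluster_params <- function(epsilon = 30, min_pts = 20) {
  stopifnot(epsilon > 0, min_pts >= 1, min_pts == round(min_pts))
  structure(list(epsilon = epsilon, min_pts = as.integer(min_pts)),
            class = "cluster_params")
}

#' @rdname cluster_params
#' @export
monomer_params <- function(epsilon = 60, min_pts = 10) {
  cluster_params(epsilon, min_pts)
}

#' Density-based clustering (DBSCAN) of a localization table
#'
#' Standard DBSCAN semantics in the 2-D Euclidean metric: a point is a
#' *core* point when at least `min_pts` points (itself included) lie within
#' `epsilon`; clusters are the connected components of core points under
#' epsilon-reachability together with their *border* points (non-core
#' points within `epsilon` of a core point); everything else is *noise*
#' (label -1).  Labels are deterministic for a fixed input order: clusters
#' are numbered by their first core point, and a border point reachable
#' from several clusters joins the lowest cluster id.
#'
#' @param table a [localization_table()] (or any data frame with `x`, `y`).
#' @param params a [cluster_params()].
#' @param denominator_n total used for the clustered-fraction percentage;
#'   defaults to `nrow(table)`.  [two_stage_cluster()] uses it to report
#'   the fraction against the pre-filter total.
#' @return An object of class `"cluster_assignment"`: a list with integer
#'   `label` (-1 = noise), character `status` (`"core"`, `"border"`,
#'   `"noise"`), `n_clusters`, `clustered_fraction` (percent of the
#'   denominator) and the parameters used.
#' @export
run_dbscan <- function(table, params = cluster_params(),
                       denominator_n = nrow(table)) {
  stopifnot(inherits(params, "cluster_params"))
  n <- nrow(table)
  if (n == 0L) {
    return(structure(list(label = integer(), status = character(),
                          n_clusters = 0L, clustered_fraction = 0,
                          params = params, n = 0L,
                          denominator_n = denominator_n),
                     class = "cluster_assignment"))
  }
  nb <- fr_query(table$x, table$y, table$x, table$y, params$epsilon)
  n_nbr <- vapply(nb, function(e) length(e$idx), integer(1))
  core <- n_nbr >= params$min_pts
  label <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || label[i] != -1L) next
    cl <- cl + 1L
    label[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      reach <- nb[[j]]$idx
      new_core <- reach[core[reach] & label[reach] == -1L]
      label[new_core] <- cl
      queue <- c(queue, new_core)
    }
  }
  # border points: lowest cluster id among core neighbors
  for (i in which(!core)) {
    cn <- nb[[i]]$idx
    lbl <- label[cn[core[cn]]]
    if (length(lbl)) label[i] <- min(lbl)
  }
  status <- ifelse(core, "core", ifelse(label >= 0L, "border", "noise"))
  structure(list(
    label = label, status = status, n_clusters = cl,
    clustered_fraction = 100 * sum(label >= 0L) / max(denominator_n, 1L),
    params = params, n = n, denominator_n = denominator_n
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "DBSCAN assignment: %d localizations, %d cluster(s), %.1f%% clustered\n",
    x$n, x$n_clusters, x$clustered_fraction))
  cat(sprintf("  epsilon = %g nm, MinPts = %d; %d core, %d border, %d noise\n",
              x$params$epsilon, x$params$min_pts,
              sum(x$status == "core"), sum(x$status == "border"),
              sum(x$status == "noise")))
  invisible(x)
}

#' @export
summary.cluster_assignment <- function(object, ...) {
  sizes <- if (object$n_clusters > 0) {
    as.integer(table(object$label[object$label >= 0L]))
  } else {
    integer()
  }
  out <- list(n = object$n, n_clusters = object$n_clusters,
              clustered_fraction = object$clustered_fraction,
              cluster_sizes = sizes)
  class(out) <- "summary.cluster_assignment"
  out
}

#' @export
print.summary.cluster_assignment <- function(x, ...) {
  cat(sprintf("%d localizations in %d clusters (%.1f%% clustered)\n",
              x$n, x$n_clusters, x$clustered_fraction))
  if (length(x$cluster_sizes)) {
    cat("cluster sizes (localizations):\n")
    print(summary(x$cluster_sizes))
  }
  invisible(x)
}

#' Two-stage nanodomain clustering
#'
#' Stage 1 runs DBSCAN with the monomer-filter parameters and discards the
#' noise-labeled localizations (the "monomer fraction"); stage 2 runs
#' DBSCAN with the cluster parameters on the survivors.  The clustered
#' fraction is reported, by default, against the total number of input
#' localizations (before monomer filtering); `denominator = "filtered"`
#' reports it against the stage-1 survivors instead.
#'
#' @param table a [localization_table()].
#' @param monomer_params stage-1 [cluster_params()] (default 60 nm / 10).
#' @param params stage-2 [cluster_params()] (default 30 nm / 20).
#' @param denominator `"total"` or `"filtered"`.
#' @return A `"cluster_assignment"` aligned to `table` (length
#'   `nrow(table)`): localizations removed in stage 1 carry label -1 and
#'   status `"noise"`.  Extra fields record the stage-1 survivor count.
#' @export
two_stage_cluster <- function(table,
                              monomer_params = nanodomain::monomer_params(),
                              params = cluster_params(),
                              denominator = c("total", "filtered")) {
  denominator <- match.arg(denominator)
  n <- nrow(table)
  stage1 <- run_dbscan(table, monomer_params)
  keep <- stage1$label >= 0L
  denom <- if (denominator == "total") n else sum(keep)
  stage2 <- run_dbscan(table[keep, , drop = FALSE], params,
                       denominator_n = max(denom, 1L))
  label <- rep(-1L, n)
  status <- rep("noise", n)
  label[keep] <- stage2$label
  status[keep] <- stage2$status
  structure(list(
    label = label, status = status, n_clusters = stage2$n_clusters,
    clustered_fraction = if (n == 0L) 0 else
      100 * sum(label >= 0L) / max(denom, 1L),
    params = params, monomer_params = monomer_params,
    n = n, denominator_n = denom, n_after_monomer_filter = sum(keep)
  ), class = "cluster_assignment")
}

#' Color palette for cluster maps
#'
#' One distinct color per cluster; noise is drawn gray.
#' @param n number of clusters.
#' @return Character vector of `n` colors.
#' @export
cluster_palette <- function(n) {
  if (n <= 0) return(character())
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                 c = 100, l = 60)
}

#' Write a cluster map
#'
#' Writes the per-localization assignment as CSV (`x`, `y`, `label`,
#' `status`) and, optionally, a rendered scatter map (PNG) with one color
#' per cluster and non-clustered localizations in gray.
#'
#' @param assignment a `"cluster_assignment"` aligned to `table`.
#' @param table the clustered [localization_table()].
#' @param path CSV output path.
#' @param plot_path optional PNG output path.
#' @return `path`, invisibly.
#' @export
cluster_map <- function(assignment, table, path, plot_path = NULL) {
  if (length(assignment$label) != nrow(table)) {
    stop("assignment and table lengths differ (",
         length(assignment$label), " vs ", nrow(table), ")")
  }
  utils::write.csv(
    data.frame(x = table$x, y = table$y, label = assignment$label,
               status = assignment$status),
    path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 1200, height = 1200, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(assignment, table)
  }
  invisible(path)
}

#' Plot a cluster assignment
#'
#' Scatter map of the localizations, color-coded by cluster with noise in
#' gray.
#'
#' @param x a `"cluster_assignment"`.
#' @param table the clustered [localization_table()].
#' @param pch,cex,... passed to [graphics::plot()].
#' @export
plot.cluster_assignment <- function(x, table, pch = 16, cex = 0.3, ...) {
  cols <- rep("gray70", length(x$label))
  if (x$n_clusters > 0) {
    pal <- cluster_palette(x$n_clusters)
    sel <- x$label >= 1L
    cols[sel] <- pal[x$label[sel]]
  }
  graphics::plot(table$x, table$y, col = cols, pch = pch, cex = cex,
                 asp = 1, xlab = "x (nm)", ylab = "y (nm)", ...)
  invisible(x)
}
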
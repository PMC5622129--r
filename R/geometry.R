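#' Convex hull by Andrew's monotone chain
#'
#' Returns the hull vertices in counter-clockwise order with no three
#' consecutive collinear vertices.  Degenerate inputs follow the
#' conventions used downstream: a single (possibly repeated) point returns
#' that point, a collinear set returns its two extreme endpoints; both have
#' zero area.
#'
#' @param points a 2-column matrix (or data frame) of x/y positions in nm.
#' @return A 2-column matrix of hull vertices, counter-clockwise.
#' @export
#' @examples
#' convex_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)))
convex_hull <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) == 0L) stop("convex_hull: empty input")
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2L) return(unname(pts))
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(idx) {
    hull <- integer()
    for (i in idx) {
      while (length(hull) >= 2L &&
             cross(pts[hull[length(hull) - 1L], ],
                   pts[hull[length(hull)], ], pts[i, ]) <= 0) {
        hull <- hull[-length(hull)]
      }
      hull <- c(hull, i)
    }
    hull
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  idx <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(idx) < 3L) {        # collinear set: the two extremes
    return(unname(pts[c(1L, n), , drop = FALSE]))
  }
  unname(pts[idx, , drop = FALSE])
}

#' Polygon area by the shoelace (Gauss / surveyor's) formula
#'
#' `|sum(x_i * y_{i+1} - x_{i+1} * y_i)| / 2`; orientation-independent via
#' the absolute value.  Fewer than three vertices give area 0.
#'
#' @param vertices 2-column matrix of polygon vertices, in order (the
#'   polygon is closed implicitly).
#' @return Area in nm^2.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(seq_len(n)[-1], 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Per-cluster hulls, areas and equivalent diameters
#'
#' For every cluster in the assignment computes the convex hull of its
#' member localizations, the shoelace area, and the diameter of the circle
#' with equal area (`2 * sqrt(area / pi)`) -- the package's "cluster
#' diameter" convention for irregular clusters.  Clusters with fewer than
#' three distinct non-collinear members are reported with area 0 and
#' `degenerate = TRUE`; they are excluded from distribution fits.
#'
#' @param assignment a `"cluster_assignment"` aligned to `table`.
#' @param table the clustered [localization_table()].
#' @return A list of class `"cluster_geometry_list"`: data frame `sizes`
#'   (`cluster_id`, `n_localizations`, `area`, `equivalent_diameter`,
#'   `degenerate`) and list `hulls` of vertex matrices.
#' @export
cluster_sizes <- function(assignment, table) {
  if (length(assignment$label) != nrow(table)) {
    stop("assignment and table lengths differ")
  }
  ids <- sort(unique(assignment$label[assignment$label >= 0L]))
  hulls <- vector("list", length(ids))
  sizes <- data.frame(cluster_id = ids,
                      n_localizations = integer(length(ids)),
                      area = numeric(length(ids)),
                      equivalent_diameter = numeric(length(ids)),
                      degenerate = logical(length(ids)))
  for (k in seq_along(ids)) {
    m <- assignment$label == ids[k]
    pts <- cbind(table$x[m], table$y[m])
    h <- convex_hull(pts)
    a <- polygon_area(h)
    hulls[[k]] <- h
    sizes$n_localizations[k] <- sum(m)
    sizes$area[k] <- a
    sizes$equivalent_diameter[k] <- 2 * sqrt(a / pi)
    sizes$degenerate[k] <- a <= 0
  }
  structure(list(sizes = sizes, hulls = hulls),
            class = "cluster_geometry_list")
}

#' @export
print.cluster_geometry_list <- function(x, ...) {
  s <- x$sizes
  ok <- !s$degenerate
  cat(sprintf("Cluster geometry: %d cluster(s), %d with positive area\n",
              nrow(s), sum(ok)))
  if (any(ok)) {
    cat(sprintf("  median area %.0f nm^2, median equivalent diameter %.1f nm\n",
                stats::median(s$area[ok]),
                stats::median(s$equivalent_diameter[ok])))
  }
  invisible(x)
}

#' Lognormal fit of the cluster-size distribution
#'
#' Maximum-likelihood lognormal fit of the chosen size variable (hull area
#' or equivalent diameter): `log_mu` and `log_sigma` are the mean and the
#' maximum-likelihood (1/n) standard deviation of the log sizes.
#' Degenerate (zero-area) clusters are excluded; at least 5 positive sizes
#' are required.  The empirical cumulative curve is returned alongside for
#' cumulative-distribution plots.
#'
#' @param geometries a `"cluster_geometry_list"` from [cluster_sizes()],
#'   or a numeric vector of sizes.
#' @param variable `"area"` (nm^2) or `"diameter"` (nm).
#' @return An object of class `"size_distribution_fit"`: `log_mu`,
#'   `log_sigma` (guarded below by 1e-6), `n_clusters`, `variable`, and
#'   `cumulative_curve` (data frame `size`, `cumulative`, non-decreasing
#'   from 1/n to 1).
#' @export
fit_size_distribution <- function(geometries, variable = c("area",
                                                           "diameter")) {
  variable <- match.arg(variable)
  sizes <- if (is.numeric(geometries)) {
    geometries
  } else {
    s <- geometries$sizes[!geometries$sizes$degenerate, , drop = FALSE]
    if (variable == "area") s$area else s$equivalent_diameter
  }
  sizes <- sizes[is.finite(sizes) & sizes > 0]
  if (length(sizes) < 5L) {
    stop("fit error: need >= 5 clusters with positive size, have ",
         length(sizes))
  }
  ls <- log(sizes)
  log_mu <- mean(ls)
  log_sigma <- max(sqrt(mean((ls - log_mu)^2)), 1e-6)
  sorted <- sort(sizes)
  structure(list(
    log_mu = log_mu, log_sigma = log_sigma, n_clusters = length(sizes),
    variable = variable,
    cumulative_curve = data.frame(size = sorted,
                                  cumulative = seq_along(sorted) /
                                    length(sorted))
  ), class = "size_distribution_fit")
}

#' @export
print.size_distribution_fit <- function(x, ...) {
  cat(sprintf(
    "Lognormal %s fit: n = %d, log_mu = %.4f, log_sigma = %.4f\n",
    x$variable, x$n_clusters, x$log_mu, x$log_sigma))
  cat(sprintf("  median %s = %.1f %s\n", x$variable, exp(x$log_mu),
              if (x$variable == "area") "nm^2" else "nm"))
  invisible(x)
}

#' Plot an empirical cumulative size distribution with its lognormal fit
#'
#' @param x a `"size_distribution_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.size_distribution_fit <- function(x, ...) {
  cc <- x$cumulative_curve
  graphics::plot(cc$size, cc$cumulative, type = "s",
                 xlab = sprintf("cluster %s (%s)", x$variable,
                                if (x$variable == "area") "nm^2" else "nm"),
                 ylab = "cumulative probability", ylim = c(0, 1), ...)
  xx <- seq(min(cc$size), max(cc$size), length.out = 200)
  graphics::lines(xx, stats::plnorm(xx, x$log_mu, x$log_sigma), col = "red")
  invisible(x)
}
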
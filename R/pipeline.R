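#' Run the nanodomain analysis pipeline over a manifest of images
#'
#' For every image listed in the manifest: read the localization table,
#' optionally apply the photon quality filter, the activation-cycle
#' filter and consecutive-frame merging, run the two-stage DBSCAN
#' clustering, and compute per-cluster geometry.  Failures are recorded
#' per image and the run continues.  The aggregate report carries the
#' per-condition clustered-fraction distributions and pooled lognormal
#' cluster-size fits, with all stage parameters logged.  The pipeline is
#' deterministic given the manifest and parameters.
#'
#' @param manifest data frame with columns `path` (localization CSV),
#'   `condition` (group label, non-empty) and optionally `region`
#'   (e.g. soma / extension / varicosity) -- region is a manifest label,
#'   never computed.
#' @param dialect a [loc_dialect()] for reading the CSVs.
#' @param cycle a [cycle_config()], or `NULL` to skip photon filtering,
#'   cycle filtering and merging.
#' @param apply_cycle_filter,apply_merge,apply_quality_filter which
#'   preprocessing stages to run (ignored when `cycle` is `NULL`).
#' @param monomer_params,params the two DBSCAN stages
#'   ([monomer_params()], [cluster_params()]).
#' @param denominator clustered-fraction denominator, `"total"` or
#'   `"filtered"`.
#' @param size_variable size variable for the per-condition fits.
#' @param output_dir optional directory; when given, per-image cluster
#'   maps (CSV), the per-image statistics table and a JSON report are
#'   written there.
#' @return An object of class `"pipeline_report"`: data frame `images`
#'   (per-image statistics and status), data frame `conditions`
#'   (per-condition n / mean / sem of the clustered fraction), list
#'   `size_fits` (per-condition `"size_distribution_fit"` or `NULL`),
#'   list `parameters`, and list `failures`.
#' @export
run_pipeline <- function(manifest, dialect = loc_dialect(),
                         cycle = NULL,
                         apply_cycle_filter = FALSE, apply_merge = FALSE,
                         apply_quality_filter = TRUE,
                         monomer_params = nanodomain::monomer_params(),
                         params = cluster_params(),
                         denominator = c("total", "filtered"),
                         size_variable = c("area", "diameter"),
                         output_dir = NULL) {
  denominator <- match.arg(denominator)
  size_variable <- match.arg(size_variable)
  stopifnot(is.data.frame(manifest),
            all(c("path", "condition") %in% names(manifest)),
            nrow(manifest) >= 1,
            all(nzchar(as.character(manifest$condition))))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  images <- data.frame(
    path = as.character(manifest$path),
    condition = as.character(manifest$condition),
    region = if ("region" %in% names(manifest)) {
      as.character(manifest$region)
    } else {
      NA_character_
    },
    status = "ok", n_localizations = NA_real_, n_clusters = NA_real_,
    clustered_fraction = NA_real_, median_diameter = NA_real_,
    stringsAsFactors = FALSE
  )
  failures <- list()
  all_sizes <- list()
  for (i in seq_len(nrow(images))) {
    res <- tryCatch({
      tab <- read_localizations(images$path[i], dialect)
      if (!is.null(cycle)) {
        if (apply_quality_filter) tab <- quality_filter(tab, cycle)
        if (apply_cycle_filter) tab <- storm_cycle_filter(tab, cycle)
        if (apply_merge) tab <- merge_consecutive_detections(tab, cycle)
      }
      asg <- two_stage_cluster(tab, monomer_params, params,
                               denominator = denominator)
      geo <- cluster_sizes(asg, tab)
      if (!is.null(output_dir)) {
        cluster_map(asg, tab, file.path(output_dir, sprintf(
          "image_%03d_clusters.csv", i)))
      }
      list(tab = tab, asg = asg, geo = geo)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      images$status[i] <- "failed"
      failures[[length(failures) + 1L]] <-
        list(image = i, path = images$path[i],
             message = conditionMessage(res))
      next
    }
    ok_sizes <- res$geo$sizes[!res$geo$sizes$degenerate, , drop = FALSE]
    images$n_localizations[i] <- nrow(res$tab)
    images$n_clusters[i] <- res$asg$n_clusters
    images$clustered_fraction[i] <- res$asg$clustered_fraction
    images$median_diameter[i] <- if (nrow(ok_sizes)) {
      stats::median(ok_sizes$equivalent_diameter)
    } else {
      NA_real_
    }
    if (nrow(ok_sizes)) {
      all_sizes[[i]] <- data.frame(
        condition = images$condition[i],
        size = if (size_variable == "area") ok_sizes$area else
          ok_sizes$equivalent_diameter)
    }
  }
  ok <- images$status == "ok"
  conditions <- do.call(rbind, lapply(
    split(images[ok, , drop = FALSE], images$condition[ok]),
    function(d) data.frame(
      condition = d$condition[1], n_images = nrow(d),
      mean_clustered_fraction = mean(d$clustered_fraction),
      sem_clustered_fraction = stats::sd(d$clustered_fraction) /
        sqrt(nrow(d)))))
  rownames(conditions) <- NULL
  pooled <- do.call(rbind, all_sizes)
  size_fits <- if (!is.null(pooled)) {
    lapply(split(pooled$size, pooled$condition), function(s) {
      if (sum(s > 0) >= 5) fit_size_distribution(s, size_variable) else NULL
    })
  } else {
    list()
  }
  report <- structure(list(
    images = images, conditions = conditions, size_fits = size_fits,
    failures = failures,
    parameters = list(
      cycle = if (is.null(cycle)) NULL else unclass(cycle),
      monomer_params = unclass(monomer_params), params = unclass(params),
      denominator = denominator, size_variable = size_variable,
      stages = c(quality_filter = apply_quality_filter && !is.null(cycle),
                 cycle_filter = apply_cycle_filter && !is.null(cycle),
                 merge = apply_merge && !is.null(cycle))
    )
  ), class = "pipeline_report")
  if (!is.null(output_dir)) {
    utils::write.csv(images, file.path(output_dir, "per_image_stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

report_to_list <- function(report) {
  list(
    images = report$images,
    conditions = report$conditions,
    size_fits = lapply(report$size_fits, function(f) {
      if (is.null(f)) NULL else
        list(log_mu = f$log_mu, log_sigma = f$log_sigma,
             n_clusters = f$n_clusters, variable = f$variable)
    }),
    failures = report$failures,
    parameters = report$parameters
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d image(s), %d failed\n",
              nrow(x$images), length(x$failures)))
  if (nrow(x$conditions)) {
    cat("per-condition clustered fraction (% of localizations):\n")
    print(x$conditions, row.names = FALSE)
  }
  invisible(x)
}

pooled_sd <- function(values, groups) {
  ss <- tapply(values, groups, function(v) sum((v - mean(v))^2))
  df <- sum(tapply(values, groups, length) - 1L)
  if (df <= 0) return(NA_real_)
  sqrt(sum(ss) / df)
}

#' Compare a per-image statistic across conditions
#'
#' Classical group comparisons of per-image (not per-localization) values:
#' an unpaired equal-variance two-sample t-test, a one-way ANOVA, or a
#' two-way ANOVA (factor crossing with interaction), each followed by
#' Bonferroni-adjusted pairwise contrasts computed with the pooled
#' residual variance (`p_adj = min(1, p * n_contrasts)`).
#'
#' @param data data frame of per-image statistics.
#' @param value name of the value column.
#' @param group name of the grouping (condition) column.
#' @param group2 optional second factor (two-way ANOVA).
#' @param test `"t"`, `"anova1"` or `"anova2"`; the default picks `"t"`
#'   for two groups and one factor, `"anova1"` for more, `"anova2"` when
#'   `group2` is given.
#' @return An object of class `"group_comparison"`: data frame `groups`
#'   (`group`, `n`, `mean`, `sem`), the test name, `statistic`
#'   (t or F), `p_value`, data frame `contrasts` with Bonferroni-adjusted
#'   p-values, and the `anova_table` where applicable.
#' @export
compare_groups <- function(data, value, group, group2 = NULL,
                           test = NULL) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  v <- data[[value]]
  g <- factor(data[[group]])
  ng <- nlevels(g)
  if (ng < 2) stop("need >= 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop("degenerate group (n < 2): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (is.null(test)) {
    test <- if (!is.null(group2)) "anova2" else if (ng == 2) "t" else
      "anova1"
  }
  test <- match.arg(test, c("t", "anova1", "anova2"))
  groups <- data.frame(
    group = levels(g), n = as.integer(sizes),
    mean = as.numeric(tapply(v, g, mean)),
    sem = as.numeric(tapply(v, g, stats::sd) / sqrt(sizes)))
  anova_table <- NULL
  if (test == "t") {
    m <- groups$mean; n <- groups$n
    sp <- pooled_sd(v, g)
    se <- sp * sqrt(1 / n[1] + 1 / n[2])
    df <- sum(n) - 2L
    tstat <- if (se > 0) (m[1] - m[2]) / se else
      if (m[1] == m[2]) 0 else sign(m[1] - m[2]) * Inf
    p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df) else 0
    statistic <- tstat
    contrasts <- data.frame(
      contrast = paste(levels(g)[1], "vs", levels(g)[2]),
      difference = m[1] - m[2], p = p, p_adj = min(1, p))
  } else if (test == "anova1") {
    fit <- stats::aov(v ~ g)
    at <- summary(fit)[[1]]
    anova_table <- at
    statistic <- at$`F value`[1]
    p <- at$`Pr(>F)`[1]
    contrasts <- bonferroni_pairwise(v, g, mse = at$`Mean Sq`[2],
                                     df = at$Df[2])
  } else {
    if (is.null(group2) || !group2 %in% names(data)) {
      stop("two-way ANOVA needs a group2 column")
    }
    g2 <- factor(data[[group2]])
    fit <- stats::aov(v ~ g * g2)
    at <- summary(fit)[[1]]
    anova_table <- at
    statistic <- at$`F value`[1]
    p <- at$`Pr(>F)`[1]
    resid_row <- nrow(at)
    contrasts <- bonferroni_pairwise(v, g, mse = at$`Mean Sq`[resid_row],
                                     df = at$Df[resid_row])
  }
  structure(list(groups = groups, test = test, statistic = statistic,
                 p_value = p, contrasts = contrasts,
                 anova_table = anova_table),
            class = "group_comparison")
}

bonferroni_pairwise <- function(v, g, mse, df) {
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  k <- ncol(pairs)
  m <- tapply(v, g, mean)
  n <- tapply(v, g, length)
  out <- data.frame(contrast = character(k), difference = numeric(k),
                    p = numeric(k), p_adj = numeric(k))
  for (j in seq_len(k)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
    d <- m[[a]] - m[[b]]
    tstat <- if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
    p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df) else 0
    out$contrast[j] <- paste(a, "vs", b)
    out$difference[j] <- d
    out$p[j] <- p
    out$p_adj[j] <- min(1, p * k)
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s): statistic = %.4g, p = %.4g\n",
              switch(x$test, t = "unpaired two-tailed t-test",
                     anova1 = "one-way ANOVA",
                     anova2 = "two-way ANOVA"),
              x$statistic, x$p_value))
  print(x$groups, row.names = FALSE)
  cat("Bonferroni-adjusted contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
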
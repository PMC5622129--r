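#' Construct and validate a localization table
#'
#' The central data structure: one row per detected single-molecule
#' localization with positions in nanometers, the acquisition frame index,
#' the photon count, a label-channel identifier and (optionally) the
#' localization precision.  Rows failing validation can either abort or be
#' dropped with a count of rejects attached.
#'
#' @param x,y numeric positions in nm; must be finite.
#' @param frame integer acquisition frame indices, 0-based, non-negative.
#' @param photons photon counts, `>= 0`; default `NA` (unknown).
#' @param channel integer channel identifier, default 0.
#' @param precision optional localization uncertainty in nm, `> 0` when given.
#' @param drop_invalid if `TRUE`, rows failing validation are dropped and
#'   counted in `attr(, "n_rejected")` instead of raising an error.
#'
#' @return A `data.frame` of class `"localization_table"` with columns
#'   `x`, `y`, `frame`, `photons`, `channel`, `precision`.
#' @export
#' @examples
#' localization_table(x = c(0, 100), y = c(0, 50), frame = c(0, 1))
localization_table <- function(x = numeric(), y = numeric(),
                               frame = integer(),
                               photons = NA_real_, channel = 0L,
                               precision = NA_real_,
                               drop_invalid = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n, length(frame) %in% c(1L, n))
  tab <- data.frame(
    x = as.numeric(x), y = as.numeric(y),
    frame = rep_len(as.integer(round(as.numeric(frame))), n),
    photons = rep_len(as.numeric(photons), n),
    channel = rep_len(as.integer(channel), n),
    precision = rep_len(as.numeric(precision), n)
  )
  ok <- is.finite(tab$x) & is.finite(tab$y) &
    !is.na(tab$frame) & tab$frame >= 0L &
    (is.na(tab$photons) | tab$photons >= 0) &
    (is.na(tab$precision) | tab$precision > 0)
  if (!all(ok)) {
    if (!drop_invalid) {
      stop("invalid localization rows: ", sum(!ok),
           " (non-finite coordinates, negative frame/photons, ",
           "or non-positive precision)")
    }
    tab <- tab[ok, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, n_rejected = sum(!ok),
            class = c("localization_table", "data.frame"))
}

#' Test/assert the localization-table contract
#' @param tab object to check.
#' @return `is_localization_table` returns a logical;
#'   `assert_localization_table` returns `tab` invisibly or errors.
#' @export
is_localization_table <- function(tab) {
  is.data.frame(tab) &&
    all(c("x", "y", "frame", "photons", "channel", "precision") %in%
          names(tab))
}

#' @rdname is_localization_table
#' @export
assert_localization_table <- function(tab) {
  if (!is_localization_table(tab)) {
    stop("not a localization table (need columns x, y, frame, photons, ",
         "channel, precision)")
  }
  invisible(tab)
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("Localization table: %d localizations", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", %d frame(s), %d channel(s)",
                length(unique(x$frame)), length(unique(x$channel))))
    cat(sprintf("\n  x: [%.1f, %.1f] nm, y: [%.1f, %.1f] nm",
                min(x$x), max(x$x), min(x$y), max(x$y)))
  }
  cat("\n")
  invisible(x)
}

#' Column-mapping dialect for reading localization files
#'
#' Maps the canonical columns onto the headers of a delimited export and
#' declares the coordinate unit.  Common SMLM exports use headers such as
#' `"x [nm]"`; the mapping is matched exactly against the file header.
#'
#' @param x,y,frame,photons,channel,precision header names in the file;
#'   `photons`, `channel`, `precision` may be `NA` (absent).
#' @param unit `"nm"` or `"pixel"`; pixel coordinates are converted with
#'   `pixel_size`.
#' @param pixel_size camera pixel size in nm (default 160, a typical EMCCD
#'   at 100x magnification); only used when `unit = "pixel"`.
#' @return A list of class `"loc_dialect"`.
#' @export
loc_dialect <- function(x = "x_nm", y = "y_nm", frame = "frame",
                        photons = "photons", channel = "channel",
                        precision = "precision_nm",
                        unit = c("nm", "pixel"), pixel_size = 160) {
  unit <- match.arg(unit)
  stopifnot(pixel_size > 0)
  structure(list(x = x, y = y, frame = frame, photons = photons,
                 channel = channel, precision = precision,
                 unit = unit, pixel_size = pixel_size),
            class = "loc_dialect")
}

detect_delimiter <- function(header_line) {
  counts <- vapply(c(",", "\t", ";"), function(d)
    lengths(regmatches(header_line, gregexpr(d, header_line, fixed = TRUE))),
    integer(1))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Read a localization table from delimited text
#'
#' Accepts comma/tab/semicolon-delimited files with a header line.  The
#' dialect maps the required columns (`x`, `y`, `frame`) and any optional
#' ones onto the file headers and declares the unit.  Rows with unparseable
#' numeric cells or failing validation are dropped and counted in the
#' attributes `n_rejected`; surviving rows keep their file order.
#'
#' @param path file to read.
#' @param dialect a [loc_dialect()]; the default matches the canonical
#'   format written by [write_localizations()].
#' @return A [localization_table()].  Attribute `n_rejected` counts dropped
#'   rows.
#' @export
read_localizations <- function(path, dialect = loc_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header_line <- readLines(path, n = 1L)
  if (!length(header_line)) stop("empty file: ", path)
  sep <- detect_delimiter(header_line)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  required <- c(x = dialect$x, y = dialect$y, frame = dialect$frame)
  for (col in names(required)) {
    if (!required[[col]] %in% names(raw)) {
      stop("schema error: required column '", required[[col]],
           "' (", col, ") missing from ", path)
    }
  }
  num <- function(header) {
    if (is.na(header) || !header %in% names(raw)) {
      return(rep(NA_real_, nrow(raw)))
    }
    v <- raw[[header]]
    v[!nzchar(v)] <- NA
    suppressWarnings(as.numeric(v))
  }
  x <- num(dialect$x); y <- num(dialect$y); frame <- num(dialect$frame)
  if (dialect$unit == "pixel") {
    x <- x * dialect$pixel_size
    y <- y * dialect$pixel_size
  }
  parse_ok <- !(is.na(x) | is.na(y) | is.na(frame))
  photons <- num(dialect$photons)
  channel <- num(dialect$channel)
  channel[is.na(channel)] <- 0
  tab <- localization_table(
    x = x[parse_ok], y = y[parse_ok],
    frame = frame[parse_ok],
    photons = photons[parse_ok],
    channel = channel[parse_ok],
    precision = num(dialect$precision)[parse_ok],
    drop_invalid = TRUE
  )
  attr(tab, "n_rejected") <- attr(tab, "n_rejected") + sum(!parse_ok)
  tab
}

#' Write a localization table in the canonical format
#'
#' Canonical header: `x_nm, y_nm, frame, photons, channel, precision_nm`,
#' comma-separated.  Missing optional values are written as empty fields so
#' that a read/write round trip preserves their absence.  Coordinates are
#' written at full double precision (`%.10g`), making the round trip the
#' identity for values representable at that precision.
#'
#' @param table a [localization_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  assert_localization_table(table)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.10g", v))
  lines <- c(
    "x_nm,y_nm,frame,photons,channel,precision_nm",
    if (nrow(table)) {
      paste(fmt(table$x), fmt(table$y), table$frame, fmt(table$photons),
            table$channel, fmt(table$precision), sep = ",")
    }
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
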
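# Columnar interchange formats. Every table is CSV with a leading comment
# header declaring the schema name and version; numeric columns are written
# with 17 significant digits so that write/read round trips are bit-exact.
# Timestamps are stored as decimal seconds since 1970-01-01T00:00:00 UTC.

io_schemas <- function() {
  list(
    particles = list(
      version = 1L,
      columns = c("timestamp", "d_opt", "af", "fl_a", "fl_b", "fl_c",
                  "quality_flags"),
      time_cols = "timestamp",
      int_cols = "quality_flags",
      units = "timestamp: s since epoch (UTC); d_opt: um; af: -; fl_*: instrument units"
    ),
    track = list(
      version = 1L,
      columns = c("timestamp", "lat", "lon", "u10n"),
      time_cols = "timestamp",
      int_cols = character(0),
      units = "timestamp: s since epoch (UTC); lat/lon: deg; u10n: m s-1 (10-m neutral)"
    ),
    marine = list(
      version = 1L,
      columns = c("timestamp", "variable", "value", "category"),
      time_cols = "timestamp",
      int_cols = character(0),
      units = "timestamp: s since epoch (UTC); value: variable-specific"
    ),
    proxies = list(
      version = 1L,
      columns = c("timestamp", "variable", "value", "averaging_window"),
      time_cols = "timestamp",
      int_cols = character(0),
      units = "timestamp: s since epoch (UTC); averaging_window: 1h or 24h"
    ),
    ft = list(
      version = 1L,
      columns = c("fl_a", "fl_b", "fl_c"),
      time_cols = character(0),
      int_cols = character(0),
      units = "fl_*: instrument units (forced-trigger background)"
    )
  )
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out[is.infinite(x)] <- ifelse(x[is.infinite(x)] > 0, "Inf", "-Inf")
  out
}

write_schema_csv <- function(x, path, kind) {
  sch <- io_schemas()[[kind]]
  missing <- setdiff(sch$columns, names(x))
  if (length(missing)) {
    stop(sprintf("missing mandatory column(s) for %s: %s", kind,
                 paste(missing, collapse = ", ")))
  }
  x <- x[, sch$columns, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# schema: %s v%d", kind, sch$version),
    sprintf("# units: %s", sch$units)
  ), con)
  out <- x
  for (cl in sch$time_cols) out[[cl]] <- fmt_num(as.numeric(x[[cl]]))
  for (cl in setdiff(names(out), c(sch$time_cols, sch$int_cols))) {
    if (is.numeric(out[[cl]])) out[[cl]] <- fmt_num(out[[cl]])
  }
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_schema_csv <- function(path, kind) {
  sch <- io_schemas()[[kind]]
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  expected <- sprintf("# schema: %s v%d", kind, sch$version)
  if (!identical(header, expected)) {
    stop(sprintf("file %s does not declare schema '%s v%d'",
                 path, kind, sch$version))
  }
  x <- read.csv(path, comment.char = "#", colClasses = "character",
                check.names = FALSE)
  missing <- setdiff(sch$columns, names(x))
  if (length(missing)) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  x <- x[, sch$columns, drop = FALSE]
  n_in <- nrow(x)
  bad <- rep(FALSE, n_in)
  num_cols <- c(sch$time_cols,
                setdiff(sch$columns, c(sch$time_cols, "variable", "category",
                                       "averaging_window")))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(x[[cl]]))
    bad <- bad | (is.na(v) & !(x[[cl]] %in% c("NA", "Inf", "-Inf")))
    x[[cl]] <- v
  }
  for (cl in sch$int_cols) x[[cl]] <- as.integer(x[[cl]])
  for (cl in sch$time_cols) x[[cl]] <- as_utc(x[[cl]])
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read and write particle record tables
#'
#' Single-particle records: `timestamp` (UTC), `d_opt` (optical diameter,
#' um), `af` (asymmetry factor), `fl_a`/`fl_b`/`fl_c` (fluorescence
#' amplitudes, instrument units) and `quality_flags` (integer bit set).
#' Files are schema-versioned CSV; rows with unparsable numeric fields are
#' dropped on read and counted in the `n_rejected` attribute (see
#' [io_rejections()]), so `accepted + rejected = input rows`.
#'
#' @param x particle data frame.
#' @param path file path.
#' @return `read_particles()` returns the particle data frame;
#'   `write_particles()` returns `path` invisibly.
#' @export
write_particles <- function(x, path) write_schema_csv(x, path, "particles")

#' @rdname write_particles
#' @export
read_particles <- function(path) read_schema_csv(path, "particles")

#' Read and write ship-track tables
#'
#' Columns: `timestamp` (UTC), `lat`, `lon` (degrees, longitude normalised
#' to (-180, 180]) and `u10n` (10-m neutral wind speed, m/s).
#'
#' @inheritParams write_particles
#' @export
write_track <- function(x, path) write_schema_csv(x, path, "track")

#' @rdname write_track
#' @export
read_track <- function(path) {
  x <- read_schema_csv(path, "track")
  x$lon <- normalize_lon(x$lon)
  x
}

#' Read and write marine point-sample tables
#'
#' Columns: `timestamp` (UTC), `variable` (label such as HDNA, Pras3, TEP),
#' `value` (variable-specific units) and `category` (one of `microbe_count`,
#' `taxa_mass`, `OM`).
#'
#' @inheritParams write_particles
#' @export
write_marine <- function(x, path) write_schema_csv(x, path, "marine")

#' @rdname write_marine
#' @export
read_marine <- function(path) read_schema_csv(path, "marine")

#' Read and write auxiliary proxy series tables
#'
#' Columns: `timestamp`, `variable` (`u10n`, `coarse_number_conc`,
#' `chloride`, `sodium`), `value` and `averaging_window` (`1h`, or `24h`
#' for filter-based sodium).
#'
#' @inheritParams write_particles
#' @export
write_proxies <- function(x, path) write_schema_csv(x, path, "proxies")

#' @rdname write_proxies
#' @export
read_proxies <- function(path) read_schema_csv(path, "proxies")

#' Read and write forced-trigger background tables
#'
#' Columns: `fl_a`, `fl_b`, `fl_c` (instrument units).
#'
#' @inheritParams write_particles
#' @export
write_ft <- function(x, path) write_schema_csv(x, path, "ft")

#' @rdname write_ft
#' @export
read_ft <- function(path) read_schema_csv(path, "ft")

#' Number of rows rejected while reading a table
#'
#' @param x a table returned by one of the `read_*` functions.
#' @return integer count of dropped rows (0 if none recorded).
#' @export
io_rejections <- function(x) {
  r <- attr(x, "n_rejected")
  if (is.null(r)) 0L else r
}

#' Normalise longitudes to (-180, 180]
#'
#' @param lon numeric vector of degrees longitude.
#' @return normalised longitudes.
#' @export
normalize_lon <- function(lon) {
  out <- lon %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Group records into fixed-width time bins
#'
#' Bins are half-open, left-closed UTC intervals `[t, t + width)` anchored at
#' `origin` (default: the start of the bin containing the earliest record).
#' Unsorted input is handled; every record lands in exactly one bin.
#'
#' @param x data frame with a `timestamp` column.
#' @param bin_width_s bin width in seconds (> 0).
#' @param origin optional POSIXct bin origin.
#' @return named list of data frames, one per nonempty bin, names the ISO
#'   bin start times; each element carries a `bin_start` attribute.
#' @export
align_to_bins <- function(x, bin_width_s, origin = NULL) {
  stopifnot_scalar_num(bin_width_s, "bin_width_s")
  if (bin_width_s <= 0) stop("bin_width_s must be positive")
  tt <- as.numeric(x$timestamp)
  t0 <- if (is.null(origin)) floor(min(tt) / bin_width_s) * bin_width_s
        else as.numeric(origin)
  bin <- floor((tt - t0) / bin_width_s)
  groups <- split(seq_len(nrow(x)), bin)
  out <- lapply(groups, function(i) x[i, , drop = FALSE])
  starts <- as_utc(t0 + as.numeric(names(groups)) * bin_width_s)
  names(out) <- format(starts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (i in seq_along(out)) attr(out[[i]], "bin_start") <- starts[i]
  out
}
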
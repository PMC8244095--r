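#' Pair marine point samples with the overlapping hourly aerosol average
#'
#' Each marine sample is joined to the hourly aerosol bin containing its
#' timestamp (half-open bins `[t, t + 1h)`). Samples falling in hours with
#' no usable aerosol data are dropped and counted in the `n_dropped`
#' attribute.
#'
#' @param marine data frame with `timestamp`, `variable`, `value`.
#' @param aerosol hourly series from [time_binned_series()] (`bin_start`
#'   plus value columns); bins whose `aerosol_col` value is `NA` are unusable.
#' @param aerosol_col name of the aerosol column to pair (default
#'   `"frac_fluor"`).
#' @return data frame with the marine columns plus `bin_start` and the
#'   paired aerosol value in column `aerosol`; attribute `n_dropped`.
#' @export
pair_marine_to_aerosol <- function(marine, aerosol, aerosol_col = "frac_fluor") {
  tb <- as.numeric(aerosol$bin_start)
  if (nrow(aerosol) > 1L) {
    w <- diff(tb)
    if (any(abs(w - 3600) > 1e-6)) stop("aerosol series must be hourly")
  }
  tm <- as.numeric(marine$timestamp)
  idx <- findInterval(tm, tb)
  idx[idx < 1L] <- NA_integer_
  # samples after the last bin's end fall outside the series
  idx[!is.na(idx) & tm >= tb[length(tb)] + 3600] <- NA_integer_
  val <- rep(NA_real_, length(tm))
  ok <- !is.na(idx)
  val[ok] <- aerosol[[aerosol_col]][idx[ok]]
  keep <- !is.na(val)
  out <- marine[keep, , drop = FALSE]
  out$bin_start <- aerosol$bin_start[idx[keep]]
  out$aerosol <- val[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Pearson product-moment correlation coefficient
#'
#' Thin, defensive wrapper: requires at least 3 complete pairs and nonzero
#' variance in both variables (the coefficient is undefined otherwise).
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson's R.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Subsampling bootstrap of the correlation coefficient
#'
#' Repeats the Pearson correlation `n_rep` times on random subsets
#' containing a fraction `frac` of the available pairs, drawn without
#' replacement, to obtain a spread estimate for the coefficient. Draws with
#' zero variance in either variable are discarded and counted.
#'
#' @param x,y numeric vectors of paired observations (length >= `min_pairs`).
#' @param n_rep number of subsample draws (default 100).
#' @param frac fraction of pairs per draw (default 0.6).
#' @param seed integer seed for reproducibility.
#' @param min_pairs minimum pair count for a reportable result (default 25).
#' @return list with `r_full` (all-pairs R), `r` (vector of subsample Rs),
#'   `mean`, `sd`, `interval` (central 90%), `n_pairs`, `n_discarded`.
#' @export
bootstrap_r <- function(x, y, n_rep = 100, frac = 0.6, seed = NULL,
                        min_pairs = 25) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_pairs) stop("need at least ", min_pairs, " pairs")
  if (!is.null(seed)) set.seed(seed)
  m <- max(3L, floor(frac * n))
  r <- numeric(0)
  n_discarded <- 0L
  for (i in seq_len(n_rep)) {
    idx <- sample.int(n, m)
    if (sd(x[idx]) == 0 || sd(y[idx]) == 0) {
      n_discarded <- n_discarded + 1L
      next
    }
    r <- c(r, cor(x[idx], y[idx]))
  }
  list(
    r_full = pearson_r(x, y),
    r = r,
    mean = mean(r),
    sd = if (length(r) > 1L) sd(r) else 0,
    interval = quantile(r, c(0.05, 0.95), names = FALSE),
    n_pairs = n,
    n_discarded = n_discarded
  )
}

#' Permutation p-value for a Pearson correlation
#'
#' Two-sided permutation test: `y` is randomly permuted `n_perm` times and
#' the p-value is `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)` (add-one
#' correction, so p is never exactly 0).
#'
#' @param x,y numeric vectors of paired observations.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for reproducibility.
#' @param min_pairs minimum pair count (default 25).
#' @return p-value in (0, 1].
#' @export
permutation_p <- function(x, y, n_perm = 10000, seed = NULL, min_pairs = 25) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_pairs) stop("need at least ", min_pairs, " pairs")
  r_obs <- pearson_r(x, y)
  if (!is.null(seed)) set.seed(seed)
  # correlation against permuted y via centred cross-products (fast path)
  xc <- (x - mean(x)) / sd(x)
  yc <- (y - mean(y)) / sd(y)
  n <- length(x)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    sum(xc * yc[sample.int(n, n)]) / (n - 1)
  }, numeric(1))
  (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
}

#' Binned median/IQR curve on a logarithmic abscissa
#'
#' Splits the data into `n_bins` bins equidistant in log10(x) between the
#' smallest and largest x, and reports the median and interquartile range of
#' y per bin. Bins with fewer than `n_min` points are flagged.
#'
#' @param x positive numeric vector (the binning variable).
#' @param y numeric vector of equal length.
#' @param n_bins number of logarithmic bins (default 10).
#' @param n_min minimum points per reportable bin (default 5).
#' @return data frame `x_lo`, `x_hi`, `n`, `y_median`, `y_q25`, `y_q75`, `ok`.
#' @export
binned_median_iqr <- function(x, y, n_bins = 10, n_min = 5) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (any(x <= 0)) stop("x must be positive for logarithmic binning")
  if (!length(x)) stop("no complete pairs")
  edges <- 10^seq(log10(min(x)), log10(max(x)), length.out = n_bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  out <- lapply(seq_len(n_bins), function(k) {
    sel <- idx == k
    n_k <- sum(sel)
    q <- if (n_k > 0) quantile(y[sel], c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(x_lo = edges[k], x_hi = edges[k + 1], n = n_k,
               y_median = q[2], y_q25 = q[1], y_q75 = q[3],
               ok = n_k >= n_min)
  })
  do.call(rbind, out)
}

#' Per-time-bin ABC class counts
#'
#' Helper for the subsampling analyses: counts particles of each ABC class
#' (at the classification's threshold level) in fixed-width time bins. The
#' resampling unit of [class_fraction_bootstrap()] is one such time bin.
#'
#' @param particles particle data frame with `timestamp`.
#' @param labels classification from [classify_particles()].
#' @param bin_width_s time bin width in seconds (default 300, i.e. 5 min).
#' @return list with `bin_start` (POSIXct vector) and `counts` (matrix,
#'   bins x 7 classes); only bins containing at least one in-tier particle
#'   are retained.
#' @export
class_counts_by_bin <- function(particles, labels, bin_width_s = 300) {
  keep <- labels$abc_class != "none"
  tt <- as.numeric(particles$timestamp)[keep]
  cls <- factor(labels$abc_class[keep], levels = abc_levels())
  if (!length(tt)) stop("no particles in the fluorescence tier")
  t0 <- floor(min(tt) / bin_width_s) * bin_width_s
  bin <- as.integer(floor((tt - t0) / bin_width_s)) + 1L
  n_bins <- max(bin)
  cnt <- table(factor(bin, levels = seq_len(n_bins)), cls)
  m <- matrix(as.numeric(cnt), n_bins, length(abc_levels()),
              dimnames = list(NULL, abc_levels()))
  nonempty <- rowSums(m) > 0
  list(
    bin_start = as_utc(t0 + (which(nonempty) - 1L) * bin_width_s),
    counts = m[nonempty, , drop = FALSE]
  )
}

#' Subsampling bootstrap of ABC class fractions
#'
#' Estimates the sampling variability of the ABC class fractions by
#' recomputing them on random subsamples of the time-binned data. Two modes:
#' `"fixed_count"` draws `size` time bins without replacement (288 five-min
#' bins correspond to 12 h of data); `"window_24h"` draws a random 24 h
#' window that contains at least `min_window_h` hours of data and uses all
#' bins inside it.
#'
#' @param bins output of [class_counts_by_bin()].
#' @param mode `"fixed_count"` or `"window_24h"`.
#' @param size number of bins per draw in `fixed_count` mode (default 288).
#' @param n_rep number of replicates (default 100).
#' @param min_window_h minimum data coverage (hours) for a usable 24 h
#'   window (default 12).
#' @param seed integer seed.
#' @return list with `fractions` (matrix, `n_rep` x 7 classes), `median` and
#'   `q25`/`q75` per class, and `mode`.
#' @export
class_fraction_bootstrap <- function(bins, mode = c("fixed_count", "window_24h"),
                                     size = 288, n_rep = 100,
                                     min_window_h = 12, seed = NULL) {
  mode <- match.arg(mode)
  m <- bins$counts
  tt <- as.numeric(bins$bin_start)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m)
  ord <- order(tt)
  tt <- tt[ord]
  m <- m[ord, , drop = FALSE]
  bin_w <- if (n > 1L) min(diff(tt)) else 300
  starts <- NULL
  if (mode == "window_24h") {
    # candidate window starts: any bin start such that [s, s + 24h) holds
    # at least min_window_h hours of binned data
    need <- min_window_h * 3600 / bin_w
    in_window <- findInterval(tt + 86400 - 1e-6, tt) - seq_along(tt) + 1L
    starts <- tt[in_window >= need]
    if (!length(starts)) stop("no 24 h window with at least ",
                              min_window_h, " h of data")
  }
  draw_rows <- function() {
    if (mode == "fixed_count") {
      if (n < size) stop("not enough time bins for fixed_count size ", size)
      sample.int(n, size)
    } else {
      s <- starts[sample.int(length(starts), 1L)]
      which(tt >= s & tt < s + 86400)
    }
  }
  fr <- t(vapply(seq_len(n_rep), function(i) {
    rows <- draw_rows()
    tot <- colSums(m[rows, , drop = FALSE])
    tot / sum(tot)
  }, numeric(ncol(m))))
  colnames(fr) <- colnames(m)
  list(
    fractions = fr,
    median = apply(fr, 2, median),
    q25 = apply(fr, 2, quantile, 0.25),
    q75 = apply(fr, 2, quantile, 0.75),
    mode = mode
  )
}
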
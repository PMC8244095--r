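#' Particle number concentration from a count
#'
#' Converts a particle count to a number concentration in particles per
#' litre given the instrument sample flow and the averaging duration.
#'
#' @param count particle count(s).
#' @param flow_lpm sample flow in litres per minute (must be positive).
#' @param duration_min averaging duration in minutes (must be positive).
#' @return concentration(s) in L^-1.
#' @export
number_concentration <- function(count, flow_lpm, duration_min) {
  if (!is.numeric(flow_lpm) || any(flow_lpm <= 0)) stop("flow_lpm must be positive")
  if (!is.numeric(duration_min) || any(duration_min <= 0)) stop("duration_min must be positive")
  count / (flow_lpm * duration_min)
}

#' Partition a particle stream at 1 micrometre optical diameter
#'
#' Fine particles have optical diameter strictly below 1 um; particles at
#' exactly 1 um go to the coarse partition.
#'
#' @param particles particle data frame with a `d_opt` column (um).
#' @return list with data frames `fine` and `coarse`.
#' @export
split_fine_coarse <- function(particles) {
  fine <- particles$d_opt < 1
  list(
    fine = particles[fine, , drop = FALSE],
    coarse = particles[!fine, , drop = FALSE]
  )
}

#' Default logarithmic size grid
#'
#' 16 logarithmically spaced bins spanning 0.5 to 16 um (17 edges). The
#' instrument's nominal optical sizing range tops out between 14 and 16 um
#' depending on convention, so the upper edge is configurable.
#'
#' @param n_bins number of bins.
#' @param lo,hi lower and upper edge in um.
#' @return numeric vector of bin edges.
#' @export
default_size_edges <- function(n_bins = 16, lo = 0.5, hi = 16) {
  exp(seq(log(lo), log(hi), length.out = n_bins + 1))
}

#' Time-binned particle counts, concentrations and fluorescent fractions
#'
#' Aggregates a labelled particle stream into fixed-width time bins
#' (half-open, left-closed, UTC), reporting coarse-particle counts,
#' number concentrations and the fluorescent / hyper-fluorescent fractions
#' of the total coarse count. Bins with zero coarse particles carry `NA`
#' fractions (missing, never zero).
#'
#' @param particles particle data frame (`timestamp`, `d_opt`, ...).
#' @param labels classification from [classify_particles()] at 3-sigma
#'   (its `tier` column distinguishes fluorescent and hyper-fluorescent).
#' @param bin_width_s bin width in seconds (default 3600).
#' @param flow_lpm sample flow (L/min) for count-to-concentration conversion.
#' @param t_start,t_end optional campaign bounds (POSIXct); default spans the
#'   observed record range. Empty interior bins are retained.
#' @param coarse_only restrict to coarse particles (d_opt >= 1 um); default TRUE.
#' @return data frame, one row per bin: `bin_start` (POSIXct), counts
#'   `n_total`, `n_fluor`, `n_hyper`, concentrations `conc_total`,
#'   `conc_fluor`, `conc_hyper` (L^-1), and `frac_fluor`, `frac_hyper`.
#' @export
time_binned_series <- function(particles, labels, bin_width_s = 3600,
                               flow_lpm = 0.23, t_start = NULL, t_end = NULL,
                               coarse_only = TRUE) {
  stopifnot_scalar_num(bin_width_s, "bin_width_s")
  if (bin_width_s <= 0) stop("bin_width_s must be positive")
  if (nrow(particles) != nrow(labels)) stop("particles and labels must align")
  tt <- as.numeric(particles$timestamp)
  keep <- if (coarse_only) particles$d_opt >= 1 else rep(TRUE, length(tt))
  tt <- tt[keep]
  tier <- labels$tier[keep]
  t0 <- if (is.null(t_start)) floor(min(tt) / bin_width_s) * bin_width_s else as.numeric(t_start)
  t1 <- if (is.null(t_end)) max(tt) else as.numeric(t_end)
  n_bins <- max(1L, as.integer(ceiling((t1 - t0) / bin_width_s)))
  bin <- as.integer(floor((tt - t0) / bin_width_s)) + 1L
  inside <- bin >= 1L & bin <= n_bins
  bin <- bin[inside]; tier <- tier[inside]
  n_total <- tabulate(bin, n_bins)
  n_fluor <- tabulate(bin[tier != "none"], n_bins)
  n_hyper <- tabulate(bin[tier == "hyper_fluorescent"], n_bins)
  dur_min <- bin_width_s / 60
  frac_fluor <- ifelse(n_total > 0, n_fluor / n_total, NA_real_)
  frac_hyper <- ifelse(n_total > 0, n_hyper / n_total, NA_real_)
  data.frame(
    bin_start = as_utc(t0 + (seq_len(n_bins) - 1L) * bin_width_s),
    n_total = n_total, n_fluor = n_fluor, n_hyper = n_hyper,
    conc_total = number_concentration(n_total, flow_lpm, dur_min),
    conc_fluor = number_concentration(n_fluor, flow_lpm, dur_min),
    conc_hyper = number_concentration(n_hyper, flow_lpm, dur_min),
    frac_fluor = frac_fluor, frac_hyper = frac_hyper
  )
}

# Internal: size-bin index with overflow as NA.
size_bin_index <- function(d, edges) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    stop("size bin edges must be strictly increasing, length >= 2")
  }
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(edges) - 1L] <- NA_integer_
  idx
}

#' Number size distribution dN/dlogD
#'
#' Histogram of optical diameters on a logarithmic grid, normalised to
#' dN/dlogD in L^-1 (base-10 log). Particles outside the grid are counted in
#' an `overflow` attribute, never silently lost. When `time_bin_s` is given,
#' a per-time-bin distribution is computed first and the per-size-bin median
#' and interquartile range across time bins are reported (the campaign-median
#' size distribution).
#'
#' @param particles particle data frame (`timestamp`, `d_opt`).
#' @param edges size bin edges in um (default [default_size_edges()]).
#' @param flow_lpm sample flow, L/min.
#' @param duration_min total sampling duration in minutes (required for the
#'   pooled variant; inferred per time bin otherwise).
#' @param time_bin_s if non-NULL, compute the median/IQR across time bins of
#'   this width (seconds).
#' @return data frame with `d_lo`, `d_hi`, `d_mid` (geometric midpoint),
#'   `count`, `dNdlogD` and, for the median variant, `dNdlogD_q25`,
#'   `dNdlogD_q75`. Attribute `overflow` counts out-of-grid particles.
#' @export
size_distribution <- function(particles, edges = default_size_edges(),
                              flow_lpm = 0.23, duration_min = NULL,
                              time_bin_s = NULL) {
  idx <- size_bin_index(particles$d_opt, edges)
  n_bins <- length(edges) - 1L
  dlog <- diff(log10(edges))
  base <- data.frame(
    d_lo = edges[-length(edges)], d_hi = edges[-1],
    d_mid = sqrt(edges[-length(edges)] * edges[-1])
  )
  overflow <- sum(is.na(idx))
  if (is.null(time_bin_s)) {
    if (is.null(duration_min)) stop("duration_min required for pooled distribution")
    cnt <- tabulate(idx[!is.na(idx)], n_bins)
    base$count <- cnt
    base$dNdlogD <- number_concentration(cnt, flow_lpm, duration_min) / dlog
  } else {
    tt <- as.numeric(particles$timestamp)
    t0 <- floor(min(tt) / time_bin_s) * time_bin_s
    tb <- as.integer(floor((tt - t0) / time_bin_s)) + 1L
    n_t <- max(tb)
    ok <- !is.na(idx)
    # joint (time, size) histogram via a single flat tabulate pass
    flat <- (tb[ok] - 1L) * n_bins + idx[ok]
    m <- matrix(tabulate(flat, n_t * n_bins), n_t, n_bins, byrow = TRUE)
    conc <- sweep(number_concentration(m, flow_lpm, time_bin_s / 60),
                  2, dlog, "/")
    base$count <- colSums(m)
    base$dNdlogD <- apply(conc, 2, median)
    base$dNdlogD_q25 <- apply(conc, 2, quantile, 0.25)
    base$dNdlogD_q75 <- apply(conc, 2, quantile, 0.75)
  }
  attr(base, "overflow") <- overflow
  base
}

#' Size-resolved fluorescent fraction
#'
#' Fraction of particles in each size bin that are in the fluorescence tier.
#' Empty bins are reported as `NA` (flagged missing, never zero).
#'
#' @param particles particle data frame with `d_opt`.
#' @param labels classification from [classify_particles()]; the tier
#'   membership used is `tier != "none"` (so classify at the threshold level
#'   of interest).
#' @param edges size bin edges in um.
#' @return data frame `d_lo`, `d_hi`, `d_mid`, `n`, `n_tier`, `fraction`.
#' @export
size_resolved_fraction <- function(particles, labels,
                                   edges = default_size_edges()) {
  if (nrow(particles) != nrow(labels)) stop("particles and labels must align")
  idx <- size_bin_index(particles$d_opt, edges)
  n_bins <- length(edges) - 1L
  ok <- !is.na(idx)
  n <- tabulate(idx[ok], n_bins)
  n_tier <- tabulate(idx[ok & labels$tier != "none"], n_bins)
  data.frame(
    d_lo = edges[-length(edges)], d_hi = edges[-1],
    d_mid = sqrt(edges[-length(edges)] * edges[-1]),
    n = n, n_tier = n_tier,
    fraction = ifelse(n > 0, n_tier / n, NA_real_)
  )
}

#' Asymmetry-factor probability density per size class
#'
#' Normalised histograms of the asymmetry factor (AF, the instrument's shape
#' metric; low values indicate near-spherical particles) within particle size
#' classes. Each class density integrates to 1; empty classes are flagged.
#'
#' @param particles particle data frame with `d_opt` and `af`.
#' @param size_class_edges edges (um) of the size classes (default
#'   0.5, 2.5, 5, 14 um, i.e. classes <2.5, 2.5-5, 5-14).
#' @param af_edges AF histogram bin edges (default 0 to 40 by 1).
#' @return data frame `size_class`, `af_lo`, `af_hi`, `density`, `n_class`;
#'   `density` is `NA` for empty classes.
#' @export
af_pdf <- function(particles, size_class_edges = c(0.5, 2.5, 5, 14),
                   af_edges = seq(0, 40, by = 1)) {
  cls <- size_bin_index(particles$d_opt, size_class_edges)
  afb <- size_bin_index(particles$af, af_edges)
  n_cls <- length(size_class_edges) - 1L
  n_afb <- length(af_edges) - 1L
  lab <- sprintf("%g-%g um", size_class_edges[-length(size_class_edges)],
                 size_class_edges[-1])
  out <- lapply(seq_len(n_cls), function(k) {
    sel <- !is.na(cls) & cls == k & !is.na(afb)
    n_k <- sum(sel)
    cnt <- tabulate(afb[sel], n_afb)
    width <- diff(af_edges)
    data.frame(
      size_class = lab[k],
      af_lo = af_edges[-length(af_edges)], af_hi = af_edges[-1],
      density = if (n_k > 0) cnt / (n_k * width) else NA_real_,
      n_class = n_k
    )
  })
  do.call(rbind, out)
}

#' Latitude-binned box statistics of a time series
#'
#' Groups a time-binned series by the ship's latitude in fixed-width bins
#' (default 4 degrees, intervals left-closed `[b, b + width)`) and reports
#' median, interquartile range and 5th/95th percentiles per bin. The track
#' latitude is matched to each series bin by nearest timestamp.
#'
#' @param series data frame with `bin_start` and the value columns.
#' @param track data frame with `timestamp`, `lat`.
#' @param value_cols names of the series columns to summarise.
#' @param width_deg bin width in degrees latitude.
#' @param n_min bins with fewer samples are flagged (`ok = FALSE`).
#' @return data frame with `lat_lo`, `lat_hi`, `n`, `ok` and, per value
#'   column, `<col>_median`, `<col>_q25`, `<col>_q75`, `<col>_q05`,
#'   `<col>_q95`.
#' @export
latitude_binning <- function(series, track, value_cols, width_deg = 4,
                             n_min = 5) {
  stopifnot_scalar_num(width_deg, "width_deg")
  t_series <- as.numeric(series$bin_start)
  t_track <- as.numeric(track$timestamp)
  nearest <- findInterval(t_series, t_track, all.inside = TRUE)
  use_next <- abs(t_track[pmin(nearest + 1L, length(t_track))] - t_series) <
    abs(t_track[nearest] - t_series)
  nearest[use_next] <- nearest[use_next] + 1L
  lat <- track$lat[nearest]
  bin_lo <- floor(lat / width_deg) * width_deg
  out <- lapply(sort(unique(bin_lo)), function(b) {
    sel <- bin_lo == b
    row <- data.frame(lat_lo = b, lat_hi = b + width_deg,
                      n = sum(sel), ok = sum(sel) >= n_min)
    for (cl in value_cols) {
      v <- series[[cl]][sel]
      v <- v[is.finite(v)]
      q <- if (length(v)) quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
           else rep(NA_real_, 5)
      row[[paste0(cl, "_q05")]] <- q[1]
      row[[paste0(cl, "_q25")]] <- q[2]
      row[[paste0(cl, "_median")]] <- q[3]
      row[[paste0(cl, "_q75")]] <- q[4]
      row[[paste0(cl, "_q95")]] <- q[5]
    }
    row
  })
  do.call(rbind, out)
}
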
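#' Great-circle distance between points, in kilometres
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorised over all four
#' coordinate arguments (recycled to a common length).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of arc at the equator, ~111.19 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]")
  }
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, a) # guard rounding at antipodes
  2 * r * asin(sqrt(a))
}

#' Minimum distance from each track point to a coastline
#'
#' The coastline is a densified vertex cloud (vertex spacing at most ~10 km,
#' see [generate_coastline()]); at the 100 km scales relevant to marine
#' segregation the vertex-minimum is an adequate stand-in for the true
#' point-to-polyline distance. An empty coastline (open ocean) yields `Inf`
#' everywhere.
#'
#' @param track data frame with `lat`, `lon` columns.
#' @param coastline data frame with `lat`, `lon` vertex columns (possibly
#'   zero rows).
#' @param chunk internal block size controlling peak memory of the
#'   track-by-vertex distance matrix.
#' @return numeric vector, one distance (km) per track row.
#' @export
distance_to_land <- function(track, coastline, chunk = 2000L) {
  n <- nrow(track)
  if (is.null(coastline) || nrow(coastline) == 0L) return(rep(Inf, n))
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    d <- outer(seq_along(idx), seq_len(nrow(coastline)),
               function(i, j) haversine_km(track$lat[idx][i], track$lon[idx][i],
                                           coastline$lat[j], coastline$lon[j]))
    out[idx] <- apply(d, 1, min)
  }
  out
}

#' Segregate a ship track into pristine-marine and terrestrially influenced
#'
#' Points strictly farther than `threshold_km` from every coastline vertex
#' are pristine-marine; all others (including points exactly at the
#' threshold) are terrestrially influenced. The default threshold is 200 km.
#'
#' @param track data frame with `timestamp`, `lat`, `lon`.
#' @param coastline coastline vertex data frame, or `NULL` for open ocean.
#' @param threshold_km segregation distance in km.
#' @param distances optional precomputed distances (km) matching `track`
#'   rows; skips the coastline search.
#' @return data frame with `timestamp`, `distance_to_land_km`, and factor
#'   `category` (`pristine_marine` / `terrestrial`).
#' @export
segregate <- function(track, coastline = NULL, threshold_km = 200,
                      distances = NULL) {
  # Inf is a legal degenerate threshold (everything terrestrial)
  if (!is.numeric(threshold_km) || length(threshold_km) != 1L ||
      is.na(threshold_km)) {
    stop("'threshold_km' must be a single number")
  }
  d <- if (is.null(distances)) distance_to_land(track, coastline) else distances
  if (length(d) != nrow(track)) stop("distances length must match track rows")
  data.frame(
    timestamp = track$timestamp,
    distance_to_land_km = d,
    category = factor(ifelse(d > threshold_km, "pristine_marine", "terrestrial"),
                      levels = c("pristine_marine", "terrestrial"))
  )
}

#' Scan segregation thresholds for the correlation plateau
#'
#' For each candidate distance threshold, computes the Pearson correlation
#' between a fluorescent-particle series and a sea spray proxy series over
#' the subset of bins farther from land than the threshold. As contaminated
#' near-land bins are progressively excluded the correlation rises and then
#' stabilises; the plateau estimate is the smallest threshold `t*` whose
#' correlation lies within `eps` of the median correlation over all
#' larger-or-equal (unflagged) thresholds. The tail median is a stable
#' reference: it makes the estimate insensitive to sampling noise in the
#' small subsets left at the largest thresholds. For a flat curve (no
#' terrestrial contamination) the estimate is the smallest threshold.
#' Thresholds whose subset has fewer than `min_pairs` pairs are flagged and
#' excluded from the plateau search.
#'
#' @param fluor numeric vector (e.g. hourly fluorescent concentration).
#' @param proxy numeric vector of the same length (e.g. hourly wind speed).
#' @param distances numeric vector of the same length: distance to land (km)
#'   for each bin.
#' @param thresholds candidate thresholds in km (at least 2).
#' @param eps plateau stability tolerance on Pearson R (default 0.02).
#' @param min_pairs minimum usable pairs per subset (default 25).
#' @return list of class `threshold_scan` with elements `curve` (data frame
#'   `threshold_km`, `r`, `n`, `ok`), `plateau_km`, and `eps`.
#' @export
scan_distance_threshold <- function(fluor, proxy, distances, thresholds,
                                    eps = 0.02, min_pairs = 25) {
  if (length(thresholds) < 2L) stop("need at least 2 candidate thresholds")
  n <- length(fluor)
  if (length(proxy) != n || length(distances) != n) {
    stop("fluor, proxy and distances must have equal length")
  }
  thresholds <- sort(thresholds)
  curve <- lapply(thresholds, function(t0) {
    sel <- which(distances > t0 & is.finite(fluor) & is.finite(proxy))
    ok <- length(sel) >= min_pairs &&
      sd(fluor[sel]) > 0 && sd(proxy[sel]) > 0
    data.frame(
      threshold_km = t0,
      r = if (ok) cor(fluor[sel], proxy[sel]) else NA_real_,
      n = length(sel),
      ok = ok
    )
  })
  curve <- do.call(rbind, curve)
  if (!any(curve$ok)) stop("no threshold leaves enough pairs (all subsets too small)")
  usable <- curve[curve$ok, , drop = FALSE]
  plateau <- NA_real_
  for (i in seq_len(nrow(usable))) {
    if (abs(usable$r[i] - median(usable$r[i:nrow(usable)])) < eps) {
      plateau <- usable$threshold_km[i]
      break
    }
  }
  structure(list(curve = curve, plateau_km = plateau, eps = eps),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Distance-threshold correlation scan (eps = %g)\n", x$eps))
  cat(sprintf("Plateau estimate: %s km\n",
              format(x$plateau_km)))
  print(x$curve, ...)
  invisible(x)
}
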
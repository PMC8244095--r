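#' Forced-trigger statistics and fluorescence detection thresholds
#'
#' Forced-trigger (FT) records are background measurements taken with no
#' particle present. Their per-channel mean and sample standard deviation
#' define the fluorescence detection thresholds: a particle is fluorescent
#' in a channel when its amplitude exceeds the FT mean plus 3 standard
#' deviations (the 3-sigma threshold), and hyper-fluorescent when it exceeds
#' the FT mean plus 9 standard deviations (9-sigma).
#'
#' @param ft data frame of forced-trigger records with numeric columns
#'   `fl_a`, `fl_b`, `fl_c` (instrument units), e.g. from
#'   [generate_ft_records()] or [read_ft()].
#' @return An object of class `threshold_set`: a list with per-channel
#'   vectors `mean`, `sd`, `t3` (`mean + 3 sd`), `t9` (`mean + 9 sd`),
#'   the record count `n`, and the channel excitation/emission metadata.
#' @examples
#' ft <- generate_ft_records(1000, c(50, 45, 40), c(8, 7, 6), seed = 1)
#' compute_ft_stats(ft)
#' @export
compute_ft_stats <- function(ft) {
  cols <- c("fl_a", "fl_b", "fl_c")
  missing <- setdiff(cols, names(ft))
  if (length(missing)) {
    stop("forced-trigger table lacks column(s): ", paste(missing, collapse = ", "))
  }
  n <- vapply(cols, function(cl) sum(!is.na(ft[[cl]])), integer(1))
  if (any(n < 2L)) {
    stop("each channel needs at least 2 forced-trigger records (sd undefined)")
  }
  m <- vapply(cols, function(cl) mean(ft[[cl]], na.rm = TRUE), numeric(1))
  s <- vapply(cols, function(cl) sd(ft[[cl]], na.rm = TRUE), numeric(1))
  names(m) <- names(s) <- c("A", "B", "C")
  out <- list(
    mean = m, sd = s,
    t3 = m + 3 * s, t9 = m + 9 * s,
    n = n, channels = wibs_channels()
  )
  class(out) <- "threshold_set"
  out
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Fluorescence threshold set (forced-trigger derived)\n")
  tab <- data.frame(
    channel = names(x$mean),
    ft_mean = x$mean, ft_sd = x$sd,
    t3 = x$t3, t9 = x$t9, n = x$n,
    row.names = NULL
  )
  print(tab, ...)
  invisible(x)
}

# Internal: per-channel exceedance matrix at the k-sigma thresholds.
channel_exceedance <- function(particles, th, tier_k) {
  t_k <- if (tier_k == 3) th$t3 else th$t9
  cbind(
    A = particles$fl_a > t_k[["A"]],
    B = particles$fl_b > t_k[["B"]],
    C = particles$fl_c > t_k[["C"]]
  )
}

#' Classify particles into fluorescence tiers and ABC classes
#'
#' A particle belongs to the fluorescent tier if at least one channel
#' amplitude strictly exceeds its 3-sigma threshold, and to the
#' hyper-fluorescent tier (a subset of the fluorescent tier) if at least one
#' channel exceeds its 9-sigma threshold. The ABC class is the combination
#' of channels that are "on" at the `tier_k`-sigma thresholds: one of A, B,
#' C, AB, AC, BC, ABC (seven non-empty classes), or `none`.
#'
#' With `tier_k = 9` the reported `tier` is `none` for particles that are
#' only fluorescent at 3-sigma, so `tier == "none"` is always equivalent to
#' `abc_class == "none"` at the chosen threshold level.
#'
#' @param particles data frame with numeric columns `fl_a`, `fl_b`, `fl_c`.
#' @param th a `threshold_set` from [compute_ft_stats()].
#' @param tier_k 3 or 9; which threshold level defines the classification.
#' @return data frame with factor columns `tier`
#'   (`none`/`fluorescent`/`hyper_fluorescent`) and `abc_class`
#'   (`none`/A/B/C/AB/AC/BC/ABC), one row per particle.
#' @export
classify_particles <- function(particles, th, tier_k = 3) {
  stopifnot(inherits(th, "threshold_set"))
  if (!tier_k %in% c(3, 9)) stop("tier_k must be 3 or 9")
  on_k <- channel_exceedance(particles, th, tier_k)
  code <- 4L * on_k[, "A"] + 2L * on_k[, "B"] + on_k[, "C"]
  abc <- factor(abc_code_table()[code + 1L],
                levels = c("none", abc_levels()))
  if (tier_k == 3) {
    on9 <- channel_exceedance(particles, th, 9)
    hyper <- rowSums(on9) > 0L
    tier <- ifelse(code > 0L,
                   ifelse(hyper, "hyper_fluorescent", "fluorescent"),
                   "none")
  } else {
    tier <- ifelse(code > 0L, "hyper_fluorescent", "none")
  }
  data.frame(
    tier = factor(tier, levels = tier_levels()),
    abc_class = abc
  )
}

#' Channel B-to-A fluorescence ratio (approximate humification index)
#'
#' The ratio of the channel B amplitude (420-650 nm emission) to the channel
#' A amplitude (310-400 nm emission), both under 280 nm excitation. High
#' values indicate humic-like, low values protein-like fluorophores. It is
#' computed for every particle; to keep measurement noise at low signal
#' levels from influencing the ratio, amplitudes below the `tier_k`-sigma
#' detection threshold in channels A and B are replaced by the forced-trigger
#' mean of that channel before forming the ratio.
#'
#' @inheritParams classify_particles
#' @return numeric vector of ratios, one per particle.
#' @export
compute_rb2a <- function(particles, th, tier_k = 3) {
  stopifnot(inherits(th, "threshold_set"))
  if (!tier_k %in% c(3, 9)) stop("tier_k must be 3 or 9")
  if (th$mean[["A"]] <= 0) stop("channel A forced-trigger mean must be positive")
  t_k <- if (tier_k == 3) th$t3 else th$t9
  fa <- ifelse(particles$fl_a > t_k[["A"]], particles$fl_a, th$mean[["A"]])
  fb <- ifelse(particles$fl_b > t_k[["B"]], particles$fl_b, th$mean[["B"]])
  fb / fa
}

#' Fraction of each ABC class among in-tier particles
#'
#' @param labels data frame from [classify_particles()] (columns `tier`,
#'   `abc_class`).
#' @return named numeric vector of length 7 (classes A, B, C, AB, AC, BC,
#'   ABC) summing to 1.
#' @export
class_fractions <- function(labels) {
  keep <- labels$abc_class != "none"
  if (!any(keep)) stop("no particles in the fluorescence tier")
  tab <- table(factor(labels$abc_class[keep], levels = abc_levels()))
  setNames(as.numeric(tab) / sum(tab), abc_levels())
}

#' Quality masks
#'
#' Named predicates over particle records used to remove suspect samples
#' (e.g. segments contaminated by ship exhaust). The exact contamination
#' criteria are campaign-specific, so the mask is pluggable: built-in masks
#' are `"pass_all"` (keep everything) and `"flag_clean"` (keep records whose
#' `quality_flags` bit set is 0); any function mapping the particle data
#' frame to a logical keep-vector can be supplied instead.
#'
#' @param particles particle data frame (see [read_particles()] for the schema).
#' @param mask mask name (`"pass_all"`, `"flag_clean"`) or a predicate
#'   function `f(particles) -> logical`.
#' @return The filtered data frame, with attribute `mask_report`: a list with
#'   `n_in`, `n_removed`, and `removed_fraction`.
#' @export
apply_quality_mask <- function(particles, mask = "pass_all") {
  keep <- if (is.function(mask)) {
    mask(particles)
  } else if (identical(mask, "pass_all")) {
    rep(TRUE, nrow(particles))
  } else if (identical(mask, "flag_clean")) {
    particles$quality_flags == 0L
  } else {
    stop("unknown quality mask: ", mask)
  }
  if (!is.logical(keep) || length(keep) != nrow(particles)) {
    stop("mask predicate must return one logical per record")
  }
  keep[is.na(keep)] <- FALSE
  out <- particles[keep, , drop = FALSE]
  attr(out, "mask_report") <- list(
    n_in = nrow(particles),
    n_removed = sum(!keep),
    removed_fraction = if (nrow(particles)) sum(!keep) / nrow(particles) else 0
  )
  out
}
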
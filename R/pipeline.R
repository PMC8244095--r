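#' Default pipeline configuration
#'
#' @param preset a [scenario_preset()] or preset name.
#' @param out_dir output directory for the report bundle (`NULL`: nothing is
#'   written, results are only returned).
#' @param ... overrides for config fields: `tier_k` (3), `threshold_km`
#'   (200), `hour_bin_s` (3600), `mask` ("pass_all"), `scan_thresholds`
#'   (25 to 500 km by 25), `scan_eps` (0.02), `n_boot` (100), `boot_frac`
#'   (0.6), `n_perm` (2000), `min_pairs` (25), `stat_seed` (1),
#'   `write_particles` (FALSE).
#' @return named list.
#' @export
pipeline_config <- function(preset = "pristine", out_dir = NULL, ...) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  cfg <- list(
    preset = preset,
    out_dir = out_dir,
    tier_k = 3,
    threshold_km = 200,
    hour_bin_s = 3600,
    mask = "pass_all",
    scan_thresholds = seq(25, 500, by = 25),
    scan_eps = 0.02,
    n_boot = 100,
    boot_frac = 0.6,
    n_perm = 2000,
    min_pairs = 25,
    stat_seed = 1,
    write_particles = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

# Internal: match hourly series rows to segregation categories.
hourly_category <- function(series, seg, bin_width_s = 3600) {
  ts <- as.numeric(series$bin_start)
  st <- as.numeric(seg$timestamp)
  idx <- findInterval(ts, st, all.inside = TRUE)
  # a series hour is pristine only if its containing track bins all are;
  # conservatively use the track point at the bin start
  seg$category[idx]
}

#' Run the full campaign analysis pipeline
#'
#' simulate -> derive thresholds -> mask -> classify (3 and 9 sigma) ->
#' aggregate -> segregate by distance to land -> threshold scan ->
#' marine correlations -> summary report. Fully deterministic for a fixed
#' config (the preset seed drives the simulation, `stat_seed` the resampling
#' statistics).
#'
#' @param config list from [pipeline_config()].
#' @return list of class `pipeline_result` with elements `thresholds`,
#'   `hourly` (hourly series + distance + category), `summary` (named
#'   medians/IQRs), `class_fractions` (3 and 9 sigma), `rb2a` (quantiles per
#'   tier), `scan` (threshold scan, if a coastline exists), `correlations`
#'   (marine correlation table), `mask_report`, and `campaign`.
#'   If `out_dir` is set the tables are also written there as CSV.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  camp <- tryCatch(generate_campaign(cfg$preset),
                   error = function(e) stop("stage simulate: ", conditionMessage(e)))

  th <- tryCatch(compute_ft_stats(camp$ft),
                 error = function(e) stop("stage thresholds: ", conditionMessage(e)))

  particles <- tryCatch(apply_quality_mask(camp$particles, cfg$mask),
                        error = function(e) stop("stage mask: ", conditionMessage(e)))
  mask_report <- attr(particles, "mask_report")

  labels3 <- tryCatch(classify_particles(particles, th, 3),
                      error = function(e) stop("stage classify: ", conditionMessage(e)))
  labels9 <- classify_particles(particles, th, 9)

  t_start <- camp$truth$bin$bin_start[1]
  t_end <- as_utc(as.numeric(t_start) + cfg$preset$duration_h * 3600)
  eff_flow <- cfg$preset$flow_lpm * cfg$preset$duty_cycle
  hourly <- tryCatch(
    time_binned_series(particles, labels3, bin_width_s = cfg$hour_bin_s,
                       flow_lpm = eff_flow,
                       t_start = t_start, t_end = t_end),
    error = function(e) stop("stage aggregate: ", conditionMessage(e)))

  seg <- tryCatch(
    segregate(camp$track, camp$coastline, threshold_km = cfg$threshold_km,
              distances = camp$truth$bin$distance_to_land_km),
    error = function(e) stop("stage segregate: ", conditionMessage(e)))
  hourly$distance_to_land_km <- {
    st <- as.numeric(seg$timestamp)
    idx <- findInterval(as.numeric(hourly$bin_start), st, all.inside = TRUE)
    seg$distance_to_land_km[idx]
  }
  hourly$category <- hourly_category(hourly, seg)

  pristine <- hourly[hourly$category == "pristine_marine" & hourly$n_total > 0, ]
  q <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  summary_stats <- c(
    n_hours_pristine = nrow(pristine),
    median_conc_fluor = q(pristine$conc_fluor)[2],
    iqr_lo_conc_fluor = q(pristine$conc_fluor)[1],
    iqr_hi_conc_fluor = q(pristine$conc_fluor)[3],
    median_conc_hyper = q(pristine$conc_hyper)[2],
    median_frac_fluor_pct = 100 * q(pristine$frac_fluor)[2],
    median_frac_hyper_pct = 100 * q(pristine$frac_hyper)[2]
  )

  cf3 <- class_fractions(labels3)
  cf9 <- tryCatch(class_fractions(labels9), error = function(e) NULL)
  rq <- function(lab) {
    r <- compute_rb2a(particles, th, cfg$tier_k)
    keep <- lab$tier != "none"
    if (!any(keep)) return(NULL)
    quantile(r[keep], c(0.05, 0.25, 0.5, 0.75, 0.95))
  }
  rb2a <- list(fluorescent = rq(labels3), hyper_fluorescent = rq(labels9))

  scan <- NULL
  if (nrow(camp$coastline) > 0) {
    ok <- hourly$n_total > 0
    scan <- tryCatch(
      scan_distance_threshold(hourly$conc_fluor[ok],
                              {
                                ut <- camp$track$u10n
                                st <- as.numeric(camp$track$timestamp)
                                idx <- findInterval(as.numeric(hourly$bin_start)[ok], st,
                                                    all.inside = TRUE)
                                ut[idx]
                              },
                              hourly$distance_to_land_km[ok],
                              cfg$scan_thresholds, eps = cfg$scan_eps,
                              min_pairs = cfg$min_pairs),
      error = function(e) stop("stage scan: ", conditionMessage(e)))
  }

  correlations <- NULL
  if (!is.null(camp$marine)) {
    # marine-aerosol links are assessed over the pristine-marine subset only;
    # non-pristine hours are blanked (not removed) to keep the series hourly
    hr <- hourly
    blank <- hr$category != "pristine_marine"
    hr$frac_fluor[blank] <- NA_real_
    hr$frac_hyper[blank] <- NA_real_
    correlations <- tryCatch(
      correlate_marine(camp$marine, hr,
                       n_boot = cfg$n_boot,
                       boot_frac = cfg$boot_frac, n_perm = cfg$n_perm,
                       min_pairs = cfg$min_pairs, seed = cfg$stat_seed),
      error = function(e) stop("stage correlate: ", conditionMessage(e)))
  }

  out <- structure(list(
    thresholds = th,
    hourly = hourly,
    summary = summary_stats,
    class_fractions = list(k3 = cf3, k9 = cf9),
    rb2a = rb2a,
    scan = scan,
    correlations = correlations,
    mask_report = mask_report,
    campaign = camp
  ), class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_bundle(out, cfg)
  out
}

#' Marine-aerosol correlation table
#'
#' Pairs every seawater variable with the hourly fluorescent and
#' hyper-fluorescent coarse-particle fractions and computes Pearson's R, the
#' 100x60% subsampling bootstrap spread and a permutation p-value for each
#' pair with at least `min_pairs` simultaneous points. Results significant
#' at the 90% level have `p_perm < 0.1`.
#'
#' @param marine marine sample table (`timestamp`, `variable`, `value`,
#'   `category`).
#' @param hourly hourly series from [time_binned_series()] (needs
#'   `frac_fluor` and `frac_hyper`); restrict it to pristine hours first if
#'   that is the analysis intent.
#' @param n_boot,boot_frac,n_perm,min_pairs,seed statistics settings.
#' @return data frame, one row per (variable, aerosol fraction) pair:
#'   `variable`, `category`, `aerosol`, `n_pairs`, `r`, `boot_sd`,
#'   `boot_lo`, `boot_hi`, `p_perm`, `significant_90`.
#' @export
correlate_marine <- function(marine, hourly, n_boot = 100, boot_frac = 0.6,
                             n_perm = 2000, min_pairs = 25, seed = 1) {
  out <- list()
  k <- 0L
  for (frac_col in c("frac_fluor", "frac_hyper")) {
    for (v in unique(marine$variable)) {
      mv <- marine[marine$variable == v, , drop = FALSE]
      paired <- pair_marine_to_aerosol(mv, hourly, aerosol_col = frac_col)
      ok <- is.finite(paired$value) & is.finite(paired$aerosol)
      n <- sum(ok)
      if (n < min_pairs) next
      x <- paired$value[ok]; y <- paired$aerosol[ok]
      r <- pearson_r(x, y)
      bt <- bootstrap_r(x, y, n_rep = n_boot, frac = boot_frac,
                        seed = seed, min_pairs = min_pairs)
      pp <- permutation_p(x, y, n_perm = n_perm, seed = seed,
                          min_pairs = min_pairs)
      k <- k + 1L
      out[[k]] <- data.frame(
        variable = v, category = mv$category[1], aerosol = frac_col,
        n_pairs = n, r = r, boot_sd = bt$sd,
        boot_lo = bt$interval[1], boot_hi = bt$interval[2],
        p_perm = pp, significant_90 = pp < 0.1
      )
    }
  }
  if (!k) stop("no marine variable has enough simultaneous pairs")
  do.call(rbind, out)
}

write_bundle <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out_dir, f)
  if (isTRUE(cfg$write_particles)) {
    write_particles(res$campaign$particles, pth("particles.csv"))
  }
  write_ft(res$campaign$ft, pth("ft.csv"))
  write_track(res$campaign$track, pth("track.csv"))
  if (!is.null(res$campaign$marine)) write_marine(res$campaign$marine, pth("marine.csv"))
  write_proxies(res$campaign$proxies, pth("proxies.csv"))
  th <- res$thresholds
  writeLines(c(
    sprintf("ft_mean_%s=%.10g", c("a", "b", "c"), th$mean),
    sprintf("ft_sd_%s=%.10g", c("a", "b", "c"), th$sd),
    sprintf("t3_%s=%.10g", c("a", "b", "c"), th$t3),
    sprintf("t9_%s=%.10g", c("a", "b", "c"), th$t9)
  ), pth("thresholds.txt"))
  hourly_out <- res$hourly
  hourly_out$bin_start <- as.numeric(hourly_out$bin_start)
  utils::write.csv(hourly_out, pth("hourly.csv"), row.names = FALSE)
  cf <- rbind(
    data.frame(tier_k = 3, class = names(res$class_fractions$k3),
               fraction = as.numeric(res$class_fractions$k3)),
    if (!is.null(res$class_fractions$k9))
      data.frame(tier_k = 9, class = names(res$class_fractions$k9),
                 fraction = as.numeric(res$class_fractions$k9))
  )
  utils::write.csv(cf, pth("class_fractions.csv"), row.names = FALSE)
  if (!is.null(res$correlations)) {
    utils::write.csv(res$correlations, pth("correlations.csv"), row.names = FALSE)
  }
  if (!is.null(res$scan)) {
    utils::write.csv(res$scan$curve, pth("scan_curve.csv"), row.names = FALSE)
    writeLines(sprintf("plateau_km=%g", res$scan$plateau_km), pth("plateau.txt"))
  }
  writeLines(sprintf("%s=%.10g", names(res$summary), res$summary),
             pth("summary.txt"))
  invisible(cfg$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Campaign pipeline result\n")
  cat(sprintf("  pristine-marine hours: %d\n", as.integer(x$summary["n_hours_pristine"])))
  cat(sprintf("  median fluorescent conc: %.3g L^-1 (IQR %.3g-%.3g)\n",
              x$summary["median_conc_fluor"], x$summary["iqr_lo_conc_fluor"],
              x$summary["iqr_hi_conc_fluor"]))
  cat(sprintf("  median hyper-fluorescent conc: %.3g L^-1\n",
              x$summary["median_conc_hyper"]))
  cat(sprintf("  median fluorescent fraction: %.3g%%; hyper: %.3g%%\n",
              x$summary["median_frac_fluor_pct"], x$summary["median_frac_hyper_pct"]))
  if (!is.null(x$scan)) {
    cat(sprintf("  distance-threshold plateau: %g km\n", x$scan$plateau_km))
  }
  invisible(x)
}
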
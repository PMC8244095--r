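test_that("number concentration is count over sampled volume", {
  expect_equal(number_concentration(120, 1, 60), 2)
  expect_equal(number_concentration(0, 0.23, 5), 0)
  expect_error(number_concentration(10, 0, 5), "flow")
  expect_error(number_concentration(10, 1, -5), "duration")
  # Poisson stream oracle: estimate within 3 sqrt(lambda)/(flow*duration)
  set.seed(1)
  lambda <- 500
  est <- number_concentration(rpois(1, lambda), 2, 10)
  expect_lt(abs(est - lambda / 20), 3 * sqrt(lambda) / 20)
})

test_that("fine/coarse partition cuts at 1 um with the tie going coarse", {
  p <- toy_particles(rep(1, 4), 1, 1)
  p$d_opt <- c(0.9, 1.0, 1.1, 0.5)
  sp <- split_fine_coarse(p)
  expect_equal(sp$fine$d_opt, c(0.9, 0.5))
  expect_equal(sp$coarse$d_opt, c(1.0, 1.1))
  # conservation on a random stream
  set.seed(2)
  p2 <- toy_particles(rep(1, 500), 1, 1)
  p2$d_opt <- rlnorm(500, 0, 0.5)
  sp2 <- split_fine_coarse(p2)
  expect_equal(nrow(sp2$fine) + nrow(sp2$coarse), 500L)
})

test_that("size distribution integrates to the total concentration", {
  p <- toy_particles(rep(1, 1), 1, 1)
  p$d_opt <- 2
  sd1 <- size_distribution(p, flow_lpm = 1, duration_min = 1)
  expect_equal(sum(sd1$count > 0), 1L)
  # integral of dN/dlogD over the grid equals the total concentration
  set.seed(3)
  n <- 20000
  p2 <- toy_particles(rep(1, n), 1, 1)
  p2$d_opt <- rlnorm(n, log(2), 0.4)
  edges <- default_size_edges()
  sd2 <- size_distribution(p2, edges, flow_lpm = 1, duration_min = 5)
  dlog <- diff(log10(edges))
  in_grid <- n - attr(sd2, "overflow")
  expect_equal(sum(sd2$dNdlogD * dlog), in_grid / 5)
  # overflow is tallied, not lost
  expect_equal(sum(sd2$count) + attr(sd2, "overflow"), n)
})

test_that("size distribution recovers a known lognormal mode", {
  set.seed(4)
  n <- 1e5
  p <- toy_particles(rep(1, n), 1, 1)
  p$d_opt <- rlnorm(n, log(3), 0.3)
  edges <- exp(seq(log(0.5), log(16), length.out = 33))
  sdist <- size_distribution(p, edges, flow_lpm = 1, duration_min = 1)
  mode_mid <- sdist$d_mid[which.max(sdist$dNdlogD)]
  # dN/dlogD of a lognormal peaks at the median (3 um); one bin of slack
  expect_gt(mode_mid, 3 / exp(diff(log(edges))[1]))
  expect_lt(mode_mid, 3 * exp(diff(log(edges))[1]))
})

test_that("median-over-time size distribution brackets the pooled one", {
  camp <- generate_campaign(small_preset(duration_h = 6, seed = 6))
  sdist <- size_distribution(camp$particles, flow_lpm = 0.115,
                             time_bin_s = 3600)
  expect_true(all(c("dNdlogD_q25", "dNdlogD_q75") %in% names(sdist)))
  occupied <- sdist$count > 50
  expect_true(all(sdist$dNdlogD_q25[occupied] <= sdist$dNdlogD[occupied]))
  expect_true(all(sdist$dNdlogD_q75[occupied] >= sdist$dNdlogD[occupied]))
})

test_that("size-resolved fluorescent fraction flags empty bins and recovers ramps", {
  th <- toy_thresholds()
  # all-fluorescent toy stream: fraction 1 in occupied bins, NA elsewhere
  p <- toy_particles(rep(100, 50), 100, 100)
  p$d_opt <- runif(50, 2, 4)
  lab <- classify_particles(p, th, 3)
  srf <- size_resolved_fraction(p, lab)
  expect_true(all(srf$fraction[srf$n > 0] == 1))
  expect_true(all(is.na(srf$fraction[srf$n == 0])))

  # size-ramped fluorescence probability recovered within binomial tolerance
  set.seed(5)
  n <- 50000
  d <- exp(runif(n, log(0.6), log(14)))
  prob <- pmin(0.9, 0.02 + 0.5 * (log(d) - log(0.6)) / log(14 / 0.6))
  is_fl <- runif(n) < prob
  p2 <- toy_particles(ifelse(is_fl, 100, 10), 10, 10)
  p2$d_opt <- d
  lab2 <- classify_particles(p2, th, 3)
  srf2 <- size_resolved_fraction(p2, lab2)
  for (k in which(srf2$n > 200)) {
    sel <- d >= srf2$d_lo[k] & d < srf2$d_hi[k]
    expected <- mean(prob[sel])
    expect_lt(abs(srf2$fraction[k] - expected),
              3 * sqrt(expected * (1 - expected) / srf2$n[k]) + 1e-9)
  }
})

test_that("asymmetry-factor densities integrate to 1 per size class", {
  p <- toy_particles(rep(1, 3000), 1, 1)
  set.seed(6)
  p$d_opt <- runif(3000, 0.6, 13)
  p$af <- ifelse(p$d_opt < 2.5, rlnorm(3000, log(5), 0.2),
                 rlnorm(3000, log(15), 0.2))
  pdf <- af_pdf(p)
  for (cls in unique(pdf$size_class)) {
    rows <- pdf[pdf$size_class == cls, ]
    if (all(is.na(rows$density))) next
    expect_equal(sum(rows$density * (rows$af_hi - rows$af_lo)), 1)
  }
  # modes land in the expected AF range per class
  small <- pdf[pdf$size_class == "0.5-2.5 um", ]
  big <- pdf[pdf$size_class == "5-14 um", ]
  expect_lt(small$af_lo[which.max(small$density)], 8)
  expect_gt(big$af_lo[which.max(big$density)], 10)
  # single AF value: density 1/width in one bin
  p1 <- toy_particles(rep(1, 10), 1, 1)
  p1$af <- 5.5
  pdf1 <- af_pdf(p1, size_class_edges = c(0.5, 14), af_edges = 0:40)
  expect_equal(sum(pdf1$density > 0), 1L)
  expect_equal(max(pdf1$density), 1)
})

test_that("latitude binning produces ordered box statistics", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  n <- 240
  track <- data.frame(timestamp = t0 + (0:(n - 1)) * 3600,
                      lat = seq(-70, -40, length.out = n), lon = 0)
  series <- data.frame(bin_start = track$timestamp, conc = rep(5, n))
  lb <- latitude_binning(series, track, "conc", width_deg = 4)
  expect_true(all(lb$conc_median == 5))
  expect_equal(lb$lat_hi - lb$lat_lo, rep(4, nrow(lb)))

  # a linear latitudinal ramp yields monotone bin medians
  series$conc <- track$lat * 2 + 100
  lb2 <- latitude_binning(series, track, "conc", width_deg = 4)
  expect_true(all(diff(lb2$conc_median) > 0))
  # half-open convention: a point exactly on a boundary joins the bin above it
  tr1 <- data.frame(timestamp = t0 + 1:2, lat = c(-48, -47.9), lon = 0)
  s1 <- data.frame(bin_start = t0 + 1:2, v = c(1, 2))
  lb3 <- latitude_binning(s1, tr1, "v", width_deg = 4, n_min = 1)
  expect_equal(nrow(lb3), 1L)
  expect_equal(lb3$lat_lo, -48)
  # undersampled bins are flagged
  expect_true(all(lb3$ok))
  lb4 <- latitude_binning(s1, tr1, "v", width_deg = 4, n_min = 5)
  expect_false(any(lb4$ok))
})

test_that("hourly series conserve counts and order fractions", {
  camp <- generate_campaign(small_preset(duration_h = 12, seed = 14))
  th <- compute_ft_stats(camp$ft)
  lab <- classify_particles(camp$particles, th, 3)
  hh <- time_binned_series(camp$particles, lab, flow_lpm = 0.115)
  expect_equal(sum(hh$n_total), sum(camp$particles$d_opt >= 1))
  expect_true(all(hh$n_hyper <= hh$n_fluor))
  expect_true(all(hh$frac_hyper <= hh$frac_fluor, na.rm = TRUE))
  expect_true(all(hh$frac_fluor >= 0 & hh$frac_fluor <= 1, na.rm = TRUE))
  # concentration = count / (flow x duration)
  expect_equal(hh$conc_total, hh$n_total / (0.115 * 60))
})
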
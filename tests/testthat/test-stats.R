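test_that("marine samples pair with the hourly bin containing them", {
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  aerosol <- data.frame(bin_start = t0 + (0:23) * 3600,
                        frac_fluor = seq(0.01, 0.24, by = 0.01))
  marine <- data.frame(timestamp = t0 + c(10.5, 0.2, 23.9) * 3600,
                       variable = "HDNA", value = c(1, 2, 3))
  paired <- pair_marine_to_aerosol(marine, aerosol)
  expect_equal(paired$bin_start, t0 + c(10, 0, 23) * 3600)
  expect_equal(paired$aerosol, c(0.11, 0.01, 0.24))
  expect_equal(attr(paired, "n_dropped"), 0L)

  # samples in hours with no aerosol data are dropped and counted
  aerosol$frac_fluor[11] <- NA
  m2 <- data.frame(timestamp = t0 + c(10.5, 5.5, 30) * 3600,
                   variable = "HDNA", value = 1:3)
  p2 <- pair_marine_to_aerosol(m2, aerosol)
  expect_equal(nrow(p2), 1L)
  expect_equal(attr(p2, "n_dropped"), 2L)

  # pair count equals a brute-force interval join
  set.seed(1)
  m3 <- data.frame(timestamp = t0 + runif(200, -5, 30) * 3600,
                   variable = "x", value = rnorm(200))
  p3 <- pair_marine_to_aerosol(m3, aerosol)
  brute <- sum(vapply(as.numeric(m3$timestamp), function(tm) {
    any(tm >= as.numeric(aerosol$bin_start) &
        tm < as.numeric(aerosol$bin_start) + 3600 &
        !is.na(aerosol$frac_fluor))
  }, logical(1)))
  expect_equal(nrow(p3), brute)
  expect_error(pair_marine_to_aerosol(m3, data.frame(
    bin_start = t0 + c(0, 100), frac_fluor = 1:2)), "hourly")
})

test_that("Pearson correlation matches hand computation and guards degeneracy", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  # five-point textbook set, frozen from the closed-form product-moment sum:
  # x = 1..5, y = (2,4,5,4,5): sum of cross-deviations 6, sum sq dev 10 and 6
  expect_equal(pearson_r(1:5, c(2, 4, 5, 4, 5)), 6 / sqrt(60))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(rep(1, 10), 1:10), "zero variance")
})

test_that("subsampling bootstrap reports spread and honours the seed", {
  x <- 1:40
  y <- 3 * x + 2
  bt <- bootstrap_r(x, y, n_rep = 50, seed = 1)
  expect_equal(bt$r, rep(1, 50))
  expect_equal(bt$sd, 0)
  # independent pairs: mean near 0, central interval covers 0
  set.seed(2)
  x2 <- rnorm(200); y2 <- rnorm(200)
  bt2 <- bootstrap_r(x2, y2, n_rep = 100, seed = 3)
  expect_lt(abs(bt2$mean), 0.3)
  expect_lt(bt2$interval[1], 0)
  expect_gt(bt2$interval[2], 0)
  # bit-identical under the same seed
  bt3 <- bootstrap_r(x2, y2, n_rep = 100, seed = 3)
  expect_identical(bt2, bt3)
  # subsample size is 60% of the pairs, drawn without replacement
  expect_equal(length(bt2$r), 100L)
  expect_error(bootstrap_r(1:10, 1:10), "at least 25")
  # zero-variance draws are discarded and logged
  xz <- c(rep(1, 29), 2)
  yz <- c(rep(5, 29), 6)
  btz <- bootstrap_r(xz, yz, n_rep = 20, seed = 4)
  expect_equal(length(btz$r) + btz$n_discarded, 20L)
  expect_gt(btz$n_discarded, 0L)
})

test_that("permutation p-values are exact at the extremes and reproducible", {
  x <- 1:30
  p <- permutation_p(x, x, n_perm = 999, seed = 1)
  expect_equal(p, 1 / 1000)
  expect_identical(permutation_p(x, x, n_perm = 999, seed = 1), p)
  set.seed(5)
  a <- rnorm(40); b <- rnorm(40)
  p2 <- permutation_p(a, b, n_perm = 999, seed = 2)
  expect_gte(p2, 1 / 1000)
  expect_lte(p2, 1)
  expect_error(permutation_p(1:10, 1:10), "at least 25")
})

test_that("log-binned medians match direct percentile computation", {
  set.seed(6)
  x <- rlnorm(500, 1, 1)
  y <- 2 * log(x) + rnorm(500, 0, 0.1)
  bm <- binned_median_iqr(x, y, n_bins = 10)
  expect_equal(nrow(bm), 10L)
  # brute-force per-bin percentiles on the same edges
  edges <- 10^seq(log10(min(x)), log10(max(x)), length.out = 11)
  for (k in seq_len(10)) {
    sel <- if (k < 10) x >= edges[k] & x < edges[k + 1]
           else x >= edges[k] & x <= edges[k + 1]
    if (!any(sel)) next
    expect_equal(bm$y_median[k], median(y[sel]))
    expect_equal(bm$y_q25[k], unname(quantile(y[sel], 0.25)))
    expect_equal(bm$y_q75[k], unname(quantile(y[sel], 0.75)))
  }
  # monotone relation gives monotone bin medians
  ok <- bm$ok
  expect_true(all(diff(bm$y_median[ok]) > 0))
  # constant y gives constant medians
  bmc <- binned_median_iqr(x, rep(7, 500))
  expect_true(all(bmc$y_median[bmc$n > 0] == 7))
  expect_error(binned_median_iqr(c(-1, 1, 2), 1:3), "positive")
  # sparse bins are flagged
  expect_true(any(!binned_median_iqr(c(rep(1, 50), 1000), rnorm(51))$ok))
})

test_that("median statistics are invariant under record order permutation", {
  set.seed(9)
  x <- rlnorm(300, 0, 1); y <- rnorm(300)
  perm <- sample(300)
  expect_equal(binned_median_iqr(x, y), binned_median_iqr(x[perm], y[perm]))
})

test_that("class-fraction subsampling reproduces known mixtures", {
  th <- toy_thresholds()
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  # 600 five-min bins of pure class B: every replicate is identical
  nb <- 600
  p <- toy_particles(rep(10, nb), th$t3[["B"]] + 1, 10)
  p$timestamp <- t0 + (seq_len(nb) - 1) * 300
  lab <- classify_particles(p, th, 3)
  bins <- class_counts_by_bin(p, lab, 300)
  cb <- class_fraction_bootstrap(bins, "fixed_count", size = 288, n_rep = 25,
                                 seed = 1)
  expect_equal(nrow(cb$fractions), 25L) # replicate count honoured exactly
  expect_true(all(cb$fractions[, "B"] == 1))

  # homogeneous A/B mixture: subsample fractions near the global fraction
  set.seed(2)
  n <- 6000
  is_a <- runif(n) < 0.4
  p2 <- toy_particles(ifelse(is_a, 100, 10), ifelse(is_a, 10, 100), 10)
  p2$timestamp <- t0 + sort(runif(n, 0, nb * 300))
  lab2 <- classify_particles(p2, th, 3)
  bins2 <- class_counts_by_bin(p2, lab2, 300)
  cb2 <- class_fraction_bootstrap(bins2, "fixed_count", size = 288, n_rep = 50,
                                  seed = 3)
  global_a <- mean(is_a)
  expect_lt(abs(cb2$median[["A"]] - global_a), 0.05)
  expect_true(all(abs(rowSums(cb2$fractions) - 1) < 1e-12))

  # 24-h windows with at least 12 h of data
  cb3 <- class_fraction_bootstrap(bins2, "window_24h", n_rep = 10, seed = 4)
  expect_equal(nrow(cb3$fractions), 10L)
  expect_lt(abs(median(cb3$fractions[, "A"]) - global_a), 0.1)
  # no qualifying window -> error
  short <- list(bin_start = bins2$bin_start[1:10], counts = bins2$counts[1:10, ])
  expect_error(class_fraction_bootstrap(short, "window_24h", n_rep = 2, seed = 1),
               "24 h window")
  expect_error(class_fraction_bootstrap(short, "fixed_count", size = 288,
                                        n_rep = 2, seed = 1),
               "not enough")
})
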
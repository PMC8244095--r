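test_that("forced-trigger statistics use sample sd and derive 3/9-sigma thresholds", {
  # zero-variance channel: thresholds collapse onto the mean
  ft0 <- data.frame(fl_a = c(100, 100, 100), fl_b = c(100, 100, 100),
                    fl_c = c(100, 100, 100))
  th0 <- compute_ft_stats(ft0)
  expect_equal(unname(th0$mean), rep(100, 3))
  expect_equal(unname(th0$sd), rep(0, 3))
  expect_equal(th0$t3, th0$mean)
  expect_equal(th0$t9, th0$mean)

  # mean 100, sample sd 10 -> t3 = 130, t9 = 190
  ft1 <- data.frame(fl_a = c(90, 100, 110), fl_b = c(90, 100, 110),
                    fl_c = c(90, 100, 110))
  th1 <- compute_ft_stats(ft1)
  expect_equal(unname(th1$sd), rep(10, 3))
  expect_equal(unname(th1$t3), rep(130, 3))
  expect_equal(unname(th1$t9), rep(190, 3))

  expect_error(compute_ft_stats(data.frame(fl_a = 1, fl_b = 1, fl_c = 1)),
               "at least 2")
  expect_error(compute_ft_stats(data.frame(fl_a = c(1, 2), fl_b = c(1, 2))),
               "fl_c")
})

test_that("forced-trigger statistics recover a known generator within 3 SE", {
  ft <- generate_ft_records(10000, c(50, 40, 30), c(5, 4, 3), seed = 1)
  th <- compute_ft_stats(ft)
  se_mean <- c(5, 4, 3) / sqrt(10000)
  se_sd <- c(5, 4, 3) / sqrt(2 * 10000)
  expect_true(all(abs(th$mean - c(50, 40, 30)) < 3 * se_mean))
  expect_true(all(abs(th$sd - c(5, 4, 3)) < 3 * se_sd))
  expect_equal(th$t3, th$mean + 3 * th$sd)
  expect_equal(th$t9, th$mean + 9 * th$sd)
})

test_that("classification reproduces the exhaustive channel-pattern truth table", {
  th <- toy_thresholds()
  # all 8 on/off patterns at 3-sigma (on = threshold + 1, off = threshold - 1)
  lo <- th$t3 - 1; hi <- th$t3 + 1
  pats <- expand.grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE), C = c(FALSE, TRUE))
  p <- toy_particles(ifelse(pats$A, hi["A"], lo["A"]),
                     ifelse(pats$B, hi["B"], lo["B"]),
                     ifelse(pats$C, hi["C"], lo["C"]))
  lab <- classify_particles(p, th, 3)
  # independent truth-table oracle built from the pattern itself
  oracle <- apply(pats, 1, function(b) {
    s <- paste0(c("A", "B", "C")[as.logical(b)], collapse = "")
    if (s == "") "none" else s
  })
  expect_equal(as.character(lab$abc_class), oracle)
  expect_setequal(setdiff(unique(oracle), "none"),
                  c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  expect_equal(sum(lab$tier == "none"), 1L)
  # exactly at the threshold is NOT an exceedance (strict inequality)
  p_tie <- toy_particles(th$t3[["A"]], 0, 0)
  expect_equal(as.character(classify_particles(p_tie, th, 3)$abc_class), "none")
})

test_that("hyper-fluorescent tier is a subset of the fluorescent tier", {
  th <- toy_thresholds()
  set.seed(42)
  p <- toy_particles(runif(500, 0, 200), runif(500, 0, 200), runif(500, 0, 200))
  l3 <- classify_particles(p, th, 3)
  l9 <- classify_particles(p, th, 9)
  hyper <- l9$tier == "hyper_fluorescent"
  expect_true(all(l3$tier[hyper] == "hyper_fluorescent"))
  expect_true(all(l3$tier[hyper] != "none"))
  # tier none <=> class none at each level
  expect_equal(l3$tier == "none", l3$abc_class == "none")
  expect_equal(l9$tier == "none", l9$abc_class == "none")
  # monotonicity: 9-sigma tier count never exceeds 3-sigma tier count
  expect_lte(sum(l9$tier != "none"), sum(l3$tier != "none"))
})

test_that("B-to-A ratio censors sub-threshold amplitudes at the FT mean", {
  th <- toy_thresholds() # means 50/45/40, t3 80/75/70
  # both channels above threshold and equal -> ratio 1
  expect_equal(compute_rb2a(toy_particles(100, 100, 0), th, 3), 1)
  # channel A below threshold -> its amplitude is replaced by the FT mean
  r <- compute_rb2a(toy_particles(60, 90, 0), th, 3)
  expect_equal(r, 90 / 50)
  # both below -> fully censored floor: ft_mean_b / ft_mean_a
  r2 <- compute_rb2a(toy_particles(10, 10, 0), th, 3)
  expect_equal(r2, 45 / 50)
  # censoring respects the tier's own threshold (9-sigma case)
  r9 <- compute_rb2a(toy_particles(100, 90, 0), th, 9) # both < t9
  expect_equal(r9, 45 / 50)
})

test_that("B-to-A ratio is invariant under common rescaling of both channels", {
  th <- toy_thresholds()
  p <- toy_particles(c(100, 60, 10), c(90, 120, 30), 0)
  r1 <- compute_rb2a(p, th, 3)
  lambda <- 3.7
  ft_scaled <- data.frame(fl_a = lambda * c(40, 50, 60),
                          fl_b = lambda * c(35, 45, 55),
                          fl_c = lambda * c(30, 40, 50))
  th_s <- compute_ft_stats(ft_scaled)
  p_s <- p
  p_s$fl_a <- p$fl_a * lambda
  p_s$fl_b <- p$fl_b * lambda
  r2 <- compute_rb2a(p_s, th_s, 3)
  expect_equal(r1, r2)
})

test_that("class fractions recover known mixture probabilities and sum to 1", {
  th <- toy_thresholds()
  p10 <- toy_particles(rep(0, 10), rep(th$t3[["B"]] + 1, 10), rep(0, 10))
  f <- class_fractions(classify_particles(p10, th, 3))
  expect_equal(unname(f["B"]), 1)
  expect_equal(sum(f), 1)

  # known class probabilities, n = 50000 -> binomial 3-sigma recovery
  probs <- c(A = 0.3, B = 0.25, C = 0.05, AB = 0.2, AC = 0.02, BC = 0.08,
             ABC = 0.1)
  set.seed(7)
  n <- 50000
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)
  on_a <- grepl("A", cls); on_b <- grepl("B", cls); on_c <- grepl("C", cls)
  p <- toy_particles(ifelse(on_a, 100, 10), ifelse(on_b, 100, 10),
                     ifelse(on_c, 100, 10))
  f2 <- class_fractions(classify_particles(p, th, 3))
  tol <- 3 * sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(f2[names(probs)] - probs) < tol))
  expect_equal(sum(f2), 1)

  expect_error(class_fractions(classify_particles(toy_particles(1, 1, 1), th, 3)),
               "no particles")
})

test_that("quality masks remove the expected records and report the fraction", {
  p <- toy_particles(rep(10, 300), 10, 10)
  out <- apply_quality_mask(p, "pass_all")
  expect_identical(nrow(out), 300L)
  expect_equal(attr(out, "mask_report")$removed_fraction, 0)

  # inject a contaminated segment covering a third of the stream
  p$quality_flags <- rep(c(1L, 0L, 0L), each = 100)
  out2 <- apply_quality_mask(p, "flag_clean")
  expect_equal(attr(out2, "mask_report")$removed_fraction, 1 / 3)
  expect_true(all(out2$quality_flags == 0L))

  # custom predicate
  out3 <- apply_quality_mask(p, function(x) x$fl_a > 5)
  expect_equal(nrow(out3), 300L)
  expect_error(apply_quality_mask(p, "no_such_mask"), "unknown")
})
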
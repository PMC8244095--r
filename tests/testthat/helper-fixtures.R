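# Shared fixture builders. All synthetic, built in code at test time.

# A small, fast campaign preset (1 synthetic day unless overridden).
small_preset <- function(...) {
  args <- list(...)
  defaults <- list(name = "pristine", duration_h = 24, n_ft = 2000, seed = 11)
  defaults[names(args)] <- args
  do.call(scenario_preset, defaults)
}

# A threshold set with round numbers (FT mean 50/45/40, sd 10/10/10):
# t3 = 80/75/70, t9 = 140/135/130.
toy_thresholds <- function() {
  ft <- data.frame(
    fl_a = c(40, 50, 60), fl_b = c(35, 45, 55), fl_c = c(30, 40, 50)
  )
  compute_ft_stats(ft)
}

# Particle records with given amplitudes and defaults elsewhere.
toy_particles <- function(fl_a, fl_b, fl_c, d_opt = 2,
                          t0 = as.POSIXct("2020-01-01", tz = "UTC")) {
  n <- max(length(fl_a), length(fl_b), length(fl_c))
  data.frame(
    timestamp = t0 + seq_len(n) * 60,
    d_opt = rep_len(d_opt, n),
    af = rep_len(5, n),
    fl_a = rep_len(fl_a, n), fl_b = rep_len(fl_b, n), fl_c = rep_len(fl_c, n),
    quality_flags = rep_len(0L, n)
  )
}
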
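# pbapr — single-particle fluorescent bioaerosol analysis for ship-based marine campaigns

`pbapr` analyses ultraviolet light-induced fluorescence (UV-LIF)
single-particle data of the kind a wideband integrated bioaerosol sensor
(WIBS) produces during an oceanographic cruise. It is aimed at aerosol and
aerobiology researchers who want to quantify primary biological aerosol
particles (PBAP) in sea spray aerosol (SSA): how many coarse particles
(optical diameter > 1 µm) fluoresce, what fluorescence classes they fall
into, how those quantities vary with wind, latitude and distance to land,
and whether they track the biology of the underlying seawater.

## What it computes

* **Thresholds** — per-channel forced-trigger (background) statistics and
  the derived detection thresholds `t3 = mean + 3·sd`, `t9 = mean + 9·sd`.
* **Classification** — each particle is *fluorescent* if any channel
  amplitude strictly exceeds its 3σ threshold, *hyper-fluorescent* (a
  subset) beyond 9σ, and gets an ABC class (A, B, C, AB, AC, BC, ABC) from
  the combination of "on" channels.
* **R<sub>B2A</sub>** — the channel B-to-A amplitude ratio, an approximate
  humification index (high = humic-like, low = protein-like); amplitudes
  below threshold are censored at the forced-trigger mean.
* **Aggregation** — hourly concentration/fraction series, number size
  distributions dN/dlogD with campaign median and IQR, size-resolved
  fluorescent fractions, asymmetry-factor PDFs per size class, 4° latitude
  bins.
* **Geospatial segregation** — haversine distance to a densified coastline;
  *pristine-marine* means strictly farther than 200 km from any land; a
  threshold scan locates that distance as the plateau of the correlation
  between fluorescent concentration and SSA proxies.
* **Statistics** — marine samples paired to overlapping hourly aerosol
  averages; Pearson R with a 100 × 60% subsampling bootstrap and two-sided
  permutation p-values (≥ 25 simultaneous pairs required); log-binned
  median/IQR curves; class-fraction subsampling (288 five-min bins, or
  24 h windows with ≥ 12 h of data).
* **Synthetic campaigns** — `generate_campaign()` builds complete
  campaigns (particles, forced-trigger records, ship track, coastline,
  proxies, seawater samples) with known ground truth, so the entire
  pipeline is testable without instrument data. The calibrated `pristine`
  preset reproduces the campaign statistics characteristic of remote
  Southern-Ocean air: median fluorescent fraction 1.6% of coarse
  particles, hyper-fluorescent 0.13%, concentrations ≈ 11 and
  0.9 L⁻¹.

## Worked example

```r
library(pbapr)

camp <- generate_campaign(scenario_preset("pristine", duration_h = 168, seed = 1))
th <- compute_ft_stats(camp$ft)
th
#> Fluorescence threshold set (forced-trigger derived)
#>   channel  ft_mean    ft_sd       t3        t9    n
#> 1       A 50.05032 8.006629 74.07021 122.10998 5000
#> 2       B 45.11663 7.036902 66.22733 108.44874 5000
#> 3       C 39.91756 6.080709 58.15969  94.64394 5000

lab <- classify_particles(camp$particles, th, tier_k = 3)
hourly <- time_binned_series(camp$particles, lab,
                             flow_lpm = camp$preset$flow_lpm * camp$preset$duty_cycle)
round(100 * median(hourly$frac_fluor, na.rm = TRUE), 2)
#> [1] 1.8
round(median(hourly$conc_fluor), 1)
#> [1] 11.1
round(class_fractions(lab), 3)
#>     A     B     C    AB    AC    BC   ABC
#> 0.252 0.329 0.083 0.194 0.011 0.035 0.096
```

The first number is the median percentage of coarse particles that
fluoresce in this one-week miniature (the calibration target is 1.6%; a
single week carries sizeable natural variability from the latent biology
and wind processes). The median fluorescent concentration lands near the
11 L⁻¹ calibration point, and the class fractions show the
protein-dominated A/B/AB mixture expected of marine bacteria-like
particles.

The numbered scripts in `analysis/` run the full-scale workflow
(simulate → classify → aggregate → segregate/scan → correlate → report)
and write their tables under `results/`. The methods vignette
(`vignettes/campaign-analysis.Rmd`) documents the models, calibration and
design choices.

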
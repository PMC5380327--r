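# smfstools

Simulation and analysis of AFM single-molecule force spectroscopy (SMFS)
pulling experiments on tandem polyproteins.

When an engineered chain of repeated protein domains is stretched between
an AFM tip and a surface at constant speed, each domain ruptures in turn
and the force-extension record shows a characteristic sawtooth. Three
quantities summarise such experiments: the unfolding force `F_u` of each
rupture peak (peak height above the baseline), the contour-length
increment `ΔL_c` released per unfolding, and the persistence length `L_p`
of the stretched chain, the last two obtained by fitting the worm-like
chain (WLC) model to each rising edge,

    F(x) = (k_B T / L_p) [ 1/4 (1 − x/L_c)^−2 − 1/4 + x/L_c ].

Repeating the experiment at several pulling speeds probes the unfolding
kinetics: under the Bell model, `k_u(F) = k_u0 · exp(F x_u / k_B T)`, the
most probable rupture force grows linearly with the log of the loading
rate `r = k_c v`,

    F*(r) = (k_B T / x_u) · ln( r x_u / (k_B T k_u0) ),

so a linear fit of force against `ln r` yields the distance to the
transition state `x_u` (slope) and the zero-force unfolding rate `k_u0`
(intercept). The package implements this whole chain — thermal-tune
cantilever calibration from noise spectra, baseline/peak detection,
per-peak WLC fits, per-curve force statistics (`cv = σ/μ`), and the
Bell-Evans fit — together with a Monte Carlo simulator of the pulling
experiment itself (WLC tether in series with a Hookean cantilever,
Bell-model rupture, pickup/adhesion/noise artifacts) that produces curves
with ground-truth event logs for end-to-end validation. The built-in
presets model octameric constructs of calcium-dependent bacterial adhesin
extender domains with GFP and titin I27 as reference fingerprints.

The methods vignette (`vignettes/force-spectroscopy.Rmd`) documents the
models, defaults and numerical choices in detail.

## Worked example

Simulate one pull of the eight-repeat construct at 1 µm/s, analyse the
curve, and fit the loading-rate dependence from idealised rupture
sampling at the four experimental speeds:

```r
library(smfstools)

construct <- construct_preset("RII8")
protocol  <- pulling_protocol(speed = 1000, cantilever_k = 0.15)  # nm/s, N/m
sim <- simulate_pull(construct, protocol, seed = 7)
tab <- analyze_curve(sim$curve)
tab[, c("peak_idx", "extension_nm", "Fu_pN", "Lc_nm", "Lp_nm", "dLc_nm", "label")]
#>    peak_idx extension_nm Fu_pN  Lc_nm  Lp_nm dLc_nm    label
#> 1         1        2.989 155.4     NA     NA     NA adhesion
#> 2         2       33.525 253.8  42.46 0.1198     NA      RII
#> 3         3       62.521 247.3  71.75 0.2801  29.29      RII
#> 4         4       91.520 220.5 104.79 0.3054  33.04      RII
#> ...
#> 10       10      279.046 517.2 303.63 0.3102  33.91   detach
```

The surface bump at 3 nm is labelled an adhesion artifact, the eight
repeat unfoldings appear as `RII` peaks roughly 30 nm apart with fitted
contour increments near the generative 33.2 nm and persistence lengths
near the generative 0.3 nm, and the final 517 pN rupture is the tether
detachment.

```r
b <- bell_params(k_u0 = 0.003, x_u = 0.2)      # 1/s, nm
set.seed(7)
rows <- do.call(rbind, lapply(c(50, 200, 1000, 4880), function(v) {
  f <- simulate_constant_loading(b, 150 * v, 2000)   # r = k_c v in pN/s
  data.frame(speed = v, mode_pN = force_summary(f, "mode")$force)
}))
fit_bell_evans(speed_series(rows$speed, 0.15, rows$mode_pN))
#> Bell-Evans fit (n = 4): x_u = 0.196 +/- 0.0015 nm, k_u0 = 0.00448 1/s (x/ 1.1)
```

The fit recovers the generative `x_u = 0.2 nm` within 2 % and `k_u0 =
0.003 1/s` within a factor of 1.5. Cantilever calibration round-trips the
same way:

```r
sp  <- simulate_thermal_spectrum(target_k = 0.15, noise_level = 0.05, seed = 7)
calibrate_spectrum(sp)$spring_constant
#> [1] 0.1490      # N/m, vs the 0.15 target

contour_per_aa(33.2, 4.8, 104, digits = 2)
#> [1] 0.37        # nm per amino acid for the 104-residue repeat
```

## Command line

A thin CLI over the same functions supports reproducible pipelines
(`inst/cli/smfs.R`):

```sh
Rscript inst/cli/smfs.R simulate  --config run.json --out curves/
Rscript inst/cli/smfs.R calibrate --spectrum sp1.tsv --spectrum sp2.tsv
Rscript inst/cli/smfs.R analyze   --in curves/ --out events.csv --min-peaks 5
Rscript inst/cli/smfs.R kinetics  --table events.csv --out bell.json
Rscript inst/cli/smfs.R report    --table events.csv
```

Curves are TSV with `#key=value` headers (piezo-coordinate and
nanonewton columns are converted on read); configuration is strict JSON
with a mandatory seed; identical config and seed reproduce the output
tree byte for byte.

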
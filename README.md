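# lspheno

Land-surface phenology extraction and hydrothermal attribution for
gridded 8-day composite time series — with a synthetic-data generator
carrying exact ground truth, so the entire chain is testable end-to-end
without any satellite downloads.

The package is aimed at ecologists and remote-sensing analysts who work
with MODIS-style vegetation-index records and want a tested, scriptable
implementation of a widely used analysis chain:

1. **Index computation and reconstruction** — EVI and MSAVI from
   reflectance bands, snow-contamination removal, Savitzky–Golay
   smoothing, growing-season (May–October) aggregation.
2. **Dynamic-threshold phenology** — per pixel and year, the start of
   season (SOS) is the last upward crossing of
   `r(t) = (VI − VI_min)/(VI_max − VI_min) = θ` before the seasonal peak
   of MSAVI, the end of season (EOS) the first downward crossing after
   the peak of EVI, and LOS = EOS − SOS.
3. **Trend mapping** — Theil–Sen slope
   `Slope = Med((X_j − X_i)/(j − i))` with the Mann–Kendall test
   (`Var(S) = K(K−1)(2K+5)/18`, continuity-corrected `Z`), stratified
   into five significance classes at the 1.64/1.96 normal critical
   values, plus the SOS/EOS contribution decomposition of LOS change.
4. **Geodetector attribution** — quintile discretization of drivers, the
   factor detector `Q = 1 − Σ_U D_U σ²_U / (D σ²)`, permutation (or
   noncentral-F) significance, and pairwise interaction detection.
5. **Partial-correlation response analysis** —
   `R_VL|M = (R_VL − R_VM R_LM)/√((1−R²_VM)(1−R²_LM))` with the
   t-transform on `n − 3` df, and response profiles binned by temperature
   or moisture level.
6. **Persistence** — rescaled-range (R/S) Hurst exponents with 3σ
   pre-cleaning, and the 3×3 future-trend classification combining the
   EOS slope (±0.5 d/a) with persistence bands (H < 0.4 reversal,
   H > 0.6 continuation).

Hydrothermal layers: growing-season land-surface temperature (GLST),
effective moisture `GEM = (GPRE − GET)/GPRE`, and shortwave albedo
`0.160 B1 + 0.291 B2 + 0.243 B3 + 0.116 B4 + 0.112 B5 + 0.081 B7 −
0.0015` (GSA).

## Worked example

```r
library(lspheno)

# a 20x20, 20-year scene: green-up near DOY 150, senescence near 280,
# EOS delayed +0.2205 d/a and SOS advanced -0.1102 d/a, light noise
cfg <- sim_config(grid_shape = c(20, 20), seed = 1,
                  noise = list(vi_sd = 0.02, snow_prob = 0.1))
scene <- simulate_reflectance_cube(cfg)

evi   <- savitzky_golay_smooth(remove_snow_contamination(compute_evi(scene$bands)))
msavi <- savitzky_golay_smooth(remove_snow_contamination(compute_msavi(scene$bands)))
sos <- extract_sos(msavi)   # SOS from MSAVI
eos <- extract_eos(evi)     # EOS from EVI
los <- compute_los(sos, eos)
cat(sprintf("mean SOS %.2f, EOS %.2f, LOS %.2f days\n",
            mean(sos$values, na.rm = TRUE), mean(eos$values, na.rm = TRUE),
            mean(los$values, na.rm = TRUE)))
#> mean SOS 146.82, EOS 284.39, LOS 137.57 days

# regional EOS trend: recovered rate, Mann-Kendall class
rate_eos <- theil_sen_slope(rowMeans(stack_matrix(eos)), eos$years)
rate_sos <- theil_sen_slope(rowMeans(stack_matrix(sos)), sos$years)
mk <- mann_kendall(rowMeans(stack_matrix(eos)))
cat(sprintf("EOS rate %+.4f d/a (Z = %.2f, %s); injected %+.4f\n",
            rate_eos, mk$z,
            as.character(classify_significance(rate_eos, mk$z)),
            cfg$phenology$eos_trend))
#> EOS rate +0.2256 d/a (Z = 6.07, significant increase); injected +0.2205

contribution_shares(rate_sos, rate_eos)
#> share_sos share_eos
#>  30.19036  69.80964

# Hurst recovery on fractional Gaussian noise with known H = 0.8
hurst_exponent(simulate_fgn(2048, 0.8, seed = 2))
#> <hurst_result> H = 0.762 (r2 = 0.998, 4 scales, n = 2048)
```

The mean dates sit ~2 days from the configured truth (the extraction
tolerance under noise); the EOS delay is recovered and flagged
significant, and the delayed EOS accounts for about two thirds of the
LOS lengthening.

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each a thin
script over the package functions, writing tables under
`results/analysis/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the synthetic scene (cubes to `scratch/`, ground truth to `results/`) |
| `02_phenology.R` | indices → smoothing → SOS/EOS/LOS; accuracy vs truth; area shares |
| `03_trends.R` | trend maps, five-class shares, regional rates, LOS contribution split |
| `04_geodetector.R` | known-Q validation; factor + interaction detectors per 5-year window |
| `05_association.R` | partial correlations (n = 20 years) and binned EOS response profiles |
| `06_hurst.R` | fGn calibration of the R/S estimator; per-pixel H and future-trend shares |

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript "$s"; done`

`run_pipeline(pipeline_config(...))` executes the same chain in one call
with stage toggles, pinned CSV formatting and a YAML run manifest.

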
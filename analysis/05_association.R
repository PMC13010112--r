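#!/usr/bin/env Rscript
# Partial-correlation response analysis: interannual regional-mean
# correlations between phenology and the hydrothermal layers (n = 20
# years), and pooled pixel-year profiles binned by temperature and
# moisture level.

source(file.path("analysis", "00_settings.R"))

cfg <- scene_config()
ref <- simulate_reflectance_cube(cfg)
clim <- simulate_climate_cubes(cfg)
evi <- savitzky_golay_smooth(
  remove_snow_contamination(compute_evi(ref$bands)))
msavi <- savitzky_golay_smooth(
  remove_snow_contamination(compute_msavi(ref$bands)))
sos <- extract_sos(msavi)
eos <- extract_eos(evi)
los <- compute_los(sos, eos)

glst <- growing_season_aggregate(clim$lst)
gpre <- growing_season_aggregate(clim$pre, statistic = "sum")
get_ <- growing_season_aggregate(clim$et, statistic = "sum")
gem <- compute_gem(gpre, get_)

mean_series <- function(ys) rowMeans(stack_matrix(ys), na.rm = TRUE)
targets <- list(SOS = sos, EOS = eos, LOS = los)
rows <- lapply(names(targets), function(nm) {
  v <- mean_series(targets[[nm]])
  with_glst <- partial_corr_series(v, mean_series(glst), mean_series(gem))
  with_gem <- partial_corr_series(v, mean_series(gem), mean_series(glst))
  data.frame(dependent = nm,
             independent = c("GLST", "GEM"),
             r_partial = c(with_glst$r_partial, with_gem$r_partial),
             n = c(with_glst$n, with_gem$n),
             p = c(with_glst$p_value, with_gem$p_value))
})
headline <- do.call(rbind, rows)
save_table(headline, "05_partial_correlations.csv")

profiles <- binned_partial_profiles(
  c(stack_matrix(eos)), c(stack_matrix(glst)), c(stack_matrix(gem)),
  bin_by = "glst")
save_table(profiles, "05_eos_profiles_by_glst.csv")

eg <- headline[headline$dependent == "EOS" &
                 headline$independent == "GLST", ]
message(sprintf(
  "EOS ~ GLST | GEM: r = %+.2f (n = %d, p = %.3f)%s.",
  eg$r_partial, eg$n, eg$p, ifelse(eg$p < 0.05, " *", "")))
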
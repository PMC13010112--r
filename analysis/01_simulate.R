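#!/usr/bin/env Rscript
# Generate the synthetic scene: seven reflectance bands whose EVI/MSAVI
# cycles carry known SOS/EOS crossings, plus LST / precipitation /
# evapotranspiration cubes with injected trends. Cubes go to scratch/
# (they are bulky and fully reproducible); the ground-truth summary goes
# to results/.

source(file.path("analysis", "00_settings.R"))

cfg <- scene_config()
ref <- simulate_reflectance_cube(cfg)
clim <- simulate_climate_cubes(cfg)

dir.create(SCRATCH_DIR, recursive = TRUE, showWarnings = FALSE)
for (b in names(ref$bands)) {
  write_raster_cube(ref$bands[[b]], file.path(SCRATCH_DIR, b))
}
for (v in c("lst", "pre", "et")) {
  write_raster_cube(clim[[v]], file.path(SCRATCH_DIR, v))
}

tr <- ref$truth
truth_summary <- data.frame(
  quantity = c("mean true SOS (year 1)", "mean true EOS (year 1)",
               "mean true LOS (year 1)", "injected SOS trend (d/a)",
               "injected EOS trend (d/a)", "injected LST trend (K/a)"),
  value = c(mean(tr$true_sos[1, , ]), mean(tr$true_eos[1, , ]),
            mean(tr$true_los[1, , ]), cfg$phenology$sos_trend,
            cfg$phenology$eos_trend, cfg$trend$lst))
save_table(truth_summary, "01_ground_truth.csv")

message(sprintf(
  "Scene: %d x %d pixels, %d years. True SOS spans %.0f-%.0f DOY, EOS %.0f-%.0f.",
  cfg$grid_shape[1], cfg$grid_shape[2], cfg$years,
  min(tr$true_sos), max(tr$true_sos), min(tr$true_eos), max(tr$true_eos)))
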
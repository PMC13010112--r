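#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: the synthetic-data
#' generator settings plus every stage parameter. Fully serialisable to
#' YAML; the effective config is written next to a run's outputs.
#'
#' @param sim a [sim_config()].
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("phenology", "trend", "geodetector", "association", "hurst")`;
#'   earlier stages a requested stage depends on always run.
#' @param theta dynamic-threshold fraction (default 0.2).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters (default 7, 2).
#' @param snow_winter_doy,snow_percentile snow-removal parameters.
#' @param n_strata geodetector strata per driver.
#' @param hurst_scales scales for the per-pixel R/S fit on yearly series.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = tempfile("lspheno_run_"),
                            stages = c("phenology", "trend", "geodetector",
                                       "association", "hurst"),
                            theta = 0.2, sg_window = 7L, sg_polyorder = 2L,
                            snow_winter_doy = c(60, 305),
                            snow_percentile = 50,
                            n_strata = 5L,
                            hurst_scales = 4:10) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(sim = sim, out_dir = out_dir, stages = stages,
                 theta = theta, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 snow_winter_doy = snow_winter_doy,
                 snow_percentile = snow_percentile,
                 n_strata = as.integer(n_strata),
                 hurst_scales = as.integer(hurst_scales)),
            class = "pipeline_config")
}

# pinned CSV writer: fixed numeric formatting makes runs byte-stable
write_table <- function(df, path, config_hash, digits = 8L) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_,
           trimws(formatC(x, digits = digits, format = "g")))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the analysis chain end-to-end on generated data: reflectance
#' and climate simulation, vegetation indices with snow removal and
#' Savitzky-Golay smoothing, dynamic-threshold phenology (SOS from MSAVI,
#' EOS from EVI), growing-season hydrothermal layers (GLST, GEM, GSA),
#' Theil-Sen / Mann-Kendall trend maps, the geodetector suite, partial
#' correlations, and Hurst-based future-trend classification. Tables are
#' written as CSV (with the run's config hash in a header line) together
#' with a YAML run manifest.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (invisible elements: `phenology`,
#'   `hydro`, `trend`, `geodetector`, `association`, `hurst`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- rapply(unclass(config), identity, how = "list")
  # hash the scientific configuration only, not where it is written
  hash <- rlang::hash(cfg_plain[setdiff(names(cfg_plain), "out_dir")])
  t0 <- Sys.time()
  res <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate + indices + phenology (always needed) ------------------
  ref <- stage("simulate", simulate_reflectance_cube(config$sim))
  clim <- stage("simulate", simulate_climate_cubes(config$sim))

  ph <- stage("phenology", {
    evi <- compute_evi(ref$bands)
    msavi <- compute_msavi(ref$bands)
    evi <- remove_snow_contamination(evi, config$snow_winter_doy,
                                     config$snow_percentile)
    msavi <- remove_snow_contamination(msavi, config$snow_winter_doy,
                                       config$snow_percentile)
    evi_s <- savitzky_golay_smooth(evi, config$sg_window,
                                   config$sg_polyorder)
    msavi_s <- savitzky_golay_smooth(msavi, config$sg_window,
                                     config$sg_polyorder)
    sos <- extract_sos(msavi_s, theta = config$theta)
    eos <- extract_eos(evi_s, theta = config$theta)
    list(evi = evi_s, msavi = msavi_s, sos = sos, eos = eos,
         los = compute_los(sos, eos))
  })
  res$phenology <- ph

  hyd <- stage("hydro", {
    glst <- growing_season_aggregate(clim$lst)
    gpre <- growing_season_aggregate(clim$pre, statistic = "sum")
    get_ <- growing_season_aggregate(clim$et, statistic = "sum")
    gsa <- growing_season_mean(compute_shortwave_albedo(ref$bands))
    list(glst = glst, gpre = gpre, get = get_, gsa = gsa,
         gem = compute_gem(gpre, get_))
  })
  res$hydro <- hyd

  mean_series <- function(ys) rowMeans(stack_matrix(ys), na.rm = TRUE)

  if ("trend" %in% config$stages) {
    res$trend <- stage("trend", {
      maps <- list(sos = trend_map(ph$sos), eos = trend_map(ph$eos),
                   los = trend_map(ph$los), glst = trend_map(hyd$glst),
                   gem = trend_map(hyd$gem), gsa = trend_map(hyd$gsa))
      rate_sos <- theil_sen_slope(mean_series(ph$sos), ph$sos$years)
      rate_eos <- theil_sen_slope(mean_series(ph$eos), ph$eos$years)
      shares <- contribution_shares(rate_sos, rate_eos)
      regional <- data.frame(
        variable = names(maps),
        mean_slope = vapply(maps, function(m)
          mean(m$slope, na.rm = TRUE), numeric(1L)))
      write_table(regional, file.path(config$out_dir, "trend_regional.csv"),
                  hash)
      write_table(data.frame(margin = c("sos", "eos"),
                             rate = c(rate_sos, rate_eos),
                             share_pct = shares),
                  file.path(config$out_dir, "contribution_shares.csv"),
                  hash)
      list(maps = maps, rate_sos = rate_sos, rate_eos = rate_eos,
           shares = shares)
    })
  }

  if ("geodetector" %in% config$stages) {
    res$geodetector <- stage("geodetector", {
      drivers <- list(GEM = hyd$gem, GLST = hyd$glst, GSA = hyd$gsa,
                      GPRE = hyd$gpre, GET = hyd$get)
      det <- run_detector_suite(ph$eos, drivers,
                                n_strata = config$n_strata)
      write_table(det$factors,
                  file.path(config$out_dir, "geodetector_factors.csv"),
                  hash)
      write_table(det$interactions,
                  file.path(config$out_dir, "geodetector_interactions.csv"),
                  hash)
      det
    })
  }

  if ("association" %in% config$stages) {
    res$association <- stage("association", {
      v <- mean_series(ph$eos)
      l <- mean_series(hyd$glst)
      m <- mean_series(hyd$gem)
      headline <- partial_corr_series(v, l, m)
      profiles <- binned_partial_profiles(
        c(stack_matrix(ph$eos)), c(stack_matrix(hyd$glst)),
        c(stack_matrix(hyd$gem)))
      write_table(profiles,
                  file.path(config$out_dir, "partial_corr_profiles.csv"),
                  hash)
      list(headline = headline, profiles = profiles)
    })
  }

  if ("hurst" %in% config$stages) {
    res$hurst <- stage("hurst", {
      m <- stack_matrix(ph$eos)
      slope <- res$trend$maps$eos$slope
      if (is.null(slope)) {
        slope <- matrix(apply(m, 2L, theil_sen_slope, t = ph$eos$years),
                        dim(ph$eos$values)[2L], dim(ph$eos$values)[3L])
      }
      h <- suppressWarnings(apply(m, 2L, function(x) {
        x <- x[is.finite(x)]
        if (length(x) < 8L) return(NA_real_)
        tryCatch(hurst_exponent(x, scales = config$hurst_scales)$h,
                 error = function(e) NA_real_)
      }))
      h_map <- matrix(h, dim(ph$eos$values)[2L], dim(ph$eos$values)[3L])
      cls <- classify_future_trend(c(slope), c(h_map))
      cls_map <- matrix(as.character(cls), nrow(h_map), ncol(h_map))
      shares <- hurst_area_shares(h_map, cls_map)
      write_table(shares$h_intervals,
                  file.path(config$out_dir, "hurst_intervals.csv"), hash)
      write_table(shares$classes,
                  file.path(config$out_dir, "future_trend_classes.csv"),
                  hash)
      list(h_map = h_map, class_map = cls_map, shares = shares)
    })
  }

  manifest <- list(
    stages = config$stages,
    seed = config$sim$seed,
    config_hash = hash,
    package_version = as.character(utils::packageVersion("lspheno")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(cfg_plain, file.path(config$out_dir, "config.yaml"))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
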
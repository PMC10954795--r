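# End-to-end orchestration: synthesize -> preprocess -> plots/predictors ->
# fit -> validate -> classify -> render, from a single seeded config.

#' Default pipeline configuration
#'
#' All thresholds default to the study constants: 54.3-ha paddock with the
#' published cover shares, 660-731 m elevation at 10-m cells, 3-minute fix
#' schedule over the seven sampling periods (animal numbers and missed-fix
#' rates taken from the bundled period table), 194 50-m-diameter plots kept
#' at least 13 m from the fence, 75/25 development/validation split, |r| >
#' 0.60 collinearity screen, 20 Spearman classes, 1,000 bootstrap
#' replicates at the 90% level, and the 25 m / 75% association rule.
#'
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @return nested config list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    landscape = list(target_area_ha = 54.3,
                     cover_fractions = c(wood = 0.558, shrub = 0.260,
                                         grasslands = 0.069, rock = 0.100,
                                         feedwater = 0.013),
                     elev_range = c(660, 731), cell_size = 10),
    simulation = list(
      true_beta = c(feedwater = 1.5, elevation = -0.02, distfeed = -0.0015,
                    distfence = 0.005, TPI = -0.5),
      fix_interval = 180, ehpe_mean = 1100, ehpe_sd = 800,
      out_of_fence_prob = 0.002, autocorrelation = 0,
      periods = NULL),  # NULL = the bundled seven sampling periods
    cleaning = list(speed_max = 3, turn_max = 170, ehpe_max_cm = NULL),
    association = list(dist_threshold = 25, frac_threshold = 0.75),
    split = list(dev_fraction = 0.75),
    plots = list(n_target = 194, radius = 25, min_fence_dist = 13,
                 min_spacing = 0),
    model = list(preset = "final_full", collinearity_threshold = 0.60,
                 bootstrap_B = 1000L, ci_level = 0.90),
    validation = list(n_classes = 20L),
    map = list(resolution = 25)
  )
}

# the seven sampling-period windows with animal counts and missed-fix rates
pipeline_periods <- function(cfg_sim) {
  if (!is.null(cfg_sim$periods)) return(cfg_sim$periods)
  p <- reference_table("periods")
  data.frame(period = seq_len(nrow(p)), season = p$season,
             start = as.POSIXct(p$start, tz = "UTC"),
             end = as.POSIXct(p$end, tz = "UTC") + 86400,
             n_animals = p$n_animals,
             missed_fix_prob = pmin(pmax(1 - p$fix_rate_mean / 100, 0), 1))
}

#' Run the full synthetic RSPF pipeline
#'
#' Executes every stage in order on a synthetic landscape and writes the
#' artifacts (grids, GeoJSON layers, fix and table CSVs, validation JSON,
#' prediction rasters) plus a manifest of md5 hashes to `out_dir`.
#' Re-running with the same config reproduces the hashes.
#'
#' @param config list from [default_run_config()] (possibly modified), or a
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results: landscape,
#'   fixes, table, fit, bootstrap, validation, classes, emmeans, map,
#'   manifest path.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("rspf_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  ## stage 1: landscape
  lc <- cfg$landscape
  land <- generate_landscape(lc$target_area_ha,
                             cover_fractions = unlist(lc$cover_fractions),
                             elev_range = lc$elev_range,
                             cell_size = lc$cell_size, seed = seed)
  terrain <- compute_terrain(land$dem, land$cell_size)
  gp <- function(f) file.path(out_dir, f)
  write_ascii_grid(land$dem, gp("dem.asc"), land$xmin, land$ymin,
                   land$cell_size)
  covm <- land$cover
  write_ascii_grid(covm, gp("cover.asc"), land$xmin, land$ymin,
                   land$cell_size)
  jsonlite::write_json(list(classes = cover_classes(),
                            codes = seq_along(cover_classes())),
                       gp("cover_legend.json"), auto_unbox = TRUE)
  write_geojson(gp("fence.geojson"), polygon = land$fence)
  write_geojson(gp("water_point.geojson"),
                points = data.frame(x = land$water_point["x"],
                                    y = land$water_point["y"],
                                    name = "water"))

  ## stage 2: tracks over the sampling periods
  sm <- cfg$simulation
  periods <- pipeline_periods(sm)
  fixes_l <- list(); windows_l <- list()
  for (i in seq_len(nrow(periods))) {
    pc <- sim_config(true_beta = sm$true_beta,
                     n_animals = periods$n_animals[i],
                     start = periods$start[i], end = periods$end[i],
                     fix_interval = sm$fix_interval,
                     ehpe_mean = sm$ehpe_mean, ehpe_sd = sm$ehpe_sd,
                     missed_fix_prob = periods$missed_fix_prob[i],
                     out_of_fence_prob = sm$out_of_fence_prob,
                     autocorrelation = sm$autocorrelation,
                     seed = seed + 1000L * i)
    fx <- simulate_tracks(land, pc)
    if (nrow(fx) == 0L) next
    fx$animal_id <- sprintf("p%d_%s", periods$period[i], fx$animal_id)
    fx$period <- periods$period[i]
    fx$season <- periods$season[i]
    fixes_l[[i]] <- fx
    windows_l[[i]] <- data.frame(period = periods$period[i],
                                 animal_id = unique(fx$animal_id),
                                 start = periods$start[i],
                                 end = periods$end[i])
  }
  fixes <- do.call(rbind, fixes_l)
  windows <- do.call(rbind, windows_l)
  write_fixes_csv(fixes, gp("fixes_raw.csv"))

  ## stage 3: cleaning, fix rate, association
  cl <- cfg$cleaning
  keep_cols <- c("animal_id", "timestamp", "x", "y", "ehpe_cm")
  cleaned <- clean_fixes(fixes[, c(keep_cols, "period", "season")],
                         land$fence, deployment_windows = windows,
                         speed_max = cl$speed_max, turn_max = cl$turn_max,
                         ehpe_max_cm = cl$ehpe_max_cm)
  write_fixes_csv(cleaned, gp("fixes_clean.csv"))
  jsonlite::write_json(as.list(attr(cleaned, "removal_log")),
                       gp("removal_log.json"), auto_unbox = TRUE)
  frate <- compute_fix_rate(cleaned, sm$fix_interval, windows)
  utils::write.csv(frate, gp("fix_rate.csv"), row.names = FALSE)
  assoc_l <- lapply(split(cleaned, cleaned$period), function(d) {
    if (length(unique(d$animal_id)) < 2L) return(NULL)
    assess_association(d, dist_threshold = cfg$association$dist_threshold,
                       frac_threshold = cfg$association$frac_threshold,
                       match_tolerance = sm$fix_interval / 2)
  })
  assoc <- do.call(rbind, assoc_l)
  if (!is.null(assoc)) utils::write.csv(assoc, gp("association.csv"),
                                        row.names = FALSE)

  ## stage 4: split, plots, predictors, counts
  sp <- split_dev_val(cleaned, cfg$split$dev_fraction, seed = seed + 1L)
  plots <- sample_plots(land$fence, cfg$plots$n_target,
                        radius = cfg$plots$radius,
                        min_fence_dist = cfg$plots$min_fence_dist,
                        min_spacing = cfg$plots$min_spacing,
                        seed = seed + 2L)
  write_geojson(gp("plots.geojson"), points = plots[, c("x", "y", "plot_id",
                                                        "radius")])
  table <- extract_predictors(plots, land, terrain)
  table$dev_count <- count_fixes_in_plots(sp$dev, plots)
  table$val_count <- count_fixes_in_plots(sp$val, plots)
  utils::write.csv(table, gp("predictor_table.csv"), row.names = FALSE)

  ## stage 5: collinearity screen and model fit
  numeric_preds <- c("elevation", "slope", "TRI", "TPI", "wood", "shrub",
                     "grasslands", "feedwater", "rock", "distfence",
                     "distfeed")
  screen <- screen_collinearity(table, numeric_preds,
                                cfg$model$collinearity_threshold)
  utils::write.csv(screen$flagged, gp("collinearity_flags.csv"),
                   row.names = FALSE)
  if (identical(cfg$model$preset, "general")) {
    cands <- enumerate_candidates(numeric_preds,
                                  collinear_pairs = screen$flagged,
                                  max_base = 5L)
    fits <- lapply(cands, fit_nb_rspf, table = table)
    board <- rank_by_aic(fits, k = 10L)
    utils::write.csv(board, gp("aic_leaderboard.csv"), row.names = FALSE)
    terms <- cands[[board$id[1L]]]
  } else {
    terms <- rspf_preset(cfg$model$preset)
  }
  fit <- fit_nb_rspf(terms, table)
  boot <- bootstrap_cis(fit, table, B = cfg$model$bootstrap_B,
                        level = cfg$model$ci_level, seed = seed + 3L)
  coefs <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                      se = unname(fit$se), lower90 = boot$lower,
                      upper90 = boot$upper, p = unname(fit$wald_p))
  utils::write.csv(coefs, gp("fit_coefficients.csv"), row.names = FALSE)

  ## stage 6: validation, classification, marginal means
  pred <- predict_use(fit, table)
  val <- spearman_validation(pred, table$val_count,
                             n_classes = cfg$validation$n_classes,
                             plot_ids = table$plot_id)
  jsonlite::write_json(list(rs = val$rs, class_table = val$class_table),
                       gp("validation.json"), auto_unbox = TRUE, digits = NA)
  classes <- classify_quartiles(pred, table$plot_id)
  utils::write.csv(classes, gp("use_classes.csv"), row.names = FALSE)
  emm <- class_emmeans(classes, table)
  utils::write.csv(emm, gp("class_emmeans.csv"), row.names = FALSE)

  ## stage 7: prediction raster
  map <- render_use_map(fit, land, resolution = cfg$map$resolution,
                        terrain = terrain)
  write_ascii_grid(map$prob, gp("use_probability.asc"), map$xmin, map$ymin,
                   map$cell_size)
  write_ascii_grid(map$class, gp("use_class.asc"), map$xmin, map$ymin,
                   map$cell_size)

  ## manifest
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config = cfg, seed = seed,
                   files = as.list(stats::setNames(unname(hashes), files)))
  jsonlite::write_json(manifest, gp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  invisible(list(landscape = land, terrain = terrain, fixes = fixes,
                 cleaned = cleaned, split = sp, plots = plots,
                 table = table, screen = screen, fit = fit,
                 bootstrap = boot, validation = val, classes = classes,
                 emmeans = emm, map = map, out_dir = out_dir,
                 manifest = gp("manifest.json")))
}

#' Refit the chosen model per season
#'
#' Subsets cleaned fixes by season label, re-splits each season into
#' development and validation sets, recounts fixes per plot, refits the
#' preset model (summer uses the `final_summer` preset unless overridden),
#' and validates each seasonal fit.
#'
#' @param cleaned cleaned fixes with a `season` column.
#' @param plots plot frame.
#' @param table plot predictor table (counts are recomputed per season).
#' @param dev_fraction development split share (default 0.75).
#' @param seed integer seed.
#' @param preset_by_season named overrides, e.g. c(summer =
#'   "final_summer"); seasons not named use `default_preset`.
#' @param default_preset preset for unlisted seasons.
#' @param min_fixes warn when a season has fewer fixes (still fitted).
#' @return list with `fits` (per season), `comparison` (data.frame season,
#'   n_fixes, rs, preset) and `coefficients` (long data.frame).
#' @export
seasonal_refit <- function(cleaned, plots, table, dev_fraction = 0.75,
                           seed = 1L,
                           preset_by_season = c(summer = "final_summer"),
                           default_preset = "final_full",
                           min_fixes = 500L) {
  if (is.null(cleaned$season)) stop("cleaned fixes need a 'season' column")
  seasons <- unique(cleaned$season)
  if (length(seasons) < 2L) stop("need at least 2 seasons")
  fits <- list(); comp <- list(); coefs <- list()
  for (s in seasons) {
    d <- cleaned[cleaned$season == s, , drop = FALSE]
    if (nrow(d) < min_fixes)
      warning("season '", s, "' has only ", nrow(d), " fixes")
    spl <- split_dev_val(d, dev_fraction, seed = seed + match(s, seasons))
    tb <- table
    tb$dev_count <- count_fixes_in_plots(spl$dev, plots)
    tb$val_count <- count_fixes_in_plots(spl$val, plots)
    preset <- if (s %in% names(preset_by_season)) preset_by_season[[s]]
              else default_preset
    fit <- fit_nb_rspf(rspf_preset(preset), tb)
    rs <- if (isTRUE(fit$converged))
      spearman_validation(predict_use(fit, tb), tb$val_count,
                          plot_ids = tb$plot_id)$rs
    else NA_real_
    fits[[s]] <- fit
    comp[[s]] <- data.frame(season = s, n_fixes = nrow(d), preset = preset,
                            rs = rs)
    if (isTRUE(fit$converged))
      coefs[[s]] <- data.frame(season = s, term = names(fit$beta),
                               estimate = unname(fit$beta),
                               se = unname(fit$se))
  }
  list(fits = fits, comparison = do.call(rbind, c(comp, make.row.names = FALSE)),
       coefficients = do.call(rbind, c(coefs, make.row.names = FALSE)))
}
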
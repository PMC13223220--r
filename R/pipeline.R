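#' Pipeline configuration
#'
#' Collects the end-to-end settings: the synthetic-landscape configuration,
#' analysis thresholds, seeds, attribution budget and output options. All
#' randomness flows from the named seeds.
#'
#' @param synthetic a [synthetic_config()]; the synthetic generator is the
#'   data source (real-data ingestion goes through the raster readers).
#' @param split_seed seed of the block shuffle split (default 77, matching
#'   the reference protocol).
#' @param grid_mode `"reduced"` or `"full"` hyperparameter grid.
#' @param attribution run the attribution stage.
#' @param attribution_max_n per-section record cap for the attribution
#'   stage (subsampled reproducibly).
#' @param repeats CV fold-assignment reshuffles.
#' @param nrounds,early_stopping boosting budget.
#' @param stable_band pixel-trend stable band, RSEI per decade.
#' @param class_breaks RSEI classification thresholds, strictly increasing
#'   and spanning \[0, 1\].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            split_seed = 77L, grid_mode = "reduced",
                            attribution = TRUE, attribution_max_n = 4000L,
                            repeats = 1L, nrounds = 300L,
                            early_stopping = 50L, stable_band = 0.005,
                            class_breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  stopifnot(all(diff(class_breaks) > 0), class_breaks[1] == 0,
            class_breaks[length(class_breaks)] == 1)
  structure(list(synthetic = synthetic, split_seed = as.integer(split_seed),
                 grid_mode = grid_mode, attribution = attribution,
                 attribution_max_n = as.integer(attribution_max_n),
                 repeats = as.integer(repeats), nrounds = as.integer(nrounds),
                 early_stopping = as.integer(early_stopping),
                 stable_band = stable_band, class_breaks = class_breaks),
            class = "pipeline_config")
}

#' Run the full corridor analysis pipeline
#'
#' simulate -> indices -> RSEI -> belts/sections -> KDE/trends ->
#' attribution. When `out_dir` is given, writes per-year RSEI and class
#' rasters (`.asc`), `belts.csv`, `sections.csv`, `trends.csv`, `kde.csv`,
#' attribution JSON/CSV reports and a `manifest.json` with seeds and
#' per-file hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_bundle` with every stage's outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  sc <- config$synthetic

  say("stage 1/5: synthetic landscape (seed ", sc$seed, ")")
  corridor <- make_corridor(sc)
  drivers <- simulate_drivers(sc, corridor)
  sim <- simulate_scenes(sc, corridor, drivers)

  say("stage 2/5: RSEI per year")
  rsei <- withCallingHandlers(
    rsei_per_year(sim$scenes, mask = corridor$buffer_mask),
    rsei_variance_warning = function(w) invokeRestart("muffleWarning"))

  say("stage 3/5: belts and sections")
  belts <- belt_statistics(rsei, corridor)
  sections <- section_summary(rsei, corridor)

  say("stage 4/5: distributions and trends")
  annual <- sections$annual_means
  trends <- list(
    north = trend_suite(annual$north, as.numeric(annual$year)),
    south = trend_suite(annual$south, as.numeric(annual$year)))
  split_year <- floor(median(as.numeric(annual$year)))
  sub <- lapply(c(north = "north", south = "south"),
                function(s) tryCatch(
                  subperiod_trends(annual[[s]], as.numeric(annual$year),
                                   split_year = split_year),
                  error = function(e) NULL))
  pix <- pixel_trends(rsei, corridor, stable_band = config$stable_band)
  last <- rsei[[length(rsei)]]
  kdes <- kde(last$rsei_layer[corridor$buffer_mask])

  attrib <- NULL
  if (config$attribution) {
    say("stage 5/5: attribution")
    samples <- build_samples(rsei, drivers, corridor)
    attrib <- lapply(c(north = "north", south = "south"), function(sec) {
      ss <- sample_records(samples[samples$section == sec, , drop = FALSE],
                           config$attribution_max_n,
                           seed = derive_seed(sc$seed, c("attr", sec)))
      plan <- spatial_block_split(ss, seed = config$split_seed)
      rows <- split_rows(ss, plan)
      fit <- tune_and_fit(ss[rows$train, , drop = FALSE],
                          grid = config$grid_mode, repeats = config$repeats,
                          nrounds = config$nrounds,
                          early_stopping = config$early_stopping,
                          seed = config$split_seed)
      test_metrics <- evaluate_model(fit, ss[rows$test, , drop = FALSE])
      audit <- leakage_audit(ss, plan, seed = config$split_seed)
      shap <- shap_analysis(fit, ss, corridor = corridor)
      baseline <- linear_baseline(ss, plan)
      list(fit_report = fit$report, test_metrics = test_metrics,
           leakage = audit, shap = shap, baseline = baseline, plan = plan,
           n = nrow(ss))
    })
  } else say("stage 5/5: attribution skipped")

  bundle <- structure(list(config = config, corridor = corridor,
                           drivers = drivers, truth = sim$truth, rsei = rsei,
                           belts = belts, sections = sections,
                           trends = trends, subperiods = sub,
                           pixel_trends = pix, kde = kdes,
                           attribution = attrib),
                      class = "pipeline_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  px <- bundle$corridor$pixel_size
  paths <- character(0)
  for (res in bundle$rsei) {
    p1 <- file.path(out_dir, sprintf("rsei_%s.asc", res$year))
    p2 <- file.path(out_dir, sprintf("class_%s.asc", res$year))
    write_raster(res$rsei_layer, p1, pixel_size = px)
    write_raster(res$class_layer, p2, pixel_size = px)
    paths <- c(paths, p1, p2)
  }
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(paths, wcsv(bundle$belts, "belts.csv"),
             wcsv(bundle$sections$annual_means, "sections.csv"),
             wcsv(data.frame(x = bundle$kde$x, f = bundle$kde$f), "kde.csv"))
  tr <- do.call(rbind, lapply(names(bundle$trends), function(sec) {
    t <- bundle$trends[[sec]]
    data.frame(section = sec, sen_decade = t$sen$slope_decade,
               mk_tau = t$mk$tau, mk_p = t$mk$p,
               ols_decade = t$ols$slope_decade, ols_r2 = t$ols$r2,
               pettitt_year = t$pettitt$change_year, pettitt_p = t$pettitt$p)
  }))
  paths <- c(paths, wcsv(tr, "trends.csv"))
  if (!is.null(bundle$attribution)) {
    for (sec in names(bundle$attribution)) {
      a <- bundle$attribution[[sec]]
      p <- file.path(out_dir, sprintf("fit_report_%s.json", sec))
      jsonlite::write_json(list(fit = a$fit_report, test = a$test_metrics,
                                leakage = unclass(a$leakage),
                                baseline = a$baseline),
                           p, auto_unbox = TRUE, digits = NA)
      paths <- c(paths,
                 p, wcsv(a$shap$ranking, sprintf("shap_global_%s.csv", sec)))
    }
  }
  manifest <- list(
    seed = bundle$config$synthetic$seed,
    split_seed = bundle$config$split_seed,
    years = bundle$config$synthetic$years,
    files = lapply(setNames(paths, basename(paths)),
                   function(p) digest::digest(file = p, algo = "xxhash64")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable summary of a pipeline bundle
#'
#' @param bundle a [run_pipeline()] result.
#' @return character vector of report lines (also printed).
#' @export
pipeline_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  s <- bundle$sections
  lines <- c(
    "== Corridor RSEI report ==",
    sprintf("Years: %s-%s; grid %dx%d at %gm",
            min(bundle$config$synthetic$years),
            max(bundle$config$synthetic$years), bundle$corridor$nrow,
            bundle$corridor$ncol, bundle$corridor$pixel_size),
    "-- Section comparison --",
    sprintf("north mean %.3f +/- %.3f (CV %.2f%%)", s$north[["mean"]],
            s$north[["sd"]], s$north[["cv_pct"]]),
    sprintf("south mean %.3f +/- %.3f (CV %.2f%%)", s$south[["mean"]],
            s$south[["sd"]], s$south[["cv_pct"]]),
    sprintf("difference (south-north) %.3f (Welch p = %.3g)", s$difference,
            s$welch_p),
    "-- Trends (per decade) --")
  for (sec in names(bundle$trends)) {
    t <- bundle$trends[[sec]]
    lines <- c(lines, sprintf(
      "%s: Sen %+.4f, MK tau %+.3f (p=%.3g), OLS %+.4f (R2=%.2f), Pettitt %s (p=%.3g)",
      sec, t$sen$slope_decade, t$mk$tau, t$mk$p, t$ols$slope_decade,
      t$ols$r2, t$pettitt$change_year, t$pettitt$p))
  }
  vr <- vapply(bundle$rsei, function(r) r$pca$variance_ratio, numeric(1))
  out_band <- vr < 0.70 | vr > 0.85
  if (any(out_band))
    lines <- c(lines, sprintf(
      "note: PC1 variance ratio outside [0.70, 0.85] in %d/%d years (range %.2f-%.2f)",
      sum(out_band), length(vr), min(vr), max(vr)))
  if (!is.null(bundle$attribution)) {
    lines <- c(lines, "-- Attribution --")
    for (sec in names(bundle$attribution)) {
      a <- bundle$attribution[[sec]]
      lines <- c(lines, sprintf(
        "%s: test R2 %.3f RMSE %.3f | d_min %.2f km, Moran train/test %.3f/%.3f | top driver %s | linear baseline R2 %.3f",
        sec, a$test_metrics$r2, a$test_metrics$rmse, a$leakage$d_min_km,
        a$leakage$moran_train, a$leakage$moran_test,
        a$shap$ranking$feature[1], a$baseline$r2))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
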
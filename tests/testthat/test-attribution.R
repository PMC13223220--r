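test_that("sample table construction uses nearest epochs and 1-km blocks", {
  w <- tiny_world()
  samples <- build_samples(w$rsei, w$drivers, w$corridor)
  expect_s3_class(samples, "sample_table")
  # nearest-epoch mapping with epochs {2000, 2005}
  expect_equal(unique(samples$epoch_year[samples$year == 2002]), 2000)
  expect_equal(unique(samples$epoch_year[samples$year == 2003]), 2005)
  expect_equal(unique(samples$epoch_year[samples$year == 2006]), 2005)
  # block ids pair floor(x/1000) with floor(y/1000)
  expect_equal(samples$block_id[1],
               paste(floor(samples$x[1] / 1000), floor(samples$y[1] / 1000),
                     sep = "_"))
  # one record per valid buffered pixel-year
  expect_equal(nrow(samples),
               sum(w$corridor$buffer_mask) * length(w$config$years))
  expect_true(all(rseicorridor:::DRIVER_NAMES %in% names(samples)))
})

test_that("spatial block split is disjoint, sized and reproducible", {
  samples <- make_sample_table(900, seed = 2)
  plan <- spatial_block_split(samples, test_fraction = 0.2, seed = 77)
  expect_length(intersect(plan$train_blocks, plan$test_blocks), 0)
  nb <- length(unique(samples$block_id))
  expect_equal(length(plan$test_blocks), round(0.2 * nb))
  plan2 <- spatial_block_split(samples, test_fraction = 0.2, seed = 77)
  expect_identical(plan, plan2)
  rows <- rseicorridor:::split_rows(samples, plan)
  expect_length(intersect(samples$block_id[rows$train],
                          samples$block_id[rows$test]), 0)
})

test_that("boosting learns deterministic targets and refuses degenerate ones", {
  # noiseless linear target on 5 informative features: near-perfect test R2
  samples <- make_sample_table(3000, seed = 5, noise_sd = 0, target_fn =
    function(d) 0.3 * d$precipitation + 0.2 * d$temperature - 0.25 * d$DEM +
      0.15 * d$GDP - 0.3 * d$nighttime_light)
  plan <- spatial_block_split(samples, seed = 77)
  rows <- rseicorridor:::split_rows(samples, plan)
  fit <- tune_and_fit(samples[rows$train, ], grid = "reduced", repeats = 1,
                      nrounds = 3000, early_stopping = 100, seed = 77)
  ev <- evaluate_model(fit, samples[rows$test, ])
  expect_gte(ev$r2, 0.99)
  # early stopping engages before the full budget on an easy target
  expect_lt(fit$model$best_iter, 3000)
  # pure-noise target: no skill
  noise <- make_sample_table(1200, seed = 6, noise_sd = 1,
                             target_fn = function(d) 0)
  rows_n <- rseicorridor:::split_rows(noise,
                                      spatial_block_split(noise, seed = 77))
  fit_n <- tune_and_fit(noise[rows_n$train, ], grid = "reduced", repeats = 1,
                        nrounds = 150, seed = 77)
  expect_lte(evaluate_model(fit_n, noise[rows_n$test, ])$r2, 0.1)
  # degenerate target
  const <- make_sample_table(200, seed = 7, noise_sd = 0,
                             target_fn = function(d) 1)
  expect_error(tune_and_fit(const, grid = "reduced"),
               class = "rsei_degenerate_error")
})

test_that("evaluation metrics match a hand-computed case", {
  obs <- c(1, 2, 3)
  pred <- c(1.5, 2, 2.5)
  m <- rseicorridor:::regression_metrics(obs, pred)
  expect_equal(m$rmse, sqrt(1 / 6))
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$r2, 0.75)
  # perfect and mean-constant predictions
  expect_equal(rseicorridor:::regression_metrics(obs, obs)$r2, 1)
  expect_equal(rseicorridor:::regression_metrics(obs, rep(2, 3))$r2, 0)
})

test_that("Moran's I matches the hand-evaluated chain example", {
  # 1-D values [1,1,2,2] under binary chain adjacency: I = 1/3
  nb <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  expect_equal(moran_i(c(1, 1, 2, 2), nb, style = "B"), 1 / 3)
  expect_warning(res <- moran_i(rep(1, 4), nb), "undefined")
  expect_true(is.na(res))
})

test_that("leakage audit reports planted separations and Moran's I", {
  # two blocks of points with a planted 4 km gap
  df <- make_sample_table(400, seed = 3)
  df$x <- rep(c(250, 4250), each = 200)
  df$y <- rep(seq(250, by = 500, length.out = 200), 2)
  df$block_id <- rep(c("a", "b"), each = 200)
  plan <- structure(list(train_blocks = "a", test_blocks = "b",
                         test_fraction = 0.5, seed = 1),
                    class = "split_plan")
  rep <- leakage_audit(df, plan)
  expect_equal(rep$d_min_km, 4.0)
  expect_gte(rep$d_mean_km, rep$d_min_km)
  expect_lte(abs(rep$moran_train), 1.05)
  # constant target: Moran undefined with warning
  df$rsei <- 1
  expect_warning(expect_warning(rep2 <- leakage_audit(df, plan),
                                "undefined"), "undefined")
  expect_true(is.na(rep2$moran_train))
})

test_that("Shapley values satisfy local accuracy and match the R oracle", {
  samples <- make_sample_table(500, seed = 8, target_fn = function(d)
    0.5 * d$precipitation - 0.4 * d$nighttime_light +
      0.3 * d$precipitation * d$temperature)
  X <- rseicorridor:::feature_matrix(samples)
  model <- gbt_fit(X, samples$rsei, fast_params, nrounds = 30, seed = 1)
  sh <- shap_analysis(model, samples)
  expect_lt(sh$local_accuracy_err, 1e-6)
  # production TreeSHAP equals the in-package brute-force subset oracle
  brute <- rseicorridor:::.gbt_shap_brute_cpp(model, X[1:40, ])
  fast <- rseicorridor:::.gbt_shap_cpp(model, X[1:40, ])
  expect_lt(max(abs(brute$phi - fast$phi)), 1e-10)
  # and both match a fully independent R implementation on a tiny model
  small <- gbt_fit(X[1:150, 1:4], samples$rsei[1:150],
                   list(max_depth = 2L, learning_rate = 0.3, subsample = 1,
                        colsample = 1, alpha = 0, lambda = 1),
                   nrounds = 3, seed = 2)
  oracle <- shap_oracle_r(small, X[1:10, 1:4])
  got <- rseicorridor:::.gbt_shap_cpp(small, X[1:10, 1:4])
  expect_lt(max(abs(oracle$phi - got$phi)), 1e-10)
  expect_equal(oracle$base, got$base, tolerance = 1e-10)
})

test_that("Shapley ranking and dependence recover planted structure", {
  samples <- make_sample_table(1200, seed = 9, noise_sd = 0.02, target_fn =
    function(d) -0.6 * d$nighttime_light + 0.2 * d$temperature +
      0.1 * d$slope)
  X <- rseicorridor:::feature_matrix(samples)
  model <- gbt_fit(X, samples$rsei, fast_params, nrounds = 200, seed = 3)
  sh <- shap_analysis(model, samples)
  expect_equal(sh$ranking$feature[1], "nighttime_light")
  dep <- sh$dependence$nighttime_light
  expect_lt(cor(dep$value, dep$phi), 0)
  # a null feature ranks below every effectful feature
  rk <- sh$ranking
  expect_lt(rk$mean_abs_phi[rk$feature == "population"],
            min(rk$mean_abs_phi[rk$feature %in%
                                  c("nighttime_light", "temperature")]))
})

test_that("ablation separates dominant, null and collinear features", {
  samples <- make_sample_table(1200, seed = 10, noise_sd = 0.02, target_fn =
    function(d) -0.6 * d$nighttime_light + 0.2 * d$temperature)
  plan <- spatial_block_split(samples, seed = 77)
  abl_dom <- ablation(samples, "nighttime_light", params = fast_params,
                      seed = 77, plan = plan, nrounds = 150)
  abl_null <- ablation(samples, "aspect", params = fast_params, seed = 77,
                       plan = plan, nrounds = 150)
  expect_gt(abl_dom$delta_r2, abl_null$delta_r2)
  expect_lt(abs(abl_null$delta_r2), 0.02)
  # perfectly collinear feature: removing the duplicate costs nothing
  dup <- samples
  dup$GDP <- dup$nighttime_light
  abl_dup <- ablation(dup, "GDP", params = fast_params, seed = 77,
                      plan = plan, nrounds = 150)
  expect_lt(abs(abl_dup$delta_r2), 0.02)
})

test_that("linear baseline matches boosting on linear targets, loses on interactions", {
  lin <- make_sample_table(1500, seed = 11, noise_sd = 0.02, target_fn =
    function(d) 0.4 * d$precipitation - 0.3 * d$nighttime_light)
  plan <- spatial_block_split(lin, seed = 77)
  rows <- rseicorridor:::split_rows(lin, plan)
  base_lin <- linear_baseline(lin, plan)
  fit <- rseicorridor:::fit_fixed(lin, rows$train, fast_params, TRUE, 77,
                                  nrounds = 200)
  boost_lin <- evaluate_model(fit, lin[rows$test, ])
  expect_equal(base_lin$r2, boost_lin$r2, tolerance = 0.1)

  inter <- make_sample_table(1500, seed = 12, noise_sd = 0.02, target_fn =
    function(d) 1.5 * (d$precipitation - 0.5) * (d$temperature - 0.5))
  plan_i <- spatial_block_split(inter, seed = 77)
  rows_i <- rseicorridor:::split_rows(inter, plan_i)
  base_int <- linear_baseline(inter, plan_i)
  fit_i <- rseicorridor:::fit_fixed(inter, rows_i$train, fast_params, TRUE,
                                    77, nrounds = 200)
  boost_int <- evaluate_model(fit_i, inter[rows_i$test, ])
  expect_gt(boost_int$r2, base_int$r2 + 0.2)
  # perfect fit edge case
  perfect <- list(r2 = 1, rmse = 0, mae = 0)
  expect_equal(rseicorridor:::regression_metrics(1:4, 1:4), perfect)
})

test_that("random-vs-block inflation is positive on autocorrelated targets, ~0 on white noise", {
  # spatially smooth target: block split must look harder than random split
  smooth_target <- function(n, seed, scale) {
    withr::with_seed(seed, {
      side <- ceiling(sqrt(n))
      f <- rseicorridor:::gaussian_field(side, side, scale)
      df <- make_sample_table(n, seed = seed + 100, noise_sd = 0,
                              target_fn = function(d) 0)
      ij <- cbind(pmin(side, floor(df$y / 500) + 1),
                  pmin(side, floor(df$x / 500) + 1))
      df$rsei <- f[ij] + rnorm(n, sd = 0.05)
      df
    })
  }
  pos <- 0
  for (seed in 1:5) {
    df <- smooth_target(900, seed, scale = 6)
    inf <- random_vs_block(df, params = fast_params, seed = seed,
                           nrounds = 120)
    if (inf$inflation > 0) pos <- pos + 1
  }
  expect_gte(pos, 3)
  # white-noise world: inflation within noise of zero
  wn <- make_sample_table(900, seed = 31, noise_sd = 1,
                          target_fn = function(d) 0)
  inf_wn <- random_vs_block(wn, params = fast_params, seed = 31,
                            nrounds = 80)
  expect_lt(abs(inf_wn$inflation), 0.1)
  # determinism
  inf2 <- random_vs_block(wn, params = fast_params, seed = 31, nrounds = 80)
  expect_equal(inf_wn$inflation, inf2$inflation)
})
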
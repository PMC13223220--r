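#' Hyperparameter grids for the boosted-tree regressor
#'
#' `"full"` is the six-parameter space explored in the reference protocol
#' (1296 combinations); `"reduced"` is a two-combination desk-scale grid
#' for tests and synthetic acceptance runs.
#'
#' @param which `"full"` or `"reduced"`.
#' @return data frame of hyperparameter combinations.
#' @export
gbt_param_grid <- function(which = c("reduced", "full")) {
  which <- match.arg(which)
  if (which == "full")
    expand.grid(max_depth = c(3L, 5L, 7L, 9L),
                learning_rate = c(0.01, 0.05, 0.1, 0.3),
                subsample = c(0.6, 0.8, 1.0),
                colsample = c(0.6, 0.8, 1.0),
                alpha = c(0, 0.5, 1), lambda = c(1, 2, 5))
  else
    expand.grid(max_depth = c(3L, 5L), learning_rate = 0.1,
                subsample = 0.8, colsample = 0.8, alpha = 0, lambda = 1)
}

#' Build the pixel-year sample table for attribution
#'
#' One record per valid buffered pixel and year: coordinates (pixel
#' centers, metres), the 1-km spatial block id (`floor(x/block_m)` paired
#' with `floor(y/block_m)`), section, the RSEI target, and the nine driver
#' features taken from the epoch nearest to the RSEI year.
#'
#' @param rsei_results list of `rsei_result` objects.
#' @param drivers a [simulate_drivers()] result (or any `driver_stack`).
#' @param corridor a [make_corridor()] result.
#' @param block_m spatial block edge length in metres (default 1000).
#' @return data frame of class `sample_table`.
#' @export
build_samples <- function(rsei_results, drivers, corridor, block_m = 1000) {
  stopifnot(inherits(drivers, "driver_stack"), length(drivers$epoch_years) >= 1L)
  idx <- which(corridor$buffer_mask)
  out <- lapply(rsei_results, function(res) {
    year <- res$year
    ey <- nearest_epoch(year, drivers$epoch_years)
    ep <- drivers$epochs[[as.character(ey)]]
    if (is.null(ep)) stop("missing driver epoch ", ey)
    rsei <- res$rsei_layer[idx]
    ok <- is.finite(rsei)
    df <- data.frame(x = corridor$x[idx][ok], y = corridor$y[idx][ok],
                     year = year, epoch_year = ey,
                     section = corridor$section[idx][ok],
                     rsei = rsei[ok])
    for (f in DRIVER_NAMES) df[[f]] <- as.numeric(ep[[f]][idx][ok])
    df
  })
  samples <- do.call(rbind, out)
  samples$block_id <- paste(floor(samples$x / block_m),
                            floor(samples$y / block_m), sep = "_")
  rownames(samples) <- NULL
  class(samples) <- c("sample_table", "data.frame")
  samples
}

#' Random subsample of a sample table
#'
#' @param samples a [build_samples()] table.
#' @param n maximum number of records to keep.
#' @param seed RNG seed.
#' @return subsampled `sample_table`.
#' @export
sample_records <- function(samples, n, seed = 1L) {
  if (nrow(samples) <= n) return(samples)
  with_seed(seed, samples[sort(sample(nrow(samples), n)), , drop = FALSE])
}

#' Spatial block train/test split
#'
#' Randomly partitions the 1-km blocks (not the records) so that all
#' records of a block fall on one side, mirroring a grouped shuffle split.
#'
#' @param samples a [build_samples()] table.
#' @param test_fraction fraction of blocks assigned to the test side.
#' @param seed RNG seed (default 77).
#' @return object of class `split_plan` with `train_blocks`, `test_blocks`.
#' @export
spatial_block_split <- function(samples, test_fraction = 0.2, seed = 77L) {
  blocks <- unique(samples$block_id)
  if (length(blocks) < 2L) stop("need at least 2 spatial blocks to split")
  shuffled <- with_seed(seed, sample(blocks))
  n_test <- max(1L, round(test_fraction * length(blocks)))
  structure(list(test_blocks = shuffled[seq_len(n_test)],
                 train_blocks = shuffled[-seq_len(n_test)],
                 test_fraction = test_fraction, seed = seed),
            class = "split_plan")
}

split_rows <- function(samples, plan) {
  list(train = which(samples$block_id %in% plan$train_blocks),
       test = which(samples$block_id %in% plan$test_blocks))
}

feature_matrix <- function(samples, drop = NULL) {
  feats <- setdiff(DRIVER_NAMES, drop)
  as.matrix(samples[, feats, drop = FALSE])
}

#' Fit a gradient-boosted tree regressor
#'
#' Squared-loss boosting with depth-limited exact-greedy trees, L1/L2 leaf
#' regularization, row and column subsampling, and optional early stopping
#' against a validation set.
#'
#' @param X numeric feature matrix.
#' @param y numeric target.
#' @param params list/1-row data frame with `max_depth`, `learning_rate`,
#'   `subsample`, `colsample`, `alpha`, `lambda`.
#' @param Xval,yval optional validation set for early stopping.
#' @param nrounds maximum boosting rounds.
#' @param early_stopping stop after this many rounds without validation
#'   improvement (0 disables).
#' @param seed RNG seed for subsampling.
#' @return object of class `gbt_model`.
#' @export
gbt_fit <- function(X, y, params, Xval = NULL, yval = NULL, nrounds = 300L,
                    early_stopping = 50L, seed = 1L) {
  if (sd(y) == 0) stop_degenerate("degenerate target: zero variance")
  if (is.null(Xval)) {
    Xval <- X[0, , drop = FALSE]
    yval <- numeric(0)
    early_stopping <- 0L
  }
  model <- with_seed(seed, .gbt_train_cpp(
    X, y, Xval, yval, as.integer(nrounds),
    as.integer(params$max_depth), params$learning_rate, params$subsample,
    params$colsample, params$alpha, params$lambda, 0.0, 1.0,
    as.integer(early_stopping)))
  model$params <- as.list(params)
  model$feature_names <- colnames(X)
  model
}

#' @export
predict.gbt_model <- function(object, newdata, ntree_limit = NULL, ...) {
  if (is.null(ntree_limit)) ntree_limit <- object$best_iter
  .gbt_predict_cpp(object, as.matrix(newdata), as.integer(ntree_limit))
}

#' Tune and fit the boosted model under block-grouped cross-validation
#'
#' Grid search over `grid` scored by mean validation RMSE across
#' block-grouped CV folds (optionally repeated with reshuffled fold
#' assignments); early stopping is applied within every fold. The winning
#' combination is refit on the training data with a seed-derived 10%
#' block-grouped validation slice for early stopping.
#'
#' @param samples training `sample_table` (typically one section's training
#'   records).
#' @param grid `"reduced"`, `"full"` or a data frame of combinations.
#' @param cv_folds number of CV folds (blocks are assigned to folds).
#' @param repeats number of fold-assignment reshuffles averaged.
#' @param nrounds,early_stopping boosting budget and patience.
#' @param seed RNG seed controlling folds, validation slice and
#'   subsampling.
#' @param drop optional feature names to exclude (for ablation).
#' @return list of class `gbt_fit_result`: `model`, `report` (best
#'   hyperparameters, train metrics, rounds used, sample sizes) and
#'   `cv_table`.
#' @export
tune_and_fit <- function(samples, grid = "reduced", cv_folds = 5L,
                         repeats = 3L, nrounds = 300L, early_stopping = 50L,
                         seed = 77L, drop = NULL) {
  stopifnot(nrow(samples) > 0L)
  if (is.character(grid)) grid <- gbt_param_grid(grid)
  X <- feature_matrix(samples, drop = drop)
  y <- samples$rsei
  if (sd(y) == 0) stop_degenerate("degenerate target: zero variance")
  blocks <- unique(samples$block_id)
  cv_folds <- min(cv_folds, length(blocks))

  fold_tables <- lapply(seq_len(repeats), function(rep) {
    shuffled <- with_seed(derive_seed(seed, c("cv", rep)), sample(blocks))
    setNames(rep_len(seq_len(cv_folds), length(shuffled)), shuffled)
  })

  scores <- matrix(NA_real_, nrow(grid), repeats * cv_folds)
  for (gi in seq_len(nrow(grid))) {
    col <- 0L
    for (rep in seq_len(repeats)) {
      fold_of <- fold_tables[[rep]][samples$block_id]
      for (fold in seq_len(cv_folds)) {
        col <- col + 1L
        tr <- which(fold_of != fold)
        va <- which(fold_of == fold)
        if (!length(va) || !length(tr)) next
        m <- gbt_fit(X[tr, , drop = FALSE], y[tr], grid[gi, ],
                     X[va, , drop = FALSE], y[va], nrounds = nrounds,
                     early_stopping = early_stopping,
                     seed = derive_seed(seed, c("fit", gi, rep, fold)))
        scores[gi, col] <- min(m$eval_log, na.rm = TRUE)
      }
    }
  }
  cv_rmse <- rowMeans(scores, na.rm = TRUE)
  best <- which.min(cv_rmse)
  best_params <- grid[best, , drop = FALSE]

  # final refit: 10% of training blocks held out block-grouped for early stop
  val_blocks <- with_seed(derive_seed(seed, "final-val"),
                          sample(blocks, max(1L, round(0.1 * length(blocks)))))
  va <- which(samples$block_id %in% val_blocks)
  tr <- setdiff(seq_len(nrow(samples)), va)
  model <- gbt_fit(X[tr, , drop = FALSE], y[tr], best_params,
                   X[va, , drop = FALSE], y[va], nrounds = nrounds,
                   early_stopping = early_stopping,
                   seed = derive_seed(seed, "final-fit"))
  train_metrics <- regression_metrics(y, predict(model, X))
  report <- list(best_params = as.list(best_params),
                 cv_rmse = cv_rmse[best],
                 train_r2 = train_metrics$r2, train_rmse = train_metrics$rmse,
                 train_mae = train_metrics$mae,
                 rounds_used = model$nrounds_used,
                 best_iteration = model$best_iter,
                 n_train = nrow(samples), cv_folds = cv_folds,
                 repeats = repeats)
  structure(list(model = model, report = report,
                 cv_table = cbind(grid, cv_rmse = cv_rmse)),
            class = "gbt_fit_result")
}

#' Evaluate a fitted model on held-out samples
#'
#' @param model a `gbt_model` (or `gbt_fit_result`).
#' @param samples test `sample_table` (disjoint blocks).
#' @return list with `r2`, `rmse`, `mae`, `n`.
#' @export
evaluate_model <- function(model, samples) {
  if (inherits(model, "gbt_fit_result")) model <- model$model
  if (!nrow(samples)) stop("empty test set")
  drop <- setdiff(DRIVER_NAMES, model$feature_names)
  pred <- predict(model, feature_matrix(samples, drop = drop))
  c(regression_metrics(samples$rsei, pred), list(n = nrow(samples)))
}

#' Moran's I under explicit neighbour lists
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with binary (`"B"`)
#' or row-standardized (`"W"`) weights.
#' @param values numeric vector.
#' @param neighbors list of integer neighbour indices per observation.
#' @param style `"B"` binary or `"W"` row-standardized weights.
#' @return Moran's I, or `NA` (with a warning) for a constant input.
#' @export
moran_i <- function(values, neighbors, style = c("B", "W")) {
  style <- match.arg(style)
  n <- length(values)
  stopifnot(length(neighbors) == n)
  if (sd(values) == 0) {
    warning("constant values: Moran's I undefined")
    return(NA_real_)
  }
  z <- values - mean(values)
  num <- 0; S0 <- 0
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (!length(nb)) next
    w <- if (style == "W") 1 / length(nb) else 1
    num <- num + sum(w * z[i] * z[nb])
    S0 <- S0 + w * length(nb)
  }
  (n / S0) * num / sum(z^2)
}

knn_moran <- function(coords, values, k = 8L, style = "W") {
  n <- nrow(coords)
  if (n <= k) k <- max(1L, n - 1L)
  nn <- FNN::get.knn(coords, k = k)$nn.index
  neighbors <- lapply(seq_len(n), function(i) nn[i, ])
  moran_i(values, neighbors, style = style)
}

#' Spatial-leakage audit of a split plan
#'
#' Reports the distance from every test record to its nearest training
#' record (minimum and mean, km) and the approximate Moran's I of the
#' target within each partition, computed with k-nearest-neighbour (k = 8)
#' row-standardized weights on a capped random subsample.
#'
#' @param samples a `sample_table`.
#' @param plan a [spatial_block_split()] plan.
#' @param k neighbours for the Moran approximation.
#' @param max_points Moran subsample cap.
#' @param seed RNG seed for the subsample.
#' @return list of class `leakage_report`: `d_min_km`, `d_mean_km`,
#'   `moran_train`, `moran_test`, `n_train`, `n_test`.
#' @export
leakage_audit <- function(samples, plan, k = 8L, max_points = 5000L,
                          seed = 1L) {
  rows <- split_rows(samples, plan)
  if (!length(rows$train) || !length(rows$test))
    stop("both partitions must be non-empty")
  tr <- as.matrix(samples[rows$train, c("x", "y")])
  te <- as.matrix(samples[rows$test, c("x", "y")])
  d <- FNN::get.knnx(tr, te, k = 1L)$nn.dist[, 1]

  moran_part <- function(idx, tag) {
    sub <- if (length(idx) > max_points)
      with_seed(derive_seed(seed, tag), sample(idx, max_points)) else idx
    v <- samples$rsei[sub]
    if (sd(v) == 0) {
      warning("constant target in ", tag, " partition: Moran's I undefined")
      return(NA_real_)
    }
    knn_moran(as.matrix(samples[sub, c("x", "y")]), v, k = k, style = "W")
  }
  structure(list(d_min_km = min(d) / 1000, d_mean_km = mean(d) / 1000,
                 moran_train = moran_part(rows$train, "train"),
                 moran_test = moran_part(rows$test, "test"),
                 n_train = length(rows$train), n_test = length(rows$test)),
            class = "leakage_report")
}

# fit with fixed params on given training rows, early-stopped on a held-out
# slice (block-grouped or random according to `grouped`)
fit_fixed <- function(samples, rows, params, grouped, seed, nrounds = 300L,
                      early_stopping = 50L, drop = NULL) {
  X <- feature_matrix(samples, drop = drop)
  y <- samples$rsei
  if (grouped) {
    blocks <- unique(samples$block_id[rows])
    vb <- with_seed(derive_seed(seed, "val"),
                    sample(blocks, max(1L, round(0.1 * length(blocks)))))
    va <- rows[samples$block_id[rows] %in% vb]
  } else {
    va <- with_seed(derive_seed(seed, "val"),
                    sample(rows, max(1L, round(0.1 * length(rows)))))
  }
  tr <- setdiff(rows, va)
  gbt_fit(X[tr, , drop = FALSE], y[tr], params, X[va, , drop = FALSE], y[va],
          nrounds = nrounds, early_stopping = early_stopping,
          seed = derive_seed(seed, "fit"))
}

#' Performance inflation of a random split over the spatial block split
#'
#' Fits the same model specification under (a) the block-grouped split and
#' (b) a record-level random split with the same test fraction and seed,
#' and reports `inflation = R2(random) - R2(block)`: on spatially
#' autocorrelated data the random split leaks neighbouring pixels into the
#' test set and inflates apparent skill.
#'
#' @param samples a `sample_table`.
#' @param params fixed hyperparameters (list or 1-row data frame); if
#'   `NULL`, a reduced-grid [tune_and_fit()] is run per split.
#' @param seed RNG seed.
#' @param test_fraction held-out fraction.
#' @param nrounds,early_stopping boosting budget.
#' @return list of class `inflation_report` with `r2_block`, `r2_random`,
#'   `inflation`.
#' @export
random_vs_block <- function(samples, params = NULL, seed = 77L,
                            test_fraction = 0.2, nrounds = 300L,
                            early_stopping = 50L) {
  plan <- spatial_block_split(samples, test_fraction, seed)
  rows_b <- split_rows(samples, plan)
  n_test <- max(1L, round(test_fraction * nrow(samples)))
  test_r <- with_seed(derive_seed(seed, "random-split"),
                      sample(nrow(samples), n_test))
  rows_r <- list(train = setdiff(seq_len(nrow(samples)), test_r),
                 test = test_r)

  fit_eval <- function(rows, grouped, tag) {
    if (is.null(params)) {
      fr <- tune_and_fit(samples[rows$train, , drop = FALSE],
                         grid = "reduced", repeats = 1L, nrounds = nrounds,
                         early_stopping = early_stopping,
                         seed = derive_seed(seed, tag))
      model <- fr$model
    } else {
      model <- fit_fixed(samples, rows$train, params, grouped,
                         derive_seed(seed, tag), nrounds, early_stopping)
    }
    evaluate_model(model, samples[rows$test, , drop = FALSE])
  }
  eb <- fit_eval(rows_b, TRUE, "block")
  er <- fit_eval(rows_r, FALSE, "random")
  structure(list(r2_block = eb$r2, r2_random = er$r2,
                 rmse_block = eb$rmse, rmse_random = er$rmse,
                 inflation = er$r2 - eb$r2),
            class = "inflation_report")
}

#' Shapley-value interpretation of a fitted boosted model
#'
#' Exact path-dependent tree-Shapley values for every record: local
#' accuracy (`base + sum(phi) = prediction`) holds to numerical precision.
#' Returns the global ranking by mean absolute Shapley value, per-feature
#' dependence series, and (when a corridor is supplied) per-feature spatial
#' maps obtained by averaging record-level values per pixel across years.
#'
#' @param model a `gbt_model` or `gbt_fit_result`.
#' @param samples records to explain.
#' @param corridor optional [make_corridor()] result for spatial maps.
#' @return list of class `shap_report`: `phi` (record x feature matrix),
#'   `base`, `ranking` (data frame), `dependence` (named list),
#'   `spatial` (named list of layers or `NULL`), `local_accuracy_err`.
#' @export
shap_analysis <- function(model, samples, corridor = NULL) {
  if (inherits(model, "gbt_fit_result")) model <- model$model
  drop <- setdiff(DRIVER_NAMES, model$feature_names)
  X <- feature_matrix(samples, drop = drop)
  sh <- .gbt_shap_cpp(model, X)
  phi <- sh$phi
  colnames(phi) <- colnames(X)
  pred <- predict(model, X)
  err <- max(abs(sh$base + rowSums(phi) - pred))

  ranking <- data.frame(feature = colnames(X),
                        mean_abs_phi = colMeans(abs(phi)))
  ranking <- ranking[order(-ranking$mean_abs_phi), ]
  rownames(ranking) <- NULL

  dependence <- lapply(setNames(colnames(X), colnames(X)), function(f)
    data.frame(value = X[, f], phi = phi[, f]))

  spatial <- NULL
  if (!is.null(corridor)) {
    px <- corridor$pixel_size
    cell <- (round(samples$y / px + 0.5) - 1L) * corridor$ncol +
      round(samples$x / px + 0.5)
    spatial <- lapply(setNames(colnames(X), colnames(X)), function(f) {
      sums <- tapply(phi[, f], cell, mean)
      layer <- matrix(NA_real_, corridor$nrow, corridor$ncol)
      ij <- as.integer(names(sums)) - 1L
      layer[cbind(ij %/% corridor$ncol + 1L, ij %% corridor$ncol + 1L)] <- sums
      layer
    })
  }
  structure(list(phi = phi, base = sh$base, ranking = ranking,
                 dependence = dependence, spatial = spatial,
                 local_accuracy_err = err),
            class = "shap_report")
}

#' Feature-ablation effect on held-out skill
#'
#' Refits the model without one feature under the same split and seed and
#' reports `delta_r2 = R2(full) - R2(ablated)` on the test blocks.
#'
#' @param samples a `sample_table`.
#' @param feature driver name to remove.
#' @param params fixed hyperparameters (list); `NULL` tunes a reduced grid.
#' @param seed RNG seed.
#' @param plan optional pre-built [spatial_block_split()] plan.
#' @param nrounds,early_stopping boosting budget.
#' @return list of class `ablation_report` with `r2_full`, `r2_ablated`,
#'   `delta_r2`.
#' @export
ablation <- function(samples, feature, params = NULL, seed = 77L,
                     plan = NULL, nrounds = 300L, early_stopping = 50L) {
  stopifnot(feature %in% DRIVER_NAMES)
  if (is.null(plan)) plan <- spatial_block_split(samples, seed = seed)
  rows <- split_rows(samples, plan)
  fit_one <- function(drop, tag) {
    if (is.null(params)) {
      fr <- tune_and_fit(samples[rows$train, , drop = FALSE],
                         grid = "reduced", repeats = 1L, nrounds = nrounds,
                         early_stopping = early_stopping,
                         seed = derive_seed(seed, tag), drop = drop)
      fr$model
    } else {
      fit_fixed(samples, rows$train, params, TRUE, derive_seed(seed, tag),
                nrounds, early_stopping, drop = drop)
    }
  }
  r2_full <- evaluate_model(fit_one(NULL, "full"),
                            samples[rows$test, , drop = FALSE])$r2
  r2_abl <- evaluate_model(fit_one(feature, "ablated"),
                           samples[rows$test, , drop = FALSE])$r2
  structure(list(feature = feature, r2_full = r2_full, r2_ablated = r2_abl,
                 delta_r2 = r2_full - r2_abl),
            class = "ablation_report")
}

#' Multiple-linear-regression baseline under the same split
#'
#' Ordinary least squares on the same nine features (land use entering as
#' its integer code), trained on the plan's training blocks and evaluated
#' on its test blocks.
#'
#' @param samples a `sample_table`.
#' @param plan a [spatial_block_split()] plan.
#' @return list with `r2`, `rmse`, `mae`, `n`.
#' @export
linear_baseline <- function(samples, plan) {
  rows <- split_rows(samples, plan)
  if (!length(rows$test)) stop("empty test set")
  df <- as.data.frame(feature_matrix(samples))
  df$rsei <- samples$rsei
  fit <- lm(rsei ~ ., data = df[rows$train, , drop = FALSE])
  pred <- predict(fit, df[rows$test, , drop = FALSE])
  c(regression_metrics(samples$rsei[rows$test], pred),
    list(n = length(rows$test)))
}
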
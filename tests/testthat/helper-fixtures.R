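# Small shared fixtures, generated in code.

# compact corridor world: 24 x 40 grid is the smallest comfortable domain
# holding the 5 km buffer (21 rows at 500 m)
tiny_config <- function(seed = 11L, ...) {
  synthetic_config(grid_shape = c(24L, 40L), years = 2000:2006,
                   epoch_years = c(2000, 2005), seed = seed,
                   months_per_year = 2L, ...)
}

tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config()
      corridor <- make_corridor(cfg)
      drivers <- simulate_drivers(cfg, corridor)
      sim <- simulate_scenes(cfg, corridor, drivers)
      rsei <- suppressWarnings(rsei_per_year(sim$scenes,
                                             mask = corridor$buffer_mask))
      cache <<- list(config = cfg, corridor = corridor, drivers = drivers,
                     scenes = sim$scenes, truth = sim$truth, rsei = rsei)
    }
    cache
  }
})

# synthetic attribution table with a known functional target, bypassing the
# raster pipeline: features are iid unless `smooth_field` supplies spatial
# structure over a grid of pixel coordinates
make_sample_table <- function(n = 600L, seed = 1L, target_fn = NULL,
                              noise_sd = 0.02, block_m = 1000) {
  withr::with_seed(seed, {
    side <- ceiling(sqrt(n))
    xy <- expand.grid(col = seq_len(side), row = seq_len(side))[seq_len(n), ]
    df <- data.frame(x = (xy$col - 0.5) * 500, y = (xy$row - 0.5) * 500,
                     year = 2000L, epoch_year = 2000L,
                     section = ifelse(xy$col <= side / 2, "north", "south"))
    for (f in rseicorridor:::DRIVER_NAMES) df[[f]] <- runif(n)
    df$land_use <- as.numeric(sample(1:5, n, replace = TRUE))
    if (is.null(target_fn))
      target_fn <- function(d) 0.5 * d$precipitation - 0.3 * d$nighttime_light
    df$rsei <- target_fn(df) + rnorm(n, sd = noise_sd)
    df$block_id <- paste(floor(df$x / block_m), floor(df$y / block_m),
                         sep = "_")
    class(df) <- c("sample_table", "data.frame")
    df
  })
}

fast_params <- list(max_depth = 3L, learning_rate = 0.1, subsample = 0.8,
                    colsample = 0.8, alpha = 0, lambda = 1)

# independent R Shapley oracle for one boosted model: enumerates subsets of
# each tree's used features with cover-weighted conditional expectations
shap_oracle_r <- function(model, X) {
  ntree <- min(model$best_iter, length(model$trees))
  p <- ncol(X)
  phi <- matrix(0, nrow(X), p)
  base <- model$base
  expv <- function(tr, node, S, x) {
    f <- tr$feature[node + 1]
    if (f < 0) return(tr$value[node + 1])
    if ((f + 1) %in% S) {
      nxt <- if (x[f + 1] < tr$thr[node + 1]) tr$left[node + 1]
             else tr$right[node + 1]
      return(expv(tr, nxt, S, x))
    }
    l <- tr$left[node + 1]; r <- tr$right[node + 1]
    (tr$cover[l + 1] * expv(tr, l, S, x) +
       tr$cover[r + 1] * expv(tr, r, S, x)) / tr$cover[node + 1]
  }
  for (k in seq_len(ntree)) {
    tr <- model$trees[[k]]
    used <- sort(unique(tr$feature[tr$feature >= 0])) + 1
    m <- length(used)
    if (m == 0) { base <- base + tr$value[1]; next }
    base <- base + expv(tr, 0, integer(0), X[1, ])
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      for (f in used) {
        others <- setdiff(used, f)
        for (k2 in 0:length(others)) {
          combs <- if (k2 == 0) list(integer(0)) else
            asplit(utils::combn(others, k2), 2)
          for (S in combs) {
            w <- factorial(k2) * factorial(m - k2 - 1) / factorial(m)
            phi[i, f] <- phi[i, f] +
              w * (expv(tr, 0, c(S, f), x) - expv(tr, 0, S, x))
          }
        }
      }
    }
  }
  list(phi = phi, base = base)
}
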
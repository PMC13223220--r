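# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-seed below 2^31 from a base seed and a stage tag
derive_seed <- function(seed, tag) {
  h <- digest::digest(list(as.integer(seed), tag), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483646L) + 1L
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("rsei_degenerate_error", "error")))
}

check_congruent <- function(...) {
  layers <- list(...)
  layers <- layers[!vapply(layers, is.null, logical(1))]
  dims <- vapply(layers, function(x) paste(dim(x), collapse = "x"), character(1))
  if (length(unique(dims)) > 1L)
    stop("layers are not congruent: grids ", paste(unique(dims), collapse = " vs "))
  invisible(TRUE)
}

# smoothed standard-Gaussian random field (mean 0, sd 1) on an r x c grid;
# scale <= 0 gives plain white noise.  Smoothing is periodic (FFT) which is
# adequate for synthetic landscapes.
gaussian_field <- function(nrow, ncol, scale) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  if (scale <= 0) return(z)
  ky <- c(0:floor(nrow / 2), -(ceiling(nrow / 2) - 1):-1) / nrow
  kx <- c(0:floor(ncol / 2), -(ceiling(ncol / 2) - 1):-1) / ncol
  # Gaussian transfer function in frequency space
  filt <- exp(-2 * pi^2 * scale^2 * (outer(ky^2, kx^2, "+")))
  sm <- Re(fft(fft(z) * filt, inverse = TRUE)) / (nrow * ncol)
  (sm - mean(sm)) / sd(sm)
}

r2_score <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

regression_metrics <- function(obs, pred) {
  list(r2 = r2_score(obs, pred),
       rmse = sqrt(mean((obs - pred)^2)),
       mae = mean(abs(obs - pred)))
}
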
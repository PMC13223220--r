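#' Gaussian kernel density estimate
#'
#' `f(x) = 1/(n h) * sum_i K((x - x_i)/h)` with the Gaussian kernel. The
#' default bandwidth is Silverman's rule of thumb
#' (`0.9 min(sd, IQR/1.34) n^(-1/5)`); an explicit `bandwidth` overrides
#' it. The default grid spans the data range +/- 5 bandwidths so the
#' numerical integral of the density is ~1.
#'
#' @param values finite numeric sample (n >= 2).
#' @param bandwidth optional kernel bandwidth `h > 0`.
#' @param grid optional evaluation points; default 512 points over
#'   data +/- 5h.
#' @param n_grid grid size when `grid` is not supplied.
#' @return list of class `kde_result`: `x`, `f`, `h`, `n`,
#'   `kernel = "gaussian"`.
#' @export
kde <- function(values, bandwidth = NULL, grid = NULL, n_grid = 512L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values")
  if (is.null(bandwidth)) {
    if (sd(values) == 0)
      stop_degenerate("zero-variance sample: supply an explicit bandwidth")
    bandwidth <- bw.nrd0(values)
  }
  stopifnot(bandwidth > 0)
  if (is.null(grid))
    grid <- seq(min(values) - 5 * bandwidth, max(values) + 5 * bandwidth,
                length.out = n_grid)
  f <- vapply(grid, function(x0)
    mean(dnorm((x0 - values) / bandwidth)) / bandwidth, numeric(1))
  structure(list(x = grid, f = f, h = bandwidth, n = n, kernel = "gaussian"),
            class = "kde_result")
}

#' Theil-Sen slope of a time series
#'
#' Median of all pairwise slopes `(x_j - x_i) / (t_j - t_i)`.
#' @param values numeric series.
#' @param years observation times (default consecutive).
#' @return list with `slope_yr` and `slope_decade` (`= 10 * slope_yr`).
#' @export
sens_slope <- function(values, years = seq_along(values)) {
  stopifnot(length(values) == length(years), length(unique(years)) >= 2L)
  dt <- outer(years, years, "-")
  dv <- outer(values, values, "-")
  sel <- upper.tri(dt) & dt != 0
  slope <- median(dv[sel] / dt[sel])
  list(slope_yr = slope, slope_decade = 10 * slope)
}

#' Mann-Kendall trend test
#'
#' `S` is the sum of pairwise difference signs; `tau` uses the
#' tie-corrected denominator; the p-value uses the normal approximation
#' with the tie-corrected variance and a continuity correction.
#' @param values numeric series (n >= 4).
#' @param years observation times.
#' @return list with `S`, `tau`, `var_S`, `z`, `p`.
#' @export
mann_kendall <- function(values, years = seq_along(values)) {
  n <- length(values)
  stopifnot(n >= 4L, length(years) == n)
  ord <- order(years)
  x <- values[ord]
  sgn <- sign(outer(x, x, FUN = function(a, b) b - a))
  S <- sum(sgn[upper.tri(sgn)])
  ties <- table(x)
  t_corr <- sum(ties * (ties - 1) * (2 * ties + 5))
  var_S <- (n * (n - 1) * (2 * n + 5) - t_corr) / 18
  tie_half <- sum(ties * (ties - 1)) / 2
  denom <- sqrt((n * (n - 1) / 2 - tie_half) * (n * (n - 1) / 2))
  tau <- if (denom > 0) S / denom else 0
  z <- if (var_S > 0) (S - sign(S)) / sqrt(var_S) else 0
  p <- 2 * pnorm(-abs(z))
  list(S = S, tau = tau, var_S = var_S, z = z, p = min(p, 1))
}

#' Pettitt change-point test
#'
#' `U_t = sum_{i<=t} sum_{j>t} sign(x_j - x_i)`; the statistic is
#' `K = max_t |U_t|`, the change point is reported as the last index of the
#' first regime (and the corresponding year), and the approximate p-value
#' is `2 exp(-6 K^2 / (n^3 + n^2))`, clipped to \[0, 1\].
#' @param values numeric series (n >= 4).
#' @param years observation times.
#' @return list with `K`, `change_index`, `change_year`, `p`, `U` (the
#'   statistic at every split).
#' @export
pettitt <- function(values, years = seq_along(values)) {
  n <- length(values)
  stopifnot(n >= 4L, length(years) == n)
  ord <- order(years)
  x <- values[ord]; yr <- years[ord]
  sgn <- sign(outer(x, x, FUN = function(a, b) b - a))  # sgn[i, j] = sign(x_j - x_i)
  U <- vapply(seq_len(n - 1L), function(t)
    sum(sgn[seq_len(t), (t + 1L):n]), numeric(1))
  K <- max(abs(U))
  t_hat <- which.max(abs(U))
  p <- min(2 * exp(-6 * K^2 / (n^3 + n^2)), 1)
  list(K = K, change_index = t_hat, change_year = yr[t_hat], p = p, U = U)
}

#' Ordinary least squares trend
#'
#' @param values numeric series (n >= 3).
#' @param years observation times.
#' @return list with `slope_yr`, `slope_decade`, `p`, `r2`, `intercept`.
#' @export
ols_trend <- function(values, years = seq_along(values)) {
  stopifnot(length(values) >= 3L, length(years) == length(values))
  fit <- lm(values ~ years)
  sm <- summary(fit)
  list(slope_yr = unname(coef(fit)[2]),
       slope_decade = 10 * unname(coef(fit)[2]),
       p = sm$coefficients[2, 4], r2 = sm$r.squared,
       intercept = unname(coef(fit)[1]))
}

#' Year-over-year differences
#'
#' @param values numeric series (n >= 2).
#' @return length `n - 1` vector of consecutive differences.
#' @export
delta_series <- function(values) {
  stopifnot(length(values) >= 2L)
  diff(values)
}

#' Full trend suite for one series
#'
#' Theil-Sen, Mann-Kendall, OLS, Pettitt and the year-over-year delta
#' series in one object.
#' @param values numeric series (n >= 4).
#' @param years observation times.
#' @return list of class `trend_stats`.
#' @export
trend_suite <- function(values, years = seq_along(values)) {
  structure(list(sen = sens_slope(values, years),
                 mk = mann_kendall(values, years),
                 ols = ols_trend(values, years),
                 pettitt = pettitt(values, years),
                 delta = delta_series(values),
                 years = years, n = length(values)),
            class = "trend_stats")
}

#' Sub-period trend analysis around a split year
#'
#' Runs the trend suite on `[first .. split_year]` and
#' `[split_year + 1 .. last]`.
#' @param values numeric series.
#' @param years observation times.
#' @param split_year last year of the first sub-period (default 2010).
#' @return list with elements `first` and `second` (each a `trend_stats`).
#' @export
subperiod_trends <- function(values, years, split_year = 2010) {
  a <- years <= split_year
  if (sum(a) < 3L || sum(!a) < 3L)
    stop("each sub-period needs at least 3 observations (split at ",
         split_year, " leaves ", sum(a), " + ", sum(!a), ")")
  list(first = trend_suite(values[a], years[a]),
       second = trend_suite(values[!a], years[!a]))
}

#' Per-pixel Sen-slope trend map
#'
#' Computes the Theil-Sen slope (per decade) for every valid buffered pixel
#' across years and classifies pixels as improving / stable / degrading
#' using a symmetric stable band around zero.
#'
#' @param rsei_results list of `rsei_result` objects or layers (>= 3 years).
#' @param corridor a [make_corridor()] result.
#' @param stable_band absolute per-decade slope below or equal to which a
#'   pixel counts as stable (default 0.005 RSEI/decade).
#' @return list of class `pixel_trend_map`: `slope_layer` (per decade),
#'   `class_layer` (character), and per-section + overall percentage
#'   tables `percentages`.
#' @export
pixel_trends <- function(rsei_results, corridor, stable_band = 0.005) {
  layers <- as_layer_list(rsei_results)
  stopifnot(length(layers) >= 3L)
  years <- as.numeric(names(layers))
  if (any(is.na(years))) years <- seq_along(layers)
  idx <- which(corridor$buffer_mask)
  Y <- vapply(layers, function(l) l[idx], numeric(length(idx)))  # n_pix x n_yr

  pairs <- combn(length(years), 2L)
  dt <- years[pairs[2, ]] - years[pairs[1, ]]
  slopes <- (Y[, pairs[2, ], drop = FALSE] - Y[, pairs[1, ], drop = FALSE]) /
    rep(dt, each = nrow(Y))
  slope_dec <- 10 * apply(slopes, 1L, median, na.rm = TRUE)

  slope_layer <- matrix(NA_real_, corridor$nrow, corridor$ncol)
  slope_layer[idx] <- slope_dec
  cls <- ifelse(is.na(slope_dec), NA_character_,
                ifelse(slope_dec > stable_band, "improving",
                       ifelse(slope_dec < -stable_band, "degrading", "stable")))
  class_layer <- matrix(NA_character_, corridor$nrow, corridor$ncol)
  class_layer[idx] <- cls

  pct <- function(sel) {
    v <- cls[sel]
    v <- v[!is.na(v)]
    setNames(100 * vapply(c("improving", "stable", "degrading"),
                          function(k) sum(v == k), numeric(1)) /
               max(1L, length(v)),
             c("improving", "stable", "degrading"))
  }
  sec <- corridor$section[idx]
  structure(list(slope_layer = slope_layer, class_layer = class_layer,
                 stable_band = stable_band,
                 percentages = list(overall = pct(rep(TRUE, length(cls))),
                                    north = pct(sec == "north"),
                                    south = pct(sec == "south"))),
            class = "pixel_trend_map")
}
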
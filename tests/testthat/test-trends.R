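# brute-force oracles used throughout this file
sen_brute <- function(v, yr) {
  s <- c()
  for (i in seq_along(v)) for (j in seq_along(v))
    if (j > i && yr[j] != yr[i]) s <- c(s, (v[j] - v[i]) / (yr[j] - yr[i]))
  median(s)
}
mk_S_brute <- function(v) {
  S <- 0
  for (i in seq_along(v)) for (j in seq_along(v))
    if (j > i) S <- S + sign(v[j] - v[i])
  S
}
pettitt_brute <- function(v) {
  n <- length(v)
  U <- sapply(1:(n - 1), function(t) {
    u <- 0
    for (i in 1:t) for (j in (t + 1):n) u <- u + sign(v[j] - v[i])
    u
  })
  list(K = max(abs(U)), t = which.max(abs(U)))
}

test_that("Sen, Mann-Kendall and Pettitt match brute-force enumeration (n <= 15)", {
  withr::with_seed(21, {
    for (n in 4:15) {
      for (rep in 1:4) {
        v <- round(rnorm(n), 2)
        if (rep == 2) v[sample(n, 2)] <- v[1]  # force ties
        yr <- 2000 + seq_len(n)
        expect_equal(sens_slope(v, yr)$slope_yr, sen_brute(v, yr))
        mk <- mann_kendall(v, yr)
        expect_equal(mk$S, mk_S_brute(v))
        expect_lte(abs(mk$tau), 1)
        pt <- pettitt(v, yr)
        pb <- pettitt_brute(v)
        expect_equal(pt$K, pb$K)
        expect_equal(pt$change_index, pb$t)
      }
    }
  })
})

test_that("Sen slope handles exact lines, constants and outliers", {
  expect_equal(sens_slope(1:5, 0:4)$slope_yr, 1.0)
  expect_equal(sens_slope(1:5, 0:4)$slope_decade, 10.0)
  expect_equal(sens_slope(rep(2, 6))$slope_yr, 0)
  # outlier-resistant: brute-enumerated median of the 10 pairwise slopes is 1
  expect_equal(sens_slope(c(0, 1, 2, 3, 100), 0:4)$slope_yr, 1.0)
})

test_that("Mann-Kendall endpoints and tie behaviour", {
  mk_up <- mann_kendall(1:5)
  expect_equal(mk_up$S, 10)
  expect_equal(mk_up$tau, 1.0)
  mk_dn <- mann_kendall(5:1)
  expect_equal(mk_dn$S, -10)
  expect_equal(mk_dn$tau, -1.0)
  mk_eq <- mann_kendall(rep(1, 6))
  expect_equal(mk_eq$S, 0)
  expect_equal(mk_eq$tau, 0)
  # tie-corrected variance never exceeds the untied variance
  withr::with_seed(3, {
    for (rep in 1:20) {
      v <- sample(1:5, 12, replace = TRUE)
      n <- length(v)
      expect_lte(mann_kendall(v)$var_S, n * (n - 1) * (2 * n + 5) / 18)
    }
  })
})

test_that("Pettitt locates steps, degenerates on constants, mirrors on reversal", {
  pt <- pettitt(c(0, 0, 0, 1, 1, 1))
  expect_equal(pt$change_index, 3)
  expect_equal(pt$K, 9)
  const <- pettitt(rep(1, 8))
  expect_equal(const$K, 0)
  expect_equal(const$p, 1)
  withr::with_seed(9, {
    v <- rnorm(12) + rep(c(0, 2), c(5, 7))
    a <- pettitt(v)
    b <- pettitt(rev(v))
    expect_equal(a$K, b$K)
    expect_equal(b$change_index, length(v) - a$change_index)
  })
})

test_that("OLS trend: exact lines, decade scaling and null coverage", {
  fit <- ols_trend(2 + 0.3 * (0:9), 2000:2009)
  expect_equal(fit$r2, 1.0)
  expect_equal(fit$slope_decade, 10 * fit$slope_yr)
  expect_equal(fit$slope_yr, 0.3)
  # null slope: 95% CI covers zero in >= 90% of seeded replicates
  covered <- withr::with_seed(31, {
    sum(vapply(1:100, function(i) {
      y <- rnorm(21)
      f <- lm(y ~ x, data = data.frame(x = 1:21, y = y))
      ci <- confint(f)[2, ]
      ci[1] <= 0 && ci[2] >= 0
    }, logical(1)))
  })
  expect_gte(covered, 90)
})

test_that("delta series telescopes", {
  expect_equal(delta_series(c(0.5, 0.6, 0.55)), c(0.1, -0.05))
  expect_equal(delta_series(rep(1, 5)), rep(0, 4))
  v <- withr::with_seed(2, rnorm(10))
  expect_equal(sum(delta_series(v)), v[10] - v[1])
})

test_that("sub-period analysis splits correctly and rejects short halves", {
  years <- 2000:2020
  vshape <- c(seq(1, 0, length.out = 11), seq(0.1, 1, length.out = 10))
  sp <- subperiod_trends(vshape, years, split_year = 2010)
  expect_lt(sp$first$sen$slope_yr, 0)
  expect_gt(sp$second$sen$slope_yr, 0)
  mono <- seq(0, 1, length.out = 21)
  sp2 <- subperiod_trends(mono, years)
  expect_gt(sp2$first$sen$slope_yr, 0)
  expect_gt(sp2$second$sen$slope_yr, 0)
  expect_error(subperiod_trends(mono, years, split_year = 2019), "at least 3")
})

test_that("KDE closed forms, normalization and symmetry", {
  # two coincident points, h = 1, evaluated at the point: dnorm(0)
  k <- kde(c(0, 0), bandwidth = 1, grid = 0)
  expect_equal(k$f, 1 / sqrt(2 * pi), tolerance = 1e-12)
  # integral ~1 on data +/- 5h
  v <- withr::with_seed(5, rnorm(400, 2, 0.7))
  k2 <- kde(v)
  integral <- sum(k2$f) * diff(k2$x[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
  # symmetric sample: f(-x) = f(x)
  a <- 1.3
  grid <- seq(-4, 4, length.out = 101)
  k3 <- kde(c(-a, a), bandwidth = 0.5, grid = grid)
  expect_equal(k3$f, rev(k3$f), tolerance = 1e-12)
  # unimodal Gaussian data: density peak within h of the sample mean
  expect_lt(abs(k2$x[which.max(k2$f)] - mean(v)), k2$h)
  expect_error(kde(rep(1, 5)), class = "rsei_degenerate_error")
  expect_equal(kde(rep(1, 5), bandwidth = 0.5)$h, 0.5)
})

test_that("pixel trend maps classify planted slopes", {
  w <- tiny_world()
  corridor <- w$corridor
  nr <- corridor$nrow; nc <- corridor$ncol
  years <- 2000:2008
  mk_stack <- function(slope_layer) {
    out <- lapply(years, function(y)
      0.5 + slope_layer * (y - 2000) / 10)
    names(out) <- years
    out
  }
  # uniform +0.02/decade: all improving
  pt <- pixel_trends(mk_stack(matrix(0.02, nr, nc)), corridor,
                     stable_band = 0.005)
  expect_equal(unname(pt$percentages$overall[["improving"]]), 100)
  expect_equal(sum(pt$percentages$overall), 100)
  # half +, half -
  half <- matrix(0.02, nr, nc)
  half[, seq_len(nc / 2)] <- -0.02
  pt2 <- pixel_trends(mk_stack(half), corridor, stable_band = 0.005)
  expect_equal(unname(pt2$percentages$overall[["improving"]]), 50,
               tolerance = 2)
  # stable band 0: only exactly-zero slopes are stable
  zero <- matrix(0, nr, nc)
  zero[1:12, ] <- 0.001
  pt3 <- pixel_trends(mk_stack(zero), corridor, stable_band = 0)
  sel <- corridor$buffer_mask & zero == 0
  expect_true(all(pt3$class_layer[sel] == "stable"))
  expect_true(all(pt3$class_layer[corridor$buffer_mask & zero != 0] ==
                    "improving"))
})
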
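test_that("corridor geometry: belts, buffer and sections follow the distance rules", {
  cfg <- synthetic_config(grid_shape = c(60L, 200L))
  corridor <- make_corridor(cfg)

  # 5 km buffer of 500 m belts: 10 belts per side, ids in 1..10
  expect_equal(corridor$n_belts, 10L)
  expect_equal(max(corridor$belt_id, na.rm = TRUE), 10L)
  # pixel 750 m from the centerline sits in belt 2; centerline y = 15000
  row750 <- which(abs((seq_len(60) - 0.5) * 500 - 15000) == 750)[1]
  expect_equal(corridor$belt_id[row750, 1], 2L)
  # just beyond 5 km (5250 m on this grid) is outside the buffer
  row_out <- which(abs((seq_len(60) - 0.5) * 500 - 15000) == 5250)[1]
  expect_false(corridor$buffer_mask[row_out, 1])
  # belts are defined exactly on the buffer, and belt_id = ceiling(d/500)
  expect_identical(!is.na(corridor$belt_id), corridor$buffer_mask)
  d <- corridor$distance[corridor$buffer_mask]
  expect_equal(corridor$belt_id[corridor$buffer_mask],
               pmin(pmax(as.integer(ceiling(d / 500)), 1L), 10L))
  # every pixel has exactly one section label
  expect_true(all(corridor$section %in% c("north", "south")))
})

test_that("too-small grids fail with a sizing error naming the minimum", {
  cfg <- synthetic_config(grid_shape = c(12L, 40L))
  expect_error(make_corridor(cfg), "at least 21 rows")
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 7L)
  corridor <- make_corridor(cfg)
  d1 <- simulate_drivers(cfg, corridor)
  d2 <- simulate_drivers(cfg, corridor)
  expect_identical(d1, d2)
  s1 <- simulate_scenes(cfg, corridor, d1)
  s2 <- simulate_scenes(cfg, corridor, d2)
  expect_identical(s1, s2)
  # different seed changes the fields
  d3 <- simulate_drivers(tiny_config(seed = 8L), corridor)
  expect_false(identical(d1$epochs[[1]]$precipitation,
                         d3$epochs[[1]]$precipitation))
})

test_that("driver fields honour configured section means and epoch structure", {
  w <- tiny_world()
  drivers <- w$drivers
  corridor <- w$corridor
  north <- corridor$section == "north"
  ep <- drivers$epochs[["2000"]]
  # configured 600 (north) / 1200 (south): sample means within 5%
  expect_lt(abs(mean(ep$precipitation[north]) - 600) / 600, 0.05)
  expect_lt(abs(mean(ep$precipitation[!north]) - 1200) / 1200, 0.05)
  # static topography identical across epochs
  expect_identical(ep$DEM, drivers$epochs[["2005"]]$DEM)
  expect_identical(ep$slope, drivers$epochs[["2005"]]$slope)
  expect_identical(ep$aspect, drivers$epochs[["2005"]]$aspect)
  # land use from the declared codes, with the planted water strip
  expect_true(all(ep$land_use %in% 1:5))
  expect_true(all(ep$land_use[corridor$distance <= 250] == 3L))
})

test_that("unknown driver names in effect mappings are rejected", {
  expect_error(synthetic_config(north_effects = c(rainfall = 0.5)),
               "unknown driver name")
})

test_that("smoothing_scale 0 yields white noise; smoothing induces autocorrelation", {
  lag1 <- function(m) cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
  f0 <- withr::with_seed(5, rseicorridor:::gaussian_field(100, 100, 0))
  expect_lt(abs(lag1(f0)), 0.05)
  f6 <- withr::with_seed(5, rseicorridor:::gaussian_field(100, 100, 6))
  expect_gt(lag1(f6), 0.5)
})

test_that("planted section gap and effect directions are realized in the latent field", {
  w <- tiny_world()
  q <- w$truth$latent
  corridor <- w$corridor
  buf <- corridor$buffer_mask
  north <- corridor$section == "north" & buf
  south <- corridor$section == "south" & buf
  gaps <- apply(q, 3, function(m) mean(m[south]) - mean(m[north]))
  # trend terms are mid-year centered, so the mean gap matches section_gap
  expect_lt(abs(mean(gaps) - w$config$section_gap), 0.01)
  # south regime: nighttime light suppresses quality
  ep <- w$drivers$epochs[["2000"]]
  expect_lt(cor(q[, , 1][south], ep$nighttime_light[south]), 0)
  # north regime: precipitation enhances quality
  expect_gt(cor(q[, , 1][north], ep$precipitation[north]), 0)
})

test_that("planted monotonicity: raising a positive-effect driver raises latent quality", {
  cfg <- tiny_config(seed = 3L, noise_sd = 0, monthly_noise_sd = 0)
  corridor <- make_corridor(cfg)
  drivers <- simulate_drivers(cfg, corridor)
  q0 <- rseicorridor:::compute_latent(cfg, corridor, drivers, 2003)
  px <- which(corridor$buffer_mask & corridor$section == "north" &
                q0 > 0.1 & q0 < 0.9)[1]
  drivers2 <- drivers
  for (ey in names(drivers2$epochs))
    drivers2$epochs[[ey]]$precipitation[px] <-
      drivers2$epochs[[ey]]$precipitation[px] + 50
  q1 <- rseicorridor:::compute_latent(cfg, corridor, drivers2, 2003)
  expect_gt(q1[px], q0[px])
})

test_that("noiseless planted slopes are recovered exactly per pixel", {
  # effect_scale 0: drivers change across epochs, so only the pure-trend
  # construction is exactly linear in time
  cfg <- tiny_config(seed = 4L, noise_sd = 0, monthly_noise_sd = 0,
                     trend_slopes = c(north = 0.015, south = 0.015),
                     section_gap = 0, effect_scale = 0,
                     anchor_extremes = FALSE)
  corridor <- make_corridor(cfg)
  drivers <- simulate_drivers(cfg, corridor)
  sim <- simulate_scenes(cfg, corridor, drivers)
  px <- which(corridor$buffer_mask)[c(1, 50, 200)]
  for (p in px) {
    series <- sim$truth$latent[(seq_along(cfg$years) - 1) *
                                 prod(cfg$grid_shape) + p]
    # noiseless: lm warns about the perfect fit, which is the point here
    fit <- suppressWarnings(ols_trend(series, cfg$years))
    expect_equal(fit$slope_decade, 0.015, tolerance = 1e-10)
  }
})

test_that("index consistency: noiseless NDVI is strictly monotone in latent quality", {
  cfg <- tiny_config(seed = 5L, noise_sd = 0, monthly_noise_sd = 0)
  corridor <- make_corridor(cfg)
  drivers <- simulate_drivers(cfg, corridor)
  sim <- simulate_scenes(cfg, corridor, drivers)
  sc <- sim$scenes[[1]]
  nd <- ndvi(sc$B1, sc$B2)
  q <- sim$truth$latent[, , 1]
  sel <- corridor$buffer_mask
  expect_equal(cor(nd[sel], q[sel], method = "spearman"), 1.0)
})

test_that("all-zero effect mappings warn that attribution is untestable", {
  cfg <- tiny_config(north_effects = c(precipitation = 0),
                     south_effects = c(nighttime_light = 0))
  corridor <- make_corridor(cfg)
  drivers <- simulate_drivers(cfg, corridor)
  expect_warning(simulate_scenes(cfg, corridor, drivers), "untestable")
})
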
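#' Configuration for the synthetic corridor landscape
#'
#' Describes a rectangular grid crossed lengthwise by a canal-like
#' centerline, with a north and a south section, spatially autocorrelated
#' driver fields, and a latent ecological-quality surface with planted
#' structure: a mean north-south gap, section-specific driver effects
#' (precipitation-dominated in the north, nighttime-light-suppressed in the
#' south by default), and per-decade temporal trends of known sign.
#'
#' The temporal trend term is centered on the middle year so that the
#' long-term mean gap between sections equals `section_gap` exactly; the
#' per-pixel slope is unaffected by the centering.
#'
#' @param grid_shape integer vector `c(rows, cols)`; rows run across the
#'   corridor, columns along it.
#' @param pixel_size pixel edge length in metres.
#' @param years integer years simulated.
#' @param epoch_years years at which driver layers are available
#'   (five-yearly by default, mirroring national gridded products).
#' @param seed integer master seed; all stages derive their own sub-seed.
#' @param section_gap planted difference in mean latent quality
#'   (south minus north, dimensionless).
#' @param north_effects,south_effects named numeric vectors mapping driver
#'   names to effect sizes on latent quality (standardized scale).
#' @param noise_sd per-pixel-year latent noise standard deviation.
#' @param trend_slopes named vector `c(north=, south=)`, latent slope per
#'   decade.
#' @param smoothing_scale spatial autocorrelation range of the driver
#'   fields, in pixels; `0` gives white noise.
#' @param effect_scale multiplier converting standardized driver effects to
#'   latent-quality units. The default is calibrated once so that the
#'   latent field spans roughly the full unit interval inside the buffer
#'   (the corridor runs the gamut from degraded urban to pristine pixels);
#'   because RSEI min-max rescales PC1 per year, the planted section gap is
#'   only identifiable on the RSEI scale when the latent range is ~1.
#' @param monthly_noise_sd reflectance noise added to each monthly scene.
#' @param months_per_year number of monthly scenes averaged into the
#'   growing-season composite.
#' @param base_quality latent mean of the northern section.
#' @param buffer_km half-width of the corridor buffer, km.
#' @param belt_m width of the distance belts, metres.
#' @param water_strip plant a narrow water strip along the centerline in
#'   the land-use layer.
#' @param anchor_extremes plant a small fully-degraded (quality 0) and a
#'   pristine (quality 1) reference patch per section, so the latent field
#'   attains the unit interval's endpoints and the per-year min-max rescale
#'   behind RSEI does not stretch the planted section gap.
#' @param driver_means,driver_sds named lists of `c(north=, south=)` target
#'   means / standard deviations for the continuous drivers.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(60L, 200L),
                             pixel_size = 500,
                             years = 2000:2020,
                             epoch_years = c(2000, 2005, 2010, 2015, 2020),
                             seed = 1L,
                             section_gap = 0.08,
                             north_effects = c(precipitation = 0.5,
                                               temperature = 0.25,
                                               DEM = -0.10,
                                               nighttime_light = -0.05,
                                               GDP = 0.02),
                             south_effects = c(nighttime_light = -0.6,
                                               temperature = 0.2,
                                               slope = 0.10,
                                               GDP = -0.05,
                                               precipitation = 0.05),
                             noise_sd = 0.02,
                             trend_slopes = c(north = 0.015, south = -0.045),
                             smoothing_scale = 6,
                             effect_scale = 0.25,
                             monthly_noise_sd = 0.005,
                             months_per_year = 5L,
                             base_quality = 0.50,
                             buffer_km = 5,
                             belt_m = 500,
                             water_strip = TRUE,
                             anchor_extremes = TRUE,
                             driver_means = NULL,
                             driver_sds = NULL) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L),
            pixel_size > 0, length(years) >= 1L, buffer_km > 0, belt_m > 0)
  for (eff in list(north_effects, south_effects)) {
    bad <- setdiff(names(eff), DRIVER_NAMES)
    if (length(bad))
      stop("unknown driver name in effect mapping: ",
           paste(bad, collapse = ", "), " (declared drivers: ",
           paste(DRIVER_NAMES, collapse = ", "), ")")
  }
  if (!all(c("north", "south") %in% names(trend_slopes)))
    stop("trend_slopes must be named c(north=, south=)")

  means <- list(DEM = c(north = 45, south = 15),
                slope = c(north = 2.5, south = 2.0),
                precipitation = c(north = 600, south = 1200),
                temperature = c(north = 13, south = 17),
                GDP = c(north = 300, south = 800),
                population = c(north = 400, south = 900),
                nighttime_light = c(north = 5, south = 25))
  sds <- list(DEM = c(north = 12, south = 8),
              slope = c(north = 1.2, south = 1.0),
              precipitation = c(north = 80, south = 120),
              temperature = c(north = 1.0, south = 1.0),
              GDP = c(north = 150, south = 300),
              population = c(north = 200, south = 350),
              nighttime_light = c(north = 3, south = 12))
  if (!is.null(driver_means)) means[names(driver_means)] <- driver_means
  if (!is.null(driver_sds)) sds[names(driver_sds)] <- driver_sds

  structure(list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
                 years = as.integer(years),
                 epoch_years = as.integer(epoch_years), seed = as.integer(seed),
                 section_gap = section_gap, north_effects = north_effects,
                 south_effects = south_effects, noise_sd = noise_sd,
                 trend_slopes = trend_slopes,
                 smoothing_scale = smoothing_scale, effect_scale = effect_scale,
                 monthly_noise_sd = monthly_noise_sd,
                 months_per_year = as.integer(months_per_year),
                 base_quality = base_quality, buffer_km = buffer_km,
                 belt_m = belt_m, water_strip = water_strip,
                 anchor_extremes = anchor_extremes,
                 driver_means = means, driver_sds = sds),
            class = "synthetic_config")
}

# perpendicular distance from points (x, y) to a polyline (vertex matrix)
point_polyline_distance <- function(x, y, vertices) {
  d2 <- rep(Inf, length(x))
  for (s in seq_len(nrow(vertices) - 1L)) {
    ax <- vertices[s, 1]; ay <- vertices[s, 2]
    bx <- vertices[s + 1L, 1]; by <- vertices[s + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    d2 <- pmin(d2, (x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
  }
  sqrt(d2)
}

#' Build the corridor geometry: buffer, belts and sections
#'
#' Creates a 5-km (by default) bilateral buffer around the corridor
#' centerline, subdivides it into contiguous 500-m distance belts
#' (`belt_id = ceiling(distance / belt_m)`, clipped to the belt range), and
#' splits the corridor into a northern and a southern section at the
#' midpoint of the along-corridor axis (standing in for a climatic divide;
#' configurable via `split_x`).
#'
#' @param config a [synthetic_config()].
#' @param centerline optional polyline vertex matrix (columns x, y, metres);
#'   defaults to the horizontal midline of the grid.
#' @param split_x along-corridor coordinate of the north/south divide in
#'   metres; defaults to the middle of the grid.
#' @return an object of class `corridor_scene` with layers `distance`
#'   (metres), `buffer_mask` (logical), `belt_id` (integer, `NA` outside
#'   the buffer) and `section` (`"north"`/`"south"` character matrix).
#' @export
make_corridor <- function(config, centerline = NULL, split_x = NULL) {
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  px <- config$pixel_size
  buffer_m <- config$buffer_km * 1000
  need <- ceiling(2 * buffer_m / px) + 1L
  if (rows < need)
    stop("grid too small to contain a ", config$buffer_km,
         " km buffer: need at least ", need, " rows of ", px,
         " m pixels, got ", rows)

  xs <- (seq_len(cols) - 0.5) * px
  ys <- (seq_len(rows) - 0.5) * px
  x <- matrix(xs, rows, cols, byrow = TRUE)
  y <- matrix(ys, rows, cols)
  if (is.null(centerline))
    centerline <- cbind(x = c(0, cols * px), y = rep(rows * px / 2, 2))
  if (is.null(split_x)) split_x <- cols * px / 2

  distance <- matrix(point_polyline_distance(as.vector(x), as.vector(y),
                                             centerline), rows, cols)
  buffer_mask <- distance <= buffer_m
  n_belts <- as.integer(ceiling(buffer_m / config$belt_m))
  belt_id <- matrix(NA_integer_, rows, cols)
  belt_id[buffer_mask] <- pmin(pmax(
    as.integer(ceiling(distance[buffer_mask] / config$belt_m)), 1L), n_belts)
  section <- matrix(ifelse(x <= split_x, "north", "south"), rows, cols)

  structure(list(nrow = rows, ncol = cols, pixel_size = px,
                 centerline = centerline, split_x = split_x, x = x, y = y,
                 distance = distance, buffer_mask = buffer_mask,
                 belt_id = belt_id, section = section, n_belts = n_belts,
                 buffer_m = buffer_m, belt_m = config$belt_m),
            class = "corridor_scene")
}

#' Simulate the driver raster stack
#'
#' Generates the nine declared driver layers per epoch year as spatially
#' autocorrelated Gaussian fields with section-specific target means and
#' standard deviations. Topography (DEM, slope, aspect) is static and
#' replicated across epochs; climate and socioeconomic fields evolve
#' smoothly between epochs, with nighttime light, GDP and population
#' growing over time. Land use is categorical (cropland, forest, water,
#' built, grassland) with built-up cells clustered where nighttime light is
#' high and an optional water strip along the centerline.
#'
#' @param config a [synthetic_config()].
#' @param corridor a [make_corridor()] result.
#' @return an object of class `driver_stack`: a list with `epochs` (named
#'   list of per-epoch driver layer lists) and `epoch_years`.
#' @export
simulate_drivers <- function(config, corridor) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(corridor, "corridor_scene"))
  rows <- corridor$nrow; cols <- corridor$ncol
  north <- corridor$section == "north"
  sc <- config$smoothing_scale

  with_seed(derive_seed(config$seed, "drivers"), {
    sectioned <- function(field, mname) {
      m <- config$driver_means[[mname]]; s <- config$driver_sds[[mname]]
      out <- matrix(NA_real_, rows, cols)
      out[north] <- m[["north"]] + s[["north"]] * field[north]
      out[!north] <- m[["south"]] + s[["south"]] * field[!north]
      out
    }
    dem <- pmax(sectioned(gaussian_field(rows, cols, sc), "DEM"), 0)
    slope <- pmax(sectioned(abs(gaussian_field(rows, cols, sc)) - 0.7979,
                            "slope"), 0)
    aspect <- 360 * pnorm(gaussian_field(rows, cols, sc))
    forest_field <- gaussian_field(rows, cols, sc)

    base <- lapply(c(precipitation = "precipitation",
                     temperature = "temperature", GDP = "GDP",
                     population = "population",
                     nighttime_light = "nighttime_light"),
                   function(nm) gaussian_field(rows, cols, sc))

    epochs <- list()
    for (ey in config$epoch_years) {
      growth <- 1 + (ey - min(config$epoch_years)) /
        max(1, diff(range(config$epoch_years)))
      innov <- function(f) sqrt(0.9) * f + sqrt(0.1) * gaussian_field(rows, cols, sc)
      precipitation <- pmax(sectioned(innov(base$precipitation),
                                      "precipitation"), 0)
      temperature <- sectioned(innov(base$temperature), "temperature")
      gdp <- pmax(sectioned(innov(base$GDP), "GDP") * growth, 0)
      population <- pmax(sectioned(innov(base$population), "population") *
                           growth, 0)
      ntl <- pmax(sectioned(innov(base$nighttime_light), "nighttime_light") *
                    growth, 0)

      lu <- matrix(LAND_USE_CODES[["cropland"]], rows, cols)
      lu[forest_field > quantile(forest_field, 0.75)] <- LAND_USE_CODES[["forest"]]
      lu[forest_field < quantile(forest_field, 0.10)] <- LAND_USE_CODES[["grassland"]]
      lu[ntl > quantile(ntl, 0.85)] <- LAND_USE_CODES[["built"]]
      if (config$water_strip)
        lu[corridor$distance <= corridor$pixel_size * 0.6] <- LAND_USE_CODES[["water"]]

      epochs[[as.character(ey)]] <- list(
        DEM = dem, slope = slope, aspect = aspect,
        precipitation = precipitation, temperature = temperature,
        land_use = lu, GDP = gdp, population = population,
        nighttime_light = ntl)
    }
    structure(list(epochs = epochs, epoch_years = config$epoch_years),
              class = "driver_stack")
  })
}

nearest_epoch <- function(year, epoch_years) {
  epoch_years[which.min(abs(epoch_years - year))]
}

# standardize a driver layer with per-section statistics taken inside the
# analysis buffer, so the planted in-buffer section means of latent quality
# are exact by construction (out-of-buffer pixels reuse the same statistics)
standardize_by_section <- function(layer, north, buffer) {
  z <- layer
  for (sec in list(north, !north)) {
    v <- layer[sec & buffer]
    s <- sd(v)
    z[sec] <- if (s > 0) (layer[sec] - mean(v)) / s else 0
  }
  z
}

compute_latent <- function(config, corridor, drivers, year, noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- config$noise_sd
  rows <- corridor$nrow; cols <- corridor$ncol
  north <- corridor$section == "north"
  ey <- nearest_epoch(year, drivers$epoch_years)
  ep <- drivers$epochs[[as.character(ey)]]
  mid_year <- mean(range(config$years))

  q <- matrix(config$base_quality, rows, cols)
  q[!north] <- q[!north] + config$section_gap
  for (sec in c("north", "south")) {
    idx <- if (sec == "north") north else !north
    eff <- config[[paste0(sec, "_effects")]]
    for (f in names(eff)) {
      z <- standardize_by_section(ep[[f]], north, corridor$buffer_mask)
      q[idx] <- q[idx] + config$effect_scale * eff[[f]] * z[idx]
    }
    q[idx] <- q[idx] +
      config$trend_slopes[[sec]] * (year - mid_year) / 10
  }
  if (noise_sd > 0) q <- q + matrix(rnorm(rows * cols, sd = noise_sd), rows, cols)
  q <- pmin(pmax(q, 0), 1)
  if (isTRUE(config$anchor_extremes)) {
    for (sec in c("north", "south")) {
      a <- anchor_pixels(corridor, sec)
      q[a$low] <- 0
      q[a$high] <- 1
    }
  }
  q
}

# Planted reference extremes: each section carries a small fully degraded
# patch (quality 0, an urban-core analogue) and a pristine patch (quality 1,
# a wetland analogue), so the per-year latent field attains both ends of the
# unit interval.  RSEI is defined through a per-year min-max rescale of PC1;
# without in-buffer extremes that rescale would stretch the smooth latent
# field's narrow range and bias the recovered section gap upward.  The
# patches sit symmetrically around mid-quality, so section means shift by
# (0 - mu) + (1 - mu) ~ 0 per section.
anchor_pixels <- function(corridor, sec) {
  idx <- which(corridor$buffer_mask & corridor$section == sec)
  k <- 4L
  list(low = idx[seq(round(length(idx) * 0.3), length.out = k)],
       high = idx[seq(round(length(idx) * 0.7), length.out = k)])
}

# bands as monotone functions of latent quality q: NDVI and WET increase
# with q, LST and NDBSI decrease.
bands_from_latent <- function(q) {
  list(B1 = 0.30 - 0.25 * q,   # red
       B2 = 0.30 + 0.25 * q,   # NIR
       B3 = 0.10 - 0.02 * q,   # blue
       B4 = matrix(0.12, nrow(q), ncol(q)),  # green
       B5 = matrix(0.25, nrow(q), ncol(q)),  # NIR2
       B6 = 0.40 - 0.25 * q,   # SWIR1
       B7 = 0.30 - 0.20 * q)   # SWIR2
}

#' Simulate annual reflectance scenes with a known latent quality
#'
#' Builds, for every simulated year, `months_per_year` monthly band scenes
#' as monotone functions of the latent ecological quality plus reflectance
#' noise, composites them into an annual growing-season mean scene, and
#' records the planted truth. Latent quality is a section-specific linear
#' combination of section-standardized drivers (nearest epoch), plus a
#' mid-year-centered per-decade trend and pixel noise, clipped to \[0, 1\].
#'
#' @param config a [synthetic_config()].
#' @param corridor a [make_corridor()] result.
#' @param drivers a [simulate_drivers()] result.
#' @return list with `scenes` (one `annual_scene` per year) and `truth`
#'   (class `synthetic_truth`: the latent array, dominant drivers, effect
#'   signs, planted slopes and seed).
#' @export
simulate_scenes <- function(config, corridor, drivers) {
  stopifnot(inherits(drivers, "driver_stack"))
  if (all(c(config$north_effects, config$south_effects) == 0))
    warning("all driver effect sizes are zero; attribution recovery is untestable")
  rows <- corridor$nrow; cols <- corridor$ncol

  with_seed(derive_seed(config$seed, "scenes"), {
    latent <- array(NA_real_, c(rows, cols, length(config$years)),
                    dimnames = list(NULL, NULL, config$years))
    scenes <- vector("list", length(config$years))
    for (k in seq_along(config$years)) {
      year <- config$years[k]
      q <- compute_latent(config, corridor, drivers, year)
      latent[, , k] <- q
      monthly <- vector("list", config$months_per_year)
      for (m in seq_len(config$months_per_year)) {
        b <- bands_from_latent(q)
        if (config$monthly_noise_sd > 0)
          b <- lapply(b, function(layer) pmin(pmax(
            layer + matrix(rnorm(rows * cols, sd = config$monthly_noise_sd),
                           rows, cols), 0), 1))
        lst_c <- 35 - 15 * q
        if (config$monthly_noise_sd > 0)
          lst_c <- lst_c + matrix(rnorm(rows * cols,
                                        sd = 50 * config$monthly_noise_sd),
                                  rows, cols)
        monthly[[m]] <- annual_scene(b, lst_dn = (lst_c + 273.15) * 50,
                                     year = year)
      }
      scenes[[k]] <- growing_season_composite(monthly)
    }
    names(scenes) <- as.character(config$years)

    dominant <- c(
      north = names(config$north_effects)[which.max(abs(config$north_effects))],
      south = names(config$south_effects)[which.max(abs(config$south_effects))])
    truth <- structure(list(latent = latent, dominant_driver = dominant,
                            effect_signs = list(
                              north = sign(config$north_effects),
                              south = sign(config$south_effects)),
                            planted_slopes = config$trend_slopes,
                            section_gap = config$section_gap,
                            seed = config$seed),
                       class = "synthetic_truth")
    list(scenes = scenes, truth = truth)
  })
}
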
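#' Construct an annual scene
#'
#' Bundles the seven reflectance bands (band roles fixed by position: B1
#' red, B2 NIR, B3 blue, B4 green, B5 NIR2, B6 SWIR1, B7 SWIR2) and the
#' land-surface-temperature digital-number layer on a common grid.
#'
#' @param bands named list `B1`..`B7` of congruent reflectance matrices in
#'   \[0, 1\] (`NA` = nodata).
#' @param lst_dn land-surface-temperature digital numbers (Kelvin x 50).
#' @param year integer year label.
#' @return object of class `annual_scene`.
#' @export
annual_scene <- function(bands, lst_dn, year) {
  stopifnot(setequal(names(bands), paste0("B", 1:7)))
  do.call(check_congruent, c(unname(bands), list(lst_dn)))
  rng <- range(unlist(lapply(bands, range, na.rm = TRUE)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("reflectance outside [0, 1]: range ", rng[1], "..", rng[2])
  structure(c(bands[paste0("B", 1:7)],
              list(LST_DN = lst_dn, year = as.integer(year))),
            class = "annual_scene")
}

#' Normalized Difference Vegetation Index
#'
#' `(NIR - red) / (NIR + red)`; pixels where the denominator is zero become
#' nodata.
#' @param red,nir congruent reflectance layers.
#' @return NDVI layer in \[-1, 1\].
#' @export
ndvi <- function(red, nir) {
  check_congruent(red, nir)
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Land surface temperature in Celsius from digital numbers
#'
#' `DN * 0.02 - 273.15`; negative digital numbers become nodata.
#' @param dn digital-number layer.
#' @return LST layer in degrees Celsius.
#' @export
lst_celsius <- function(dn) {
  out <- dn * 0.02 - 273.15
  out[!is.na(dn) & dn < 0] <- NA_real_
  out
}

#' Bare soil index (SI)
#'
#' `((B1 + B6) - (B2 + B3)) / ((B1 + B6) + (B2 + B3))`; zero denominators
#' become nodata.
#' @param b1,b6,b2,b3 congruent reflectance layers (red, SWIR1, NIR, blue).
#' @return SI layer.
#' @export
soil_index <- function(b1, b6, b2, b3) {
  check_congruent(b1, b6, b2, b3)
  a <- b1 + b6; b <- b2 + b3
  den <- a + b
  out <- (a - b) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Index-based built-up index (IBI)
#'
#' `(A - B) / (A + B)` with `A = 2 B6 / (B2 + B6)` and
#' `B = B2 / (B1 + B2) + B4 / (B4 + B6)`; any zero inner denominator makes
#' the pixel nodata.
#' @param b1,b2,b4,b6 congruent reflectance layers (red, NIR, green, SWIR1).
#' @return IBI layer.
#' @export
ibi <- function(b1, b2, b4, b6) {
  check_congruent(b1, b2, b4, b6)
  d1 <- b2 + b6; d2 <- b1 + b2; d3 <- b4 + b6
  a <- 2 * b6 / d1
  b <- b2 / d2 + b4 / d3
  out <- (a - b) / (a + b)
  bad <- (!is.na(d1) & d1 == 0) | (!is.na(d2) & d2 == 0) |
    (!is.na(d3) & d3 == 0)
  out[bad] <- NA_real_
  out
}

#' Normalized difference bare soil index (NDBSI)
#'
#' Elementwise mean of SI and IBI; nodata in either input propagates.
#' @param si,ibi congruent SI and IBI layers.
#' @return NDBSI layer.
#' @export
ndbsi <- function(si, ibi) {
  check_congruent(si, ibi)
  (si + ibi) / 2
}

# tasseled-cap wetness coefficients for the seven reflectance bands
WET_COEF <- c(0.1147, 0.2489, 0.2408, 0.3132, -0.3122, -0.6416, -0.5087)

#' Tasseled-cap wetness (WET)
#'
#' Fixed linear combination of the seven reflectance bands with
#' coefficients `(0.1147, 0.2489, 0.2408, 0.3132, -0.3122, -0.6416,
#' -0.5087)`.
#' @param b1,b2,b3,b4,b5,b6,b7 congruent reflectance layers.
#' @return WET layer.
#' @export
wetness <- function(b1, b2, b3, b4, b5, b6, b7) {
  check_congruent(b1, b2, b3, b4, b5, b6, b7)
  WET_COEF[1] * b1 + WET_COEF[2] * b2 + WET_COEF[3] * b3 + WET_COEF[4] * b4 +
    WET_COEF[5] * b5 + WET_COEF[6] * b6 + WET_COEF[7] * b7
}

#' Growing-season composite of monthly scenes
#'
#' Per-pixel, per-band mean over the supplied scenes, ignoring nodata
#' months; a pixel with no valid month is nodata.
#' @param scenes non-empty list of congruent [annual_scene()] objects
#'   (typically monthly scenes of one year).
#' @return an [annual_scene()] carrying the per-pixel means.
#' @export
growing_season_composite <- function(scenes) {
  stopifnot(length(scenes) >= 1L)
  layer_names <- c(paste0("B", 1:7), "LST_DN")
  out <- lapply(layer_names, function(nm) {
    stack <- lapply(scenes, `[[`, nm)
    do.call(check_congruent, stack)
    total <- Reduce(`+`, lapply(stack, function(m) ifelse(is.na(m), 0, m)))
    count <- Reduce(`+`, lapply(stack, function(m) !is.na(m)))
    res <- total / count
    res[count == 0] <- NA_real_
    res
  })
  names(out) <- layer_names
  annual_scene(out[paste0("B", 1:7)], out$LST_DN, scenes[[1]]$year)
}

#' Min-max normalization of a layer
#'
#' `(x - min) / (max - min)` with statistics taken over valid pixels inside
#' `mask` (the analysis buffer); a constant layer is a degenerate input.
#' @param layer numeric layer.
#' @param mask optional logical layer restricting where statistics are
#'   computed (values outside are still rescaled with the same statistics).
#' @return normalized layer with attributes `min` and `max`.
#' @export
minmax_normalize <- function(layer, mask = NULL) {
  v <- if (is.null(mask)) layer else layer[mask]
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop_degenerate("fewer than 2 valid pixels to normalize")
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop_degenerate("constant layer: min-max range is zero")
  out <- (layer - lo) / (hi - lo)
  attr(out, "min") <- lo
  attr(out, "max") <- hi
  out
}

#' Compute the four RSEI component indices of a scene
#'
#' @param scene an [annual_scene()].
#' @return list of class `index_layers` with `NDVI`, `WET`, `LST` (deg C),
#'   `SI`, `IBI`, `NDBSI` and `year`.
#' @export
compute_index_layers <- function(scene) {
  stopifnot(inherits(scene, "annual_scene"))
  si <- soil_index(scene$B1, scene$B6, scene$B2, scene$B3)
  ib <- ibi(scene$B1, scene$B2, scene$B4, scene$B6)
  structure(list(NDVI = ndvi(scene$B1, scene$B2),
                 WET = wetness(scene$B1, scene$B2, scene$B3, scene$B4,
                               scene$B5, scene$B6, scene$B7),
                 LST = lst_celsius(scene$LST_DN),
                 SI = si, IBI = ib, NDBSI = ndbsi(si, ib),
                 year = scene$year),
            class = "index_layers")
}

#' Min-max normalize the four RSEI components
#'
#' @param indices an [compute_index_layers()] result.
#' @param mask optional logical analysis mask (statistics are computed
#'   within it, per year).
#' @return list of class `normalized_indices` with layers `NDVI`, `WET`,
#'   `LST`, `NDBSI` in \[0, 1\], the recorded `ranges`, and `year`.
#' @export
normalize_indices <- function(indices, mask = NULL) {
  stopifnot(inherits(indices, "index_layers"))
  nm <- c("NDVI", "WET", "LST", "NDBSI")
  out <- lapply(indices[nm], minmax_normalize, mask = mask)
  ranges <- lapply(out, function(x) c(min = attr(x, "min"), max = attr(x, "max")))
  structure(c(out, list(ranges = ranges, year = indices$year)),
            class = "normalized_indices")
}
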
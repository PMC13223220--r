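#' First principal component of the four normalized indices
#'
#' Covariance-matrix PCA (centered, not re-standardized) over valid pixels:
#' the component order is NDVI, WET, LST, NDBSI. Pixels with nodata in any
#' index, or outside `mask`, are excluded from both covariance estimation
#' and scoring.
#'
#' @param normalized a [normalize_indices()] result (or a list with the
#'   four layers).
#' @param mask optional logical analysis mask.
#' @return object of class `pca_result`: unit-norm `loadings` (4-vector),
#'   `eigenvalues` (descending), `variance_ratio` (first eigenvalue over
#'   the total), `pc1_layer`, `oriented = FALSE` and `year`.
#' @export
pca_pc1 <- function(normalized, mask = NULL) {
  nm <- c("NDVI", "WET", "LST", "NDBSI")
  layers <- normalized[nm]
  do.call(check_congruent, unname(layers))
  valid <- Reduce(`&`, lapply(layers, function(x) is.finite(x)))
  if (!is.null(mask)) valid <- valid & mask
  idx <- which(valid)
  if (length(idx) < 4L)
    stop_degenerate("fewer than 4 valid pixels for PCA")
  M <- vapply(layers, function(x) x[idx], numeric(length(idx)))
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  if (sum(eig) <= 0) stop_degenerate("zero total variance: PCA undefined")
  pc1 <- matrix(NA_real_, nrow(layers$NDVI), ncol(layers$NDVI))
  pc1[idx] <- pc$x[, 1]
  structure(list(loadings = setNames(pc$rotation[, 1], nm),
                 eigenvalues = eig,
                 variance_ratio = eig[1] / sum(eig),
                 pc1_layer = pc1, oriented = FALSE,
                 year = normalized$year),
            class = "pca_result")
}

#' Orient PC1 so that greenness loads positively
#'
#' If the NDVI loading is negative the loadings and score layer are
#' negated; a zero NDVI loading falls back to the WET sign. After
#' orientation a warning is emitted when the sign pattern differs from the
#' ecologically expected `(+, +, -, -)` for (NDVI, WET, LST, NDBSI).
#'
#' @param pca a [pca_pc1()] result.
#' @return the oriented `pca_result` (`oriented = TRUE`).
#' @export
orient_loadings <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  ref <- pca$loadings[["NDVI"]]
  if (ref == 0) ref <- pca$loadings[["WET"]]
  if (ref < 0) {
    pca$loadings <- -pca$loadings
    pca$pc1_layer <- -pca$pc1_layer
  }
  pca$oriented <- TRUE
  expected <- c(1, 1, -1, -1)
  got <- sign(pca$loadings)
  if (any(got != expected & got != 0))
    warning(warningCondition(
      paste0("PC1 loading sign pattern (", paste(got, collapse = ", "),
             ") deviates from expected (+, +, -, -) for year ",
             pca$year %||% "?"),
      class = "rsei_sign_warning"))
  pca
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rescale PC1 scores to the RSEI range
#'
#' `RSEI = (PC1 - min) / (max - min)` over valid pixels, so the layer
#' attains both 0 and 1; values closer to 1 indicate higher ecological
#' quality.
#' @param pc1_layer PC1 score layer.
#' @return RSEI layer in \[0, 1\] with attributes `pc1_min`, `pc1_max`.
#' @export
rescale_rsei <- function(pc1_layer) {
  out <- minmax_normalize(pc1_layer)
  attr(out, "pc1_min") <- attr(out, "min")
  attr(out, "pc1_max") <- attr(out, "max")
  out
}

#' Classify RSEI into the five ecological-quality levels
#'
#' Equal 0.2-wide intervals: poor \[0, 0.2), fair \[0.2, 0.4), moderate
#' \[0.4, 0.6), good \[0.6, 0.8), excellent \[0.8, 1\]. Intervals are
#' left-closed, right-open except the last, which is closed.
#' @param rsei_layer RSEI layer in \[0, 1\].
#' @return integer class layer (1 = poor .. 5 = excellent) with the level
#'   names in attribute `levels`.
#' @export
classify_rsei <- function(rsei_layer) {
  v <- rsei_layer[is.finite(rsei_layer)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("RSEI values outside [0, 1]")
  cls <- matrix(NA_integer_, nrow(rsei_layer), ncol(rsei_layer))
  ok <- is.finite(rsei_layer)
  # findInterval compares against the exact break values (no division), so
  # boundary pixels like 0.6 land in the left-closed interval they open
  cls[ok] <- findInterval(rsei_layer[ok], c(0, 0.2, 0.4, 0.6, 0.8))
  attr(cls, "levels") <- RSEI_CLASS_LEVELS
  cls
}

#' Per-year RSEI compositing pipeline
#'
#' For each annual scene: compute the four component indices, min-max
#' normalize them within the analysis mask, run covariance PCA, orient the
#' loadings, rescale PC1 to \[0, 1\] and classify. A warning (class
#' `rsei_variance_warning`) is emitted when the PC1 variance ratio falls
#' outside the 0.70-0.85 band typical of RSEI applications; the run
#' continues.
#'
#' @param scenes list of [annual_scene()] objects (one per year).
#' @param mask optional logical analysis mask (e.g. the corridor buffer).
#' @param variance_band numeric length-2; warn outside this variance-ratio
#'   interval.
#' @return list of `rsei_result` objects: `rsei_layer`, integer
#'   `class_layer`, `pc1_min`, `pc1_max`, `pca`, `year`.
#' @export
rsei_per_year <- function(scenes, mask = NULL, variance_band = c(0.70, 0.85)) {
  out <- lapply(scenes, function(scene) {
    indices <- compute_index_layers(scene)
    normalized <- normalize_indices(indices, mask = mask)
    pca <- orient_loadings(pca_pc1(normalized, mask = mask))
    if (pca$variance_ratio < variance_band[1] ||
        pca$variance_ratio > variance_band[2])
      warning(warningCondition(
        sprintf("PC1 variance ratio %.3f outside [%.2f, %.2f] for year %s",
                pca$variance_ratio, variance_band[1], variance_band[2],
                scene$year),
        class = "rsei_variance_warning"))
    rsei <- rescale_rsei(pca$pc1_layer)
    structure(list(rsei_layer = rsei, class_layer = classify_rsei(rsei),
                   pc1_min = attr(rsei, "pc1_min"),
                   pc1_max = attr(rsei, "pc1_max"),
                   pca = pca, year = scene$year),
              class = "rsei_result")
  })
  names(out) <- vapply(scenes, function(s) as.character(s$year), character(1))
  out
}
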
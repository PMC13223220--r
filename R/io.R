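#' Product profiles: scale/offset decoding applied on read
#'
#' `reflectance` decodes digital numbers times 0.0001; `lst` decodes
#' `DN * 0.02 - 273.15` to degrees Celsius; `none` reads values verbatim.
#' @param name `"none"`, `"reflectance"` or `"lst"`.
#' @return list with `scale` and `offset`.
#' @export
product_profile <- function(name = c("none", "reflectance", "lst")) {
  name <- match.arg(name)
  switch(name,
         none = list(scale = 1, offset = 0),
         reflectance = list(scale = 1e-4, offset = 0),
         lst = list(scale = 0.02, offset = -273.15))
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster exchange format: a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from the
#' top of the grid down. Integer layers round-trip bit-exactly.
#'
#' @param layer numeric or integer matrix (row 1 = top).
#' @param path output file path.
#' @param pixel_size cell size in metres.
#' @param xll,yll lower-left corner coordinates.
#' @param nodata nodata sentinel written for `NA`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, pixel_size = 500, xll = 0, yll = 0,
                         nodata = -9999) {
  header <- c(paste("ncols", ncol(layer)), paste("nrows", nrow(layer)),
              paste("xllcorner", xll), paste("yllcorner", yll),
              paste("cellsize", pixel_size), paste("NODATA_value", nodata))
  vals <- layer
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1L, function(r)
    paste(formatC(r, format = if (is.integer(layer)) "d" else "g",
                  digits = 17), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param profile optional [product_profile()] (or its name) applied as
#'   `value * scale + offset` after nodata masking.
#' @param integer coerce values to integer (for class rasters).
#' @return matrix with attributes `pixel_size`, `xll`, `yll`.
#' @export
read_raster <- function(path, profile = NULL, integer = FALSE) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(header, `[[`, character(1), 1L))
  vals <- as.numeric(vapply(header, `[[`, character(1), 2L))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nrows * ncols)
  m <- matrix(body, nrows, ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (!is.null(profile)) {
    if (is.character(profile)) profile <- product_profile(profile)
    m <- m * profile$scale + profile$offset
  }
  if (integer) storage.mode(m) <- "integer"
  attr(m, "pixel_size") <- vals[["cellsize"]]
  attr(m, "xll") <- vals[["xllcorner"]]
  attr(m, "yll") <- vals[["yllcorner"]]
  m
}

#' Read a stack of rasters, enforcing grid congruence
#'
#' @param paths named character vector of file paths.
#' @param profile optional profile applied to every layer.
#' @return named list of matrices.
#' @export
read_raster_stack <- function(paths, profile = NULL) {
  layers <- lapply(paths, read_raster, profile = profile)
  dims <- vapply(layers, function(x) paste(dim(x), collapse = "x"), character(1))
  if (length(unique(dims)) > 1L)
    stop("mismatched grids in raster stack: ",
         paste(unique(dims), collapse = " vs "))
  layers
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return named list of configuration values.
#' @export
load_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
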
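#' Belt statistics of RSEI across the corridor buffer
#'
#' Mean, standard deviation and pixel count of RSEI grouped by section and
#' distance belt, per year (or for a single layer). Empty belts are kept
#' with `n = 0` and `NA` statistics so the partition is explicit.
#'
#' @param rsei_layers a single RSEI layer, or a list of `rsei_result`
#'   objects / layers (one per year).
#' @param corridor a [make_corridor()] result.
#' @param cumulative if `TRUE`, belt `k` aggregates all pixels within the
#'   first `k` belts ("within 2000 m" style); default is per-belt.
#' @return data frame with columns `section`, `belt`, `year`, `mean`, `sd`,
#'   `n`.
#' @export
belt_statistics <- function(rsei_layers, corridor, cumulative = FALSE) {
  stopifnot(inherits(corridor, "corridor_scene"))
  layers <- as_layer_list(rsei_layers)
  res <- list()
  for (yr in names(layers)) {
    layer <- layers[[yr]]
    check_congruent(layer, corridor$belt_id)
    for (sec in c("north", "south")) {
      for (b in seq_len(corridor$n_belts)) {
        sel <- corridor$buffer_mask & corridor$section == sec &
          (if (cumulative) corridor$belt_id <= b else corridor$belt_id == b)
        v <- layer[sel & !is.na(corridor$belt_id)]
        v <- v[is.finite(v)]
        res[[length(res) + 1L]] <- data.frame(
          section = sec, belt = b, year = yr,
          mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) > 1) sd(v) else if (length(v)) 0 else NA_real_,
          n = length(v))
      }
    }
  }
  do.call(rbind, res)
}

as_layer_list <- function(x) {
  if (is.matrix(x)) return(list(layer = x))
  stopifnot(is.list(x))
  out <- lapply(x, function(el)
    if (inherits(el, "rsei_result")) el$rsei_layer else el)
  if (is.null(names(out)) || any(names(out) == ""))
    names(out) <- as.character(seq_along(out))
  out
}

#' Section summary: long-term means, variability and class composition
#'
#' Per section, the long-term mean is the mean of the annual section means,
#' the interannual sd is the sd across those annual means, and the
#' coefficient of variation is `100 * sd / mean`. The cross-section
#' difference (south minus north) is tested with Welch's two-sample t-test
#' on the annual means. Class area fractions are pooled over years.
#'
#' @param rsei_results list of `rsei_result` objects (>= 2 years).
#' @param corridor a [make_corridor()] result.
#' @param pooled if `TRUE`, long-term statistics pool all pixel-years
#'   instead of averaging annual means.
#' @return list of class `section_summary`: `annual_means` (data frame),
#'   per-section `mean`, `sd`, `cv_pct`, `class_fractions_pct`, and
#'   `difference`, `welch_t`, `welch_p`.
#' @export
section_summary <- function(rsei_results, corridor, pooled = FALSE) {
  stopifnot(length(rsei_results) >= 2L)
  layers <- as_layer_list(rsei_results)
  years <- names(layers)
  sec_mean <- function(layer, sec) {
    v <- layer[corridor$buffer_mask & corridor$section == sec]
    mean(v[is.finite(v)])
  }
  annual <- data.frame(
    year = years,
    north = vapply(layers, sec_mean, numeric(1), sec = "north"),
    south = vapply(layers, sec_mean, numeric(1), sec = "south"),
    row.names = NULL)

  stats_for <- function(sec) {
    if (pooled) {
      v <- unlist(lapply(layers, function(l)
        l[corridor$buffer_mask & corridor$section == sec]))
      v <- v[is.finite(v)]
    } else v <- annual[[sec]]
    c(mean = mean(v), sd = sd(v), cv_pct = 100 * sd(v) / mean(v))
  }
  north <- stats_for("north"); south <- stats_for("south")

  fractions <- lapply(c(north = "north", south = "south"), function(sec) {
    counts <- integer(length(RSEI_CLASS_LEVELS))
    for (res in rsei_results) {
      if (!inherits(res, "rsei_result")) next
      cls <- res$class_layer[corridor$buffer_mask & corridor$section == sec]
      cls <- cls[!is.na(cls)]
      counts <- counts + tabulate(cls, nbins = length(RSEI_CLASS_LEVELS))
    }
    if (sum(counts) == 0) return(setNames(rep(NA_real_, 5), RSEI_CLASS_LEVELS))
    setNames(100 * counts / sum(counts), RSEI_CLASS_LEVELS)
  })

  tt <- tryCatch(t.test(annual$south, annual$north),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  structure(list(annual_means = annual,
                 north = north, south = south,
                 class_fractions_pct = fractions,
                 difference = south[["mean"]] - north[["mean"]],
                 welch_t = unname(tt$statistic), welch_p = tt$p.value),
            class = "section_summary")
}

#' Area fractions of the RSEI quality classes
#'
#' @param class_layer integer class layer from [classify_rsei()].
#' @param corridor a [make_corridor()] result.
#' @param section optional `"north"` or `"south"` to restrict the domain.
#' @return named percentage vector over the five classes (sums to 100).
#' @export
area_fractions <- function(class_layer, corridor, section = NULL) {
  sel <- corridor$buffer_mask
  if (!is.null(section)) sel <- sel & corridor$section == section
  cls <- class_layer[sel]
  cls <- cls[!is.na(cls)]
  if (!length(cls))
    stop("no valid classified pixels in ",
         if (is.null(section)) "buffer" else paste(section, "section"))
  setNames(100 * tabulate(cls, nbins = length(RSEI_CLASS_LEVELS)) /
             length(cls), RSEI_CLASS_LEVELS)
}
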
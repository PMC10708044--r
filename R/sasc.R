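#' Score SFDI values for the statistics correction
#'
#' Higher SFDI means more severe damage and therefore a *lower* score, so
#' the most damaged pixels enter the area accumulation first: SFDI >= 16
#' scores 1, 15 <= SFDI < 16 scores 2, and so on down to 1 <= SFDI < 2
#' scoring 16. Pixels with SFDI < 1 (or missing) are unscored (`NA`) and
#' treated as non-affected.
#'
#' @param sfdi Numeric vector of SFDI values (NA = nodata).
#' @return Integer scores in 1..16, `NA` where unscored.
#' @examples
#' score_sfdi(c(16, 15, 1, 0.99))  # 1 2 16 NA
#' @export
score_sfdi <- function(sfdi) {
  score <- ifelse(sfdi >= 16, 1L, 17L - floor(sfdi))
  score[is.na(sfdi) | sfdi < 1] <- NA_integer_
  as.integer(score)
}

new_sasc_result <- function(selected_area, target_area, n_pixels_selected,
                            cutoff_score, class_areas) {
  structure(
    list(
      selected_area = selected_area,
      target_area = target_area,
      n_pixels_selected = n_pixels_selected,
      cutoff_score = cutoff_score,
      residual = selected_area - target_area,
      class_areas = class_areas
    ),
    class = "sasc_result"
  )
}

#' Self-adapting statistics correction: area-matched pixel selection
#'
#' Accumulates crop area over SFDI score classes, most-damaged class first,
#' and stops at the whole-class cutoff whose cumulative winter-wheat area
#' (`sum(crop_fraction * pixel_area_mu)` over selected pixels) is closest to
#' the official statistical area. On a tie between two cutoffs the smaller
#' (more conservative) selection wins. With `partial = TRUE` the final class
#' is additionally filled pixel-by-pixel in decreasing SFDI order, stopping
#' at the pixel count minimizing the area mismatch. Deterministic: identical
#' inputs give identical output.
#'
#' @param pixels Tibble with columns `row`, `col`, `sfdi`, `crop_fraction`
#'   and `pixel_area_mu` (per-pixel area in mu). A `score` column is computed
#'   with [score_sfdi()] if absent.
#' @param target_area_mu Official affected area to match, in mu (> 0).
#' @param partial Allow within-class refinement of the last class.
#' @return A list with `result` (an `sasc_result`; supports [tidy()] and
#'   [glance()]) and `pixels` (the input with `score` and `selected` columns).
#' @export
sasc_select <- function(pixels, target_area_mu, partial = FALSE) {
  require_columns(pixels, c("row", "col", "sfdi", "crop_fraction",
                            "pixel_area_mu"), "pixel table")
  if (!is.numeric(target_area_mu) || target_area_mu <= 0) {
    abort("`target_area_mu` must be a positive area in mu.")
  }
  if (any(pixels$crop_fraction < 0 | pixels$crop_fraction > 1, na.rm = TRUE)) {
    abort("`crop_fraction` must lie in [0, 1].")
  }
  if (!"score" %in% names(pixels)) {
    pixels <- dplyr::mutate(pixels, score = score_sfdi(.data$sfdi))
  }
  pixels <- dplyr::mutate(pixels,
                          wheat_area = .data$crop_fraction * .data$pixel_area_mu)
  scored <- dplyr::filter(pixels, !is.na(.data$score))
  if (nrow(scored) == 0L) {
    abort("No scored pixels (all SFDI < 1 or nodata); nothing to select.")
  }
  class_areas <- scored |>
    dplyr::group_by(score = .data$score) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      area_mu = sum(.data$wheat_area),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$score) |>
    dplyr::mutate(cum_area_mu = cumsum(.data$area_mu))
  total <- max(class_areas$cum_area_mu)
  # strict shortfall only; summation order must not trigger the warning
  # when the scored area equals the target to within rounding
  if (total < target_area_mu * (1 - 1e-9) - 1e-9) {
    warn(sprintf(
      "Total scored wheat area (%.1f mu) is below the target (%.1f mu); selecting all scored pixels.",
      total, target_area_mu
    ))
    cutoff <- max(class_areas$score)
  } else {
    # which.min takes the first (smallest cumulative area) on exact ties
    cutoff <- class_areas$score[
      which.min(abs(class_areas$cum_area_mu - target_area_mu))
    ]
  }
  sel <- !is.na(pixels$score) & pixels$score <= cutoff
  if (partial && cutoff < max(class_areas$score) + 1L) {
    sel <- refine_within_class(pixels, sel, cutoff, target_area_mu)
  }
  selected_area <- sum(pixels$wheat_area[sel])
  result <- new_sasc_result(
    selected_area = selected_area,
    target_area = target_area_mu,
    n_pixels_selected = sum(sel),
    cutoff_score = cutoff,
    class_areas = class_areas
  )
  pixels$selected <- sel
  pixels$wheat_area <- NULL
  list(result = result, pixels = pixels)
}

# Within-class refinement: drop pixels of the cutoff class (lowest SFDI
# first) or add pixels of the next class (highest SFDI first) while that
# shrinks |area - target|. Order ties broken by (row, col) for determinism.
refine_within_class <- function(pixels, sel, cutoff, target) {
  area <- sum(pixels$wheat_area[sel])
  # candidates to remove: selected pixels of the cutoff class, weakest first
  rem <- which(sel & pixels$score == cutoff)
  rem <- rem[order(pixels$sfdi[rem], -pixels$row[rem], -pixels$col[rem])]
  for (i in rem) {
    cand <- area - pixels$wheat_area[i]
    if (abs(cand - target) < abs(area - target)) {
      sel[i] <- FALSE
      area <- cand
    } else {
      break
    }
  }
  # candidates to add: unselected pixels of the next class, strongest first
  add <- which(!sel & !is.na(pixels$score) & pixels$score == cutoff + 1L)
  add <- add[order(-pixels$sfdi[add], pixels$row[add], pixels$col[add])]
  for (i in add) {
    cand <- area + pixels$wheat_area[i]
    if (abs(cand - target) < abs(area - target)) {
      sel[i] <- TRUE
      area <- cand
    } else {
      break
    }
  }
  sel
}

#' @export
print.sasc_result <- function(x, ...) {
  cat(sprintf(
    "<sasc_result> %.1f mu selected over %d pixels (target %.1f mu, cutoff score %d, residual %+.1f mu)\n",
    x$selected_area, x$n_pixels_selected, x$target_area, x$cutoff_score,
    x$residual
  ))
  invisible(x)
}

#' Tidiers for SASC selections
#'
#' `tidy()` returns the per-score-class area table (one row per score with
#' pixel count, class area and cumulative area in mu); `glance()` returns a
#' one-row summary of the selection.
#'
#' @param x An `sasc_result` from [sasc_select()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sasc_result <- function(x, ...) x$class_areas

#' @rdname tidy.sasc_result
#' @export
glance.sasc_result <- function(x, ...) {
  tibble::tibble(
    selected_area = x$selected_area,
    target_area = x$target_area,
    n_pixels_selected = x$n_pixels_selected,
    cutoff_score = x$cutoff_score,
    residual = x$residual
  )
}

#' Pixel area in mu from a geotransform
#'
#' For projected rasters the pixel footprint is `|width x height|` converted
#' at 666.67 m2/mu. For geographic (degree) rasters the cell area follows the
#' spherical approximation
#' `R^2 * dlon * (sin(lat + dlat/2) - sin(lat - dlat/2))` at the cell's
#' latitude, with the authalic Earth radius.
#'
#' @param geotransform List with `pixel_width`, `pixel_height` and `units`
#'   (`"m"` or `"deg"`), as stored in scene metadata.
#' @param latitude Cell-centre latitude in degrees (required for `"deg"`).
#' @return Area of one pixel in mu.
#' @examples
#' pixel_area_mu(list(pixel_width = 500, pixel_height = 500, units = "m"))
#' @export
pixel_area_mu <- function(geotransform, latitude = NULL) {
  w <- geotransform$pixel_width
  h <- geotransform$pixel_height
  if (is.null(w) || is.null(h) || !is.finite(w) || !is.finite(h) ||
      w == 0 || h == 0) {
    abort("Degenerate geotransform: zero or missing pixel size.")
  }
  units <- geotransform$units %||% "m"
  if (units == "m") {
    return(abs(w * h) / MU_M2)
  }
  if (units != "deg") abort("`units` must be 'm' or 'deg'.")
  if (is.null(latitude)) abort("Geographic rasters need `latitude`.")
  dlon <- abs(w) * pi / 180
  half <- abs(h) / 2
  area_m2 <- EARTH_RADIUS_M^2 * dlon *
    (sin((latitude + half) * pi / 180) - sin((latitude - half) * pi / 180))
  abs(area_m2) / MU_M2
}
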
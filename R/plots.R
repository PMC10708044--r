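# ggplot2 display methods. These are convenience views, not cartography.

#' Plot a daily NDVI curve
#'
#' @param object A [frost_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frost_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$ndvi)) +
    ggplot2::geom_line(color = "forestgreen") +
    ggplot2::geom_point(
      data = dplyr::filter(object, !.data$valid),
      color = "grey60", shape = 1, size = 1.5
    ) +
    ggplot2::labs(x = NULL, y = "NDVI") +
    ggplot2::theme_minimal()
}

#' Plot a shape-model fit
#'
#' Shows the multi-year average template, the frost-year target curve and
#' the fitted reference curve; the gap between reference and target over the
#' frost window is what the SFDI accumulates.
#'
#' @param object An `smf_fit` from [fit_smf()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smf_fit <- function(object, ...) {
  tbl <- dplyr::bind_rows(
    tibble::tibble(date = object$g$date, ndvi = object$g$ndvi,
                   curve = "multi-year average"),
    tibble::tibble(date = object$target$date, ndvi = object$target$ndvi,
                   curve = "frost year"),
    tibble::tibble(date = object$h$date, ndvi = object$h$ndvi,
                   curve = "fitted reference")
  )
  ggplot2::ggplot(tbl, ggplot2::aes(.data$date, .data$ndvi,
                                    color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = NULL, y = "NDVI", color = NULL,
      subtitle = sprintf("sx = %.3f, sy = %.3f, t0 = %.1f d, wRMSE = %.4f",
                         object$sx, object$sy, object$t0, object$objective)
    ) +
    ggplot2::theme_minimal()
}

#' Map a per-pixel quantity of a pipeline run
#'
#' `plot_sfdi_map()` shades pixels by SFDI; `plot_selection_map()` shows the
#' area-matched affected-pixel mask; both take the `pixels` tibble of a
#' `frost_run` (or any tibble with `row`, `col` and the column in question).
#'
#' @param pixels Per-pixel tibble.
#' @return A ggplot.
#' @export
plot_sfdi_map <- function(pixels) {
  ggplot2::ggplot(pixels, ggplot2::aes(.data$col, .data$row,
                                       fill = .data$sfdi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "SFDI") +
    ggplot2::theme_minimal()
}

#' @rdname plot_sfdi_map
#' @export
plot_selection_map <- function(pixels) {
  ggplot2::ggplot(pixels, ggplot2::aes(.data$col, .data$row,
                                       fill = .data$selected)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "wheat"),
      na.value = "grey90"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "affected") +
    ggplot2::theme_minimal()
}

#' @param object A `frost_run` from [run_frost_pipeline()].
#' @param ... Unused.
#' @rdname plot_sfdi_map
#' @export
autoplot.frost_run <- function(object, ...) {
  if (!is.null(object$sasc)) plot_selection_map(object$pixels)
  else plot_sfdi_map(object$pixels)
}
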
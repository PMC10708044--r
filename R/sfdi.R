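#' Frost-window constructor
#'
#' The frost window bounds the SFDI summation: from the onset of the frost
#' event (`sf_begin`) to the day the reference curve peaks (`sf_end`), both
#' inclusive, as 0-based day offsets from the season start (offset 0 =
#' season start; reports print 1-based day numbers).
#'
#' @param sf_begin,sf_end Integer day offsets, `0 <= sf_begin <= sf_end`.
#' @param source One of `"met_record"`, `"ndvi_decline"`, `"reference_peak"`.
#' @return A `frost_window` list.
#' @export
frost_window <- function(sf_begin, sf_end,
                         source = c("met_record", "ndvi_decline",
                                    "reference_peak")) {
  source <- match.arg(source)
  sf_begin <- as.integer(sf_begin)
  sf_end <- as.integer(sf_end)
  if (sf_begin < 0L || sf_begin > sf_end) {
    abort("Need 0 <= sf_begin <= sf_end.")
  }
  structure(
    list(sf_begin = sf_begin, sf_end = sf_end, source = source),
    class = "frost_window"
  )
}

#' @export
print.frost_window <- function(x, ...) {
  cat(sprintf(
    "<frost_window> day %d..%d since season start (inclusive) [%s]\n",
    x$sf_begin, x$sf_end, x$source
  ))
  invisible(x)
}

# First 0-based offset at which `values` starts a sustained decline at or
# before `before`: the first day lower than its predecessor such that each
# of the k first differences from there on drops by at least min_drop / k
# (jointly min_drop). Returns NA if none.
decline_onset <- function(values, k, min_drop, before = length(values)) {
  d <- diff(values)
  n_pos <- min(length(d) - k + 1L, before)
  if (n_pos < 1L) return(NA_integer_)
  for (i in seq_len(n_pos)) {
    seg <- d[i:(i + k - 1L)]
    if (all(seg <= -min_drop / k) && sum(seg) <= -min_drop) return(i)
  }
  NA_integer_
}

#' Detect the frost window on a pixel's curves
#'
#' `sf_begin` is taken from the meteorological record when available
#' (`met_start`); otherwise it is the first day, before the reference peak,
#' on which the affected curve begins a sustained decline: `k` consecutive
#' day-to-day drops, each of at least `min_drop / k` NDVI (so `min_drop` in
#' total), guarding against smoothing ripple and observation noise. `sf_end` is the day the
#' reference curve peaks (earliest day on ties), after which frost damage can
#' no longer be separated spectrally from normal senescence.
#'
#' @param reference The reference (frost-free) [frost_curve()].
#' @param affected The SG-filtered frost-year curve on the same grid.
#' @param met_start Optional `Date` (or 0-based day offset) of the frost
#'   onset from meteorological records.
#' @param k Consecutive declining days required to call an onset (default 2).
#' @param min_drop Minimum total NDVI drop over those `k` days (default 0.01).
#' @return A [frost_window()].
#' @export
detect_frost_window <- function(reference, affected, met_start = NULL,
                                k = 2L, min_drop = 0.01) {
  assert_same_grid(reference, affected)
  rv <- curve_values(reference)
  peak <- which.max(rv) - 1L   # earliest day on ties, 0-based
  if (!is.null(met_start)) {
    begin <- if (inherits(met_start, "Date")) {
      as.integer(met_start - reference$date[1L])
    } else {
      as.integer(met_start)
    }
    if (begin < 0L || begin >= nrow(reference)) {
      abort("`met_start` falls outside the curve window.")
    }
    if (peak < begin) {
      abort("Reference peak precedes the frost start; no valid frost window.")
    }
    return(frost_window(begin, peak, source = "met_record"))
  }
  begin <- decline_onset(curve_values(affected), k, min_drop, before = peak)
  if (is.na(begin)) {
    abort("No frost event detected: no sustained NDVI decline before the reference peak and no meteorological start date given.")
  }
  frost_window(begin, peak, source = "ndvi_decline")
}

#' Spring Frost Damage Index of a pixel
#'
#' SFDI is the cumulative daily difference between the reference NDVI curve
#' and the frost-affected NDVI curve over the frost window:
#' `SFDI = sum_{i = sf_begin}^{sf_end} (NDVIr(i) - NDVIsf(i))`, in
#' dimensionless NDVI-days. Daily terms are summed as-is by default, so days
#' on which the affected curve sits above the reference reduce the index;
#' `clip_negative = TRUE` floors each daily term at zero instead.
#'
#' @param reference,affected [frost_curve()]s on the same grid.
#' @param window A [frost_window()] (see [detect_frost_window()]).
#' @param clip_negative Floor negative daily differences at zero.
#' @return An `sfdi_value` list with elements `value` and `n_days`.
#' @export
compute_sfdi <- function(reference, affected, window, clip_negative = FALSE) {
  assert_same_grid(reference, affected)
  n <- nrow(reference)
  if (window$sf_end >= n) {
    abort("Frost window extends beyond the curve support.")
  }
  idx <- (window$sf_begin:window$sf_end) + 1L
  diffs <- curve_values(reference)[idx] - curve_values(affected)[idx]
  if (clip_negative) diffs <- pmax(diffs, 0)
  structure(
    list(value = sum(diffs), n_days = length(idx)),
    class = "sfdi_value"
  )
}

#' @export
print.sfdi_value <- function(x, ...) {
  cat(sprintf("<sfdi_value> %.4f NDVI-days over %d days\n", x$value, x$n_days))
  invisible(x)
}

# Vectorized SFDI over a matrix of affected series (n_pix x n_days) against
# per-pixel reference series R (same shape). Windows: sf_begin scalar,
# sf_end per pixel (integer vector, 0-based).
sfdi_values_mat <- function(R, A, sf_begin, sf_end, clip_negative = FALSE) {
  n <- ncol(R)
  D <- R - A
  if (clip_negative) D <- pmax(D, 0)
  vapply(seq_len(nrow(R)), function(i) {
    idx <- (sf_begin:sf_end[i]) + 1L
    sum(D[i, idx])
  }, numeric(1))
}

#' Per-pixel SFDI over a scene
#'
#' Computes the SFDI for every crop pixel of co-registered reference and
#' affected NDVI stacks in long (tidy) form. Non-crop pixels (crop fraction
#' zero or missing from `crop`) get `NA`.
#'
#' @param reference,affected Long tibbles with columns `row`, `col`, `date`,
#'   `ndvi`; `reference` may instead be a single [frost_curve()] applied to
#'   every pixel.
#' @param window A [frost_window()] applied globally, or `NULL` to detect the
#'   end per pixel from each pixel's reference peak with the shared
#'   `sf_begin` given by `met_start`.
#' @param met_start Frost onset (`Date` or 0-based offset), used when
#'   `window` is `NULL`.
#' @param crop Tibble with columns `row`, `col`, `fraction`; pixels with
#'   `fraction > 0` are crop.
#' @param clip_negative Passed to the daily-term policy of [compute_sfdi()].
#' @return A tibble with columns `row`, `col`, `sfdi`, `sf_begin`, `sf_end`.
#' @export
sfdi_map <- function(reference, affected, window = NULL, met_start = NULL,
                     crop = NULL, clip_negative = FALSE) {
  aw <- stack_to_wide(affected)
  if (inherits(reference, "frost_curve")) {
    R <- matrix(curve_values(reference), nrow(aw$values), ncol(aw$values),
                byrow = TRUE)
    rdates <- reference$date
  } else {
    rw <- stack_to_wide(reference)
    if (!identical(dim(rw$values), dim(aw$values)) ||
        !identical(rw$pixels, aw$pixels)) {
      abort("Reference and affected stacks are on different grids.")
    }
    R <- rw$values
    rdates <- rw$dates
  }
  if (!identical(as.integer(rdates), as.integer(aw$dates))) {
    abort("Reference and affected stacks cover different dates.")
  }
  n_days <- ncol(R)
  if (is.null(window)) {
    if (is.null(met_start)) {
      abort("Provide either a global `window` or `met_start`.")
    }
    begin <- if (inherits(met_start, "Date")) {
      as.integer(met_start - aw$dates[1L])
    } else {
      as.integer(met_start)
    }
    ends <- max.col(R, ties.method = "first") - 1L
    if (any(ends < begin)) {
      abort("Some pixels' reference peak precedes the frost start.")
    }
  } else {
    begin <- window$sf_begin
    ends <- rep(window$sf_end, nrow(R))
    if (window$sf_end >= n_days) abort("Frost window extends beyond the stack.")
  }
  vals <- sfdi_values_mat(R, aw$values, begin, ends, clip_negative)
  out <- dplyr::mutate(aw$pixels, sfdi = vals, sf_begin = begin,
                       sf_end = ends)
  if (!is.null(crop)) {
    require_columns(crop, c("row", "col", "fraction"), "crop-fraction table")
    out <- dplyr::left_join(out, crop, by = c("row", "col"))
    out$sfdi[is.na(out$fraction) | out$fraction <= 0] <- NA_real_
    out$fraction <- NULL
  }
  out
}

# Long stack (row, col, date, ndvi) -> list(pixels, dates, values matrix).
# Pixel order is row-major and deterministic.
stack_to_wide <- function(stack) {
  require_columns(stack, c("row", "col", "date", "ndvi"), "NDVI stack")
  stack <- dplyr::arrange(stack, .data$row, .data$col, .data$date)
  dates <- sort(unique(stack$date))
  pixels <- dplyr::distinct(stack[c("row", "col")])
  n_days <- length(dates)
  if (nrow(stack) != nrow(pixels) * n_days) {
    abort("NDVI stack is ragged: every pixel must have every date.")
  }
  values <- matrix(stack$ndvi, nrow = nrow(pixels), ncol = n_days,
                   byrow = TRUE)
  list(pixels = pixels, dates = dates, values = values)
}
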
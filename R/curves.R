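#' Normalized difference vegetation index
#'
#' Computes NDVI = (nir - red) / (nir + red) from red and near-infrared
#' surface reflectance. Observations that cannot yield a meaningful index
#' are flagged invalid (returned as `NA`) rather than raising an error:
#' a zero band sum, a negative reflectance, or a non-finite input.
#' Values are clamped to the theoretical range \[-1, 1\].
#'
#' @param red,nir Numeric vectors of surface reflectance in \[0, 1\];
#'   recycled to a common length only if one is scalar.
#' @return Numeric vector of NDVI values with `NA` where invalid.
#' @examples
#' ndvi(0.05, 0.45)   # 0.8
#' ndvi(0.3, 0.3)     # 0
#' ndvi(0.2, 0)       # -1
#' @export
ndvi <- function(red, nir) {
  if (length(red) == 1L) red <- rep(red, length(nir))
  if (length(nir) == 1L) nir <- rep(nir, length(red))
  if (length(red) != length(nir)) {
    abort("`red` and `nir` must have the same length.")
  }
  out <- (nir - red) / (nir + red)
  bad <- !is.finite(red) | !is.finite(nir) | red < 0 | nir < 0 |
    (red + nir) == 0
  out[bad] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Construct a daily NDVI curve
#'
#' A `frost_curve` is a tibble with one row per day and columns `date`,
#' `ndvi` and `valid`. The daily step must be uniform; `valid` marks days
#' with a usable observation (cloud-free, in-range). Invalid days may carry
#' `NA` NDVI until [fill_gaps()] is applied.
#'
#' @param date Vector of `Date`s at a strict daily step, or a single start
#'   date (then expanded to `length(ndvi)` days).
#' @param ndvi Numeric NDVI values; values outside \[-1, 1\] are clamped and
#'   flagged invalid.
#' @param valid Logical vector; defaults to `!is.na(ndvi)`.
#' @param clamp Clamp values to \[-1, 1\] and invalidate out-of-range days
#'   (the rule for *observed* NDVI). Model-derived curves (e.g. a
#'   shape-model transform evaluated at extreme scaling factors) may
#'   legitimately leave the physical range and are built with `clamp =
#'   FALSE`.
#' @return A `frost_curve` tibble.
#' @export
frost_curve <- function(date, ndvi, valid = NULL, clamp = TRUE) {
  ndvi <- as.numeric(ndvi)
  date <- as.Date(date)
  if (length(date) == 1L) date <- date + seq_along(ndvi) - 1L
  if (length(date) != length(ndvi)) {
    abort("`date` and `ndvi` must have the same length.")
  }
  if (length(date) > 1L && any(diff(as.integer(date)) != 1L)) {
    abort("`date` must advance in uniform 1-day steps.")
  }
  valid <- valid %||% !is.na(ndvi)
  if (clamp) {
    out_of_range <- !is.na(ndvi) & (ndvi < -1 | ndvi > 1)
    valid[out_of_range] <- FALSE
    ndvi <- pmin(pmax(ndvi, -1), 1)
  }
  valid[is.na(ndvi)] <- FALSE
  out <- tibble::tibble(date = date, ndvi = ndvi, valid = valid)
  class(out) <- c("frost_curve", class(out))
  out
}

#' @export
print.frost_curve <- function(x, ...) {
  cat(sprintf(
    "<frost_curve> %d days, %s to %s (%d valid)\n",
    nrow(x), format(min(x$date)), format(max(x$date)), sum(x$valid)
  ))
  NextMethod()
}

# 0-based day offsets from the curve's first day (index 0 = season start)
day_offsets <- function(curve) as.integer(curve$date - curve$date[1L])

curve_values <- function(curve) curve$ndvi

assert_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || a$date[1L] != b$date[1L]) {
    abort("Curves must share the same daily grid (length and start date).")
  }
}

#' Fill observation gaps in a daily curve
#'
#' Replaces invalid days by linear interpolation between the nearest valid
#' neighbours; leading and trailing gaps are held at the nearest valid value
#' (a single valid observation therefore propagates everywhere). A curve
#' with no valid observation at all is an unusable pixel and errors. The
#' original `valid` flags are preserved so downstream code can still tell
#' observed from interpolated days. Idempotent.
#'
#' @param curve A [frost_curve()].
#' @return A `frost_curve` with no `NA` NDVI values.
#' @export
fill_gaps <- function(curve) {
  v <- curve$valid & !is.na(curve$ndvi)
  if (sum(v) == 0L) {
    abort("Cannot fill gaps: no valid observations (unusable pixel).")
  }
  if (all(v)) return(curve)
  x <- seq_len(nrow(curve))
  filled <- if (sum(v) == 1L) {
    rep(curve$ndvi[v], nrow(curve))
  } else {
    approx(x[v], curve$ndvi[v], xout = x, rule = 2)$y
  }
  out <- curve
  out$ndvi <- ifelse(v, curve$ndvi, filled)
  out
}

# Banded smoothing matrix for Savitzky-Golay filtering of a length-n series.
# Interior rows are the classical symmetric least-squares weights; rows near
# the edges fit the polynomial on the truncated window only (no padding, no
# reflection), degree reduced if the truncated window is too short.
sg_matrix <- function(n, window = 7L, polyorder = 2L) {
  if (window %% 2L != 1L) abort("`window` must be odd.")
  if (window >= n + 1L) abort("`window` must not exceed the series length.")
  if (polyorder >= window) abort("`polyorder` must be smaller than `window`.")
  h <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  row_weights <- function(idx, i) {
    # least-squares fit of degree-p polynomial on idx, evaluated at i
    p <- min(polyorder, length(idx) - 1L)
    X <- outer(idx - i, 0:p, `^`)
    # first row of (X'X)^-1 X' gives the value of the fit at t = i
    solve(crossprod(X), t(X))[1L, ]
  }
  for (i in seq_len(n)) {
    idx <- max(1L, i - h):min(n, i + h)
    S[i, idx] <- row_weights(idx, i)
  }
  S
}

#' Savitzky-Golay smoothing of a daily NDVI curve
#'
#' Least-squares local polynomial smoothing along the time axis, the standard
#' de-noising step for satellite vegetation-index series. The curve must be
#' gap-filled first (see [fill_gaps()]). Edge handling: each output day near
#' the series boundary is the polynomial fit over the *truncated* window that
#' remains inside the series -- no reflection or padding. This choice is fixed
#' and covered by tests.
#'
#' @param curve A gap-free [frost_curve()].
#' @param window Odd window length in days (default 7).
#' @param polyorder Polynomial degree (default 2, must be `< window`).
#' @return A `frost_curve` of the same length; `valid` flags preserved.
#' @export
sg_smooth <- function(curve, window = 7L, polyorder = 2L) {
  y <- curve$ndvi
  if (anyNA(y)) abort("Curve has NA values; apply `fill_gaps()` first.")
  S <- sg_matrix(length(y), window, polyorder)
  out <- curve
  out$ndvi <- as.numeric(S %*% y)
  out
}

# Smooth many series at once: X is (n_series x n_days), returns same shape.
sg_smooth_mat <- function(X, window = 7L, polyorder = 2L) {
  S <- sg_matrix(ncol(X), window, polyorder)
  X %*% t(S)
}

#' Read/write a daily NDVI curve as CSV
#'
#' The on-disk schema is `date, ndvi, valid` (ISO dates, numeric NDVI,
#' logical validity).
#'
#' @param path File path.
#' @param curve A [frost_curve()].
#' @return `read_curve_csv()` returns a `frost_curve`;
#'   `write_curve_csv()` returns `path` invisibly.
#' @export
read_curve_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(tbl, c("date", "ndvi", "valid"), "curve CSV")
  frost_curve(as.Date(tbl$date), tbl$ndvi, as.logical(tbl$valid))
}

#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve)[c("date", "ndvi", "valid")], path)
  invisible(path)
}
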
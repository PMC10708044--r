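# Shared small helpers.

require_columns <- function(tbl, cols, what) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(tbl)
}

# Square metres per mu (Chinese area unit, 1/15 hectare).
MU_M2 <- 666.67

# Authalic (equal-area sphere) Earth radius in metres.
EARTH_RADIUS_M <- 6371007.181

#' Convert between square metres, mu and hectares
#'
#' The mu is the customary Chinese area unit used in agricultural statistics
#' (1 mu = 666.67 m2 = 1/15 ha).
#'
#' @param x Numeric area values.
#' @return Converted numeric values.
#' @export
m2_to_mu <- function(x) x / MU_M2

#' @rdname m2_to_mu
#' @export
mu_to_ha <- function(x) x * MU_M2 / 1e4

#' @rdname m2_to_mu
#' @export
ha_to_mu <- function(x) x * 1e4 / MU_M2
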
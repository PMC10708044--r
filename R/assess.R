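#' Accuracy rate between official and monitored areas
#'
#' The accuracy rate is the ratio of the smaller to the larger of the
#' official (surveyed) and monitored (mapped) affected areas, in percent:
#' `P = 100 * min(a, b) / max(a, b)`. It is symmetric in its arguments and
#' scale-invariant; 100 means perfect agreement.
#'
#' @param area_official,area_monitoring Positive areas in the same unit
#'   (conventionally mu).
#' @return Accuracy rate in percent (0, 100].
#' @examples
#' accuracy_rate(489000, 545000)  # 89.72...
#' @export
accuracy_rate <- function(area_official, area_monitoring) {
  if (!all(is.finite(area_official)) || !all(is.finite(area_monitoring)) ||
      any(area_official <= 0) || any(area_monitoring <= 0)) {
    abort("Both areas must be positive and finite.")
  }
  100 * pmin(area_official, area_monitoring) /
    pmax(area_official, area_monitoring)
}

#' Yield reduction rate
#'
#' Percent reduction of the frost-year yield relative to the mean yield of
#' normal (non-disaster) years. Negative values (a yield gain) are allowed
#' and returned as-is.
#'
#' @param normal_mean Mean yield over normal years (> 0), mass per area.
#' @param observed Frost-year yield, same unit.
#' @return Reduction rate in percent.
#' @examples
#' yield_reduction_rate(6.0, 5.4)  # 10
#' @export
yield_reduction_rate <- function(normal_mean, observed) {
  if (any(!is.finite(normal_mean)) || any(normal_mean <= 0)) {
    abort("`normal_mean` must be positive and finite.")
  }
  100 * (normal_mean - observed) / normal_mean
}

#' Classify frost-damage severity from a yield reduction rate
#'
#' Severity bands follow the official wheat low-temperature damage
#' classification: no damage when there is no reduction, mild below 10%,
#' medium from 10% up to and including 30%, severe above 30%. (Official
#' prose leaves 10-11% unassigned; this implementation assigns \[10, 30\] to
#' medium, consistent with the affected-area definition "reduced by more
#' than 10%".) Thresholds are configurable.
#'
#' @param reduction_rate Numeric vector of reduction rates in percent.
#' @param thresholds Named numeric vector `c(mild = 10, medium = 30)`: rates
#'   in `(0, mild)` are mild, `[mild, medium]` medium, `> medium` severe.
#' @return Ordered factor with levels none < mild < medium < severe.
#' @examples
#' classify_severity(c(5, 12, -3, 45))
#' @export
classify_severity <- function(reduction_rate,
                              thresholds = c(mild = 10, medium = 30)) {
  if (!all(c("mild", "medium") %in% names(thresholds)) ||
      thresholds[["mild"]] >= thresholds[["medium"]]) {
    abort("`thresholds` must supply mild < medium.")
  }
  lev <- c("none", "mild", "medium", "severe")
  cls <- dplyr::case_when(
    !is.finite(reduction_rate) ~ NA_character_,
    reduction_rate <= 0 ~ "none",
    reduction_rate < thresholds[["mild"]] ~ "mild",
    reduction_rate <= thresholds[["medium"]] ~ "medium",
    TRUE ~ "severe"
  )
  factor(cls, levels = lev, ordered = TRUE)
}

#' Per-unit yield reduction table
#'
#' Builds the validation table from a long yield table: for every
#' administrative unit the mean yield over caller-specified normal
#' (non-disaster) years is compared with the frost year, yielding the
#' reduction rate and its severity class.
#'
#' @param yields Tibble with columns `unit_name`, `year`, `yield` (see
#'   [read_yield_table()]).
#' @param frost_year The disaster year.
#' @param normal_years Years defining the normal baseline (must not include
#'   `frost_year`).
#' @param thresholds Passed to [classify_severity()].
#' @return A tibble with one row per unit: `unit_name`,
#'   `normal_mean_yield`, `year_yield`, `reduction_rate`, `severity`.
#' @export
yield_reduction_table <- function(yields, frost_year, normal_years,
                                  thresholds = c(mild = 10, medium = 30)) {
  require_columns(yields, c("unit_name", "year", "yield"), "yield table")
  if (frost_year %in% normal_years) {
    abort("`normal_years` must not contain the frost year.")
  }
  base <- yields |>
    dplyr::filter(.data$year %in% normal_years) |>
    dplyr::group_by(.data$unit_name) |>
    dplyr::summarise(normal_mean_yield = mean(.data$yield), .groups = "drop")
  frost <- yields |>
    dplyr::filter(.data$year == frost_year) |>
    dplyr::select("unit_name", year_yield = "yield")
  out <- dplyr::inner_join(base, frost, by = "unit_name")
  dplyr::mutate(
    out,
    reduction_rate = yield_reduction_rate(.data$normal_mean_yield,
                                          .data$year_yield),
    severity = classify_severity(.data$reduction_rate, thresholds)
  )
}

#' Regress a covariate on per-unit SFDI
#'
#' Ordinary least squares of a per-unit covariate (daily minimum
#' temperature, yield reduction rate, ...) on the unit's mean SFDI, the
#' diagnostic used to check that the damage index tracks independent
#' evidence of frost impact.
#'
#' @param data Tibble holding the two variables.
#' @param sfdi,covariate Column names (strings) of the predictor (mean SFDI)
#'   and response.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided, for the slope), `n`.
#' @export
sfdi_regression <- function(data, sfdi = "sfdi", covariate = "covariate") {
  require_columns(data, c(sfdi, covariate), "regression table")
  x <- data[[sfdi]]
  y <- data[[covariate]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("Need at least 3 units with finite values.")
  if (sd(x) == 0) abort("Zero variance in SFDI; regression is undefined.")
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = s$r.squared,
    p_value = s$coefficients[2L, 4L],
    n = length(x)
  )
}

#' Map per-pixel SFDI to severity classes by quantiles
#'
#' An exploratory extension (not a reproduction of any official rule):
#' scored pixels are split into mild/medium/severe by SFDI quantiles.
#'
#' @param sfdi Numeric SFDI vector (NA = nodata/unaffected).
#' @param probs Two quantile probabilities splitting mild|medium|severe.
#' @return Ordered factor as in [classify_severity()]; unscored pixels
#'   (SFDI < 1 or NA) are `none`.
#' @export
severity_from_sfdi <- function(sfdi, probs = c(0.5, 0.85)) {
  lev <- c("none", "mild", "medium", "severe")
  out <- rep("none", length(sfdi))
  scored <- !is.na(sfdi) & sfdi >= 1
  if (any(scored)) {
    qs <- quantile(sfdi[scored], probs = probs, names = FALSE)
    out[scored] <- dplyr::case_when(
      sfdi[scored] <= qs[1L] ~ "mild",
      sfdi[scored] <= qs[2L] ~ "medium",
      TRUE ~ "severe"
    )
  }
  out[is.na(sfdi)] <- NA_character_
  factor(out, levels = lev, ordered = TRUE)
}
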
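# Shared fixtures, built in code.

season_start <- as.Date("2018-03-01")

# A smooth unimodal test curve (the standard 92-day spring window).
test_template <- function(days = 92L) {
  make_reference_curve(phenology_params(), days = days,
                       start_date = season_start)
}

# A triangular curve, handy because interpolation of it is easy to reason
# about.
triangle_curve <- function(days = 92L, peak_day = 45L,
                           base = 0.2, top = 0.8) {
  d <- seq_len(days) - 1L
  up <- base + (top - base) * d / peak_day
  down <- top - (top - base) * (d - peak_day) / (days - 1L - peak_day)
  frost_curve(season_start, ifelse(d <= peak_day, up, down))
}

# Brute-force Savitzky-Golay oracle: independent per-window polynomial fit
# via lm(), truncating the window at the series edges.
sg_oracle <- function(y, window = 7L, polyorder = 2L) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    p <- min(polyorder, length(idx) - 1L)
    fit <- lm(y[idx] ~ poly(idx, p, raw = TRUE))
    unname(predict(fit, newdata = data.frame(idx = i)))
  }, numeric(1))
}

# Pointwise shape-model transform oracle, independent of the vectorized
# implementation: interpolates g by hand, one day at a time.
smf_oracle <- function(g, sx, sy, t0, bias) {
  x0 <- as.integer(g$date - g$date[1L])
  vapply(x0, function(x) {
    xs <- sx * (x + t0)
    gx <- if (xs <= min(x0)) {
      g$ndvi[1L]
    } else if (xs >= max(x0)) {
      g$ndvi[length(x0)]
    } else {
      lo <- floor(xs)
      frac <- xs - lo
      (1 - frac) * g$ndvi[lo + 1L] + frac * g$ndvi[lo + 2L]
    }
    sy * (gx + bias) - bias
  }, numeric(1))
}
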
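#' Multi-year average NDVI curve
#'
#' Pointwise arithmetic mean of several seasons' NDVI curves over an
#' identical window. The result is the shape model: the phenology a typical
#' frost-free season follows, used as the template for [fit_smf()].
#'
#' @param curves A list of [frost_curve()]s with identical length and start
#'   date (year is ignored when `align_years = TRUE`, the default, so curves
#'   from different calendar years can be averaged by day-of-window).
#' @param align_years If `TRUE`, curves are aligned by day offset within
#'   their window and dated like the first curve.
#' @return A `frost_curve` holding the mean trajectory.
#' @export
multi_year_average <- function(curves, align_years = TRUE) {
  if (length(curves) < 1L) abort("Need at least one curve.")
  n <- nrow(curves[[1L]])
  lens <- vapply(curves, nrow, integer(1))
  if (any(lens != n)) abort("All curves must have the same length.")
  if (!align_years) {
    starts <- vapply(curves, function(cv) as.integer(cv$date[1L]), integer(1))
    if (any(starts != starts[1L])) abort("Curves must share a start date.")
  }
  vals <- vapply(curves, curve_values, numeric(n))
  frost_curve(curves[[1L]]$date, rowMeans(matrix(vals, nrow = n)))
}

# Core of the shape-model transform on bare numerics. x0 are the day offsets
# on which g is sampled; the transformed curve is evaluated on the same grid.
# Outside the sampled window g is extended at its edge values.
smf_transform_values <- function(g_values, x0, sx, sy, t0, bias) {
  xs <- sx * (x0 + t0)
  g_at <- approx(x0, g_values, xout = xs, rule = 2)$y
  sy * (g_at + bias) - bias
}

#' Shape-model transform of a template NDVI curve
#'
#' Geometrically rescales the multi-year average curve `g` into a candidate
#' reference curve `h` via
#' `h(x) = sy * (g(sx * (x + t0)) + bias) - bias`:
#' `sx` and `t0` adjust phenological timing, `sy` adjusts magnitude, and
#' `bias` is a fixed crop-specific baseline-centering constant (0.61 for
#' winter wheat) about which the magnitude scaling pivots. `g` is evaluated
#' at non-integer arguments by linear interpolation and held constant beyond
#' the window.
#'
#' @param g A [frost_curve()], the shape model.
#' @param sx Time-scaling factor (nominal range \[0.9, 1.1\]).
#' @param sy Magnitude-scaling factor (nominal range \[0.5, 1.85\]).
#' @param t0 Time shift in days (nominal range \[-10, 10\]).
#' @param bias Crop-specific constant in NDVI units (default 0.61).
#' @param warn_outside Warn when parameters fall outside their nominal range.
#' @return A `frost_curve` on the same daily grid as `g`.
#' @export
smf_transform <- function(g, sx = 1, sy = 1, t0 = 0, bias = 0.61,
                          warn_outside = TRUE) {
  b <- smf_bounds()
  if (warn_outside &&
      (sx < b$sx[1] || sx > b$sx[2] || sy < b$sy[1] || sy > b$sy[2] ||
       t0 < b$t0[1] || t0 > b$t0[2])) {
    warn("Shape-model parameters outside their nominal bounds.")
  }
  x0 <- day_offsets(g)
  frost_curve(g$date,
              smf_transform_values(curve_values(g), x0, sx, sy, t0, bias),
              clamp = FALSE)
}

#' Nominal shape-model parameter bounds for winter wheat
#'
#' @return A list with elements `sx`, `sy`, `t0` (each `c(lower, upper)`).
#' @export
smf_bounds <- function() {
  list(sx = c(0.9, 1.1), sy = c(0.5, 1.85), t0 = c(-10, 10))
}

# Weighted RMSE between the transform of g and a target series.
smf_objective <- function(par, g_values, x0, target, bias, w) {
  h <- smf_transform_values(g_values, x0, par[1L], par[2L], par[3L], bias)
  sqrt(sum(w * (h - target)^2) / sum(w))
}

# Grid stage shared by fit_smf() and fit_smf_many(): for each (sx, t0) node
# the objective is linear in sy once g is resampled, so the profile-optimal
# sy is closed-form (clamped to its bounds). Returns the resampled template
# matrix and per-node quantities needed to score any target cheaply.
smf_grid <- function(g_values, x0, bias, bounds,
                     sx_step = 0.01, t0_step = 1) {
  sx_grid <- seq(bounds$sx[1], bounds$sx[2], by = sx_step)
  t0_grid <- seq(bounds$t0[1], bounds$t0[2], by = t0_step)
  nodes <- expand.grid(sx = sx_grid, t0 = t0_grid, KEEP.OUT.ATTRS = FALSE)
  # U[k, ] = g(sx_k * (x + t0_k)) + bias
  U <- t(vapply(
    seq_len(nrow(nodes)),
    function(k) {
      approx(x0, g_values, xout = nodes$sx[k] * (x0 + nodes$t0[k]), rule = 2)$y
    },
    numeric(length(x0))
  )) + bias
  list(nodes = nodes, U = U)
}

# Score one target on a precomputed grid; returns (sx, sy, t0, objective).
smf_grid_best <- function(grid, target, bias, bounds, w) {
  tt <- target + bias
  wtt <- w * tt
  num <- as.numeric(grid$U %*% wtt)
  den <- as.numeric((grid$U^2) %*% w)
  sy <- pmin(pmax(num / den, bounds$sy[1]), bounds$sy[2])
  sw <- sum(w)
  obj2 <- (sy^2 * den - 2 * sy * num + sum(w * tt^2)) / sw
  obj <- sqrt(pmax(obj2, 0))
  # tie-break toward the identity (1, 1, 0): sx first, then sy, then t0
  best <- obj <= min(obj) + 1e-12
  ord <- order(
    abs(grid$nodes$sx - 1), abs(sy - 1), abs(grid$nodes$t0)
  )
  k <- ord[which(best[ord])[1L]]
  c(sx = grid$nodes$sx[k], sy = sy[k], t0 = grid$nodes$t0[k], objective = obj[k])
}

new_smf_fit <- function(g, target, sx, sy, t0, bias, objective, weights) {
  h <- smf_transform(g, sx, sy, t0, bias, warn_outside = FALSE)
  structure(
    list(
      sx = sx, sy = sy, t0 = t0, bias = bias, objective = objective,
      g = g, target = target, h = h, weights = weights
    ),
    class = "smf_fit"
  )
}

#' Fit the shape model to a frost-year NDVI curve
#'
#' Finds the scaling parameters `(sx, sy, t0)` minimizing the weighted RMSE
#' between the transformed template ([smf_transform()]) and the target curve
#' over the bounded parameter box. The optimizer is deterministic: a coarse
#' grid over `(sx, t0)` with the weighted-least-squares optimal `sy` in
#' closed form at each node, followed by bounded local polish; ties are
#' broken toward the identity `(1, 1, 0)` in the priority order sx, sy, t0,
#' so an already-matching target returns the identity exactly. No random
#' restarts, so results are reproducible without seeds.
#'
#' @param g The shape model, a [frost_curve()] (see [multi_year_average()]).
#' @param target The SG-filtered frost-year curve on the same grid, or a list
#'   of curves (region mode: they are averaged before fitting).
#' @param bias Crop-specific constant (default 0.61, winter wheat).
#' @param weights Optional nonnegative per-day weights (default uniform).
#' @param bounds Parameter box, see [smf_bounds()].
#' @param polish Run bounded local refinement after the grid stage.
#' @return An `smf_fit` object with elements `sx`, `sy`, `t0`, `bias`,
#'   `objective` (weighted RMSE at the optimum), `g`, `target`, `h` (the
#'   fitted reference curve) and `weights`. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
fit_smf <- function(g, target, bias = 0.61, weights = NULL,
                    bounds = smf_bounds(), polish = TRUE) {
  if (is.list(target) && !inherits(target, "frost_curve")) {
    target <- multi_year_average(target)
  }
  assert_same_grid(g, target)
  x0 <- day_offsets(g)
  gv <- curve_values(g)
  tv <- curve_values(target)
  if (anyNA(tv) || anyNA(gv)) {
    abort("Curves must be gap-free before fitting; see `fill_gaps()`.")
  }
  w <- weights %||% rep(1, length(tv))
  if (length(w) != length(tv) || any(w < 0) || sum(w) == 0) {
    abort("`weights` must be nonnegative, not all zero, one per day.")
  }
  if (sd(tv[w > 0]) < 1e-10) {
    warn("Target curve is constant; returning an identity-adjacent fit.")
    grid0 <- smf_grid(gv, x0, bias, bounds, sx_step = 1, t0_step = 20)
    tt <- tv + bias
    u <- gv + bias
    sy0 <- sum(w * u * tt) / sum(w * u^2)
    sy0 <- pmin(pmax(sy0, bounds$sy[1]), bounds$sy[2])
    obj0 <- smf_objective(c(1, sy0, 0), gv, x0, tv, bias, w)
    return(new_smf_fit(g, target, 1, sy0, 0, bias, obj0, w))
  }
  grid <- smf_grid(gv, x0, bias, bounds)
  best <- smf_grid_best(grid, tv, bias, bounds, w)
  par <- best[c("sx", "sy", "t0")]
  objective <- best[["objective"]]
  if (polish) {
    ref <- optim(
      par, smf_objective,
      g_values = gv, x0 = x0, target = tv, bias = bias, w = w,
      method = "L-BFGS-B",
      lower = c(bounds$sx[1], bounds$sy[1], bounds$t0[1]),
      upper = c(bounds$sx[2], bounds$sy[2], bounds$t0[2]),
      control = list(factr = 1e4)
    )
    if (ref$value <= objective) {
      par <- ref$par
      objective <- ref$value
    }
  }
  # never worse than no transformation
  obj_id <- smf_objective(c(1, 1, 0), gv, x0, tv, bias, w)
  if (obj_id < objective) {
    par <- c(1, 1, 0)
    objective <- obj_id
  }
  new_smf_fit(g, target, unname(par[1L]), unname(par[2L]), unname(par[3L]),
              bias, objective, w)
}

#' @export
print.smf_fit <- function(x, ...) {
  cat(sprintf(
    "<smf_fit> sx = %.4f, sy = %.4f, t0 = %.2f d, bias = %.2f (wRMSE %.5f)\n",
    x$sx, x$sy, x$t0, x$bias, x$objective
  ))
  invisible(x)
}

#' Tidiers for shape-model fits
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model summary.
#'
#' @param x An `smf_fit` from [fit_smf()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.smf_fit <- function(x, ...) {
  b <- smf_bounds()
  tibble::tibble(
    term = c("sx", "sy", "t0", "bias"),
    estimate = c(x$sx, x$sy, x$t0, x$bias),
    lower = c(b$sx[1], b$sy[1], b$t0[1], NA),
    upper = c(b$sx[2], b$sy[2], b$t0[2], NA)
  )
}

#' @rdname tidy.smf_fit
#' @export
glance.smf_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_days = nrow(x$g),
    sx = x$sx, sy = x$sy, t0 = x$t0, bias = x$bias
  )
}

#' Export a shape-model fit report
#'
#' Writes the fitted parameters, objective and the per-day reference curve
#' as JSON.
#'
#' @param fit An `smf_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smf_report <- function(fit, path) {
  jsonlite::write_json(
    list(
      sx = fit$sx, sy = fit$sy, t0 = fit$t0, bias = fit$bias,
      objective = fit$objective,
      reference = list(
        date = format(fit$h$date), ndvi = fit$h$ndvi
      )
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

# Fit the shape model to many target series sharing one template. `targets`
# is (n_series x n_days). The (sx, t0) grid and resampled template are
# computed once and reused, which is what makes per-pixel fitting of whole
# scenes cheap. Returns per-series parameters and the reference matrix H.
fit_smf_many <- function(g, targets, bias = 0.61, weights = NULL,
                         bounds = smf_bounds(), polish = TRUE) {
  x0 <- day_offsets(g)
  gv <- curve_values(g)
  stopifnot(ncol(targets) == length(gv))
  w <- weights %||% rep(1, length(gv))
  grid <- smf_grid(gv, x0, bias, bounds)
  n <- nrow(targets)
  sx <- sy <- t0 <- obj <- numeric(n)
  for (i in seq_len(n)) {
    tv <- targets[i, ]
    best <- smf_grid_best(grid, tv, bias, bounds, w)
    par <- best[c("sx", "sy", "t0")]
    objective <- best[["objective"]]
    if (polish) {
      ref <- optim(
        par, smf_objective,
        g_values = gv, x0 = x0, target = tv, bias = bias, w = w,
        method = "L-BFGS-B",
        lower = c(bounds$sx[1], bounds$sy[1], bounds$t0[1]),
        upper = c(bounds$sx[2], bounds$sy[2], bounds$t0[2]),
        control = list(factr = 1e7)
      )
      if (ref$value <= objective) {
        par <- ref$par
        objective <- ref$value
      }
    }
    obj_id <- smf_objective(c(1, 1, 0), gv, x0, tv, bias, w)
    if (obj_id < objective) {
      par <- c(1, 1, 0)
      objective <- obj_id
    }
    sx[i] <- par[1L]; sy[i] <- par[2L]; t0[i] <- par[3L]; obj[i] <- objective
  }
  H <- t(vapply(
    seq_len(n),
    function(i) smf_transform_values(gv, x0, sx[i], sy[i], t0[i], bias),
    numeric(length(gv))
  ))
  list(
    params = tibble::tibble(sx = sx, sy = sy, t0 = t0, objective = obj),
    H = H
  )
}
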
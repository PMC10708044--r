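#' Pipeline configuration
#'
#' Collects every tunable of the monitoring chain with its default. The
#' shape-model bounds and bias are the winter-wheat values; the remaining
#' defaults are the package's documented choices.
#'
#' @param sg_window,sg_polyorder Savitzky-Golay window (odd, days) and
#'   polynomial degree.
#' @param bias Shape-model crop constant (0.61, winter wheat).
#' @param bounds Shape-model parameter box, see [smf_bounds()].
#' @param k,min_drop Frost-onset detection tunables, see
#'   [detect_frost_window()].
#' @param clip_negative Daily-term policy of [compute_sfdi()].
#' @param exclude_window_from_fit Give the provisional frost window zero
#'   weight when fitting the shape model, so the frost dip itself cannot
#'   drag the reference curve down (used only when a meteorological onset is
#'   known).
#' @param partial Within-class refinement in [sasc_select()].
#' @param severity_probs Quantiles for the exploratory per-pixel severity
#'   map, see [severity_from_sfdi()].
#' @return A `frost_config` list.
#' @export
frost_config <- function(sg_window = 7L, sg_polyorder = 2L,
                         bias = 0.61, bounds = smf_bounds(),
                         k = 2L, min_drop = 0.01,
                         clip_negative = FALSE,
                         exclude_window_from_fit = TRUE,
                         partial = FALSE,
                         severity_probs = c(0.5, 0.85)) {
  structure(
    list(sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         bias = bias, bounds = bounds,
         k = as.integer(k), min_drop = min_drop,
         clip_negative = clip_negative,
         exclude_window_from_fit = exclude_window_from_fit,
         partial = partial,
         severity_probs = severity_probs),
    class = "frost_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their [frost_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return A `frost_config`.
#' @export
read_frost_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(frost_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(frost_config, vals)
}

#' Run the full frost-monitoring pipeline on a scene
#'
#' Executes the whole chain on a `frost_scene` (from
#' [simulate_frost_scene()] or [read_scene()]): NDVI from the band pair,
#' gap filling and Savitzky-Golay smoothing per pixel, shape-model fitting
#' of the multi-year average curve to every crop pixel's frost-year curve,
#' per-pixel SFDI over the frost window (onset from the meteorological
#' record, end at each pixel's reference-curve peak), SFDI scoring and the
#' self-adapting statistics correction against `target_area_mu`, an
#' exploratory quantile severity map, and validation against the scene
#' truth when present. Deterministic: rerunning with the same inputs gives
#' identical output.
#'
#' @param scene A `frost_scene`.
#' @param target_area_mu Official affected-area statistic in mu; if `NULL`
#'   the SASC stage is skipped with a warning and the raw SFDI map is
#'   returned.
#' @param config A [frost_config()].
#' @param met_start Frost onset; defaults to the scene's recorded onset.
#' @param out_dir Optional directory for artifacts (CSV grids, JSON
#'   reports, config YAML).
#' @return A `frost_run` list: `pixels` (per-pixel tibble with
#'   `crop_fraction`, `pixel_area_mu`, shape-model parameters, `sfdi`,
#'   `score`, `selected`, `severity`), `sasc` (an `sasc_result` or `NULL`),
#'   `window` (onset offset and per-pixel end summary), `shape_model`,
#'   `validation`, `config` and `provenance`.
#' @export
run_frost_pipeline <- function(scene, target_area_mu = NULL,
                               config = frost_config(),
                               met_start = NULL, out_dir = NULL) {
  met_start <- met_start %||% scene$met_start
  dates <- scene$dates
  n_days <- length(dates)

  refl <- dplyr::arrange(scene$reflectance, .data$row, .data$col, .data$date)
  pixels <- dplyr::distinct(refl[c("row", "col")])
  npix <- nrow(pixels)
  if (nrow(refl) != npix * n_days) {
    abort("Reflectance stack is ragged: every pixel needs every date.")
  }
  N <- matrix(ndvi(refl$red, refl$nir), npix, n_days, byrow = TRUE)

  # gap-fill each pixel; pixels with no valid observation are unusable
  usable <- rowSums(!is.na(N)) >= 1L
  for (i in which(usable)) {
    if (anyNA(N[i, ])) {
      v <- !is.na(N[i, ])
      N[i, ] <- if (sum(v) == 1L) {
        rep(N[i, v], n_days)
      } else {
        approx(which(v), N[i, v], xout = seq_len(n_days), rule = 2)$y
      }
    }
  }
  S <- sg_matrix(n_days, config$sg_window, config$sg_polyorder)
  N[usable, ] <- N[usable, , drop = FALSE] %*% t(S)

  g <- multi_year_average(scene$history)
  g <- sg_smooth(fill_gaps(g), config$sg_window, config$sg_polyorder)

  begin <- as.integer(met_start - dates[1L])
  if (begin < 0L || begin >= n_days) {
    abort("Frost onset falls outside the season window.")
  }
  weights <- rep(1, n_days)
  if (config$exclude_window_from_fit) {
    g_peak <- which.max(curve_values(g)) - 1L
    if (g_peak > begin) weights[(begin:g_peak) + 1L] <- 0
  }

  crop <- dplyr::left_join(pixels, scene$crop, by = c("row", "col"))
  crop$fraction[is.na(crop$fraction)] <- 0
  fit_idx <- which(usable & crop$fraction > 0)

  sx <- sy <- t0 <- objective <- sfdi <- rep(NA_real_, npix)
  sf_end <- rep(NA_integer_, npix)
  if (length(fit_idx) > 0L) {
    fits <- fit_smf_many(g, N[fit_idx, , drop = FALSE], bias = config$bias,
                         weights = weights, bounds = config$bounds)
    sx[fit_idx] <- fits$params$sx
    sy[fit_idx] <- fits$params$sy
    t0[fit_idx] <- fits$params$t0
    objective[fit_idx] <- fits$params$objective
    ends <- max.col(fits$H, ties.method = "first") - 1L
    ok <- ends >= begin
    if (!all(ok)) {
      warn(sprintf(
        "%d pixel(s) have a reference peak before the frost onset; SFDI set to NA there.",
        sum(!ok)
      ))
    }
    sf_end[fit_idx] <- ifelse(ok, ends, NA_integer_)
    good <- fit_idx[ok]
    sfdi[good] <- sfdi_values_mat(
      fits$H[ok, , drop = FALSE], N[good, , drop = FALSE],
      begin, ends[ok], config$clip_negative
    )
  }

  area_mu <- pixel_area_mu(scene$geotransform)
  px <- dplyr::mutate(
    pixels,
    crop_fraction = crop$fraction,
    pixel_area_mu = area_mu,
    sx = sx, sy = sy, t0 = t0, fit_objective = objective,
    sf_begin = begin, sf_end = sf_end,
    sfdi = sfdi,
    score = score_sfdi(sfdi)
  )

  sasc <- NULL
  if (is.null(target_area_mu)) {
    warn("No target area supplied; skipping the statistics correction and returning the raw SFDI map.")
    px$selected <- NA
  } else {
    out <- sasc_select(px, target_area_mu, partial = config$partial)
    sasc <- out$result
    px <- out$pixels
  }
  px$severity <- severity_from_sfdi(px$sfdi, config$severity_probs)

  validation <- NULL
  if (!is.null(scene$truth) && !is.null(sasc)) {
    truth <- dplyr::left_join(pixels, scene$truth, by = c("row", "col"))
    agree <- mean(px$selected == truth$frost)
    validation <- list(
      true_affected_area_mu = scene$true_affected_area_mu,
      selected_area_mu = sasc$selected_area,
      accuracy_rate = accuracy_rate(scene$true_affected_area_mu,
                                    sasc$selected_area),
      pixel_agreement = agree
    )
  }

  run <- structure(
    list(
      pixels = px,
      sasc = sasc,
      window = list(sf_begin = begin, met_start = met_start,
                    sf_end_range = range(sf_end, na.rm = TRUE)),
      shape_model = g,
      validation = validation,
      config = config,
      provenance = list(
        package_version = as.character(utils::packageVersion("wheatfrost")),
        config_hash = rlang::hash(config),
        scene_seed = scene$seed
      )
    ),
    class = "frost_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.frost_run <- function(x, ...) {
  cat(sprintf(
    "<frost_run> %d pixels, frost onset day %d (0-based)\n",
    nrow(x$pixels), x$window$sf_begin
  ))
  if (!is.null(x$sasc)) print(x$sasc)
  if (!is.null(x$validation)) {
    cat(sprintf(
      "  truth: accuracy rate %.2f%%, pixel agreement %.1f%%\n",
      x$validation$accuracy_rate, 100 * x$validation$pixel_agreement
    ))
  }
  invisible(x)
}

# Write the artifact bundle of a pipeline run.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_grid_csv(run$pixels, file.path(out_dir, "sfdi.csv"), value = "sfdi")
  write_grid_csv(run$pixels, file.path(out_dir, "score.csv"), value = "score")
  px <- dplyr::mutate(run$pixels,
                      severity = as.character(.data$severity),
                      selected = as.integer(.data$selected))
  readr::write_csv(px, file.path(out_dir, "pixels.csv"))
  yaml::write_yaml(
    run$config[setdiff(names(run$config), "bounds")],
    file.path(out_dir, "config.yaml")
  )
  report <- list(
    window = list(sf_begin = run$window$sf_begin,
                  met_start = format(run$window$met_start)),
    provenance = run$provenance
  )
  if (!is.null(run$sasc)) {
    report$sasc <- as.list(glance(run$sasc))
    readr::write_csv(tidy(run$sasc), file.path(out_dir, "class_areas.csv"))
  }
  if (!is.null(run$validation)) report$validation <- run$validation
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
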
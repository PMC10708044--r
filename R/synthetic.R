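#' Double-logistic phenology parameters
#'
#' Parameterizes the idealized seasonal NDVI trajectory of a winter-wheat
#' pixel over the spring window: a winter `baseline`, an `amplitude` above
#' it, logistic green-up and senescence transitions at the two inflection
#' days with the given rates. Defaults describe a typical North-China-Plain
#' winter-wheat spring season sampled 1 March to 31 May (peak near day 45,
#' mid-April).
#'
#' @param baseline Winter NDVI level (default 0.30).
#' @param amplitude Peak minus baseline (default 0.50, > 0).
#' @param greenup_day,senescence_day Inflection day offsets (0-based from
#'   the window start; `greenup_day < senescence_day`).
#' @param greenup_rate,senescence_rate Logistic slopes in 1/day (> 0).
#' @return A `phenology_params` list.
#' @export
phenology_params <- function(baseline = 0.30, amplitude = 0.50,
                             greenup_day = 12, senescence_day = 78,
                             greenup_rate = 0.15, senescence_rate = 0.15) {
  if (amplitude <= 0) abort("`amplitude` must be > 0.")
  if (greenup_rate <= 0 || senescence_rate <= 0) abort("Rates must be > 0.")
  if (greenup_day >= senescence_day) {
    abort("`greenup_day` must precede `senescence_day`.")
  }
  structure(
    list(baseline = baseline, amplitude = amplitude,
         greenup_day = greenup_day, senescence_day = senescence_day,
         greenup_rate = greenup_rate, senescence_rate = senescence_rate),
    class = "phenology_params"
  )
}

#' Idealized frost-free reference curve
#'
#' Samples the double-logistic phenology daily:
#' `baseline + amplitude * (plogis(gr*(d - gd)) - plogis(sr*(d - sd)))`.
#' The curve is unimodal over the window and bounded in
#' `[baseline, baseline + amplitude]`.
#'
#' @param params A [phenology_params()].
#' @param days Window length in days (default 92: 1 March-31 May).
#' @param start_date First day of the window.
#' @return A [frost_curve()].
#' @export
make_reference_curve <- function(params, days = 92L,
                                 start_date = as.Date("2018-03-01")) {
  if (!inherits(params, "phenology_params")) {
    abort("`params` must come from `phenology_params()`.")
  }
  d <- seq_len(days) - 1L
  v <- params$baseline + params$amplitude *
    (stats::plogis(params$greenup_rate * (d - params$greenup_day)) -
     stats::plogis(params$senescence_rate * (d - params$senescence_day)))
  frost_curve(start_date, v)
}

#' Frost-dip injection parameters
#'
#' Describes the synthetic NDVI dip a frost event carves into a pixel's
#' curve: zero at `onset_day - 1`, deepening to `depth`, and closed again
#' `recovery_days` after the eve of onset. `linear_vee` is a symmetric
#' triangular dip (deepest at mid-recovery); `exponential` drops to `depth`
#' at onset and decays back to zero.
#'
#' @param onset_day 0-based day offset of the frost onset (default 33,
#'   mirroring a 3 April onset in a 1 March window).
#' @param depth Maximum NDVI drop (>= 0).
#' @param recovery_days Days from the eve of onset until the dip closes
#'   (default 10, a 3-13 April impact).
#' @param profile `"linear_vee"` or `"exponential"`.
#' @return A `frost_injection` list.
#' @export
frost_injection <- function(onset_day = 33L, depth = 0.35,
                            recovery_days = 10L,
                            profile = c("linear_vee", "exponential")) {
  profile <- match.arg(profile)
  if (depth < 0) abort("`depth` must be >= 0.")
  if (recovery_days < 1) abort("`recovery_days` must be >= 1.")
  structure(
    list(onset_day = as.integer(onset_day), depth = depth,
         recovery_days = as.integer(recovery_days), profile = profile),
    class = "frost_injection"
  )
}

# Dip magnitude at 0-based day offsets d (vectorized).
dip_profile <- function(d, inj) {
  t0 <- inj$onset_day - 1L            # dip is zero here
  rel <- d - t0
  out <- numeric(length(d))
  inside <- rel > 0 & rel < inj$recovery_days
  if (inj$profile == "linear_vee") {
    half <- inj$recovery_days / 2
    out[inside] <- inj$depth * (1 - abs(rel[inside] - half) / half)
  } else {
    out[inside] <- inj$depth *
      exp(-3 * (rel[inside] - 1) / inj$recovery_days)
  }
  out
}

#' Inject a frost dip into an NDVI curve
#'
#' Subtracts the dip profile of a [frost_injection()] from the curve,
#' clamping the result at -1.
#'
#' @param curve A [frost_curve()].
#' @param inj A [frost_injection()].
#' @return The damaged `frost_curve`.
#' @export
inject_frost <- function(curve, inj) {
  d <- day_offsets(curve)
  if (inj$onset_day < 0 || inj$onset_day > max(d)) {
    abort("`onset_day` falls outside the curve window.")
  }
  frost_curve(curve$date, pmax(curve$ndvi - dip_profile(d, inj), -1),
              valid = curve$valid)
}

#' Invert NDVI to a synthetic red/NIR band pair
#'
#' Fixed band model `nir = c * (1 + ndvi)`, `red = c * (1 - ndvi)` with
#' `c = 0.25`, so [ndvi()] recovers the input exactly and both reflectances
#' stay in \[0, 0.5\] for NDVI in \[-1, 1\].
#'
#' @param x NDVI values.
#' @return A list with `red` and `nir` vectors.
#' @export
reflectance_from_ndvi <- function(x) {
  list(red = 0.25 * (1 - x), nir = 0.25 * (1 + x))
}

#' Simulate a synthetic frost scene with known truth
#'
#' Generates everything the monitoring pipeline consumes, with ground truth
#' attached: a daily red/NIR reflectance stack for the frost year (clean
#' double-logistic phenology, a frost dip on a random subset of crop pixels,
#' optional Gaussian NDVI noise and observation gaps), a crop-fraction
#' raster, a small set of frost-free history seasons (with mild year-to-year
#' amplitude/timing variation) whose average is the shape model, and the
#' true affected area implied by the frost mask. All randomness flows from
#' `seed`.
#'
#' @param nrow,ncol Scene size in pixels.
#' @param frost_fraction Probability a crop pixel is frost-damaged.
#' @param depth_range Range of per-pixel dip depths (NDVI), drawn uniformly.
#' @param onset_day,recovery_days Frost timing shared by all damaged pixels
#'   (see [frost_injection()]).
#' @param noise_sd Per-day Gaussian NDVI noise (0 = noise-free).
#' @param gap_rate Probability an observation day is missing (cloud).
#' @param crop_fraction_range Crop fraction of crop pixels, drawn uniformly.
#' @param noncrop_fraction Share of pixels with no wheat at all.
#' @param n_history_years Frost-free seasons behind the shape model.
#' @param params Base [phenology_params()].
#' @param days Window length (default 92, 1 March-31 May).
#' @param start_date First day of the window.
#' @param pixel_size_m Pixel edge length in metres (default 500).
#' @param seed Integer RNG seed (required; the scene is reproducible).
#' @return A `frost_scene` list: `reflectance` (long tibble `row`, `col`,
#'   `date`, `red`, `nir`; NA on gap days), `crop` (`row`, `col`,
#'   `fraction`), `history` (list of frost-free [frost_curve()]s), `truth`
#'   (`row`, `col`, `frost`, `depth`), `true_affected_area_mu`,
#'   `geotransform`, `dates`, `met_start` (the onset as a `Date`), `seed`.
#' @export
simulate_frost_scene <- function(nrow = 24L, ncol = 24L,
                                 frost_fraction = 0.3,
                                 depth_range = c(0.25, 0.55),
                                 onset_day = 33L, recovery_days = 10L,
                                 noise_sd = 0.01, gap_rate = 0.05,
                                 crop_fraction_range = c(0.4, 1),
                                 noncrop_fraction = 0.1,
                                 n_history_years = 5L,
                                 params = phenology_params(),
                                 days = 92L,
                                 start_date = as.Date("2018-03-01"),
                                 pixel_size_m = 500,
                                 seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible scene.")
  set.seed(seed)
  npix <- nrow * ncol
  pixels <- tidyr::expand_grid(row = seq_len(nrow), col = seq_len(ncol))
  clean <- make_reference_curve(params, days, start_date)
  dates <- clean$date

  # history seasons: the same phenology with mild year effects
  history <- lapply(seq_len(n_history_years), function(y) {
    p <- params
    p$amplitude <- max(0.05, params$amplitude + rnorm(1, 0, 0.03))
    shift <- rnorm(1, 0, 2)
    p$greenup_day <- params$greenup_day + shift
    p$senescence_day <- params$senescence_day + shift
    make_reference_curve(p, days, start_date)
  })

  crop_fraction <- runif(npix, crop_fraction_range[1], crop_fraction_range[2])
  crop_fraction[runif(npix) < noncrop_fraction] <- 0
  is_crop <- crop_fraction > 0

  frost <- is_crop & runif(npix) < frost_fraction
  depth <- ifelse(frost, runif(npix, depth_range[1], depth_range[2]), 0)

  # per-pixel NDVI matrix (npix x days)
  N <- matrix(clean$ndvi, npix, days, byrow = TRUE)
  if (any(frost)) {
    dip <- dip_profile(day_offsets(clean),
                       frost_injection(onset_day, 1, recovery_days))
    N <- N - outer(depth, dip)
  }
  if (noise_sd > 0) N <- N + matrix(rnorm(npix * days, 0, noise_sd), npix)
  N <- pmin(pmax(N, -1), 1)

  refl <- reflectance_from_ndvi(as.numeric(t(N)))  # day-fastest order
  gap <- runif(npix * days) < gap_rate
  refl$red[gap] <- NA_real_
  refl$nir[gap] <- NA_real_

  reflectance <- tidyr::expand_grid(pixels, date = dates)
  reflectance$red <- refl$red
  reflectance$nir <- refl$nir

  geotransform <- list(pixel_width = pixel_size_m,
                       pixel_height = pixel_size_m, units = "m")
  area_mu <- pixel_area_mu(geotransform)
  truth <- dplyr::mutate(pixels, frost = frost, depth = depth)
  structure(
    list(
      reflectance = reflectance,
      crop = dplyr::mutate(pixels, fraction = crop_fraction),
      history = history,
      truth = truth,
      true_affected_area_mu = sum(crop_fraction[frost]) * area_mu,
      geotransform = geotransform,
      dates = dates,
      met_start = dates[1L] + onset_day,
      params = params,
      seed = seed
    ),
    class = "frost_scene"
  )
}

#' @export
print.frost_scene <- function(x, ...) {
  n <- dplyr::n_distinct(x$reflectance$row)
  m <- dplyr::n_distinct(x$reflectance$col)
  cat(sprintf(
    "<frost_scene> %dx%d pixels, %d days, %d frost pixels, true affected area %.1f mu (seed %d)\n",
    n, m, length(x$dates), sum(x$truth$frost), x$true_affected_area_mu,
    x$seed
  ))
  invisible(x)
}
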
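test_that("frost window detection finds onset and reference peak", {
  ref <- test_template()              # peaks on day 45
  aff <- inject_frost(ref, frost_injection(onset_day = 33, depth = 0.35,
                                           recovery_days = 10))
  # onset from the NDVI decline
  w <- detect_frost_window(ref, aff)
  expect_equal(w$sf_begin, 33L)
  expect_equal(w$sf_end, 45L)
  expect_equal(w$source, "ndvi_decline")
  # onset from the meteorological record (a 3 April start, 1 March window)
  w2 <- detect_frost_window(ref, aff, met_start = as.Date("2018-04-03"))
  expect_equal(w2$sf_begin, 33L)
  expect_equal(w2$source, "met_record")
  # an undamaged pixel raises "no frost event"
  expect_error(detect_frost_window(ref, ref), "No frost event")
  # met start after the reference peak is invalid
  expect_error(detect_frost_window(ref, aff, met_start = 60L),
               "peak precedes")
})

test_that("injected dips are located within a day across seeds", {
  ref <- test_template()
  for (s in 1:20) {
    set.seed(s)
    onset <- sample(20:38, 1)
    aff <- inject_frost(ref, frost_injection(onset, depth = 0.3,
                                             recovery_days = 10))
    noisy <- frost_curve(aff$date, aff$ndvi + rnorm(92, 0, 0.005))
    sm <- sg_smooth(fill_gaps(noisy))
    w <- detect_frost_window(ref, sm)
    expect_lte(abs(w$sf_begin - onset), 1)
  }
})

test_that("compute_sfdi matches closed forms and a summation oracle", {
  ref <- test_template()
  w <- frost_window(33, 45)
  # zero difference
  expect_equal(compute_sfdi(ref, ref, w)$value, 0)
  # constant difference: n * d over an inclusive window
  shifted <- frost_curve(ref$date, ref$ndvi - 0.05)
  expect_equal(compute_sfdi(ref, shifted, frost_window(10, 19))$value, 0.5)
  expect_equal(compute_sfdi(ref, shifted, frost_window(10, 19))$n_days, 10L)
  # arbitrary pairs against term-by-term summation
  set.seed(13)
  for (i in 1:10) {
    a <- frost_curve(season_start, runif(60, 0, 1))
    b <- frost_curve(season_start, runif(60, 0, 1))
    lo <- sample(0:20, 1); hi <- sample(40:59, 1)
    manual <- sum(vapply((lo:hi) + 1L,
                         function(j) a$ndvi[j] - b$ndvi[j], numeric(1)))
    expect_equal(compute_sfdi(a, b, frost_window(lo, hi))$value, manual,
                 tolerance = 1e-12)
  }
  expect_error(compute_sfdi(ref, ref, frost_window(80, 95)), "beyond")
})

test_that("SFDI is additive, monotone in dip depth, and scales linearly", {
  ref <- test_template()
  aff <- inject_frost(ref, frost_injection(onset_day = 33, depth = 0.4,
                                           recovery_days = 10))
  s_all <- compute_sfdi(ref, aff, frost_window(20, 50))$value
  s_a <- compute_sfdi(ref, aff, frost_window(20, 35))$value
  s_b <- compute_sfdi(ref, aff, frost_window(36, 50))$value
  expect_equal(s_all, s_a + s_b)
  # deepening the dip never decreases SFDI
  depths <- seq(0, 0.5, by = 0.1)
  vals <- vapply(depths, function(d) {
    dam <- inject_frost(ref, frost_injection(33, d, 10))
    compute_sfdi(ref, dam, frost_window(33, 45))$value
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  # scaling the difference scales the index
  lam <- 3
  wider <- frost_curve(ref$date, ref$ndvi - lam * (ref$ndvi - aff$ndvi),
                       clamp = FALSE)
  expect_equal(compute_sfdi(ref, wider, frost_window(33, 45))$value,
               lam * compute_sfdi(ref, aff, frost_window(33, 45))$value)
  # clip-at-zero variant never goes below the literal sum
  above <- frost_curve(ref$date, ref$ndvi + 0.05)
  expect_equal(compute_sfdi(ref, above, frost_window(10, 19))$value, -0.5)
  expect_equal(compute_sfdi(ref, above, frost_window(10, 19),
                            clip_negative = TRUE)$value, 0)
})

test_that("sfdi_map agrees with looped scalar calls and honours the mask", {
  ref <- test_template()
  set.seed(17)
  scene <- simulate_frost_scene(nrow = 4, ncol = 4, noise_sd = 0.02,
                                gap_rate = 0, seed = 99)
  stack <- scene$reflectance |>
    dplyr::mutate(ndvi = ndvi(red, nir)) |>
    dplyr::select(row, col, date, ndvi)
  w <- frost_window(33, 45)
  out <- sfdi_map(ref, stack, window = w)
  expect_equal(nrow(out), 16L)
  # consistency with the scalar path, pixel by pixel
  for (i in c(1L, 7L, 16L)) {
    px <- dplyr::filter(stack, row == out$row[i], col == out$col[i])
    scalar <- compute_sfdi(ref, frost_curve(px$date, px$ndvi), w)
    expect_equal(out$sfdi[i], scalar$value)
  }
  # a 1x1 raster reduces to compute_sfdi
  one <- dplyr::filter(stack, row == 1, col == 1)
  expect_equal(sfdi_map(ref, one, window = w)$sfdi,
               compute_sfdi(ref, frost_curve(one$date, one$ndvi), w)$value)
  # non-crop pixels become nodata
  crop0 <- dplyr::mutate(dplyr::distinct(stack[c("row", "col")]),
                         fraction = 0)
  expect_true(all(is.na(sfdi_map(ref, stack, window = w, crop = crop0)$sfdi)))
  # ragged stacks are rejected
  expect_error(sfdi_map(ref, stack[-1, ], window = w), "ragged")
})
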
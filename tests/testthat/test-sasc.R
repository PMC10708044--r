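# Exhaustive oracle: try every whole-class prefix cutoff and return the one
# whose cumulative wheat area is closest to the target (first on ties).
sasc_oracle_cutoff <- function(pixels, target) {
  scored <- pixels[!is.na(score_sfdi(pixels$sfdi)), ]
  scored$score <- score_sfdi(scored$sfdi)
  cuts <- sort(unique(scored$score))
  areas <- vapply(cuts, function(s) {
    sel <- scored$score <= s
    sum(scored$crop_fraction[sel] * scored$pixel_area_mu[sel])
  }, numeric(1))
  list(cutoff = cuts[which.min(abs(areas - target))], areas = areas,
       cuts = cuts)
}

random_pixel_table <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    row = rep(seq_len(ceiling(sqrt(n))), each = ceiling(sqrt(n)))[1:n],
    col = rep(seq_len(ceiling(sqrt(n))), times = ceiling(sqrt(n)))[1:n],
    sfdi = runif(n, 0, 20),
    crop_fraction = runif(n),
    pixel_area_mu = 375
  )
}

test_that("score_sfdi implements the score table", {
  expect_equal(score_sfdi(c(16, 15, 1, 0.99)), c(1L, 2L, 16L, NA))
  expect_equal(score_sfdi(18.7), 1L)
  expect_equal(score_sfdi(15.999), 2L)
  expect_equal(score_sfdi(1.5), 16L)
  expect_equal(score_sfdi(c(NA, 0, -2)), c(NA_integer_, NA, NA))
  # every scored bin [17-s, 18-s) maps to s
  s <- score_sfdi(seq(1, 15.99, by = 0.01))
  expect_true(all(s %in% 1:16))
  expect_true(all(diff(s) <= 0))
})

test_that("sasc_select picks the area-nearest whole-class cutoff", {
  # single pixel, exact match
  one <- tibble::tibble(row = 1, col = 1, sfdi = 16, crop_fraction = 1,
                        pixel_area_mu = 375)
  out <- sasc_select(one, 375)
  expect_equal(out$result$selected_area, 375)
  expect_equal(out$result$residual, 0)
  expect_true(out$pixels$selected)
  # classes with areas [100, 50, 30] mu and target 140 -> classes {1, 2}
  tbl <- tibble::tibble(
    row = 1:3, col = 1,
    sfdi = c(16.5, 15.5, 14.5),       # scores 1, 2, 3
    crop_fraction = 1,
    pixel_area_mu = c(100, 50, 30)
  )
  out <- sasc_select(tbl, 140)
  expect_equal(out$result$cutoff_score, 2L)
  expect_equal(out$result$selected_area, 150)
  expect_equal(out$pixels$selected, c(TRUE, TRUE, FALSE))
  # tie between cutoffs goes to the smaller selection
  tie <- tibble::tibble(row = 1:2, col = 1, sfdi = c(16.5, 15.5),
                        crop_fraction = 1, pixel_area_mu = c(100, 20))
  expect_equal(sasc_select(tie, 110)$result$cutoff_score, 1L)
})

test_that("sasc_select equals the exhaustive prefix-search oracle", {
  for (seed in 1:50) {
    tbl <- random_pixel_table(64, seed)
    target <- runif(1, 100, sum(tbl$crop_fraction) * 375)
    res <- suppressWarnings(sasc_select(tbl, target))$result
    oracle <- sasc_oracle_cutoff(tbl, target)
    expect_equal(res$cutoff_score, oracle$cutoff)
    # optimality: no whole-class cutoff does better
    expect_true(all(abs(res$selected_area - target) <=
                      abs(oracle$areas - target) + 1e-9))
    # cumulative area is monotone in the cutoff
    expect_true(all(diff(oracle$areas) >= 0))
  }
})

test_that("sasc selections are ordered, deterministic and warn when short", {
  tbl <- random_pixel_table(100, 7)
  out <- sasc_select(tbl, 5000)
  px <- out$pixels
  # every selected score <= every unselected scored score
  sel_scores <- px$score[which(px$selected)]
  unsel_scores <- px$score[which(!px$selected & !is.na(px$score))]
  if (length(sel_scores) && length(unsel_scores)) {
    expect_lte(max(sel_scores), min(unsel_scores))
  }
  # bit-identical rerun
  expect_identical(out, sasc_select(tbl, 5000))
  # target beyond the scored area selects everything, with a warning
  expect_warning(all_out <- sasc_select(tbl, 1e9), "below the target")
  expect_true(all(all_out$pixels$selected[!is.na(all_out$pixels$score)]))
  # degenerate inputs
  expect_error(sasc_select(tbl, -5), "positive")
  none <- dplyr::mutate(tbl, sfdi = 0.5)
  expect_error(sasc_select(none, 100), "No scored")
})

test_that("partial selection refines the final class toward the target", {
  tbl <- random_pixel_table(64, 42)
  target <- 4000
  whole <- sasc_select(tbl, target)$result
  part <- sasc_select(tbl, target, partial = TRUE)$result
  expect_lte(abs(part$residual), abs(whole$residual))
})

test_that("pixel_area_mu converts projected and geographic cells", {
  m500 <- list(pixel_width = 500, pixel_height = 500, units = "m")
  expect_equal(pixel_area_mu(m500), 375, tolerance = 0.01 / 375)
  one_m2 <- list(pixel_width = 1, pixel_height = 1, units = "m")
  expect_equal(pixel_area_mu(one_m2), 0.0015, tolerance = 1e-4)
  expect_error(pixel_area_mu(list(pixel_width = 0, pixel_height = 5,
                                  units = "m")), "Degenerate")
  # spherical cell at several latitudes against a geodesic polygon oracle
  skip_if_not_installed("geosphere")
  deg <- list(pixel_width = 0.005, pixel_height = 0.005, units = "deg")
  for (lat in c(0, 36.5, 60)) {
    ours <- pixel_area_mu(deg, latitude = lat)
    poly <- cbind(
      c(0, 0.005, 0.005, 0, 0),
      lat + c(-0.0025, -0.0025, 0.0025, 0.0025, -0.0025)
    )
    oracle <- geosphere::areaPolygon(poly, a = 6371007.181, f = 0) / 666.67
    expect_equal(ours, oracle, tolerance = 1e-3)
  }
})
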
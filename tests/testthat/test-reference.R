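test_that("multi_year_average is the pointwise mean", {
  g <- test_template()
  expect_equal(multi_year_average(list(g, g))$ndvi, g$ndvi)
  c1 <- frost_curve(season_start, rep(0.2, 10))
  c2 <- frost_curve(season_start, rep(0.4, 10))
  expect_equal(multi_year_average(list(c1, c2))$ndvi, rep(0.3, 10))
  # independent summation oracle on random curves
  set.seed(21)
  curves <- lapply(1:5, function(i) {
    frost_curve(season_start, runif(30, 0, 0.9))
  })
  manual <- Reduce(`+`, lapply(curves, function(cv) cv$ndvi)) / 5
  expect_equal(multi_year_average(curves)$ndvi, manual)
  expect_error(multi_year_average(list(c1, frost_curve(season_start, 1:5 / 10))),
               "same length")
})

test_that("smf_transform matches its closed forms and a pointwise oracle", {
  g <- test_template()
  # identity under unit scaling, any bias
  expect_equal(smf_transform(g, 1, 1, 0, bias = 0.3)$ndvi, g$ndvi)
  # constant template closed form
  gc <- frost_curve(season_start, rep(0.2, 20))
  expect_equal(smf_transform(gc, 1, 2, 0, bias = 0.61,
                             warn_outside = FALSE)$ndvi,
               rep(2 * (0.2 + 0.61) - 0.61, 20))
  # triangular template against the hand-rolled pointwise oracle
  tri <- triangle_curve()
  h <- smf_transform(tri, 1.05, 1.2, 3, bias = 0.61)
  expect_equal(h$ndvi, smf_oracle(tri, 1.05, 1.2, 3, 0.61), tolerance = 1e-12)
  # sy = 1 makes the transform bias-independent
  expect_equal(smf_transform(tri, 1.08, 1, -5, bias = 0)$ndvi,
               smf_transform(tri, 1.08, 1, -5, bias = 0.61)$ndvi)
  expect_warning(smf_transform(g, sx = 1.5), "bounds")
})

test_that("fit_smf recovers itself and known transformations", {
  g <- test_template()
  self <- fit_smf(g, g)
  expect_equal(self$sx, 1)
  expect_equal(self$sy, 1)
  expect_equal(self$t0, 0)
  expect_lt(self$objective, 1e-12)
  # noise-free parameter recovery
  truth <- c(sx = 1.05, sy = 1.3, t0 = -4)
  target <- smf_transform(g, truth["sx"], truth["sy"], truth["t0"])
  fit <- fit_smf(g, target)
  expect_lt(abs(fit$sx - truth["sx"]), 0.01)
  expect_lt(abs(fit$sy - truth["sy"]), 0.02)
  expect_lt(abs(fit$t0 - truth["t0"]), 0.5)
  # tidiers
  td <- tidy(fit)
  expect_equal(td$term, c("sx", "sy", "t0", "bias"))
  expect_equal(glance(fit)$objective, fit$objective)
})

test_that("fit_smf is never worse than the identity or a lattice oracle", {
  g <- test_template()
  set.seed(31)
  for (i in 1:5) {
    target <- frost_curve(
      g$date,
      smf_transform(g, runif(1, 0.92, 1.08), runif(1, 0.7, 1.6),
                    runif(1, -8, 8))$ndvi + rnorm(92, 0, 0.03),
      clamp = FALSE
    )
    fit <- fit_smf(g, target)
    w <- rep(1, 92)
    obj_id <- wheatfrost:::smf_objective(c(1, 1, 0), g$ndvi, 0:91,
                                         target$ndvi, 0.61, w)
    expect_lte(fit$objective, obj_id)
    # exhaustive coarse lattice (steps 0.01 / 0.05 / 1 day)
    lattice <- expand.grid(sx = seq(0.9, 1.1, 0.01),
                           sy = seq(0.5, 1.85, 0.05),
                           t0 = seq(-10, 10, 1))
    objs <- vapply(seq_len(nrow(lattice)), function(k) {
      wheatfrost:::smf_objective(unlist(lattice[k, ]), g$ndvi, 0:91,
                                 target$ndvi, 0.61, w)
    }, numeric(1))
    expect_lte(fit$objective, min(objs) + 1e-3)
  }
})

test_that("fit_smf honours weights, region mode and degenerate targets", {
  g <- test_template()
  target <- smf_transform(g, 1.02, 1.1, 2)
  # corrupt a stretch of days, then exclude it via weights: fit unaffected
  bad <- target
  bad$ndvi[30:40] <- bad$ndvi[30:40] - 0.4
  w <- rep(1, 92); w[30:40] <- 0
  fit <- fit_smf(g, frost_curve(bad$date, bad$ndvi, clamp = FALSE),
                 weights = w)
  expect_lt(abs(fit$sx - 1.02), 0.01)
  expect_lt(abs(fit$sy - 1.1), 0.02)
  expect_lt(abs(fit$t0 - 2), 0.5)
  # region mode averages the target list first
  fit_region <- fit_smf(g, list(target, target))
  expect_equal(fit_region$sx, fit_smf(g, target)$sx, tolerance = 1e-6)
  expect_warning(fit_const <- fit_smf(g, frost_curve(g$date, rep(0.4, 92))),
                 "constant")
  expect_equal(fit_const$sx, 1)
  expect_equal(fit_const$t0, 0)
})

test_that("noisy parameter recovery succeeds in at least 90% of seeds", {
  g <- test_template()
  target0 <- smf_transform(g, 1.05, 1.3, -4)
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    noisy <- frost_curve(target0$date, target0$ndvi + rnorm(92, 0, 0.02),
                         clamp = FALSE)
    fit <- fit_smf(g, noisy)
    if (abs(fit$sx - 1.05) <= 0.03 && abs(fit$sy - 1.3) <= 0.06 &&
        abs(fit$t0 + 4) <= 1.5) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 45L)
})
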
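test_that("peak locations follow the vertex and endpoint rules", {
  # symmetric quadratic peaks at the center
  fit <- fake_fit("m2", c("(Intercept)" = 1, X2 = -0.01))
  expect_equal(x_max(fit)$x_max, 0)

  # vertex of an offset quadratic, against the grid-search oracle
  fit <- fake_fit("m3", c("(Intercept)" = 1, X = 1, X2 = -0.1))
  xm <- x_max(fit)
  expect_equal(xm$x_max, 5.0)
  expect_equal(xm$x_max, grid_peak(1, 1, -0.1)$x, tolerance = 0.01)
  expect_false(xm$boundary)

  # linear structures peak at the signed endpoint
  fit <- fake_fit("m1", c("(Intercept)" = 0.2, X = 0.01))
  expect_equal(x_max(fit)$x_max, 30)
  fit <- fake_fit("m1", c("(Intercept)" = 0.2, X = -0.01))
  expect_equal(x_max(fit)$x_max, -30)

  # flat structures report the central point
  fit <- fake_fit("m0", c("(Intercept)" = 0.5))
  expect_equal(x_max(fit)$x_max, 0)

  # a vertex beyond the sampled range is clamped and flagged
  fit <- fake_fit("m3", c("(Intercept)" = 1, X = 1, X2 = -0.01))
  xm <- x_max(fit)
  expect_equal(xm$x_max, 30)
  expect_true(xm$boundary)

  # a convex quadratic peaks at whichever endpoint predicts more
  fit <- fake_fit("m3", c("(Intercept)" = 1, X = 0.1, X2 = 0.001))
  xm <- x_max(fit)
  expect_equal(xm$x_max, 30)
  expect_true(xm$boundary)

  expect_error(x_max(fake_fit("z1", c("(Intercept)" = 1, lnZ = -0.5))),
               "x-axis")
})

test_that("the closed-form vertex agrees with grid search over random draws", {
  set.seed(2024)
  for (i in 1:150) {
    I <- runif(1, 0, 3); A <- runif(1, -1, 1); B <- -runif(1, 0.001, 0.1)
    fit <- fake_fit("m3", c("(Intercept)" = I, X = A, X2 = B))
    xm <- x_max(fit)$x_max
    oracle <- grid_peak(I, A, B)
    expect_lte(abs(xm - oracle$x), 0.01)
    expect_equal(I + A * xm + B * xm^2, oracle$value, tolerance = 1e-4)
  }
})

test_that("peak humidity maximizes the predicted elevation over replicates", {
  fit <- fake_fit("m0", c("(Intercept)" = 0.5))
  pk <- delta_rh_max(fit)
  expect_equal(pk$delta_rh_max, 0.5)
  expect_equal(pk$x_max, 0)
  expect_true(is.na(pk$replicate))

  fit <- fake_fit("m2", c("(Intercept)" = 1, X2 = -0.001))
  pk <- delta_rh_max(fit)
  expect_equal(pk$delta_rh_max, 1)
  expect_equal(pk$x_max, 0)

  # replicate intercept shifts: replicate 2 carries the maximum
  fit <- fake_fit("m6", c("(Intercept)" = 1, X2 = -0.001,
                          r2 = 0.3, r3 = 0, r4 = 0))
  pk <- delta_rh_max(fit)
  expect_equal(pk$delta_rh_max, 1.3)
  expect_equal(pk$replicate, 2L)
  # exhaustive oracle over the (fine X grid) x replicate plane
  grid_best <- max(vapply(1:4, function(t) {
    I <- 1 + c(0, 0.3, 0, 0)[t]
    grid_peak(I, 0, -0.001)$value
  }, numeric(1)))
  expect_equal(pk$delta_rh_max, grid_best, tolerance = 1e-6)

  # ties resolve to the earliest replicate
  fit <- fake_fit("m4", c("(Intercept)" = 1, r2 = 0, r3 = 0, r4 = 0))
  expect_equal(delta_rh_max(fit)$replicate, 1L)
})

test_that("peak elevation shifts one-for-one with the intercept and ignores random effects", {
  base <- c("(Intercept)" = 1, X = 0.5, X2 = -0.02, r2 = 0.1, r3 = -0.1, r4 = 0)
  f1 <- fake_fit("m7", base)
  shifted <- base; shifted["(Intercept)"] <- base[["(Intercept)"]] + 0.77
  f2 <- fake_fit("m7", shifted)
  expect_equal(delta_rh_max(f2)$delta_rh_max,
               delta_rh_max(f1)$delta_rh_max + 0.77)
  f3 <- f1; f3$random_intercepts <- c(flower1 = 5, flower2 = -5)
  expect_equal(delta_rh_max(f3)$delta_rh_max, delta_rh_max(f1)$delta_rh_max)
})

test_that("species summary rows are assembled consistently from the pipeline", {
  d <- simulate_delta_rh(n_flowers = 5, seed = 61, species = "sp A")
  sel_x <- select_transect_model(d, "x")
  sel_z <- select_transect_model(d, "z")
  peak <- delta_rh_max(chosen_fit(sel_x))
  row <- assemble_species_summary(sel_x, sel_z, peak,
                                  list(name = "sp A", floral_type = "flower"))
  expect_equal(row$best_x_model, sel_x$chosen)
  expect_equal(row$best_z_model, sel_z$chosen)
  expect_equal(row$delta_rh_max, peak$delta_rh_max)
  expect_equal(row$x_max_mm, peak$x_max)
  expect_true(is.na(row$rank))

  # control rows are excluded from species ranks
  ctrl <- row
  ctrl$name <- "TWL control"; ctrl$is_control <- TRUE
  ctrl$delta_rh_max <- row$delta_rh_max / 2
  ranked <- rank_species_summary(rbind(row, ctrl))
  expect_true(is.na(ranked$rank[ranked$is_control]))
  expect_equal(ranked$rank[!ranked$is_control], 1L)

  # axis-less data fails loudly
  expect_error(select_transect_model(d[d$axis == "x", ], "z"), "no z-axis")
  # mismatched species between axes fail
  d2 <- d; d2$species <- "sp B"
  sel_z2 <- select_transect_model(d2, "z")
  expect_error(assemble_species_summary(sel_x, sel_z2, peak, list(name = "sp A")),
               "inconsistent species")
  # a peak computed from a non-chosen model is rejected
  other <- delta_rh_max(sel_x$fits[[setdiff(sel_x$aic_table$model[
    !sel_x$aic_table$failed], sel_x$chosen)[1]]])
  expect_error(assemble_species_summary(sel_x, sel_z, other, list(name = "sp A")),
               "chosen")
})

test_that("threshold classification reproduces the published survey counts", {
  s <- load_survey_summary()
  counts <- threshold_counts(s)
  expect_equal(counts$above_twl, 30)
  expect_equal(counts$above_tw, 13)
  expect_equal(counts$above_intensity, 6)
  expect_equal(counts$x_max_central, 22)
  expect_equal(counts$x_max_offset_5mm, 5)
  expect_equal(counts$non_quadratic_x, 3)

  # controls only -> every species count is zero
  ctrl_only <- s[s$is_control, ]
  counts0 <- threshold_counts(ctrl_only)
  expect_equal(counts0$n_species, 0)
  expect_equal(counts0$above_twl + counts0$above_tw + counts0$above_intensity +
                 counts0$x_max_central + counts0$x_max_offset_5mm +
                 counts0$non_quadratic_x, 0)

  expect_error(threshold_counts(s[s$name != "TW control", ]), "TW control")
})
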
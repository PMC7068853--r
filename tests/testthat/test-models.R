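test_that("design matrices evaluate the indicator scheme correctly", {
  # flat model: a single intercept column
  X <- build_design("m0", c(-30, 0, 30), c(1, 2, 3))
  expect_equal(colnames(X), "(Intercept)")
  expect_equal(unname(X[, 1]), c(1, 1, 1))

  # full x model on the first replicate: all indicator columns are zero
  X <- build_design("m10", -30, 1)
  expect_equal(unname(drop(X)), c(1, -30, 900, rep(0, 9)))
  expect_equal(colnames(X),
               c("(Intercept)", "X", "X2", "r2", "r3", "r4",
                 "g2X", "g3X", "g4X", "c2X2", "c3X2", "c4X2"))

  # third replicate activates exactly the r3 indicator
  X <- build_design("z3", 5, 3)
  expect_equal(unname(drop(X)), c(1, log(5), 0, 1, 0))
  expect_equal(colnames(X), c("(Intercept)", "lnZ", "r2", "r3", "r4"))

  # interacting columns multiply indicator and position
  X <- build_design("m10", 10, 2)
  expect_equal(unname(X[, "g2X"]), 10)
  expect_equal(unname(X[, "c2X2"]), 100)
  expect_equal(unname(X[, c("g3X", "c3X2")]), c(0, 0))

  expect_error(build_design("z1", c(-5, 5), c(1, 1)), "positive")
  expect_error(build_design("m1", 0, 5), "replicate")
})

test_that("no spec includes an interaction without its main term", {
  for (id in c(transect_model_ids("x"), transect_model_ids("z"))) {
    spec <- transect_model_spec(id)
    if ("g" %in% spec$terms) expect_true("A" %in% spec$terms, label = id)
    if ("c" %in% spec$terms) expect_true("B" %in% spec$terms, label = id)
    # design width matches the free fixed-effect count
    X <- build_design(spec, rep(ifelse(spec$axis == "x", 10, 5), 4), 1:4)
    expected_p <- 1 + ("A" %in% spec$terms) + ("B" %in% spec$terms) +
      3 * sum(c("r", "g", "c") %in% spec$terms)
    expect_equal(ncol(X), expected_p, label = id)
  }
  expect_error(transect_model_spec("m11"), "unknown model id")
})

test_that("constant responses give a boundary fit with the constant intercept", {
  d <- simulate_delta_rh(transect_truth(x_model = "m0", x_params = list(I = 0.7),
                                        z_model = "z0", z_params = list(I = 0.7),
                                        sigma_flower = 0),
                         n_flowers = 3, resid_sd = 0, seed = 1)
  fit <- suppressWarnings(fit_transect_model(d, "m0"))
  expect_equal(unname(coef(fit)[1]), 0.7, tolerance = 1e-6)
  expect_true(fit$boundary)
  expect_lt(fit$sigma2, 1e-8)
})

test_that("fixed-effects fits reproduce ordinary least squares exactly", {
  truth <- transect_truth(x_model = "m2", x_params = list(I = 1, B = -0.002),
                          z_model = "z0", z_params = list(I = 0.5),
                          sigma_flower = 0)
  d <- simulate_delta_rh(truth, n_flowers = 6, resid_sd = 0.05, seed = 42)
  dx <- d[d$axis == "x", ]
  fit <- fit_transect_model(dx, "m2", random_intercept = FALSE)
  ols <- lm(delta_rh ~ I(offset_mm^2), data = dx)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
  # and the estimates recover the truth within 3 standard errors
  se <- summary(ols)$coefficients[, 2]
  expect_lt(abs(coef(fit)[1] - 1), 3 * se[1])
  expect_lt(abs(coef(fit)[2] - (-0.002)), 3 * se[2])
})

test_that("mixed-model log-likelihoods match a dense multivariate-normal oracle", {
  d <- simulate_delta_rh(n_flowers = 4, seed = 7)
  for (id in c("m7", "m2", "m0")) {
    fit <- fit_transect_model(d, id)
    expect_true(fit$random)
    expect_equal(fit$logLik, dense_logLik(fit), tolerance = 1e-6, label = id)
  }
  fit <- fit_transect_model(d, "z3")
  expect_equal(fit$logLik, dense_logLik(fit), tolerance = 1e-6)
  # AIC bookkeeping: k = fixed effects + 2 variance parameters
  fit <- fit_transect_model(d, "m7")
  expect_equal(fit$k, 6 + 2)
  expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$k)
})

test_that("nested specs never decrease the maximized log-likelihood", {
  nested_in <- function(a, b) {   # is a nested in b?
    sa <- transect_model_spec(a); sb <- transect_model_spec(b)
    sa$axis == sb$axis && all(sa$terms %in% sb$terms)
  }
  ids <- transect_model_ids("x")
  for (seed in 1:4) {
    d <- simulate_delta_rh(n_flowers = 4, seed = 100 + seed)
    ll <- vapply(ids, function(id) fit_transect_model(d, id)$logLik, numeric(1))
    for (a in ids) for (b in ids) {
      if (a != b && nested_in(a, b))
        expect_gte(ll[b], ll[a] - 1e-4)
    }
  }
})

test_that("reflecting the x axis negates slope terms and preserves fit quality", {
  truth <- transect_truth(x_model = "m3",
                          x_params = list(I = 1, A = 0.02, B = -0.002))
  d <- simulate_delta_rh(truth, n_flowers = 4, seed = 17)
  d <- d[d$axis == "x", ]
  d_ref <- d
  d_ref$offset_mm <- -d_ref$offset_mm
  f1 <- fit_transect_model(d, "m3")
  f2 <- fit_transect_model(d_ref, "m3")
  expect_equal(unname(coef(f2)["X"]), -unname(coef(f1)["X"]), tolerance = 1e-6)
  expect_equal(unname(coef(f2)["(Intercept)"]), unname(coef(f1)["(Intercept)"]),
               tolerance = 1e-6)
  expect_equal(unname(coef(f2)["X2"]), unname(coef(f1)["X2"]), tolerance = 1e-6)
  expect_equal(f2$aic, f1$aic, tolerance = 1e-6)
})

test_that("model selection builds a complete AIC table with a zero-delta winner", {
  d <- simulate_delta_rh(n_flowers = 5, seed = 23)
  sel <- select_transect_model(d, "x")
  tab <- sel$aic_table
  expect_setequal(tab$model, transect_model_ids("x"))
  expect_equal(min(tab$delta_aic, na.rm = TRUE), 0)
  expect_true(all(tab$delta_aic >= 0, na.rm = TRUE))
  expect_equal(tab$delta_aic[tab$model == sel$chosen], 0)
  expect_true(sel$chosen %in% sel$best_set)
  expect_s3_class(chosen_fit(sel), "transect_fit")

  selz <- select_transect_model(d, "z")
  expect_setequal(selz$aic_table$model, transect_model_ids("z"))
})

test_that("specs that cannot be fitted are recorded as failures, not dropped", {
  d <- simulate_delta_rh(n_flowers = 4, n_replicates = 1, seed = 3)
  sel <- select_transect_model(d, "x")
  tab <- sel$aic_table
  needs_reps <- vapply(tab$model, function(id)
    any(c("r", "g", "c") %in% transect_model_spec(id)$terms), logical(1))
  expect_true(all(tab$failed[needs_reps]))
  expect_true(all(!tab$failed[!needs_reps]))
  expect_match(tab$message[needs_reps][1], "replicate")
  expect_true(sel$chosen %in% c("m0", "m1", "m2", "m3"))
})
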
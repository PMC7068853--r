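test_that("phylogenetic correlations match their definitions", {
  # star tree under BM: no shared history, identity correlation
  C <- build_correlation(star_tree(5), "BM")
  expect_equal(unname(C), diag(5))

  # sisters sharing 60% of tree height correlate at 0.6
  tr <- ape::read.tree(text = "((A:0.4,B:0.4):0.6,C:1);")
  C <- build_correlation(tr, "BM")
  expect_equal(C["A", "B"], 0.6)
  expect_equal(C["A", "C"], 0)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1))

  # branch-length rescaling leaves the BM correlation unchanged
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 37
  expect_equal(build_correlation(tr2, "BM"), C)
})

test_that("OU correlation approaches BM as alpha vanishes and decays with distance", {
  set.seed(41)
  tr <- ape::rphylo(6, 1, 0.3)
  bm <- build_correlation(tr, "BM")
  ou <- build_correlation(tr, "OU", alpha = 1e-6)
  expect_lt(max(abs(ou - bm)), 1e-4)

  # off-diagonals strictly decrease with patristic distance
  ou <- build_correlation(tr, "OU", alpha = 2)
  d <- stats::cophenetic(tr)[rownames(ou), colnames(ou)]
  off <- upper.tri(ou)
  ord <- order(d[off])
  expect_true(all(diff(ou[off][ord]) <= 1e-12))
  expect_equal(unname(diag(ou)), rep(1, 6))

  # the stationary form is available and also has unit diagonal
  ou_s <- build_correlation(tr, "OU", alpha = 2, ou_form = "stationary")
  expect_equal(unname(diag(ou_s)), rep(1, 6))
  expect_error(build_correlation(tr, "OU"), "alpha")
})

test_that("GLS under an identity correlation equals ordinary least squares", {
  sim <- simulate_phylo_traits(25, model = "star", seed = 5)
  tr <- star_tree(25)
  fit <- pgls(response ~ span + floral_type + grown_outside, sim$traits, tr, "BM")
  ols <- lm(response ~ span + floral_type + grown_outside, sim$traits)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-10)
  # the GLS likelihood at the identity equals the direct Gaussian likelihood
  n <- nrow(sim$traits)
  sigma2 <- sum(residuals(ols)^2) / n
  ll <- sum(dnorm(sim$traits$response, fitted(ols), sqrt(sigma2), log = TRUE))
  expect_equal(fit$logLik, ll, tolerance = 1e-8)
})

test_that("GLS matches nlme::gls under Brownian correlation", {
  sim <- simulate_phylo_traits(30, seed = 11)
  fit <- pgls(response ~ span + floral_type + grown_outside,
              sim$traits, sim$tree, "BM")
  d <- sim$traits
  rownames(d) <- d$species
  ref <- nlme::gls(response ~ span + floral_type + grown_outside, data = d,
                   correlation = ape::corBrownian(1, sim$tree, form = ~species),
                   method = "ML")
  expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
})

test_that("model comparisons agree with a brute-force likelihood oracle", {
  sim <- simulate_phylo_traits(25, model = "star", seed = 9)
  tr <- star_tree(25)
  full <- pgls(response ~ span + floral_type + grown_outside, sim$traits, tr, "BM")
  null <- pgls(response ~ 1, sim$traits, tr, "BM")
  cmp <- compare_models(full, null, nested = TRUE)
  # brute-force: both are OLS; evaluate Gaussian likelihoods directly
  ll_of <- function(fml) {
    f <- lm(fml, sim$traits)
    s2 <- sum(residuals(f)^2) / nrow(sim$traits)
    sum(dnorm(sim$traits$response, fitted(f), sqrt(s2), log = TRUE))
  }
  lr_oracle <- 2 * (ll_of(response ~ span + floral_type + grown_outside) -
                      ll_of(response ~ 1))
  expect_equal(cmp$lr_statistic, lr_oracle, tolerance = 1e-8)
  expect_equal(cmp$df, 3)
  expect_equal(cmp$p_value, pchisq(lr_oracle, 3, lower.tail = FALSE))

  same <- compare_models(full, full, nested = FALSE)
  expect_equal(same$delta_aic, 0)
  expect_equal(same$lr_statistic, 0)

  sim2 <- simulate_phylo_traits(20, model = "star", seed = 10)
  other <- pgls(response ~ span, sim2$traits, star_tree(20), "BM")
  expect_error(compare_models(full, other), "different species")
})

test_that("PGLS failure modes are explicit", {
  sim <- simulate_phylo_traits(20, seed = 21)
  tr_missing <- ape::drop.tip(sim$tree, "sp1")
  expect_error(pgls(response ~ span, sim$traits, tr_missing), "sp1")
  d <- sim$traits
  d$span2 <- 2 * d$span
  expect_error(pgls(response ~ span + span2, d, sim$tree), "collinear.*span2")
})

test_that("profile alpha estimation is shift-invariant and recovers OU structure", {
  sim <- simulate_phylo_traits(35, model = "OU", alpha = 5, seed = 33)
  fit <- pgls(response ~ span, sim$traits, sim$tree, "OU")
  expect_true(fit$alpha_estimated)
  expect_gt(fit$alpha, 0)
  d2 <- sim$traits
  d2$response <- d2$response + 50
  fit2 <- pgls(response ~ span, d2, sim$tree, "OU")
  expect_equal(fit2$alpha, fit$alpha, tolerance = 1e-3)
  # with alpha fixed, no rate parameter enters the AIC bookkeeping
  fixed <- pgls(response ~ span, sim$traits, sim$tree, "OU", alpha = fit$alpha)
  expect_equal(fixed$k, fit$k - 1)
})
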
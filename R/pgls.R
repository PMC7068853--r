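#' Phylogenetic correlation matrix among species
#'
#' Builds the expected among-species correlation of a trait under a
#' Brownian-motion (BM) or Ornstein-Uhlenbeck (OU) process on a tree with
#' branch lengths. Under BM the correlation of two tips is their shared
#' root-to-ancestor path length divided by tree height. The default OU form
#' is the fixed-root (Hansen) structure on the height-normalized tree,
#' \deqn{C_{ij} = e^{-\alpha d_{ij}} (1 - e^{-2\alpha s_{ij}}) /
#'   \sqrt{(1 - e^{-2\alpha t_i})(1 - e^{-2\alpha t_j})},}
#' with \eqn{d} the patristic distance, \eqn{s} the shared height and
#' \eqn{t} the tip heights; its \eqn{\alpha \to 0} limit is exactly the BM
#' correlation. The stationary "Martins" form \code{exp(-alpha * d)} is
#' available via \code{ou_form = "stationary"}. In both forms \code{alpha}
#' is on the scale of a tree of unit height, and fitted rates are only
#' comparable under the same convention.
#'
#' @param tree an \code{ape} \code{"phylo"} tree with branch lengths.
#' @param model \code{"BM"} or \code{"OU"}.
#' @param alpha OU rate (> 0); required when \code{model = "OU"}.
#' @param ou_form OU parameterization, \code{"fixed_root"} (default) or
#'   \code{"stationary"}.
#' @return Symmetric correlation matrix with unit diagonal, rows and
#'   columns named by tip label.
#' @export
build_correlation <- function(tree, model = c("BM", "OU"), alpha = NULL,
                              ou_form = c("fixed_root", "stationary")) {
  model <- match.arg(model)
  ou_form <- match.arg(ou_form)
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  V <- ape::vcv(tree)
  if (model == "BM") {
    C <- stats::cov2cor(V)
  } else {
    if (is.null(alpha) || alpha <= 0) stop("OU correlation needs alpha > 0")
    height <- max(diag(V))
    d <- stats::cophenetic(tree)[rownames(V), colnames(V)] / height
    if (ou_form == "stationary") {
      C <- exp(-alpha * d)
    } else {
      s <- V / height                      # shared heights, normalized
      t_i <- diag(s)
      denom <- sqrt(outer(1 - exp(-2 * alpha * t_i),
                          1 - exp(-2 * alpha * t_i)))
      C <- exp(-alpha * d) * (1 - exp(-2 * alpha * s)) / denom
    }
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev))
    stop("correlation matrix is numerically non-positive-definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  C
}

# GLS under a fixed correlation matrix, ML variance (denominator n, the
# likelihood used for model comparison).
gls_core <- function(y, X, C) {
  n <- length(y)
  U <- chol(C)
  wy <- backsolve(U, y, transpose = TRUE)
  wX <- backsolve(U, X, transpose = TRUE)
  qr_wX <- qr(wX)
  if (qr_wX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qr_wX$pivot[seq_len(qr_wX$rank)])]
    stop("collinear predictors: ", paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qr_wX, wy)
  res <- wy - wX %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / n
  logdetC <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetC + n)
  list(beta = beta, sigma2 = sigma2, logLik = ll,
       cov_unscaled = solve(crossprod(wX)), rss = rss)
}

#' Phylogenetically controlled generalized least squares
#'
#' Fits a linear model across species whose residuals are correlated
#' according to a phylogenetic model (BM or OU), by maximum likelihood.
#' When \code{model = "OU"} and \code{alpha} is not supplied, the OU rate is
#' chosen by profile maximum likelihood over a log-spaced grid
#' (\code{1e-4}..\code{1e3}, 61 points) with local refinement.
#'
#' @param formula model formula; variables are taken from \code{data}.
#' @param data data frame, one row per species, with species names either in
#'   a \code{species} column or as row names matching the tree's tip labels.
#' @param tree an \code{ape} \code{"phylo"} tree containing every species.
#' @param model residual correlation model, \code{"BM"} or \code{"OU"}.
#' @param alpha fixed OU rate; \code{NULL} (default) estimates it for OU.
#' @param ou_form OU parameterization (see \code{\link{build_correlation}}).
#' @return An object of class \code{"humidity_pgls"} with
#'   print/summary/coef/logLik/AIC/residuals methods. AIC counts the
#'   regression coefficients, the residual variance, and the OU rate when it
#'   was estimated.
#' @export
pgls <- function(formula, data, tree, model = c("BM", "OU"), alpha = NULL,
                 ou_form = c("fixed_root", "stationary")) {
  model <- match.arg(model)
  ou_form <- match.arg(ou_form)
  species <- if (!is.null(data$species)) as.character(data$species) else rownames(data)
  if (is.null(species) || anyDuplicated(species))
    stop("data must identify each species exactly once (species column or row names)")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  complete <- stats::complete.cases(mf)
  mf <- mf[complete, , drop = FALSE]
  species <- species[complete]
  missing_tips <- setdiff(species, tree$tip.label)
  if (length(missing_tips) > 0)
    stop("species absent from the tree: ", paste(missing_tips, collapse = ", "))
  tree <- ape::keep.tip(tree, species)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (n < ncol(X) + 2)
    stop("need at least ", ncol(X) + 2, " species for ", ncol(X), " coefficients")

  fit_at <- function(a) {
    C <- build_correlation(tree, model, alpha = a,
                           ou_form = ou_form)[species, species]
    gls_core(y, X, C)
  }
  alpha_estimated <- FALSE
  if (model == "OU" && is.null(alpha)) {
    grid <- 10^seq(-4, 3, length.out = 61)
    lls <- vapply(grid, function(a) fit_at(a)$logLik, numeric(1))
    i <- which.max(lls)
    lo <- log10(grid[max(1, i - 1)])
    hi <- log10(grid[min(length(grid), i + 1)])
    opt <- stats::optimize(function(la) fit_at(10^la)$logLik,
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    alpha <- 10^opt$maximum
    alpha_estimated <- TRUE
  }
  core <- if (model == "BM") {
    C <- build_correlation(tree, "BM")[species, species]
    gls_core(y, X, C)
  } else fit_at(alpha)

  p <- ncol(X)
  k <- p + 1 + as.integer(alpha_estimated)
  # residual-df-adjusted SEs (the convention of nlme::gls, which the field
  # reports even for ML fits)
  se <- sqrt(core$sigma2 * n / (n - p) * diag(core$cov_unscaled))
  names(se) <- colnames(X)
  structure(list(coefficients = stats::setNames(drop(core$beta), colnames(X)),
                 se = se,
                 sigma2 = core$sigma2,
                 df_residual = n - p,
                 logLik = core$logLik,
                 k = k,
                 aic = -2 * core$logLik + 2 * k,
                 model = model,
                 alpha = if (model == "OU") alpha else NULL,
                 alpha_estimated = alpha_estimated,
                 n = n,
                 species = species,
                 formula = formula,
                 y = y, X = X),
            class = "humidity_pgls")
}

#' @export
coef.humidity_pgls <- function(object, ...) object$coefficients

#' @export
logLik.humidity_pgls <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
AIC.humidity_pgls <- function(object, ..., k = 2) -2 * object$logLik + k * object$k

#' @export
residuals.humidity_pgls <- function(object, ...) {
  drop(object$y - object$X %*% object$coefficients)
}

#' @export
fitted.humidity_pgls <- function(object, ...) {
  drop(object$X %*% object$coefficients)
}

#' @export
print.humidity_pgls <- function(x, ...) {
  cat("Phylogenetic GLS (", x$model,
      if (!is.null(x$alpha))
        paste0(", alpha = ", format(x$alpha, digits = 4),
               if (x$alpha_estimated) " [profile ML]" else " [fixed]"),
      "), ", x$n, " species\n", sep = "")
  cat("  logLik ", format(x$logLik, digits = 6), ", AIC ",
      format(x$aic, digits = 6), " (k = ", x$k, ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summarize a phylogenetic GLS fit
#'
#' Coefficient table with standard errors, t statistics on \code{n - p}
#' degrees of freedom, p values, and back-transformed (exponentiated)
#' effect sizes with confidence intervals, for models fitted to a
#' log-transformed response.
#'
#' @param object a \code{"humidity_pgls"}.
#' @param conf confidence level.
#' @param ... unused.
#' @return An object of class \code{"summary.humidity_pgls"}.
#' @export
summary.humidity_pgls <- function(object, conf = 0.95, ...) {
  est <- object$coefficients
  se <- object$se
  df <- object$df_residual
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(1 - (1 - conf) / 2, df)
  tab <- data.frame(estimate = est, std_error = se,
                    back_transformed = exp(est),
                    back_ci_low = exp(est - crit * se),
                    back_ci_high = exp(est + crit * se),
                    t_value = tval, df = df, p_value = pval)
  out <- list(coefficients = tab, model = object$model, alpha = object$alpha,
              logLik = object$logLik, aic = object$aic, n = object$n)
  class(out) <- "summary.humidity_pgls"
  out
}

#' @export
print.summary.humidity_pgls <- function(x, ...) {
  cat("Phylogenetic GLS (", x$model,
      if (!is.null(x$alpha)) paste0(", alpha = ", format(x$alpha, digits = 4)),
      "), ", x$n, " species; logLik ", format(x$logLik, digits = 6),
      ", AIC ", format(x$aic, digits = 6), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Compare two fitted models
#'
#' Reports the AIC difference and, for nested fits, the likelihood-ratio
#' statistic \code{2 * (logLik_a - logLik_b)} against a chi-squared
#' reference with \code{k_a - k_b} degrees of freedom.
#'
#' @param fit_a,fit_b fitted models with \code{logLik}/\code{AIC} methods
#'   and matching species sets (e.g. \code{"humidity_pgls"} objects).
#' @param nested is \code{fit_b} nested in \code{fit_a}?
#' @return An object of class \code{"model_comparison"}: \code{delta_aic}
#'   (AIC_a - AIC_b), \code{lr_statistic}, \code{df}, \code{p_value}.
#' @export
compare_models <- function(fit_a, fit_b, nested = FALSE) {
  sp_a <- fit_a$species
  sp_b <- fit_b$species
  if (!is.null(sp_a) && !is.null(sp_b) && !setequal(sp_a, sp_b))
    stop("fits cover different species sets")
  lla <- as.numeric(stats::logLik(fit_a))
  llb <- as.numeric(stats::logLik(fit_b))
  ka <- attr(stats::logLik(fit_a), "df")
  kb <- attr(stats::logLik(fit_b), "df")
  lr <- 2 * (lla - llb)
  df <- ka - kb
  out <- list(delta_aic = stats::AIC(fit_a) - stats::AIC(fit_b),
              lr_statistic = lr,
              df = if (nested) df else NA_integer_,
              p_value = if (nested && df > 0) stats::pchisq(lr, df, lower.tail = FALSE)
                        else NA_real_,
              nested = nested)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: delta AIC = %.3f, LR = %.3f",
              x$delta_aic, x$lr_statistic))
  if (x$nested)
    cat(sprintf(", chi-sq(%d) p = %.4g", x$df, x$p_value))
  cat("\n")
  invisible(x)
}
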
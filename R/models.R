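# Term sets of the humidity-structure model family.
#
# Horizontal (x) transect, full model:
#   dRH = I + i_t + (A + a_t) X + (B + b_t) X^2 + nu_flower
# with per-replicate indicator modifiers: r_t (intercept), g_t (linear term),
# c_t (curvature), all zero for the first replicate transect. The eleven
# x-axis members (m0-m10) and five vertical-axis members (z0-z4, with ln Z
# in place of X and no linear/quadratic split) are nested simplifications.
x_spec_terms <- list(
  m0  = character(0),
  m1  = "A",
  m2  = "B",
  m3  = c("A", "B"),
  m4  = "r",
  m5  = c("A", "r"),
  m6  = c("B", "r"),
  m7  = c("A", "B", "r"),
  m8  = c("A", "r", "g"),
  m9  = c("B", "r", "c"),
  m10 = c("A", "B", "r", "g", "c")
)
z_spec_terms <- list(
  z0 = character(0),
  z1 = "B",
  z2 = "r",
  z3 = c("B", "r"),
  z4 = c("B", "r", "c")
)

x_descriptions <- c(
  m0  = "flat, no replicate effects",
  m1  = "linear, no replicate effects",
  m2  = "quadratic, no replicate effects",
  m3  = "offset quadratic, no replicate effects",
  m4  = "flat, replicate intercepts",
  m5  = "linear, replicate intercepts",
  m6  = "quadratic, replicate intercepts",
  m7  = "offset quadratic, replicate intercepts",
  m8  = "linear, interacting replicate effects",
  m9  = "quadratic, interacting replicate effects",
  m10 = "full: offset quadratic, interacting replicate effects"
)
z_descriptions <- c(
  z0 = "flat, no replicate effects",
  z1 = "logarithmic, no replicate effects",
  z2 = "flat, replicate intercepts",
  z3 = "logarithmic, replicate intercepts",
  z4 = "full: logarithmic, interacting replicate effects"
)

#' Humidity-structure model specification
#'
#' Looks up one member of the transect model family by id: \code{m0}-\code{m10}
#' for the horizontal (x) axis, \code{z0}-\code{z4} for the vertical (z) axis.
#' Each spec records which terms are free: \code{A} (linear offset term, x
#' only), \code{B} (curvature, or log-slope on the z axis), \code{r}
#' (per-replicate intercept shifts), \code{g} (per-replicate changes in the
#' linear term, x only), \code{c} (per-replicate changes in curvature or log
#' slope). Interaction modifiers require their main term (\code{g} needs
#' \code{A}, \code{c} needs \code{B}).
#'
#' @param id model id, e.g. \code{"m7"} or \code{"z3"}.
#' @return An object of class \code{"transect_model_spec"}.
#' @export
transect_model_spec <- function(id) {
  if (id %in% names(x_spec_terms)) {
    axis <- "x"; terms <- x_spec_terms[[id]]; descr <- x_descriptions[[id]]
  } else if (id %in% names(z_spec_terms)) {
    axis <- "z"; terms <- z_spec_terms[[id]]; descr <- z_descriptions[[id]]
  } else {
    stop("unknown model id '", id, "' (expected m0-m10 or z0-z4)")
  }
  structure(list(id = id, axis = axis, terms = terms, description = descr),
            class = "transect_model_spec")
}

#' @export
print.transect_model_spec <- function(x, ...) {
  cat(x$id, " (", x$axis, " axis): ", x$description, "\n", sep = "")
  invisible(x)
}

#' All model ids for one axis
#'
#' @param axis \code{"x"} or \code{"z"}.
#' @return Character vector of model ids.
#' @export
transect_model_ids <- function(axis = c("x", "z")) {
  axis <- match.arg(axis)
  if (axis == "x") names(x_spec_terms) else names(z_spec_terms)
}

#' Fixed-effects design matrix for a humidity-structure model
#'
#' Builds one row per observation: intercept; \code{X} and \code{X2} (or
#' \code{lnZ}) as the spec includes them; indicator columns \code{r2},
#' \code{r3}, \code{r4} for the second to fourth replicate transects; and
#' indicator-by-position interaction columns (\code{g2X}..., \code{c2X2}...
#' or \code{c2lnZ}...). First-replicate indicators are identically zero, so
#' the base terms describe the first transect.
#'
#' @param spec a \code{\link{transect_model_spec}} (or model id).
#' @param offset numeric offsets: X in mm (x axis) or Z in mm, Z > 0 (z axis).
#' @param replicate integer replicate transect 1-4.
#' @return Numeric design matrix with named columns.
#' @export
build_design <- function(spec, offset, replicate) {
  if (is.character(spec)) spec <- transect_model_spec(spec)
  stopifnot(length(offset) == length(replicate))
  if (!all(replicate %in% 1:4))
    stop("replicate must be in 1..4")
  if (spec$axis == "z" && any(offset <= 0))
    stop("z-axis offsets must be positive for the logarithmic term")
  pos <- if (spec$axis == "x") offset else log(offset)
  cols <- list("(Intercept)" = rep(1, length(offset)))
  if ("A" %in% spec$terms) cols$X <- pos
  if ("B" %in% spec$terms) {
    if (spec$axis == "x") cols$X2 <- pos^2 else cols$lnZ <- pos
  }
  ind <- lapply(2:4, function(t) as.numeric(replicate == t))
  names(ind) <- paste0("r", 2:4)
  if ("r" %in% spec$terms) cols <- c(cols, ind)
  if ("g" %in% spec$terms) {
    gx <- lapply(ind, function(v) v * pos)
    names(gx) <- paste0("g", 2:4, "X")
    cols <- c(cols, gx)
  }
  if ("c" %in% spec$terms) {
    quad <- if (spec$axis == "x") pos^2 else pos
    cx <- lapply(ind, function(v) v * quad)
    names(cx) <- paste0("c", 2:4, if (spec$axis == "x") "X2" else "lnZ")
    cols <- c(cols, cx)
  }
  do.call(cbind, cols)
}

#' Fit one humidity-structure model
#'
#' Fits the specified member of the model family to per-period mean humidity
#' differences by maximum likelihood (not REML, because AIC comparisons span
#' models with different fixed effects), with a Gaussian random intercept
#' per flower. The AIC uses k = number of free fixed effects + 2 variance
#' parameters (flower-intercept variance and residual variance).
#'
#' With a single flower, or \code{random_intercept = FALSE}, the model drops
#' the random intercept and reduces to ordinary least squares (k counts one
#' variance parameter).
#'
#' @param data a \code{"delta_rh"} data frame (columns \code{flower},
#'   \code{replicate}, \code{offset_mm}, \code{delta_rh}, and \code{axis}
#'   if mixed axes are present).
#' @param model model id or \code{\link{transect_model_spec}}.
#' @param random_intercept include the per-flower random intercept.
#' @return An object of class \code{"transect_fit"}.
#' @export
fit_transect_model <- function(data, model, random_intercept = TRUE) {
  spec <- if (is.character(model)) transect_model_spec(model) else model
  if (!is.null(data$axis)) {
    data <- data[data$axis == spec$axis, , drop = FALSE]
    if (nrow(data) == 0)
      stop("no ", spec$axis, "-axis records in the data for model ", spec$id)
  }
  y <- data$delta_rh
  X <- build_design(spec, data$offset_mm, data$replicate)
  if ("r" %in% spec$terms || "g" %in% spec$terms || "c" %in% spec$terms) {
    missing_t <- setdiff(2:4, unique(data$replicate))
    if (length(missing_t) > 0)
      stop("model ", spec$id, " needs replicate transects ",
           paste(missing_t, collapse = ", "), " which are absent from the data")
  }
  flower <- factor(data$flower)
  n_flowers <- nlevels(flower)
  use_random <- random_intercept && n_flowers >= 2
  if (random_intercept && n_flowers < 2)
    warning("single flower: falling back to a fixed-effects fit for ", spec$id)

  p <- ncol(X)
  if (use_random) {
    df <- data.frame(y = y, flower = flower)
    xnames <- paste0("x", seq_len(p))
    df[xnames] <- as.data.frame(X)
    fml <- stats::as.formula(paste("y ~ 0 +", paste(xnames, collapse = " + "),
                                   "+ (1 | flower)"))
    fit <- lme4::lmer(fml, data = df, REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    beta <- lme4::fixef(fit)
    names(beta) <- colnames(X)
    vc <- lme4::VarCorr(fit)
    sigma2_flower <- as.numeric(vc$flower[1])
    sigma2 <- attr(vc, "sc")^2
    ll <- as.numeric(stats::logLik(fit))
    re <- lme4::ranef(fit)$flower[[1]]
    names(re) <- rownames(lme4::ranef(fit)$flower)
    k <- p + 2
  } else {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    if (anyNA(beta))
      stop("singular design for model ", spec$id,
           ": aliased columns ", paste(colnames(X)[is.na(beta)], collapse = ", "))
    n <- length(y)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n   # ML variance
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
    sigma2_flower <- 0
    re <- stats::setNames(rep(0, n_flowers), levels(flower))
    k <- p + 1
  }
  structure(list(spec = spec,
                 coefficients = beta,
                 sigma2 = sigma2,
                 sigma2_flower = sigma2_flower,
                 random_intercepts = re,
                 logLik = ll,
                 k = k,
                 aic = -2 * ll + 2 * k,
                 n_obs = length(y),
                 n_flowers = n_flowers,
                 boundary = use_random && sigma2_flower <= 1e-10,
                 random = use_random,
                 data = data,
                 species = if (!is.null(data$species)) unique(data$species) else NULL),
            class = "transect_fit")
}

#' @export
print.transect_fit <- function(x, digits = 4, ...) {
  cat("Humidity-structure model ", x$spec$id, " (", x$spec$description,
      ")\n", sep = "")
  cat("  ML fit: logLik ", format(x$logLik, digits = digits), ", AIC ",
      format(x$aic, digits = digits), " (k = ", x$k, "), n = ", x$n_obs,
      " periods, ", x$n_flowers, " flowers\n", sep = "")
  cat("  Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  Variances: flower intercept %.4g%s, residual %.4g\n",
              x$sigma2_flower, if (x$boundary) " (at boundary)" else "",
              x$sigma2))
  invisible(x)
}

#' @export
coef.transect_fit <- function(object, ...) object$coefficients

#' @export
logLik.transect_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
AIC.transect_fit <- function(object, ..., k = 2) -2 * object$logLik + k * object$k

#' Predict population-level humidity differences
#'
#' Evaluates the fitted mean structure with the flower random intercept set
#' to zero.
#'
#' @param object a \code{"transect_fit"}.
#' @param newdata data frame with \code{offset_mm} and \code{replicate};
#'   defaults to the training data.
#' @param ... unused.
#' @return Numeric vector of predicted mean humidity differences (\% RH).
#' @export
predict.transect_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  X <- build_design(object$spec, newdata$offset_mm, newdata$replicate)
  drop(X %*% object$coefficients)
}

#' @export
residuals.transect_fit <- function(object, ...) {
  mu <- predict(object) + object$random_intercepts[as.character(object$data$flower)]
  object$data$delta_rh - mu
}

#' Gaussian log-likelihood of a fitted model by direct evaluation
#'
#' Evaluates the marginal multivariate-normal density of the observations at
#' the fitted parameters using the dense covariance
#' \eqn{\sigma^2 I + \sigma^2_{flower} Z Z'}. Exists as an independent check
#' of the mixed-model likelihood on small problems.
#'
#' @param fit a \code{"transect_fit"}.
#' @return Log-likelihood value.
#' @export
dense_logLik <- function(fit) {
  data <- fit$data
  X <- build_design(fit$spec, data$offset_mm, data$replicate)
  mu <- drop(X %*% fit$coefficients)
  Z <- stats::model.matrix(~ 0 + factor(data$flower))
  V <- fit$sigma2 * diag(nrow(X)) + fit$sigma2_flower * tcrossprod(Z)
  r <- data$delta_rh - mu
  ch <- chol(V)
  logdet <- 2 * sum(log(diag(ch)))
  q <- sum(backsolve(ch, r, transpose = TRUE)^2)
  -0.5 * (nrow(X) * log(2 * pi) + logdet + q)
}
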
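anova_icc <- function(x, group) {
  group <- factor(group)
  k <- nlevels(group)
  ni <- tabulate(group)
  N <- length(x)
  gm <- tapply(x, group, mean)
  ssb <- sum(ni * (gm - mean(x))^2)
  ssw <- sum((x - gm[group])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)   # balanced: common group size
  var_between <- max(0, (msb - msw) / n0)
  total <- var_between + msw
  if (total <= 0) return(NA_real_)
  var_between / total
}

#' Within-period repeatability of humidity differences
#'
#' Estimates the repeatability (intraclass correlation) of individual
#' reading-level humidity differences, with the measurement period as the
#' grouping factor: the proportion of total variance attributable to
#' differences among periods, from a one-way random-effects Gaussian
#' decomposition (ANOVA variance components, negative between-period
#' variance truncated at zero). The standard error and confidence interval
#' come from a parametric bootstrap: Gaussian data are re-simulated from
#' the fitted variance components on the observed group structure and the
#' estimator is re-applied.
#'
#' @param x numeric readings (e.g. the \code{delta} column of
#'   \code{\link{delta_rh_readings}}).
#' @param group grouping factor (e.g. the \code{period} column).
#' @param n_bootstrap number of bootstrap refits (default 100).
#' @param conf confidence level for the percentile interval.
#' @return An object of class \code{"repeatability"}: \code{R}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{n_groups}, \code{n_bootstrap},
#'   and the variance components.
#' @export
repeatability <- function(x, group, n_bootstrap = 100, conf = 0.95) {
  group <- factor(group)
  ni <- tabulate(group)
  keep <- group %in% levels(group)[ni >= 2]
  x <- x[keep]
  group <- droplevels(group[keep])
  if (nlevels(group) < 2)
    stop("repeatability needs >= 2 measurement periods with >= 2 readings each")
  if (stats::var(x) == 0)
    stop("degenerate input: zero total variance across all readings")

  group <- factor(group)
  k <- nlevels(group)
  ni <- tabulate(group)
  N <- length(x)
  gm <- tapply(x, group, mean)
  msw <- sum((x - gm[group])^2) / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  msb <- sum(ni * (gm - mean(x))^2) / (k - 1)
  var_between <- max(0, (msb - msw) / n0)
  R <- var_between / (var_between + msw)

  boot <- vapply(seq_len(n_bootstrap), function(b) {
    mu_g <- stats::rnorm(k, mean(x), sqrt(var_between))
    sim <- mu_g[group] + stats::rnorm(N, 0, sqrt(msw))
    anova_icc(sim, group)
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  structure(list(R = R,
                 se = stats::sd(boot),
                 ci_low = min(ci[1], R), ci_high = max(ci[2], R),
                 var_between = var_between, var_within = msw,
                 n_groups = k, n_obs = N, n_bootstrap = n_bootstrap),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f (SE %.3f, 95%% CI [%.3f, %.3f])\n",
              x$R, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  %d groups, %d readings; between-group var %.4g, within %.4g\n",
              x$n_groups, x$n_obs, x$var_between, x$var_within))
  invisible(x)
}

#' Start-vs-end change in focal humidity within each measurement period
#'
#' Residual turbulence from probe movement may leave the humidity around the
#' focal probe still settling when a measurement period begins. For each
#' period this computes the mean uncorrected focal humidity over the first
#' and last 20 s of the measurement window (\code{f_first}, \code{f_last}),
#' the mean over the whole period (\code{f_mean}), and the non-directional
#' change \code{f_change}. By default \code{f_change} is the absolute
#' difference \code{|f_first - f_last|}; the squared difference is available
#' via \code{convention = "squared"}.
#'
#' @param log a \code{"probe_log"}.
#' @param convention \code{"absolute"} (default) or \code{"squared"}.
#' @param window_s length of the start and end windows (s), default 20.
#' @param layout the run layout (timing of settling/measurement windows).
#' @return A \code{"turbulence"} data frame, one row per measurement
#'   period, with a \code{flagged} column marking periods whose start or
#'   end window holds fewer than 2 readings.
#' @export
turbulence_change <- function(log, convention = c("absolute", "squared"),
                              window_s = 20,
                              layout = attr(log, "layout")) {
  convention <- match.arg(convention)
  if (is.null(layout)) layout <- transect_layout()
  if (layout$measurement_s < 2 * window_s)
    stop("measurement period must span at least ", 2 * window_s, " s")
  t0 <- layout$settling_s
  t1 <- layout$settling_s + layout$measurement_s
  foc <- log[log$probe_role == "focal" & !log$settling, , drop = FALSE]
  sp <- split(foc, period_id(foc))
  out <- do.call(rbind, lapply(sp, function(p) {
    first <- p$rh_pct[p$timestamp_s < t0 + window_s]
    last <- p$rh_pct[p$timestamp_s >= t1 - window_s]
    f_first <- mean(first)
    f_last <- mean(last)
    diffv <- f_first - f_last
    data.frame(day = p$day[1], flower = p$flower[1], species = p$species[1],
               replicate = p$replicate[1], axis = p$axis[1],
               offset_mm = p$offset_mm[1],
               f_first = f_first, f_last = f_last, f_mean = mean(p$rh_pct),
               f_change = if (convention == "absolute") abs(diffv) else diffv^2,
               flagged = length(first) < 2 || length(last) < 2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "convention") <- convention
  class(out) <- c("turbulence", "data.frame")
  out
}

#' Regression of turbulence change on mean focal humidity
#'
#' Fits \code{f_change ~ f_mean} by ordinary least squares across
#' measurement periods, testing whether the start-vs-end change in focal
#' humidity grows with how humid the sampled air is.
#'
#' @param records a \code{"turbulence"} data frame from
#'   \code{\link{turbulence_change}}; flagged periods are dropped.
#' @param conf confidence level for parameter intervals.
#' @return A \code{"turbulence_fit"}: coefficient table (estimate, standard
#'   error, confidence interval, t, p) plus the underlying \code{lm} fit.
#' @export
turbulence_regression <- function(records, conf = 0.95) {
  records <- records[!records$flagged, , drop = FALSE]
  if (nrow(records) < 3)
    stop("turbulence regression needs >= 3 unflagged periods")
  if (stats::var(records$f_mean) == 0)
    stop("zero variance in f_mean: regression is undefined")
  fit <- stats::lm(f_change ~ f_mean, data = records)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf)
  tab <- data.frame(parameter = c("Model intercept", "f_mean"),
                    estimate = sm[, 1], std_error = sm[, 2],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    t_value = sm[, 3], p_value = sm[, 4],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(coefficients = tab, df = fit$df.residual, fit = fit,
                 n = nrow(records)),
            class = "turbulence_fit")
}

#' @export
print.turbulence_fit <- function(x, ...) {
  cat("Turbulence regression: f_change ~ f_mean (", x$n, " periods, ",
      x$df, " df)\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
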
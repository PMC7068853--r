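complete_modifiers <- function(params) {
  for (nm in c("r", "g", "c")) {
    v <- params[[nm]]
    if (is.null(v)) v <- c(0, 0, 0)
    if (length(v) != 3) stop("modifier '", nm, "' must have 3 values (t = 2, 3, 4)")
    params[[nm]] <- v
  }
  for (nm in c("I", "A", "B"))
    if (is.null(params[[nm]])) params[[nm]] <- 0
  params
}

#' Ground truth for a synthetic transect dataset
#'
#' Describes the data-generating process the transect generator emulates:
#' the true humidity structure on each axis (a member of the model family
#' with its parameter values), the flower-to-flower intercept spread, the
#' sensor and microclimate noise, the slowly drifting background humidity,
#' and the focal-probe miscalibration that the cross-calibration stage must
#' undo.
#'
#' Defaults emulate the survey conditions: background humidity around
#' 49.1 \%RH; a sinusoidal within-day drift (amplitude 3 \%RH, period one
#' day) standing in for ordinary indoor humidity swings; per-reading sensor
#' noise of 0.2 \%RH; a focal probe whose raw scale differs from the
#' background probe by a few percent (true W = 0.96, M = 2 \%RH, within the
#' sensors' stated inter-unit tolerance).
#'
#' @param x_model,x_params x-axis truth: model id and parameter list with
#'   \code{I}, \code{A}, \code{B} and per-replicate modifiers \code{r},
#'   \code{g}, \code{c} (each length 3, for t = 2..4).
#' @param z_model,z_params z-axis truth (\code{I}, \code{B}, \code{r},
#'   \code{c}); \code{B} multiplies \code{ln Z}.
#' @param sigma_flower SD of the per-flower random intercept (\% RH).
#' @param reading_sd per-reading sensor noise SD (\% RH).
#' @param period_sd SD of a per-period microclimate deviation (\% RH),
#'   humidity structure fluctuation not removed by background subtraction.
#' @param background_mean mean background relative humidity (\%).
#' @param drift_amplitude amplitude of the sinusoidal background drift
#'   (\% RH) over one \code{drift_period_s}.
#' @param drift_period_s period of the background drift (s), default one day.
#' @param wander_sd stationary SD (\% RH) of a slow, spatially common
#'   room-humidity wander (AR(1) across stops). Both probes see it, so it
#'   cancels in simultaneous subtraction, but it gives the cross-calibration
#'   regression a realistic humidity range to fit across.
#' @param wander_tau_s correlation time (s) of the room wander.
#' @param W,M true focal-probe miscalibration: the recorded focal reading is
#'   \code{(true - M) / W}, so that the affine correction \code{W * raw + M}
#'   restores the background-probe scale.
#' @return An object of class \code{"transect_truth"}.
#' @export
transect_truth <- function(x_model = "m7",
                           x_params = list(I = 1.2, A = 0.03, B = -0.003,
                                           r = c(-0.2, -0.35, -0.5)),
                           z_model = "z3",
                           z_params = list(I = 1.7, B = -0.5,
                                           r = c(-0.2, -0.35, -0.5)),
                           sigma_flower = 0.1,
                           reading_sd = 0.2,
                           period_sd = 0.15,
                           background_mean = 49.1,
                           drift_amplitude = 3,
                           drift_period_s = 86400,
                           wander_sd = 4,
                           wander_tau_s = 1800,
                           W = 0.96, M = 2) {
  x_spec <- transect_model_spec(x_model)
  z_spec <- transect_model_spec(z_model)
  if (x_spec$axis != "x" || z_spec$axis != "z")
    stop("x_model must be an m-spec and z_model a z-spec")
  x_params <- complete_modifiers(x_params)
  z_params <- complete_modifiers(z_params)
  check_terms <- function(spec, params) {
    if (!"A" %in% spec$terms && params$A != 0)
      stop("truth for ", spec$id, " must not set A")
    if (!"B" %in% spec$terms && params$B != 0)
      stop("truth for ", spec$id, " must not set B")
    if (!"r" %in% spec$terms && any(params$r != 0))
      stop("truth for ", spec$id, " must not set r")
    if (!"g" %in% spec$terms && any(params$g != 0))
      stop("truth for ", spec$id, " must not set g")
    if (!"c" %in% spec$terms && any(params$c != 0))
      stop("truth for ", spec$id, " must not set c")
  }
  check_terms(x_spec, x_params)
  check_terms(z_spec, z_params)
  stopifnot(sigma_flower >= 0, reading_sd >= 0, period_sd >= 0,
            drift_amplitude >= 0, wander_sd >= 0, wander_tau_s > 0, W != 0)
  structure(list(x_model = x_model, x_params = x_params,
                 z_model = z_model, z_params = z_params,
                 sigma_flower = sigma_flower, reading_sd = reading_sd,
                 period_sd = period_sd, background_mean = background_mean,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 wander_sd = wander_sd, wander_tau_s = wander_tau_s,
                 W = W, M = M),
            class = "transect_truth")
}

# True mean humidity elevation at given offsets and replicates.
truth_mean <- function(truth, axis, offset, replicate) {
  params <- if (axis == "x") truth$x_params else truth$z_params
  mod <- function(v) ifelse(replicate == 1, 0, v[pmax(replicate - 1, 1)])
  I_t <- params$I + mod(params$r)
  A_t <- params$A + mod(params$g)
  B_t <- params$B + mod(params$c)
  if (axis == "x") I_t + A_t * offset + B_t * offset^2
  else I_t + B_t * log(offset)
}

#' Analytic peak of a ground truth
#'
#' Applies the vertex / endpoint peak rules to the true x-axis parameters,
#' giving the peak location and humidity elevation the estimation pipeline
#' should recover.
#'
#' @param truth a \code{\link{transect_truth}}.
#' @param range sampled x range (mm).
#' @return List with \code{x_max}, \code{delta_rh_max}, \code{replicate}.
#' @export
truth_peak <- function(truth, range = c(-30, 30)) {
  p <- truth$x_params
  ts <- 1:4
  xs <- vapply(ts, function(t) {
    A <- p$A + if (t == 1) 0 else p$g[t - 1]
    B <- p$B + if (t == 1) 0 else p$c[t - 1]
    if (B < 0) min(max(-A / (2 * B), range[1]), range[2])
    else if (B > 0) { ends <- range; ends[which.max(A * ends + B * ends^2)] }
    else if (A != 0) { if (A > 0) range[2] else range[1] }
    else 0
  }, numeric(1))
  vals <- truth_mean(truth, "x", xs, ts)
  best <- which.max(vals)
  list(x_max = xs[best], delta_rh_max = vals[best], replicate = ts[best])
}

#' Simulate a full probe log with known ground truth
#'
#' Emulates one day's robot run: for each replicate transect and flower, the
#' focal probe visits every x and z offset and then a probe-control position
#' beside the background probe, dwelling \code{settling_s + measurement_s}
#' seconds at each stop. Both probes record readings on a jittered ~2 s
#' cadence. The background probe reads the drifting room humidity plus
#' sensor noise; the focal probe reads the room humidity plus the true
#' humidity structure, a per-flower intercept, a per-period microclimate
#' deviation, and sensor noise — and its recorded values are distorted by
#' the true miscalibration \code{(true - M) / W}, so a fitted calibration
#' with slope W and intercept M restores them.
#'
#' @param truth a \code{\link{transect_truth}}.
#' @param n_flowers number of flowers.
#' @param n_replicates replicate transects (<= layout replicates).
#' @param layout a \code{\link{transect_layout}}.
#' @param day day identifier stamped on all rows.
#' @param species species label.
#' @param seed integer seed; identical seeds give identical logs.
#' @param cadence_s nominal sampling interval (s).
#' @param jitter_s uniform timestamp jitter (s) around the cadence.
#' @return A validated \code{"probe_log"} with the truth attached as
#'   \code{attr(, "truth")}.
#' @export
simulate_probe_log <- function(truth = transect_truth(), n_flowers = 6,
                               n_replicates = 4, layout = transect_layout(),
                               day = "day1", species = "synthetic",
                               seed = NULL, cadence_s = 2, jitter_s = 0.2) {
  if (n_replicates > layout$replicates)
    stop("n_replicates exceeds the layout's replicate count")
  if (!is.null(seed)) set.seed(seed)
  nu_x <- stats::rnorm(n_flowers, 0, truth$sigma_flower)
  nu_z <- stats::rnorm(n_flowers, 0, truth$sigma_flower)
  stop_s <- layout$settling_s + layout$measurement_s
  nominal <- seq(0, stop_s, by = cadence_s)
  level_at <- function(t_abs) {
    truth$background_mean +
      truth$drift_amplitude * sin(2 * pi * t_abs / truth$drift_period_s)
  }
  stops <- rbind(
    data.frame(axis = "x", offset = layout$x_offsets),
    data.frame(axis = "z", offset = layout$z_offsets),
    data.frame(axis = "probe_control", offset = NA_real_)
  )
  n_stops_total <- n_replicates * n_flowers * nrow(stops)
  # spatially common slow room wander, one value per stop (AR(1) across stops)
  phi <- exp(-stop_s / truth$wander_tau_s)
  wander <- as.numeric(stats::filter(
    stats::rnorm(n_stops_total, 0, truth$wander_sd * sqrt(1 - phi^2)),
    phi, method = "recursive",
    init = stats::rnorm(1, 0, truth$wander_sd)))
  pieces <- vector("list", n_stops_total)
  idx <- 0
  t_global <- 0
  for (t_rep in seq_len(n_replicates)) {
    for (fl in seq_len(n_flowers)) {
      for (s in seq_len(nrow(stops))) {
        axis <- stops$axis[s]
        off <- stops$offset[s]
        ts_f <- pmin(pmax(nominal + stats::runif(length(nominal), -jitter_s, jitter_s), 0), stop_s)
        ts_b <- pmin(pmax(nominal + stats::runif(length(nominal), -jitter_s, jitter_s), 0), stop_s)
        lev_f <- level_at(t_global + ts_f) + wander[idx + 1]
        lev_b <- level_at(t_global + ts_b) + wander[idx + 1]
        bg <- lev_b + stats::rnorm(length(ts_b), 0, truth$reading_sd)
        if (axis == "probe_control") {
          foc_true <- lev_f + stats::rnorm(length(ts_f), 0, truth$reading_sd)
        } else {
          mu <- truth_mean(truth, axis, off, t_rep) +
            (if (axis == "x") nu_x[fl] else nu_z[fl]) +
            stats::rnorm(1, 0, truth$period_sd)
          foc_true <- lev_f + mu + stats::rnorm(length(ts_f), 0, truth$reading_sd)
        }
        foc_rec <- (foc_true - truth$M) / truth$W
        flower_id <- paste0("flower", fl)
        pieces[[idx <- idx + 1]] <- data.frame(
          day = day, flower = flower_id, species = species,
          replicate = t_rep, axis = axis,
          offset_mm = off,
          probe_role = rep(c("focal", "background"),
                           c(length(ts_f), length(ts_b))),
          timestamp_s = c(ts_f, ts_b),
          rh_pct = pmin(pmax(c(foc_rec, bg), 0), 100),
          stringsAsFactors = FALSE
        )
        t_global <- t_global + stop_s
      }
    }
  }
  log <- validate_probe_log(do.call(rbind, pieces), layout)
  attr(log, "truth") <- truth
  log
}

#' Simulate per-period humidity differences directly
#'
#' Fast period-level counterpart of \code{\link{simulate_probe_log}}:
#' draws the per-period mean humidity differences the calibration stage
#' would produce, skipping reading-level generation. Used for model-recovery
#' studies where thousands of datasets are needed.
#'
#' @param truth a \code{\link{transect_truth}} (structure, flower SD).
#' @param n_flowers number of flowers.
#' @param n_replicates replicate transects.
#' @param axes which axes to generate.
#' @param resid_sd residual SD of a period-mean humidity difference (\% RH);
#'   the default 0.15 matches the microclimate and reading-noise defaults of
#'   the reading-level generator averaged over ~100 readings.
#' @param layout a \code{\link{transect_layout}}.
#' @param day,species identifiers.
#' @param seed integer seed.
#' @return A \code{"delta_rh"} data frame.
#' @export
simulate_delta_rh <- function(truth = transect_truth(), n_flowers = 6,
                              n_replicates = 4, axes = c("x", "z"),
                              resid_sd = 0.15, layout = transect_layout(),
                              day = "day1", species = "synthetic",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grids <- list(x = layout$x_offsets, z = layout$z_offsets)
  rows <- list()
  for (axis in axes) {
    nu <- stats::rnorm(n_flowers, 0, truth$sigma_flower)
    grid <- expand.grid(offset_mm = grids[[axis]],
                        replicate = seq_len(n_replicates),
                        flower = seq_len(n_flowers))
    mu <- truth_mean(truth, axis, grid$offset_mm, grid$replicate)
    rows[[axis]] <- data.frame(
      day = day, flower = paste0("flower", grid$flower), species = species,
      replicate = grid$replicate, axis = axis, offset_mm = grid$offset_mm,
      delta_rh = mu + nu[grid$flower] + stats::rnorm(nrow(grid), 0, resid_sd),
      within_period_sd = resid_sd, n_pairs = NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("delta_rh", "data.frame")
  out
}

#' Simulate a comparative dataset on a random phylogeny
#'
#' Generates a birth-death tree, trait predictors (log-normal span,
#' Bernoulli(0.5) floral type and growth condition), and a response drawn
#' multivariate-normal with mean \code{X beta} and covariance
#' \code{sigma2} times the BM or OU correlation of the tree.
#'
#' @param n_species number of tips (>= 10).
#' @param beta true coefficients, named \code{(Intercept)}, \code{span},
#'   \code{floral_type}, \code{grown_outside}.
#' @param model \code{"BM"}, \code{"OU"}, or \code{"star"} (identity
#'   correlation).
#' @param alpha OU rate (when \code{model = "OU"}).
#' @param sigma2 residual variance.
#' @param seed integer seed.
#' @param birth,death birth-death rates of the simulated tree.
#' @param span_meanlog,span_sdlog log-normal parameters of the span (mm).
#' @return List with \code{tree}, \code{traits} (data frame with a
#'   \code{species} column and \code{response}), \code{beta}, \code{sigma2}.
#' @export
simulate_phylo_traits <- function(n_species = 40,
                                  beta = c("(Intercept)" = -1.2, span = 0.01,
                                           floral_type = 0.5,
                                           grown_outside = 0.3),
                                  model = c("BM", "OU", "star"),
                                  alpha = 1, sigma2 = 1, seed = NULL,
                                  birth = 1, death = 0.2,
                                  span_meanlog = log(35), span_sdlog = 0.4) {
  model <- match.arg(model)
  if (n_species < 10) stop("n_species must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth, death = death)
  tree$tip.label <- paste0("sp", seq_len(n_species))
  traits <- data.frame(
    species = tree$tip.label,
    span = stats::rlnorm(n_species, span_meanlog, span_sdlog),
    floral_type = stats::rbinom(n_species, 1, 0.5),
    grown_outside = stats::rbinom(n_species, 1, 0.5),
    stringsAsFactors = FALSE
  )
  X <- stats::model.matrix(~ span + floral_type + grown_outside, traits)
  C <- switch(model,
              star = diag(n_species),
              BM = build_correlation(tree, "BM"),
              OU = build_correlation(tree, "OU", alpha = alpha))
  if (model != "star") C <- C[traits$species, traits$species]
  noise <- drop(crossprod(chol(sigma2 * C), stats::rnorm(n_species)))
  traits$response <- drop(X %*% beta[colnames(X)]) + noise
  list(tree = tree, traits = traits, beta = beta, sigma2 = sigma2,
       model = model)
}
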
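# Nearest-timestamp pairing of focal and background readings within one
# measurement period. Returns index pairs; focal readings with no background
# reading within the tolerance are dropped.
pair_nearest <- function(t_focal, t_background, tol) {
  ord <- order(t_background)
  tb <- t_background[ord]
  pos <- findInterval(t_focal, tb)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(tb))
  use_hi <- abs(tb[hi] - t_focal) < abs(tb[lo] - t_focal)
  j <- ifelse(use_hi, hi, lo)
  keep <- abs(tb[j] - t_focal) <= tol
  list(focal = which(keep), background = ord[j[keep]])
}

default_pairing_tol <- function(timestamps) {
  ts <- sort(unique(timestamps))
  if (length(ts) < 2) return(Inf)
  stats::median(diff(ts)) / 2
}

#' Fit the per-day, per-replicate probe cross-calibration
#'
#' During probe-control measurements the focal probe sits beside the
#' background probe, so both sample the same air. Pooling all probe-control
#' periods of each day x replicate, readings are paired by nearest timestamp
#' and an ordinary least-squares line is fitted, giving a slope \code{W} and
#' intercept \code{M} such that \code{W * focal + M} maps focal readings
#' onto the background probe's scale.
#'
#' @param log a \code{"probe_log"} containing probe-control periods.
#' @param direction which variable is the regression response.
#'   \code{"background_on_focal"} (default) fits background ~ focal, so the
#'   corrected focal reading is the predicted background-scale value and the
#'   humidity difference measured at a probe-control period is ~0 after
#'   correction. \code{"focal_on_background"} fits the reverse.
#' @param pairing_tol timestamp tolerance (s) for pairing; defaults to half
#'   the median sampling interval of each period.
#' @return A \code{"probe_calibration"} data frame with one row per
#'   day x replicate: \code{W}, \code{M}, \code{n_points}, \code{r_squared}.
#' @export
fit_probe_calibration <- function(log,
                                  direction = c("background_on_focal",
                                                "focal_on_background"),
                                  pairing_tol = NULL) {
  direction <- match.arg(direction)
  ctrl <- log[log$axis == "probe_control" & !log$settling, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no probe-control periods in the log")
  key <- paste(ctrl$day, ctrl$replicate, sep = "|")
  fits <- lapply(split(seq_len(nrow(ctrl)), key), function(idx) {
    sub <- ctrl[idx, , drop = FALSE]
    paired <- lapply(split(seq_len(nrow(sub)), period_id(sub)), function(pidx) {
      p <- sub[pidx, , drop = FALSE]
      foc <- p[p$probe_role == "focal", , drop = FALSE]
      bg <- p[p$probe_role == "background", , drop = FALSE]
      if (nrow(foc) == 0 || nrow(bg) == 0) return(NULL)
      tol <- if (is.null(pairing_tol)) default_pairing_tol(foc$timestamp_s) else pairing_tol
      pr <- pair_nearest(foc$timestamp_s, bg$timestamp_s, tol)
      data.frame(focal = foc$rh_pct[pr$focal], background = bg$rh_pct[pr$background])
    })
    xy <- do.call(rbind, paired)
    if (is.null(xy) || nrow(xy) < 3)
      stop("fewer than 3 paired probe-control readings for day x replicate ",
           key[idx[1]])
    if (stats::var(xy$focal) == 0)
      stop("degenerate focal readings (zero variance) in probe-control period(s) of day x replicate ",
           key[idx[1]])
    fit <- if (direction == "background_on_focal")
      stats::lm(background ~ focal, data = xy)
    else
      stats::lm(focal ~ background, data = xy)
    resp <- if (direction == "background_on_focal") xy$background else xy$focal
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((resp - mean(resp))^2)
    data.frame(day = sub$day[1], replicate = sub$replicate[1],
               W = unname(stats::coef(fit)[2]), M = unname(stats::coef(fit)[1]),
               n_points = nrow(xy),
               r_squared = r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  if (any(!is.finite(out$W) | out$W == 0))
    stop("calibration produced a non-finite or zero slope")
  attr(out, "direction") <- direction
  class(out) <- c("probe_calibration", "data.frame")
  out
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat("Probe cross-calibration (corrected = W * focal + M), direction: ",
      attr(x, "direction"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.probe_calibration <- function(object, ...) {
  m <- as.matrix(as.data.frame(object)[, c("W", "M")])
  rownames(m) <- paste(object$day, object$replicate, sep = "|")
  m
}

calibration_for <- function(calib, day, replicate) {
  i <- which(calib$day == day & calib$replicate == replicate)
  if (length(i) != 1)
    stop("no calibration fit for day '", day, "' replicate ", replicate,
         " (cross-day application refused)")
  calib[i, , drop = FALSE]
}

#' Apply a probe calibration to a log
#'
#' Transforms every focal reading affinely (\code{W * rh + M}) using the
#' calibration of its own day x replicate; background readings are left
#' untouched. Refuses to correct readings for which no matching
#' day x replicate fit exists.
#'
#' @param log a \code{"probe_log"}.
#' @param calib a \code{"probe_calibration"} from
#'   \code{\link{fit_probe_calibration}}.
#' @return The log with an added \code{rh_corrected} column.
#' @export
apply_calibration <- function(log, calib) {
  key_log <- paste(log$day, log$replicate, sep = "|")
  key_cal <- paste(calib$day, calib$replicate, sep = "|")
  need <- unique(key_log[log$probe_role == "focal"])
  missing_keys <- setdiff(need, key_cal)
  if (length(missing_keys) > 0)
    stop("no calibration fit for day x replicate ",
         paste(missing_keys, collapse = ", "),
         " (cross-day application refused)")
  idx <- match(key_log, key_cal)
  log$rh_corrected <- ifelse(log$probe_role == "focal",
                             calib$W[idx] * log$rh_pct + calib$M[idx],
                             log$rh_pct)
  log
}

# Reading-level corrected focal-minus-background differences, one row per
# paired reading, with the period identifier retained.
#' Reading-level humidity differences
#'
#' Pairs corrected focal readings with simultaneous background readings
#' (nearest timestamp within tolerance) inside each measurement period and
#' returns the individual differences. These are the replication level used
#' by \code{\link{repeatability}}.
#'
#' @inheritParams fit_probe_calibration
#' @param calib a \code{"probe_calibration"}.
#' @param include_settling include settling-time readings (default FALSE).
#' @return Data frame with period metadata and one \code{delta} per pair.
#' @export
delta_rh_readings <- function(log, calib, pairing_tol = NULL,
                              include_settling = FALSE) {
  log <- apply_calibration(log, calib)
  use <- if (include_settling) rep(TRUE, nrow(log)) else !log$settling
  sub <- log[use & !log$short_period, , drop = FALSE]
  pieces <- lapply(split(seq_len(nrow(sub)), period_id(sub)), function(pidx) {
    p <- sub[pidx, , drop = FALSE]
    foc <- p[p$probe_role == "focal", , drop = FALSE]
    bg <- p[p$probe_role == "background", , drop = FALSE]
    if (nrow(foc) == 0 || nrow(bg) == 0) return(NULL)
    tol <- if (is.null(pairing_tol)) default_pairing_tol(foc$timestamp_s) else pairing_tol
    pr <- pair_nearest(foc$timestamp_s, bg$timestamp_s, tol)
    if (length(pr$focal) == 0) return(NULL)
    data.frame(period = period_id(foc)[1],
               day = foc$day[1], flower = foc$flower[1],
               species = foc$species[1], replicate = foc$replicate[1],
               axis = foc$axis[1], offset_mm = foc$offset_mm[1],
               timestamp_s = foc$timestamp_s[pr$focal],
               delta = foc$rh_corrected[pr$focal] - bg$rh_pct[pr$background],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) stop("no valid focal/background pairs in the log")
  rownames(out) <- NULL
  out
}

#' Per-period mean humidity difference
#'
#' Computes the mean corrected focal-minus-background difference over each
#' measurement period, the humidity elevation at that sampling point. These
#' period means are the responses of the humidity-structure models.
#'
#' @inheritParams delta_rh_readings
#' @param include_controls keep probe-control periods in the output
#'   (default FALSE; they are useful for checking that self-calibrated
#'   probe-control differences are ~0).
#' @return A \code{"delta_rh"} data frame: day, flower, species, replicate,
#'   axis, offset_mm, delta_rh, within_period_sd, n_pairs.
#' @export
compute_delta_rh <- function(log, calib, pairing_tol = NULL,
                             include_controls = FALSE) {
  readings <- delta_rh_readings(log, calib, pairing_tol = pairing_tol)
  if (!include_controls)
    readings <- readings[readings$axis != "probe_control", , drop = FALSE]
  if (nrow(readings) == 0) stop("no valid focal/background pairs in the log")
  sp <- split(readings, readings$period)
  out <- do.call(rbind, lapply(sp, function(p) {
    data.frame(day = p$day[1], flower = p$flower[1], species = p$species[1],
               replicate = p$replicate[1], axis = p$axis[1],
               offset_mm = p$offset_mm[1],
               delta_rh = mean(p$delta),
               within_period_sd = stats::sd(p$delta),
               n_pairs = nrow(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$day, out$flower, out$replicate, out$axis, out$offset_mm), ]
  class(out) <- c("delta_rh", "data.frame")
  out
}
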
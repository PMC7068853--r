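#' Transect run layout
#'
#' Describes the sampling geometry and timing of a robot transect run: the
#' legal horizontal (x) and vertical (z) offset grids in millimetres relative
#' to the transect central point, the settling time discarded at the start of
#' each stop, the length of the measurement period, and the number of
#' replicate transects per flower.
#'
#' The default layout is the survey design: x offsets from -30 to +30 mm in
#' 5 mm steps (13 points), z offsets from 5 to 30 mm (6 points), a 30 s
#' settling time followed by a 200 s measurement period, and four replicate
#' transects.
#'
#' @param x_offsets numeric vector of legal x-axis offsets (mm).
#' @param z_offsets numeric vector of legal z-axis offsets (mm); must be > 0.
#' @param settling_s non-sampled settling time (s) at the start of each stop.
#' @param measurement_s length of the measurement period (s).
#' @param replicates number of replicate transects per flower.
#' @return An object of class \code{"transect_layout"}.
#' @export
transect_layout <- function(x_offsets = seq(-30, 30, by = 5),
                            z_offsets = seq(5, 30, by = 5),
                            settling_s = 30,
                            measurement_s = 200,
                            replicates = 4L) {
  stopifnot(is.numeric(x_offsets), length(x_offsets) >= 1,
            is.numeric(z_offsets), all(z_offsets > 0),
            settling_s >= 0, measurement_s > 0, replicates >= 1)
  structure(list(x_offsets = sort(x_offsets),
                 z_offsets = sort(z_offsets),
                 settling_s = settling_s,
                 measurement_s = measurement_s,
                 replicates = as.integer(replicates)),
            class = "transect_layout")
}

#' @export
print.transect_layout <- function(x, ...) {
  cat("Transect layout:\n")
  cat("  x offsets (mm):", paste(x$x_offsets, collapse = " "), "\n")
  cat("  z offsets (mm):", paste(x$z_offsets, collapse = " "), "\n")
  cat("  settling ", x$settling_s, " s + measurement ", x$measurement_s,
      " s, ", x$replicates, " replicate transects\n", sep = "")
  invisible(x)
}

probe_log_columns <- c("day", "flower", "species", "replicate", "axis",
                       "offset_mm", "probe_role", "timestamp_s", "rh_pct")

#' Validate a probe-log data frame
#'
#' Checks one reading per row: paired focal/background relative-humidity
#' readings grouped by day, flower, replicate transect, axis and spatial
#' offset. Flags settling-time readings instead of dropping them, and flags
#' measurement periods with fewer than two retained readings so they can be
#' excluded from downstream fits.
#'
#' @param log data frame with columns day, flower, species, replicate, axis,
#'   offset_mm, probe_role, timestamp_s, rh_pct.
#' @param layout a \code{\link{transect_layout}}.
#' @param line_offset added to row indices in error messages (used by
#'   \code{\link{read_probe_log}} to report file line numbers).
#' @return The validated log with class \code{"probe_log"} and added logical
#'   columns \code{settling} and \code{short_period}.
#' @keywords internal
validate_probe_log <- function(log, layout = transect_layout(),
                               line_offset = 0L) {
  missing_cols <- setdiff(probe_log_columns, names(log))
  if (length(missing_cols) > 0)
    stop("probe log is missing columns: ", paste(missing_cols, collapse = ", "))
  line_of <- function(i) i + line_offset

  bad <- which(!log$axis %in% c("x", "z", "probe_control"))
  if (length(bad) > 0)
    stop("malformed row at line ", line_of(bad[1]),
         ": unknown axis '", log$axis[bad[1]], "'")
  bad <- which(!is.finite(log$rh_pct) | log$rh_pct < 0 | log$rh_pct > 100)
  if (length(bad) > 0)
    stop("malformed row at line ", line_of(bad[1]),
         ": rh_pct must be a finite percentage in [0, 100], got '",
         log$rh_pct[bad[1]], "'")
  bad <- which(!is.finite(log$timestamp_s) | log$timestamp_s < 0)
  if (length(bad) > 0)
    stop("malformed row at line ", line_of(bad[1]),
         ": timestamp_s must be finite and >= 0")
  bad <- which(!log$probe_role %in% c("focal", "background"))
  if (length(bad) > 0)
    stop("malformed row at line ", line_of(bad[1]),
         ": probe_role must be 'focal' or 'background'")
  bad <- which(!log$replicate %in% seq_len(layout$replicates))
  if (length(bad) > 0)
    stop("malformed row at line ", line_of(bad[1]), ": replicate must be in 1..",
         layout$replicates, ", got '", log$replicate[bad[1]], "'")

  is_x <- log$axis == "x"
  is_z <- log$axis == "z"
  bad <- which(is_x & !log$offset_mm %in% layout$x_offsets)
  if (length(bad) > 0)
    stop("offset outside the legal x grid at line ", line_of(bad[1]),
         ": ", log$offset_mm[bad[1]], " mm")
  bad <- which(is_z & !log$offset_mm %in% layout$z_offsets)
  if (length(bad) > 0)
    stop("offset outside the legal z grid at line ", line_of(bad[1]),
         ": ", log$offset_mm[bad[1]], " mm")
  if (any(!is.na(log$offset_mm[log$axis == "probe_control"])))
    stop("probe_control rows must have missing offset_mm")

  log$replicate <- as.integer(log$replicate)
  log$settling <- log$timestamp_s < layout$settling_s
  total_span <- layout$settling_s + layout$measurement_s
  if (any(log$timestamp_s > total_span))
    stop("timestamp_s exceeds the ", total_span, " s stop duration at line ",
         line_of(which(log$timestamp_s > total_span)[1]))

  # periods with < 2 retained (non-settling) readings on either probe are
  # flagged and excluded from downstream fits, not rejected at ingest
  pid <- period_id(log)
  keep <- !log$settling
  n_focal <- tapply(keep & log$probe_role == "focal", pid, sum)
  n_bg <- tapply(keep & log$probe_role == "background", pid, sum)
  short <- names(n_focal)[n_focal < 2 | n_bg < 2]
  log$short_period <- pid %in% short
  attr(log, "layout") <- layout
  class(log) <- c("probe_log", "data.frame")
  log
}

#' Period identifier for probe-log rows
#'
#' @param log probe-log data frame.
#' @return Character vector labelling each row's measurement period
#'   (day/flower/replicate/axis/offset).
#' @export
period_id <- function(log) {
  paste(log$day, log$flower, log$replicate, log$axis,
        ifelse(is.na(log$offset_mm), "ctrl", log$offset_mm), sep = "|")
}

#' Read a probe log
#'
#' Reads a comma-separated probe log (header row; columns \code{day},
#' \code{flower}, \code{species}, \code{replicate}, \code{axis},
#' \code{offset_mm}, \code{probe_role}, \code{timestamp_s}, \code{rh_pct})
#' and validates every row against the run layout. Malformed rows and
#' offsets off the legal 5 mm grid are rejected with the offending line
#' number. Settling-time readings (the first \code{settling_s} seconds of
#' each stop) are flagged in a \code{settling} column rather than dropped,
#' so turbulence diagnostics can see the full stop.
#'
#' @param path path to a CSV probe log.
#' @param layout a \code{\link{transect_layout}} describing the legal grids.
#' @return A \code{"probe_log"} data frame (one reading per row).
#' @seealso \code{\link{write_probe_log}}, \code{\link{simulate_probe_log}}
#' @export
read_probe_log <- function(path, layout = transect_layout()) {
  if (!file.exists(path)) stop("probe log not found: ", path)
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  # header is line 1, so data row i sits on file line i + 1
  validate_probe_log(log, layout, line_offset = 1L)
}

#' Write a probe log
#'
#' Writes a probe log back to CSV in the canonical column order. A
#' write-then-read round trip reproduces identical period means.
#'
#' @param log a \code{"probe_log"} data frame.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_probe_log <- function(log, path) {
  out <- as.data.frame(log)[, probe_log_columns]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write probe log to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Summarize the measurement periods of a probe log
#'
#' @param log a \code{"probe_log"} data frame.
#' @return Data frame with one row per measurement period (day, flower,
#'   species, replicate, axis, offset_mm, reading counts, short-period flag).
#' @export
period_summary <- function(log) {
  pid <- period_id(log)
  first <- !duplicated(pid)
  out <- data.frame(
    period = pid[first],
    day = log$day[first],
    flower = log$flower[first],
    species = log$species[first],
    replicate = log$replicate[first],
    axis = log$axis[first],
    offset_mm = log$offset_mm[first],
    stringsAsFactors = FALSE
  )
  keep <- !log$settling
  out$n_focal <- as.vector(tapply(keep & log$probe_role == "focal", pid, sum)[out$period])
  out$n_background <- as.vector(tapply(keep & log$probe_role == "background", pid, sum)[out$period])
  out$short_period <- out$n_focal < 2 | out$n_background < 2
  rownames(out) <- NULL
  out[order(out$day, out$flower, out$replicate, out$axis, out$offset_mm), ]
}
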
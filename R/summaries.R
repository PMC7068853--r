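# Per-replicate effective parameters of an x-axis fit: intercept I + r_t,
# linear term A + g_t, curvature B + c_t, with first-replicate modifiers
# identically zero. Models without replicate terms collapse to a single row.
replicate_params <- function(fit) {
  if (fit$spec$axis != "x")
    stop("peak-location summaries are defined for x-axis fits, got ",
         fit$spec$id)
  b <- fit$coefficients
  val <- function(name) if (name %in% names(b)) unname(b[name]) else 0
  has_rep <- any(c("r", "g", "c") %in% fit$spec$terms)
  ts <- if (has_rep) 1:4 else NA_integer_
  out <- do.call(rbind, lapply(ts, function(t) {
    mod <- function(prefix, suffix = "") {
      if (is.na(t) || t == 1) 0 else val(paste0(prefix, t, suffix))
    }
    data.frame(t = t,
               I = val("(Intercept)") + mod("r"),
               A = val("X") + mod("g", "X"),
               B = val("X2") + mod("c", "X2"))
  }))
  rownames(out) <- NULL
  out
}

#' Peak location of the fitted horizontal humidity structure
#'
#' Returns the x offset at which the fitted model predicts the highest
#' humidity difference, per replicate transect: 0 for flat structures (any
#' offset predicts the same value), the sampled endpoint (+30 or -30 mm,
#' by the sign of the effective linear term) for linear structures, and the
#' quadratic vertex \code{-(A + a) / (2 (B + b))} for concave quadratics,
#' clamped to the sampled [-30, 30] mm range. A convex quadratic (positive
#' effective curvature) peaks at whichever endpoint predicts more, with
#' \code{boundary} set.
#'
#' @param fit an x-axis \code{"transect_fit"}.
#' @param range sampled offset range in mm.
#' @return Data frame with one row per replicate transect (a single row with
#'   \code{t = NA} for models without replicate effects): \code{t},
#'   \code{x_max}, \code{boundary}.
#' @export
x_max <- function(fit, range = c(-30, 30)) {
  pars <- replicate_params(fit)
  res <- lapply(seq_len(nrow(pars)), function(i) {
    A <- pars$A[i]; B <- pars$B[i]
    if (B < 0) {
      v <- -A / (2 * B)
      clamped <- min(max(v, range[1]), range[2])
      data.frame(x = clamped, boundary = v < range[1] || v > range[2])
    } else if (B > 0) {
      # convex: maximum sits on an endpoint of the sampled range
      ends <- range
      vals <- pars$I[i] + A * ends + B * ends^2
      data.frame(x = ends[which.max(vals)], boundary = TRUE)
    } else if (A != 0) {
      data.frame(x = if (A > 0) range[2] else range[1], boundary = FALSE)
    } else {
      data.frame(x = 0, boundary = FALSE)
    }
  })
  res <- do.call(rbind, res)
  data.frame(t = pars$t, x_max = res$x, boundary = res$boundary)
}

#' Peak humidity elevation of a fitted horizontal structure
#'
#' Evaluates the fitted mean structure (flower random intercept set to zero)
#' at each replicate transect's peak offset and returns the largest value
#' across replicates, together with where and on which replicate it occurs.
#' Ties across replicates resolve to the earliest transect.
#'
#' @param fit the chosen x-axis \code{"transect_fit"} (lowest AIC among the
#'   comparable best models).
#' @param range sampled offset range in mm.
#' @return An object of class \code{"peak_estimate"}: \code{delta_rh_max},
#'   \code{x_max}, \code{replicate} (NA for models without replicate
#'   effects), \code{boundary}, and the per-replicate table \code{per_t}.
#' @export
delta_rh_max <- function(fit, range = c(-30, 30)) {
  pars <- replicate_params(fit)
  xm <- x_max(fit, range)
  value <- pars$I + pars$A * xm$x_max + pars$B * xm$x_max^2
  best <- which.max(value)   # which.max takes the first maximum: earliest t
  structure(list(delta_rh_max = value[best],
                 x_max = xm$x_max[best],
                 replicate = pars$t[best],
                 boundary = xm$boundary[best],
                 per_t = data.frame(t = pars$t, x_max = xm$x_max,
                                    delta_rh = value,
                                    boundary = xm$boundary),
                 model = fit$spec$id),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("Peak humidity elevation %.3f %%RH at X = %.2f mm (model %s%s%s)\n",
              x$delta_rh_max, x$x_max, x$model,
              if (!is.na(x$replicate)) paste0(", replicate ", x$replicate) else "",
              if (x$boundary) ", at range boundary" else ""))
  invisible(x)
}

model_shape <- function(id) {
  spec <- transect_model_spec(id)
  if ("B" %in% spec$terms) {
    if (spec$axis == "x") "Q" else "L"   # z-axis B is the logarithmic slope
  } else if ("A" %in% spec$terms) "L" else "F"
}

#' Assemble one species summary row
#'
#' Combines the x- and z-axis model selections, the peak estimate from the
#' chosen x-axis model, and species metadata into a validated summary-table
#' row (rank is left NA; it is assigned across species when a full table is
#' built).
#'
#' @param selection_x x-axis \code{"transect_selection"}.
#' @param selection_z z-axis \code{"transect_selection"}.
#' @param peak a \code{"peak_estimate"} from the chosen x-axis model.
#' @param metadata list with \code{name} and optionally \code{is_control},
#'   \code{floral_structure}, \code{floral_type}, \code{grown_outside},
#'   \code{mean_span_mm}, \code{span_n}, \code{stomata_pct}, \code{stomata_n}.
#' @return One-row summary data frame.
#' @export
assemble_species_summary <- function(selection_x, selection_z, peak, metadata) {
  if (selection_x$axis != "x" || selection_z$axis != "z")
    stop("selections must cover the x and z axes respectively")
  sp_x <- selection_x$species
  sp_z <- selection_z$species
  if (!is.null(sp_x) && !is.null(sp_z) && !identical(sort(sp_x), sort(sp_z)))
    stop("inconsistent species ids between axes: ",
         paste(sp_x, collapse = ","), " vs ", paste(sp_z, collapse = ","))
  if (peak$model != selection_x$chosen)
    stop("peak estimate comes from model ", peak$model,
         " but the chosen x-axis model is ", selection_x$chosen)
  meta <- function(field, default = NA) {
    if (!is.null(metadata[[field]])) metadata[[field]] else default
  }
  row <- data.frame(
    rank = NA_integer_,
    name = metadata$name,
    is_control = isTRUE(meta("is_control", FALSE)),
    floral_structure = as.character(meta("floral_structure", NA_character_)),
    floral_type = as.character(meta("floral_type", NA_character_)),
    grown_outside = meta("grown_outside", NA),
    mean_span_mm = as.numeric(meta("mean_span_mm", NA_real_)),
    span_n = as.character(meta("span_n", "")),
    stomata_pct = as.numeric(meta("stomata_pct", NA_real_)),
    stomata_n = as.numeric(meta("stomata_n", NA_real_)),
    best_x_model = selection_x$chosen,
    x_shape = model_shape(selection_x$chosen),
    comparable_x_models = paste(selection_x$best_set, collapse = "|"),
    best_z_model = selection_z$chosen,
    z_shape = model_shape(selection_z$chosen),
    x_max_mm = peak$x_max,
    x_max_replicate = if (is.na(peak$replicate)) "" else as.character(peak$replicate),
    delta_rh_max = peak$delta_rh_max,
    stringsAsFactors = FALSE
  )
  validate_summary_table(row)
}

#' Rank species summary rows by peak humidity
#'
#' Assigns ascending ranks by \code{delta_rh_max} to non-control rows;
#' control rows keep NA rank.
#'
#' @param rows summary data frame.
#' @return The rows ordered by \code{delta_rh_max} with ranks filled in.
#' @export
rank_species_summary <- function(rows) {
  rows <- rows[order(rows$delta_rh_max), , drop = FALSE]
  rows$rank <- NA_integer_
  rows$rank[!rows$is_control] <- seq_len(sum(!rows$is_control))
  rownames(rows) <- NULL
  rows
}

non_quadratic_x_ids <- c("m0", "m1", "m4", "m5", "m8")

#' Control-threshold classification and structure counts
#'
#' Classifies species rows against the water-tube control baselines: the
#' count of species whose peak humidity elevation strictly exceeds the
#' lidded water tube (TWL, background-comparable extraneous humidity), the
#' open water tube (TW, the largest humidity any control produced), and a
#' fixed 3 \%RH intensity threshold. Also counts structural features: species
#' peaking exactly at the transect central point, species peaking at least
#' 5 mm off-center, and species whose best horizontal model has no curvature
#' term.
#'
#' @param rows summary data frame including the TWL and TW control rows.
#' @param intensity_threshold fixed intensity cutoff in \%RH (default 3).
#' @return An object of class \code{"humidity_counts"}.
#' @export
threshold_counts <- function(rows, intensity_threshold = 3) {
  ctrl_value <- function(label) {
    i <- which(rows$is_control & rows$name == label)
    if (length(i) != 1)
      stop("summary rows must include exactly one '", label, "' row")
    rows$delta_rh_max[i]
  }
  twl <- ctrl_value("TWL control")
  tw <- ctrl_value("TW control")
  sp <- rows[!rows$is_control, , drop = FALSE]
  counts <- list(
    n_species = nrow(sp),
    twl_value = twl,
    tw_value = tw,
    above_twl = sum(sp$delta_rh_max > twl),
    above_tw = sum(sp$delta_rh_max > tw),
    above_intensity = sum(sp$delta_rh_max > intensity_threshold),
    intensity_threshold = intensity_threshold,
    x_max_central = sum(sp$x_max_mm == 0, na.rm = TRUE),
    x_max_offset_5mm = sum(abs(sp$x_max_mm) >= 5, na.rm = TRUE),
    non_quadratic_x = sum(sp$best_x_model %in% non_quadratic_x_ids)
  )
  structure(counts, class = "humidity_counts")
}

#' @export
print.humidity_counts <- function(x, ...) {
  cat("Classification of", x$n_species, "species by peak humidity elevation:\n")
  cat(sprintf("  above TWL control (%.2f %%RH): %d\n", x$twl_value, x$above_twl))
  cat(sprintf("  above TW control (%.2f %%RH): %d\n", x$tw_value, x$above_tw))
  cat(sprintf("  above %.4g %%RH: %d\n", x$intensity_threshold, x$above_intensity))
  cat(sprintf("  peak at transect central point: %d\n", x$x_max_central))
  cat(sprintf("  peak >= 5 mm off-center: %d\n", x$x_max_offset_5mm))
  cat(sprintf("  non-quadratic best x model: %d\n", x$non_quadratic_x))
  invisible(x)
}
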
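#' Fit and compare all humidity-structure models of one axis by AIC
#'
#' Fits every member of the model family for the requested axis to one
#' species' (or control group's) per-period humidity differences, assembles
#' an AIC table, and identifies the comparable best set (models within
#' \code{delta_aic_threshold} of the minimum AIC) and the chosen model (the
#' lowest AIC; exact ties broken toward fewer parameters). Models that fail
#' to fit are recorded in the table with the failure message, not dropped
#' silently.
#'
#' @param data a \code{"delta_rh"} data frame for one species or control.
#' @param axis \code{"x"} or \code{"z"}.
#' @param delta_aic_threshold comparability threshold on delta AIC
#'   (default 2, standard information-theoretic practice).
#' @param random_intercept passed to \code{\link{fit_transect_model}}.
#' @return An object of class \code{"transect_selection"}: \code{aic_table},
#'   \code{fits} (named list), \code{chosen} (model id), \code{best_set}.
#' @export
select_transect_model <- function(data, axis = c("x", "z"),
                                  delta_aic_threshold = 2,
                                  random_intercept = TRUE) {
  axis <- match.arg(axis)
  stopifnot(delta_aic_threshold >= 0)
  if (!is.null(data$axis)) {
    data <- data[data$axis == axis, , drop = FALSE]
    if (nrow(data) == 0) stop("no ", axis, "-axis records in the data")
  }
  ids <- transect_model_ids(axis)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  rows <- lapply(ids, function(id) {
    res <- tryCatch(fit_transect_model(data, id, random_intercept = random_intercept),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(model = id, k = NA_integer_, logLik = NA_real_,
                 aic = NA_real_, failed = TRUE,
                 message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      fits[[id]] <<- res
      data.frame(model = id, k = res$k, logLik = res$logLik, aic = res$aic,
                 failed = FALSE, message = "", stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  if (all(tab$failed)) stop("every ", axis, "-axis model failed to fit")
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  ok <- which(!tab$failed)
  # lowest AIC; break exact ties toward fewer parameters
  ord <- ok[order(tab$aic[ok], tab$k[ok])]
  chosen <- tab$model[ord[1]]
  best_set <- tab$model[ok][tab$delta_aic[ok] <= delta_aic_threshold]
  structure(list(aic_table = tab[order(tab$aic), ],
                 fits = fits,
                 chosen = chosen,
                 best_set = best_set,
                 axis = axis,
                 delta_aic_threshold = delta_aic_threshold,
                 species = if (!is.null(data$species)) unique(data$species) else NULL),
            class = "transect_selection")
}

#' @export
print.transect_selection <- function(x, ...) {
  cat("Model selection (", x$axis, " axis",
      if (!is.null(x$species)) paste0(", ", paste(x$species, collapse = "/")),
      "): chosen ", x$chosen, "\n", sep = "")
  cat("  comparable best set (delta AIC <= ", x$delta_aic_threshold, "): ",
      paste(x$best_set, collapse = ", "), "\n", sep = "")
  tab <- x$aic_table
  tab$logLik <- round(tab$logLik, 2)
  tab$aic <- round(tab$aic, 2)
  tab$delta_aic <- round(tab$delta_aic, 2)
  print(tab[, c("model", "k", "logLik", "aic", "delta_aic", "failed")],
        row.names = FALSE)
  invisible(x)
}

#' Chosen fitted model of a selection
#'
#' @param selection a \code{"transect_selection"}.
#' @return The \code{"transect_fit"} with the lowest AIC.
#' @export
chosen_fit <- function(selection) selection$fits[[selection$chosen]]
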
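summary_table_columns <- c("rank", "name", "is_control", "floral_structure",
                           "floral_type", "grown_outside", "mean_span_mm",
                           "span_n", "stomata_pct", "stomata_n",
                           "best_x_model", "x_shape", "comparable_x_models",
                           "best_z_model", "z_shape", "x_max_mm",
                           "x_max_replicate", "delta_rh_max")

x_model_ids <- paste0("m", 0:10)
z_model_ids <- paste0("z", 0:4)

validate_summary_table <- function(rows) {
  missing_cols <- setdiff(summary_table_columns, names(rows))
  if (length(missing_cols) > 0)
    stop("summary table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(rows) == 0) return(rows)
  if (!all(rows$best_x_model %in% x_model_ids))
    stop("unknown x-axis model id: ",
         rows$best_x_model[!rows$best_x_model %in% x_model_ids][1])
  if (!all(rows$best_z_model %in% z_model_ids))
    stop("unknown z-axis model id: ",
         rows$best_z_model[!rows$best_z_model %in% z_model_ids][1])
  if (any(abs(rows$x_max_mm) > 30, na.rm = TRUE))
    stop("x_max_mm outside the sampled [-30, 30] mm range")
  if (any(rows$delta_rh_max < 0, na.rm = TRUE))
    stop("delta_rh_max must be >= 0")
  rows
}

#' Load the packaged humidity-survey summary
#'
#' Returns the published per-species summary of the 42-species floral
#' humidity survey plus its six control groups (T, TL, TLP, TW, TWL, TWLP):
#' floral structure, mean span, petal-stomata presence where surveyed, the
#' best-fitting x- and z-axis humidity-structure models, the peak offset
#' \code{x_max_mm} (with the replicate transect that attained it), and the
#' peak humidity elevation \code{delta_rh_max} (percentage points of
#' relative humidity above background).
#'
#' @return Data frame with one row per species or control, ordered as
#'   printed (ascending \code{delta_rh_max}, controls interleaved).
#' @export
load_survey_summary <- function() {
  path <- system.file("extdata", "humidity_survey_summary.csv",
                      package = "floralhum")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged survey summary fixture is missing or the package is not installed")
  read_summary_table(path)
}

#' Read a species summary table
#'
#' @param path CSV file in the schema written by
#'   \code{\link{write_summary_table}}.
#' @return Validated summary data frame.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop("summary table not found: ", path)
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(x_max_replicate = "character",
                                         span_n = "character",
                                         comparable_x_models = "character"))
  for (col in c("x_max_replicate", "span_n", "comparable_x_models"))
    rows[[col]][is.na(rows[[col]])] <- ""
  validate_summary_table(rows)
}

#' Write a species summary table
#'
#' Writes validated summary rows as CSV with a stable column order; a
#' write-then-read round trip is lossless (numeric cells are serialized at
#' full precision).
#'
#' @param rows summary data frame (possibly empty; an empty input yields a
#'   header-only file).
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_summary_table <- function(rows, path) {
  if (nrow(rows) > 0) rows <- validate_summary_table(rows)
  out <- rows[, summary_table_columns, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write summary table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
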
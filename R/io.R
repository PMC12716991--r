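# Plain-text table I/O. All tabular artefacts are comma-delimited with a
# header row so they round-trip through any spreadsheet or scripting
# language.

#' Write a pipeline table to CSV
#'
#' @param x data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' Validates the three channel columns on read.
#'
#' @param path CSV file with columns `event_id`, `ch_ctg`, `ch_rho`,
#'   `ch_af647` and optionally `true_label`.
#' @return data.frame.
#' @export
read_event_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  check_event_table(tab)
  tab
}

#' Read an aspiration measurement table from CSV
#'
#' @param path CSV file with columns `dP_suction_Pa`, `R_pipette_um`,
#'   `R_cell_um` and optionally `id`, `tongue_um`, `group`.
#' @return data.frame.
#' @export
read_aspiration_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dP_suction_Pa", "R_pipette_um", "R_cell_um")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("aspiration table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read a titration table from CSV
#'
#' @param path CSV file with columns `density_per_um2`, `efficiency_pct`
#'   and optionally `condition`, `replicate`.
#' @return data.frame.
#' @export
read_titration_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  as_titration_points(tab)  # validation only
  tab
}
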
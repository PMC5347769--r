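# Delimited-table readers/writers for the screen's external interfaces.

CELL_COLUMNS <- c("cell_id", "well_id", "intensity_k5", "intensity_k8",
                  "cell_area", "pyknotic")
ANNOTATION_COLUMNS <- c("well_id", "plate_id", "role", "construct_id",
                        "gene_id", "replicate_index")

#' Read a per-cell measurement table
#'
#' Delimited text with header
#' `cell_id,well_id,intensity_k5,intensity_k8,cell_area,pyknotic`.
#'
#' @param path File path.
#' @return data.frame in the cell-table schema.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) io_error("cell table not found: ", path)
  dt <- data.table::fread(path, colClasses = list(
    character = "well_id", numeric = c("intensity_k5", "intensity_k8", "cell_area"),
    logical = "pyknotic"))
  missing <- setdiff(CELL_COLUMNS, names(dt))
  if (length(missing)) io_error(path, " lacks column(s): ", paste(missing, collapse = ", "))
  data.table::setDF(dt[, CELL_COLUMNS, with = FALSE])
}

#' Read a well annotation table
#'
#' Delimited text with header
#' `well_id,plate_id,role,construct_id,gene_id,replicate_index`;
#' empty fields mark non-applicable columns (controls carry no gene,
#' gating wells neither construct nor gene).
#'
#' @param path File path.
#' @return data.frame in the annotation schema.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) io_error("annotation table not found: ", path)
  dt <- data.table::fread(path, colClasses = list(
    character = c("well_id", "plate_id", "role", "construct_id", "gene_id"),
    integer = "replicate_index"), na.strings = c("", "NA"))
  missing <- setdiff(ANNOTATION_COLUMNS, names(dt))
  if (length(missing)) io_error(path, " lacks column(s): ", paste(missing, collapse = ", "))
  data.table::setDF(dt[, ANNOTATION_COLUMNS, with = FALSE])
}

#' Write the tables of a synthetic screen
#'
#' Writes `cell_table.csv`, `annotations.csv` and `ground_truth.json`
#' under `dir`.
#'
#' @param screen A [generate_screen()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_screen_tables <- function(screen, dir) {
  if (!inherits(screen, "synthetic_screen")) input_error("screen must come from generate_screen()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cells = file.path(dir, "cell_table.csv"),
    annotations = file.path(dir, "annotations.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  data.table::fwrite(screen$cells[, CELL_COLUMNS], paths[["cells"]])
  data.table::fwrite(screen$annotations[, ANNOTATION_COLUMNS], paths[["annotations"]])
  jsonlite::write_json(list(
    differentiator_genes = screen$truth$differentiator_genes,
    cytotoxic_constructs = screen$truth$cytotoxic_constructs
  ), paths[["truth"]], pretty = TRUE)
  invisible(paths)
}

#' Validate screen input tables against their schemas
#'
#' Checks each supplied file for a well-formed header, parseable values,
#' and the row-level invariants (non-negative intensities, positive areas,
#' roles from the known set, treatment wells carrying construct and gene
#' ids, gating wells carrying neither, replicate index >= 1). Inputs are
#' never mutated.
#'
#' @param cell_table,annotation_table Optional file paths.
#' @return data.frame with one row per checked file: `file`, `table`,
#'   `pass`, `n_rows`, `first_error` (empty string when passing; otherwise
#'   names the first offending row and column).
#' @export
validate_tables <- function(cell_table = NULL, annotation_table = NULL) {
  out <- list()
  if (!is.null(cell_table)) {
    out[[length(out) + 1L]] <- validate_one(cell_table, "cells", validate_cell_rows)
  }
  if (!is.null(annotation_table)) {
    out[[length(out) + 1L]] <- validate_one(annotation_table, "annotations", validate_annotation_rows)
  }
  if (length(out) == 0) input_error("no tables supplied to validate")
  do.call(rbind, out)
}

validate_one <- function(path, table, row_check) {
  if (!file.exists(path)) io_error("file not found: ", path)
  res <- tryCatch({
    dt <- if (table == "cells") read_cell_table(path) else read_annotation_table(path)
    err <- row_check(dt)
    list(pass = identical(err, ""), n_rows = nrow(dt), first_error = err)
  }, error = function(e) list(pass = FALSE, n_rows = NA_integer_, first_error = conditionMessage(e)))
  data.frame(file = path, table = table, pass = res$pass, n_rows = res$n_rows,
             first_error = res$first_error, stringsAsFactors = FALSE)
}

first_bad <- function(bad, column, why) {
  i <- which(bad)
  if (length(i) == 0) return("")
  sprintf("row %d, column %s: %s", i[1], column, why)
}

validate_cell_rows <- function(dt) {
  checks <- c(
    first_bad(!is.finite(dt$intensity_k5) | dt$intensity_k5 < 0, "intensity_k5", "negative or non-numeric intensity"),
    first_bad(!is.finite(dt$intensity_k8) | dt$intensity_k8 < 0, "intensity_k8", "negative or non-numeric intensity"),
    first_bad(!is.finite(dt$cell_area) | dt$cell_area <= 0, "cell_area", "non-positive area"),
    first_bad(is.na(dt$pyknotic), "pyknotic", "not interpretable as logical"),
    first_bad(is.na(dt$well_id) | !nzchar(dt$well_id), "well_id", "empty well id")
  )
  hits <- checks[nzchar(checks)]
  if (length(hits)) hits[1] else ""
}

validate_annotation_rows <- function(dt) {
  is_treat <- dt$role %in% "treatment"
  is_gate <- dt$role %in% GATING_ROLES
  checks <- c(
    first_bad(is.na(dt$role) | !dt$role %in% ALL_ROLES, "role", "unknown role"),
    first_bad(is_treat & (is.na(dt$construct_id) | !nzchar(dt$construct_id)), "construct_id",
              "treatment well without construct_id"),
    first_bad(is_treat & (is.na(dt$gene_id) | !nzchar(dt$gene_id)), "gene_id",
              "treatment well without gene_id"),
    first_bad(is_gate & !is.na(dt$construct_id), "construct_id", "gating well with construct_id"),
    first_bad(is_gate & !is.na(dt$gene_id), "gene_id", "gating well with gene_id"),
    first_bad(is.na(dt$replicate_index) | dt$replicate_index < 1, "replicate_index",
              "replicate_index must be >= 1"),
    first_bad(is.na(dt$well_id) | !nzchar(dt$well_id) | duplicated(dt$well_id), "well_id",
              "empty or duplicated well id")
  )
  hits <- checks[nzchar(checks)]
  if (length(hits)) hits[1] else ""
}
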
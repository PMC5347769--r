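#' Calibrate K5/K8 positivity thresholds from gating-control wells
#'
#' The K5 threshold is set 'z' sample standard deviations above the mean K5
#' intensity of the luminal gating line (MCF7-like, K5-negative), and the K8
#' threshold likewise from the basal line (MCF10A-like, K8-negative), pooled
#' across the entire plate set. Pyknotic cells are excluded before
#' calibration. Sample SD uses the n-1 denominator; zero variance is
#' permitted (threshold equals the mean).
#'
#' @param mcf7_cells Cell table subset of MCF7-like gating wells.
#' @param mcf10a_cells Cell table subset of MCF10A-like gating wells.
#' @param z_multiplier Number of SDs above the mean (default 2.5).
#' @return A `gate_thresholds` list: `k5_threshold`, `k8_threshold`,
#'   `z_multiplier`, `n_mcf7_cells`, `n_mcf10a_cells`.
#' @export
calibrate_thresholds <- function(mcf7_cells, mcf10a_cells, z_multiplier = 2.5) {
  if (!is.numeric(z_multiplier) || length(z_multiplier) != 1 || z_multiplier <= 0) {
    config_error("z_multiplier must be a single positive number")
  }
  k5 <- gating_intensities(mcf7_cells, "intensity_k5", "MCF7")
  k8 <- gating_intensities(mcf10a_cells, "intensity_k8", "MCF10A")
  structure(list(
    k5_threshold = mean(k5) + z_multiplier * stats::sd(k5),
    k8_threshold = mean(k8) + z_multiplier * stats::sd(k8),
    z_multiplier = z_multiplier,
    n_mcf7_cells = length(k5),
    n_mcf10a_cells = length(k8)
  ), class = "gate_thresholds")
}

gating_intensities <- function(cells, channel, line) {
  check_cell_columns(cells, c(channel, "pyknotic"))
  x <- cells[[channel]][!cells$pyknotic]
  if (length(x) < 2) {
    calibration_error("need >= 2 non-pyknotic ", line, " cells to calibrate (got ", length(x), ")")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    input_error(line, " gating intensities must be finite and >= 0")
  }
  x
}

check_cell_columns <- function(cells, cols) {
  missing <- setdiff(cols, names(cells))
  if (length(missing)) input_error("cell table lacks column(s): ", paste(missing, collapse = ", "))
}

#' @export
print.gate_thresholds <- function(x, ...) {
  cat(sprintf("Gate thresholds (mean + %.3g SD of gating-control intensity)\n", x$z_multiplier))
  cat(sprintf("  K5: %.4g  (calibrated on %d MCF7-like cells)\n", x$k5_threshold, x$n_mcf7_cells))
  cat(sprintf("  K8: %.4g  (calibrated on %d MCF10A-like cells)\n", x$k8_threshold, x$n_mcf10a_cells))
  invisible(x)
}

#' Classify cells into K5/K8 populations
#'
#' A cell is positive in a channel iff its intensity strictly exceeds that
#' channel's threshold (a tie is negative); the class is the conjunction of
#' the two channel calls: `DP` (K5+K8+), `K5_only`, `K8_only`, `DN`.
#' Pyknotic cells are `excluded_pyknotic` regardless of intensity.
#'
#' @param cells Cell table (`intensity_k5`, `intensity_k8`, `pyknotic`).
#' @param thresholds A [calibrate_thresholds()] result.
#' @return Character vector, one class per cell.
#' @export
classify_cells <- function(cells, thresholds) {
  if (!inherits(thresholds, "gate_thresholds")) input_error("thresholds must be a gate_thresholds object")
  check_cell_columns(cells, c("intensity_k5", "intensity_k8", "pyknotic"))
  k5 <- cells$intensity_k5; k8 <- cells$intensity_k8
  if (any(!is.finite(k5)) || any(!is.finite(k8)) || any(k5 < 0) || any(k8 < 0)) {
    input_error("intensities must be finite and >= 0")
  }
  k5p <- k5 > thresholds$k5_threshold
  k8p <- k8 > thresholds$k8_threshold
  cls <- rep.int("DN", nrow(cells))
  cls[k5p & k8p] <- "DP"
  cls[k5p & !k8p] <- "K5_only"
  cls[!k5p & k8p] <- "K8_only"
  cls[as.logical(cells$pyknotic)] <- "excluded_pyknotic"
  cls
}

#' Summarize one well's population composition
#'
#' Counts and percentages of the four K5/K8 classes over the well's
#' non-pyknotic (analyzable) cells, with the minimum-cell-count quality
#' filter: wells with fewer than `min_cells` analyzable cells fail QC
#' (cytotoxicity guard; exactly `min_cells` passes). Percentages are
#' 100 * count / n_analyzable and are all zero (QC fail) for an empty well.
#'
#' @param cells Cell table of a single well.
#' @param thresholds A [calibrate_thresholds()] result.
#' @param min_cells Minimum analyzable cells for QC pass (default 200).
#' @return One-row data.frame (see [summarize_wells()] for columns).
#' @export
summarize_well <- function(cells, thresholds, min_cells = 200) {
  check_cell_columns(cells, "well_id")
  ids <- unique(cells$well_id)
  if (length(ids) > 1) {
    input_error("summarize_well expects cells of a single well; got ",
                length(ids), " distinct well_ids")
  }
  summarize_wells(cells, thresholds, min_cells = min_cells)
}

#' Summarize all wells of a cell table
#'
#' Vectorized per-well population accounting over a whole screen; see
#' [summarize_well()] for the per-well definitions.
#'
#' @inheritParams summarize_well
#' @param all_well_ids Optional character vector of wells that must appear
#'   in the output; wells with no cells get zero counts and `qc_pass =
#'   FALSE`.
#' @return data.frame with one row per well: `well_id`, `n_analyzable`,
#'   `n_pyknotic_excluded`, counts `n_dp`, `n_k5_only`, `n_k8_only`,
#'   `n_dn`, percentages `pct_dp`, `pct_k5_only`, `pct_k8_only`, `pct_dn`,
#'   and `qc_pass`.
#' @export
summarize_wells <- function(cells, thresholds, min_cells = 200, all_well_ids = NULL) {
  check_cell_columns(cells, c("well_id", "intensity_k5", "intensity_k8", "pyknotic"))
  if (length(min_cells) != 1 || !is.finite(min_cells) || min_cells < 0) {
    config_error("min_cells must be a single number >= 0")
  }
  cls <- classify_cells(cells, thresholds)
  dt <- data.table::data.table(well_id = cells$well_id, class = cls)
  agg <- dt[, list(
    n_pyknotic_excluded = sum(class == "excluded_pyknotic"),
    n_dp = sum(class == "DP"),
    n_k5_only = sum(class == "K5_only"),
    n_k8_only = sum(class == "K8_only"),
    n_dn = sum(class == "DN")
  ), by = "well_id"]
  if (!is.null(all_well_ids)) {
    missing <- setdiff(all_well_ids, agg$well_id)
    if (length(missing)) {
      agg <- data.table::rbindlist(list(agg, data.table::data.table(
        well_id = missing, n_pyknotic_excluded = 0L,
        n_dp = 0L, n_k5_only = 0L, n_k8_only = 0L, n_dn = 0L)))
    }
    agg <- agg[match(all_well_ids, agg$well_id), ]
  }
  agg[, n_analyzable := n_dp + n_k5_only + n_k8_only + n_dn]
  denom <- ifelse(agg$n_analyzable > 0, agg$n_analyzable, NA_real_)
  agg[, pct_dp := ifelse(is.na(denom), 0, 100 * n_dp / denom)]
  agg[, pct_k5_only := ifelse(is.na(denom), 0, 100 * n_k5_only / denom)]
  agg[, pct_k8_only := ifelse(is.na(denom), 0, 100 * n_k8_only / denom)]
  agg[, pct_dn := ifelse(is.na(denom), 0, 100 * n_dn / denom)]
  agg[, qc_pass := n_analyzable >= min_cells]
  data.table::setcolorder(agg, c("well_id", "n_analyzable", "n_pyknotic_excluded",
                                 "n_dp", "n_k5_only", "n_k8_only", "n_dn",
                                 "pct_dp", "pct_k5_only", "pct_k8_only", "pct_dn",
                                 "qc_pass"))
  data.table::setDF(agg)
}

#' Dichotomize cells by area
#'
#' Labels each cell `small` or `big` at the area cutoff (830 um^2 by
#' default); a cell exactly at the cutoff is `small`. Optionally summarizes
#' the small/big fractions per group (e.g. per well or condition).
#'
#' @param areas Numeric vector of cell areas (um^2, > 0), or a cell table
#'   with a `cell_area` column.
#' @param group Optional grouping vector (recycled against `areas`).
#' @param area_cutoff Area cutoff in um^2 (default 830).
#' @return list with `labels` (character vector) and `summary` (data.frame
#'   of `group`, `n`, `fraction_small`, `fraction_big`; fractions are `NA`
#'   for an empty input).
#' @export
classify_cell_size <- function(areas, group = NULL, area_cutoff = 830) {
  if (is.data.frame(areas)) {
    check_cell_columns(areas, "cell_area")
    areas <- areas$cell_area
  }
  if (length(area_cutoff) != 1 || !is.finite(area_cutoff) || area_cutoff <= 0) {
    config_error("area_cutoff must be a single positive number")
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    input_error("cell areas must be finite and > 0")
  }
  labels <- ifelse(areas <= area_cutoff, "small", "big")
  if (is.null(group)) group <- rep.int("all", length(areas))
  if (length(areas) == 0) {
    summary <- data.frame(group = character(0), n = integer(0),
                          fraction_small = numeric(0), fraction_big = numeric(0))
  } else {
    dt <- data.table::data.table(group = group, small = labels == "small")
    summary <- data.table::setDF(dt[, list(
      n = .N, fraction_small = mean(small), fraction_big = mean(!small)
    ), by = "group"])
  }
  list(labels = as.character(labels), summary = summary)
}

#' Compare fluorescence intensity between two cell groups
#'
#' Two-sided two-sample t-test on per-cell intensities (e.g. K5 intensity of
#' big vs small cells). The unequal-variance (Welch) form is the default;
#' set `var_equal = TRUE` for the pooled-variance form.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @param var_equal Use pooled variance instead of Welch.
#' @return list with `statistic`, `df`, `p_value`, `method`.
#' @export
compare_group_intensity <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    degenerate_error("each group needs >= 2 values (got ", length(group_a),
                     " and ", length(group_b), ")")
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    input_error("group intensities must be finite")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    degenerate_error("both groups are constant; the t statistic is undefined")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = tt$method)
}
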
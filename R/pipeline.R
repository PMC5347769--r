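#' Default pipeline configuration
#'
#' All defaults resolve to the screen's published constants: gating at
#' mean + 2.5 SD of the gating-control intensities, 200-cell well QC,
#' 830 um^2 size cutoff, hit calling at z >= 2.5 with the >= 2-construct
#' gene rule, DE filtering at |log2FC| > 0.5 and adjusted p < 0.05, and
#' HPRT1 qPCR normalization. The `simulate` block mirrors
#' [screen_design()], [effect_model()] and [intensity_model()].
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    mode = "synthetic",
    simulate = list(design = list(), effects = list(), intensity = list()),
    gating = list(z_multiplier = 2.5, min_cells = 200, area_cutoff_um2 = 830,
                  threshold_scope = "screen"),
    hits = list(z_cutoff = 2.5, min_constructs_per_gene = 2, direction = "both"),
    qpcr = list(reference_gene = "HPRT1"),
    de = list(lfc_cutoff = 0.5, alpha = 0.05),
    paths = list(cell_table = NULL, annotation_table = NULL)
  )
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, a YAML subset) with any subset of the
#' [default_config()] keys; unspecified keys keep their defaults.
#'
#' @param path Config file path.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) io_error("config file not found: ", path)
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the full screen-analysis pipeline
#'
#' Orchestrates simulate (or load) -> gate -> summarize -> score ->
#' call hits -> call genes -> report as one reproducible run. In
#' `synthetic` mode the screen is generated from the `simulate` block
#' under a seed substream derived from `config$seed`; in `user-data` mode
#' the cell and annotation tables named in `config$paths` are read and
#' validated. Identical config and seed yield identical artifacts.
#'
#' @param config Configuration list (see [default_config()]); partial
#'   lists are merged over the defaults.
#' @param outdir Optional output directory; when given, the stage tables
#'   (`cell_table.csv` in synthetic mode, `well_summary.csv`,
#'   `construct_scores.csv`, `hit_calls.csv`, `gene_calls.csv`) and JSON
#'   reports (`gate_thresholds.json`, `screen_frequencies.json`,
#'   `run_report.json`) are written there.
#' @return Invisibly, a list with the screen tables, `thresholds`,
#'   `well_summaries`, `construct_scores`, `control_stats`, `hit_calls`,
#'   `gene_calls`, `frequencies` and the `report`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- merge_config(default_config(), config)

  if (identical(cfg$mode, "synthetic")) {
    design <- do.call(screen_design, cfg$simulate$design %||% list())
    effects <- do.call(effect_model, cfg$simulate$effects %||% list())
    intensity <- do.call(intensity_model, cfg$simulate$intensity %||% list())
    screen <- generate_screen(design, effects, intensity,
                              seed = stage_seed(cfg$seed, 1L))
    cells <- screen$cells
    ann <- screen$annotations
    truth <- screen$truth
  } else if (identical(cfg$mode, "user-data")) {
    if (is.null(cfg$paths$cell_table) || is.null(cfg$paths$annotation_table)) {
      config_error("user-data mode requires paths$cell_table and paths$annotation_table")
    }
    val <- validate_tables(cfg$paths$cell_table, cfg$paths$annotation_table)
    if (!all(val$pass)) {
      bad <- val[!val$pass, ][1, ]
      io_error("stage parse [", bad$table, "]: ", bad$file, ": ", bad$first_error)
    }
    cells <- read_cell_table(cfg$paths$cell_table)
    ann <- read_annotation_table(cfg$paths$annotation_table)
    truth <- NULL
  } else {
    config_error("mode must be 'synthetic' or 'user-data'")
  }

  scope <- cfg$gating$threshold_scope %||% "screen"
  if (!scope %in% c("screen", "plate")) {
    config_error("gating.threshold_scope must be 'screen' or 'plate'")
  }
  gate <- gate_cells(cells, ann, z_multiplier = cfg$gating$z_multiplier,
                     min_cells = cfg$gating$min_cells, scope = scope)

  scores <- score_constructs(gate$well_summaries, ann)
  ctrl_stats <- control_statistics(scores)
  hits <- call_hits(scores, ctrl_stats, z_cutoff = cfg$hits$z_cutoff,
                    direction = cfg$hits$direction %||% "both")
  genes <- call_genes(hits, min_constructs = cfg$hits$min_constructs_per_gene)
  n_genes_targeted <- length(unique(ann$gene_id[!is.na(ann$gene_id)]))
  freqs <- screen_frequencies(hits, genes, n_genes_targeted)
  abs_check <- absolute_count_check(scores, ctrl_stats)

  role_counts <- table(ann$role)
  report <- list(
    package = "bilinscreen",
    version = as.character(utils::packageVersion("bilinscreen")),
    config = cfg,
    thresholds = unclass(gate$thresholds_report),
    control_stats = unclass(ctrl_stats),
    stage_counts = list(
      wells_total = nrow(ann),
      wells_by_role = as.list(role_counts),
      wells_qc_pass = sum(gate$well_summaries$qc_pass),
      wells_qc_fail = sum(!gate$well_summaries$qc_pass),
      cells_total = nrow(cells),
      constructs_scored = sum(scores$status == "scored"),
      constructs_not_scored = sum(scores$status == "not_scored")
    ),
    frequencies = unclass(freqs),
    gene_hits = genes$gene_id[genes$is_gene_hit %in% TRUE],
    warnings = list(
      not_scored_constructs = scores$construct_id[scores$status == "not_scored"],
      qc_failed_wells = sum(!gate$well_summaries$qc_pass)
    )
  )
  stopifnot(sum(role_counts) == nrow(ann)) # every well accounted for exactly once

  result <- list(cells = cells, annotations = ann, truth = truth,
                 thresholds = gate$thresholds, well_summaries = gate$well_summaries,
                 construct_scores = scores, control_stats = ctrl_stats,
                 hit_calls = hits, gene_calls = genes,
                 absolute_count = abs_check, frequencies = freqs, report = report)

  if (!is.null(outdir)) write_run_outputs(result, outdir, cfg)
  invisible(result)
}

# Calibrate (screen- or plate-scoped) and summarize all wells.
gate_cells <- function(cells, ann, z_multiplier, min_cells, scope) {
  role_of <- stats::setNames(ann$role, ann$well_id)
  plate_of <- stats::setNames(ann$plate_id, ann$well_id)
  cell_role <- role_of[cells$well_id]
  if (anyNA(cell_role)) input_error("cell table contains well_ids absent from the annotation table")

  if (scope == "screen") {
    th <- calibrate_thresholds(cells[cell_role == "gating_mcf7", , drop = FALSE],
                               cells[cell_role == "gating_mcf10a", , drop = FALSE],
                               z_multiplier = z_multiplier)
    ws <- summarize_wells(cells, th, min_cells = min_cells, all_well_ids = ann$well_id)
    list(well_summaries = ws, thresholds = th, thresholds_report = th)
  } else {
    cell_plate <- plate_of[cells$well_id]
    plates <- sort(unique(ann$plate_id))
    per_plate <- lapply(plates, function(p) {
      sub <- cells[cell_plate == p, , drop = FALSE]
      sub_role <- cell_role[cell_plate == p]
      th <- calibrate_thresholds(sub[sub_role == "gating_mcf7", , drop = FALSE],
                                 sub[sub_role == "gating_mcf10a", , drop = FALSE],
                                 z_multiplier = z_multiplier)
      list(thresholds = th,
           summaries = summarize_wells(sub, th, min_cells = min_cells,
                                       all_well_ids = ann$well_id[ann$plate_id == p]))
    })
    ws <- do.call(rbind, lapply(per_plate, `[[`, "summaries"))
    ws <- ws[match(ann$well_id, ws$well_id), ]
    rownames(ws) <- NULL
    ths <- lapply(per_plate, `[[`, "thresholds")
    names(ths) <- plates
    list(well_summaries = ws, thresholds = ths,
         thresholds_report = list(scope = "plate", per_plate = lapply(ths, unclass)))
  }
}

write_run_outputs <- function(result, outdir, cfg) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (identical(cfg$mode, "synthetic")) {
    data.table::fwrite(result$cells[, CELL_COLUMNS], file.path(outdir, "cell_table.csv"))
    data.table::fwrite(result$annotations[, ANNOTATION_COLUMNS],
                       file.path(outdir, "annotations.csv"))
  }
  data.table::fwrite(result$well_summaries, file.path(outdir, "well_summary.csv"))
  data.table::fwrite(result$construct_scores, file.path(outdir, "construct_scores.csv"))
  data.table::fwrite(result$hit_calls, file.path(outdir, "hit_calls.csv"))
  data.table::fwrite(result$gene_calls, file.path(outdir, "gene_calls.csv"))
  jsonlite::write_json(result$report$thresholds, file.path(outdir, "gate_thresholds.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(unclass(result$frequencies), file.path(outdir, "screen_frequencies.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(result$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(outdir)
}
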
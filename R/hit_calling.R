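#' Score constructs from QC-annotated well summaries
#'
#' Averages each construct's per-well metrics over its QC-passing replicate
#' wells only (matching the screen's triplicate-mean readout). Constructs
#' whose wells all fail QC are emitted with status `"not_scored"`, never
#' silently dropped. Gating wells carry no construct and are ignored.
#'
#' @param well_summaries A [summarize_wells()] result.
#' @param annotations Well annotation table (`well_id`, `role`,
#'   `construct_id`, `gene_id`, ...).
#' @return data.frame with one row per construct: `construct_id`,
#'   `gene_id`, `role`, `status`, `n_wells_total`, `n_wells_used`,
#'   `pct_k8_only`, `pct_k5_only`, `mean_analyzable_cells`,
#'   `mean_count_k8_only` (means over QC-passing wells; `NA` when
#'   not scored).
#' @export
score_constructs <- function(well_summaries, annotations) {
  ws <- data.table::as.data.table(well_summaries)
  ann <- data.table::as.data.table(annotations)
  need <- c("well_id", "role", "construct_id", "gene_id")
  missing <- setdiff(need, names(ann))
  if (length(missing)) input_error("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  m <- merge(ws, ann[, need, with = FALSE], by = "well_id")
  m <- m[!is.na(construct_id) & role %in% c("treatment", CONTROL_ROLES)]

  gene_check <- m[role == "treatment", list(n_genes = length(unique(gene_id))), by = "construct_id"]
  bad <- gene_check[n_genes > 1]
  if (nrow(bad)) {
    input_error("construct(s) mapped to multiple genes: ",
                paste(utils::head(bad$construct_id, 3), collapse = ", "))
  }

  sc <- m[, list(
    gene_id = gene_id[1], role = role[1],
    n_wells_total = .N, n_wells_used = sum(qc_pass),
    pct_k8_only = mean(pct_k8_only[qc_pass]),
    pct_k5_only = mean(pct_k5_only[qc_pass]),
    mean_analyzable_cells = mean(n_analyzable[qc_pass]),
    mean_count_k8_only = mean(n_k8_only[qc_pass])
  ), by = "construct_id"]
  sc[, status := ifelse(n_wells_used > 0, "scored", "not_scored")]
  for (col in c("pct_k8_only", "pct_k5_only", "mean_analyzable_cells", "mean_count_k8_only")) {
    data.table::set(sc, which(sc$status == "not_scored"), col, NA_real_)
  }
  data.table::setorder(sc, construct_id)
  data.table::setDF(sc)
}

#' Pooled vector-control statistics
#'
#' Mean and sample SD of each hit metric over the scored vector-control
#' constructs (empty, non-specific and GFP vectors). The MCF7/MCF10A
#' gating wells carry gating roles and are never part of this null pool.
#'
#' @param construct_scores A [score_constructs()] result.
#' @return list of class `control_stats`: per metric (`pct_k8_only`,
#'   `pct_k5_only`) the control `mean`, `sd`, and shared `n`; plus
#'   `mean_count_k8_only`.
#' @export
control_statistics <- function(construct_scores) {
  sc <- data.table::as.data.table(construct_scores)
  ctrl <- sc[role %in% CONTROL_ROLES & status == "scored"]
  if (nrow(ctrl) < 2) {
    calibration_error("need >= 2 scored control constructs (got ", nrow(ctrl), ")")
  }
  structure(list(
    pct_k8_only = list(mean = mean(ctrl$pct_k8_only), sd = stats::sd(ctrl$pct_k8_only)),
    pct_k5_only = list(mean = mean(ctrl$pct_k5_only), sd = stats::sd(ctrl$pct_k5_only)),
    mean_count_k8_only = mean(ctrl$mean_count_k8_only),
    n = nrow(ctrl)
  ), class = "control_stats")
}

#' Call construct-level hits against the control distribution
#'
#' A construct is a hit in a direction iff its replicate-averaged
#' single-positive percentage lies at least `z_cutoff` control SDs above
#' the control mean (z >= 2.5 by default; the threshold itself counts as a
#' hit). With zero control SD, any metric strictly above the control mean
#' is a hit and z is reported as `Inf`. Unscored constructs propagate
#' their `not_scored` status with `NA` calls.
#'
#' @param construct_scores A [score_constructs()] result.
#' @param control_stats A [control_statistics()] result.
#' @param z_cutoff Hit threshold in control SDs (default 2.5).
#' @param direction Which single-positive directions count toward
#'   `is_hit`: `"both"`, `"k8_only"` or `"k5_only"`.
#' @return data.frame: `construct_id`, `gene_id`, `role`, `status`,
#'   `z_k8_only`, `hit_k8_only`, `z_k5_only`, `hit_k5_only`, `is_hit`,
#'   `direction`.
#' @export
call_hits <- function(construct_scores, control_stats, z_cutoff = 2.5,
                      direction = c("both", "k8_only", "k5_only")) {
  direction <- match.arg(direction)
  if (!inherits(control_stats, "control_stats")) input_error("control_stats must come from control_statistics()")
  if (length(z_cutoff) != 1 || !is.finite(z_cutoff) || z_cutoff <= 0) {
    config_error("z_cutoff must be a single positive number")
  }
  if (!is.finite(control_stats$pct_k8_only$sd) || !is.finite(control_stats$pct_k5_only$sd)) {
    calibration_error("control SD is not finite")
  }
  sc <- data.table::as.data.table(construct_scores)
  zscore <- function(x, m, s) {
    if (s > 0) (x - m) / s else ifelse(x > m, Inf, ifelse(x < m, -Inf, 0))
  }
  sc[, z_k8_only := zscore(pct_k8_only, control_stats$pct_k8_only$mean, control_stats$pct_k8_only$sd)]
  sc[, z_k5_only := zscore(pct_k5_only, control_stats$pct_k5_only$mean, control_stats$pct_k5_only$sd)]
  sc[, hit_k8_only := z_k8_only >= z_cutoff]
  sc[, hit_k5_only := z_k5_only >= z_cutoff]
  if (direction == "k8_only") sc[, hit_k5_only := ifelse(is.na(hit_k5_only), NA, FALSE)]
  if (direction == "k5_only") sc[, hit_k8_only := ifelse(is.na(hit_k8_only), NA, FALSE)]
  sc[, is_hit := hit_k8_only | hit_k5_only]
  sc[, direction := data.table::fifelse(
    hit_k8_only & (!hit_k5_only | z_k8_only >= z_k5_only), "toward_K8_only",
    data.table::fifelse(hit_k5_only, "toward_K5_only", NA_character_))]
  out <- sc[, c("construct_id", "gene_id", "role", "status",
                "z_k8_only", "hit_k8_only", "z_k5_only", "hit_k5_only",
                "is_hit", "direction"), with = FALSE]
  data.table::setDF(out)
}

#' Gene-level replication rule
#'
#' A gene is a hit in a direction iff at least `min_constructs` distinct
#' constructs targeting it are hits in that direction (two independent
#' shRNA vectors by default). Genes with no scored construct are flagged
#' `not_scored`.
#'
#' @param hit_calls A [call_hits()] result.
#' @param min_constructs Minimum hit constructs per direction (default 2).
#' @return data.frame: `gene_id`, `n_constructs`, `n_scored`,
#'   `n_hit_k8_only`, `n_hit_k5_only`, `is_gene_hit`, `direction`,
#'   `status`.
#' @export
call_genes <- function(hit_calls, min_constructs = 2) {
  min_constructs <- assert_count(min_constructs, "min_constructs")
  hc <- data.table::as.data.table(hit_calls)
  hc <- hc[role == "treatment" & !is.na(gene_id)]
  g <- hc[, list(
    n_constructs = length(unique(construct_id)),
    n_scored = sum(status == "scored"),
    n_hit_k8_only = length(unique(construct_id[hit_k8_only %in% TRUE])),
    n_hit_k5_only = length(unique(construct_id[hit_k5_only %in% TRUE]))
  ), by = "gene_id"]
  g[, is_gene_hit := n_hit_k8_only >= min_constructs | n_hit_k5_only >= min_constructs]
  g[, direction := data.table::fifelse(
    n_hit_k8_only >= min_constructs & n_hit_k8_only >= n_hit_k5_only, "toward_K8_only",
    data.table::fifelse(n_hit_k5_only >= min_constructs, "toward_K5_only", NA_character_))]
  g[, status := ifelse(n_scored > 0, "scored", "not_scored")]
  data.table::setorder(g, gene_id)
  data.table::setDF(g)
}

#' Chance probability of a double hit
#'
#' The screen's chance arithmetic: if the background probability that a
#' single control construct scores as a hit is `p`, the probability of two
#' hits for the same gene by chance is exactly `p * p`.
#'
#' @param p Background hit probability in `[0, 1]` (vectorized).
#' @return `p^2`, exactly.
#' @export
#' @examples
#' signif(chance_double_hit(0.0237), 2)  # 0.00056
chance_double_hit <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    input_error("p must lie in [0, 1]")
  }
  p * p
}

#' Binomial chance of >= 2 hit constructs for one gene
#'
#' Diagnostic alternative to the exact `p^2` arithmetic that accounts for a
#' gene being targeted by `n_constructs` independent constructs: the
#' probability that 2 or more of them are background hits. Not used in
#' hit calling.
#'
#' @param p Background per-construct hit probability.
#' @param n_constructs Constructs targeting the gene.
#' @return `P(X >= 2)` for `X ~ Binomial(n_constructs, p)`.
#' @export
double_hit_prob_binomial <- function(p, n_constructs) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) input_error("p must lie in [0, 1]")
  n_constructs <- assert_count(n_constructs, "n_constructs")
  stats::pbinom(1, n_constructs, p, lower.tail = FALSE)
}

#' Screen-level hit frequencies
#'
#' Computes the background hit frequency among scored vector-control
#' constructs, the chance double-hit probability `p^2`, and the gene-level
#' hit frequency (genes with >= 2 positive constructs over the number of
#' genes targeted), with the counts behind each.
#'
#' @param hit_calls A [call_hits()] result.
#' @param gene_calls A [call_genes()] result.
#' @param n_genes_targeted Denominator for the gene-hit frequency.
#' @return list of class `screen_frequencies`: `background_hit_frequency`,
#'   `chance_double_hit_probability`, `gene_hit_frequency`,
#'   `n_control_hits`, `n_controls_scored`, `n_gene_hits`,
#'   `n_genes_targeted`.
#' @export
screen_frequencies <- function(hit_calls, gene_calls, n_genes_targeted) {
  n_genes_targeted <- assert_count(n_genes_targeted, "n_genes_targeted")
  hc <- data.table::as.data.table(hit_calls)
  ctrl <- hc[role %in% CONTROL_ROLES & status == "scored"]
  gc <- data.table::as.data.table(gene_calls)
  screen_frequency_report(
    n_control_hits = sum(ctrl$is_hit %in% TRUE),
    n_controls_scored = nrow(ctrl),
    n_gene_hits = sum(gc$is_gene_hit %in% TRUE),
    n_genes_targeted = n_genes_targeted
  )
}

#' Screen frequencies from raw counts
#'
#' The arithmetic behind [screen_frequencies()], exposed for worked
#' examples and reports: `p = n_control_hits / n_controls_scored`, the
#' chance double-hit probability `p^2`, and
#' `n_gene_hits / n_genes_targeted`.
#'
#' @param n_control_hits,n_controls_scored Control constructs called hit /
#'   scored.
#' @param n_gene_hits,n_genes_targeted Gene-level hits / genes targeted.
#' @return list of class `screen_frequencies` (see [screen_frequencies()]).
#' @export
#' @examples
#' f <- screen_frequency_report(11, 464, 11, 420)
#' signif(f$gene_hit_frequency, 2)  # 0.026
screen_frequency_report <- function(n_control_hits, n_controls_scored,
                                    n_gene_hits, n_genes_targeted) {
  n_controls_scored <- assert_count(n_controls_scored, "n_controls_scored")
  n_control_hits <- assert_count(n_control_hits, "n_control_hits", min = 0)
  n_gene_hits <- assert_count(n_gene_hits, "n_gene_hits", min = 0)
  n_genes_targeted <- assert_count(n_genes_targeted, "n_genes_targeted")
  if (n_controls_scored == 0) calibration_error("no scored control constructs")
  p <- n_control_hits / n_controls_scored
  structure(list(
    background_hit_frequency = p,
    chance_double_hit_probability = chance_double_hit(p),
    gene_hit_frequency = n_gene_hits / n_genes_targeted,
    n_control_hits = n_control_hits,
    n_controls_scored = n_controls_scored,
    n_gene_hits = n_gene_hits,
    n_genes_targeted = n_genes_targeted
  ), class = "screen_frequencies")
}

#' @export
print.screen_frequencies <- function(x, ...) {
  cat("Screen-level hit frequencies\n")
  cat(sprintf("  background (control) hit frequency: %.4g  (%d / %d control constructs)\n",
              x$background_hit_frequency, x$n_control_hits, x$n_controls_scored))
  cat(sprintf("  chance double-hit probability p^2:  %.4g\n", x$chance_double_hit_probability))
  cat(sprintf("  gene hit frequency:                 %.4g  (%d / %d genes)\n",
              x$gene_hit_frequency, x$n_gene_hits, x$n_genes_targeted))
  invisible(x)
}

#' Absolute K5-K8+ cell-count annotation
#'
#' Flags constructs whose mean absolute K5-K8+ (K8-only) cell count
#' strictly exceeds the control mean: induced differentiation increases
#' the absolute number of luminal cells, not just the percentage via loss
#' of double-positive cells. This is an annotation, not a hit criterion.
#'
#' @param construct_scores A [score_constructs()] result.
#' @param control_stats A [control_statistics()] result.
#' @return data.frame: `construct_id`, `mean_count_k8_only`,
#'   `control_mean_count_k8_only`, `delta_count_k8_only`,
#'   `absolute_count_increased` (`NA` for unscored constructs).
#' @export
absolute_count_check <- function(construct_scores, control_stats) {
  if (!inherits(control_stats, "control_stats")) input_error("control_stats must come from control_statistics()")
  sc <- data.table::as.data.table(construct_scores)
  ctrl_mean <- control_stats$mean_count_k8_only
  out <- sc[, c("construct_id", "mean_count_k8_only"), with = FALSE]
  out[, control_mean_count_k8_only := ctrl_mean]
  out[, delta_count_k8_only := mean_count_k8_only - ctrl_mean]
  out[, absolute_count_increased := mean_count_k8_only > ctrl_mean]
  data.table::setDF(out)
}
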
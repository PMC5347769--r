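#' Efficiency-corrected relative expression (Pfaffl ratio)
#'
#' Relative expression of a target gene in a sample versus a control,
#' normalized to a reference gene, corrected for per-assay amplification
#' efficiency:
#' `ratio = E_target^(Ct_target,control - Ct_target,sample) /
#'          E_reference^(Ct_reference,control - Ct_reference,sample)`.
#' With both delta-Ct equal to zero (a control against itself) the ratio
#' is exactly 1.
#'
#' @param ct_target_control,ct_target_sample Target-gene Cts (cycles).
#' @param ct_ref_control,ct_ref_sample Reference-gene Cts (cycles).
#' @param e_target,e_ref Amplification efficiencies in fold/cycle, in
#'   (1, 2]; default 2 (perfect doubling).
#' @return Relative expression ratio (> 0).
#' @export
#' @examples
#' pfaffl_ratio(24, 23, 20, 20)               # one-cycle doubling -> 2
#' pfaffl_ratio(24, 21.5, 20, 19.5, 1.95, 2)  # ~3.754
pfaffl_ratio <- function(ct_target_control, ct_target_sample,
                         ct_ref_control, ct_ref_sample,
                         e_target = 2, e_ref = 2) {
  for (e in list(e_target = e_target, e_ref = e_ref)) {
    if (any(!is.finite(e)) || any(e <= 1) || any(e > 2)) {
      config_error("amplification efficiencies must lie in (1, 2] fold/cycle")
    }
  }
  cts <- c(ct_target_control, ct_target_sample, ct_ref_control, ct_ref_sample)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    input_error("Ct values must be finite and > 0")
  }
  e_target^(ct_target_control - ct_target_sample) /
    e_ref^(ct_ref_control - ct_ref_sample)
}

#' Pfaffl ratios from a long Ct table
#'
#' Summarizes replicate Cts by their mean within gene and condition, then
#' applies [pfaffl_ratio()] per target gene against the reference gene.
#' The standard error of the log2 ratio is propagated from the replicate
#' Ct variances (delta method) and reported alongside.
#'
#' @param qpcr_table data.frame with columns `sample_id`, `condition`
#'   (`"control"` / `"knockdown"`), `gene`, `ct`.
#' @param reference_gene Normalization control gene (default `"HPRT1"`).
#' @param efficiencies Single value or named vector of per-gene
#'   efficiencies in (1, 2].
#' @return data.frame: `gene`, `ratio`, `n_control`, `n_knockdown`,
#'   `se_log2_ratio`.
#' @export
pfaffl_from_table <- function(qpcr_table, reference_gene = "HPRT1", efficiencies = 2) {
  need <- c("sample_id", "condition", "gene", "ct")
  missing <- setdiff(need, names(qpcr_table))
  if (length(missing)) input_error("qPCR table lacks column(s): ", paste(missing, collapse = ", "))
  dt <- data.table::as.data.table(qpcr_table)
  bad_cond <- setdiff(unique(dt$condition), c("control", "knockdown"))
  if (length(bad_cond)) input_error("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  if (!reference_gene %in% dt$gene) {
    input_error("reference gene ", reference_gene, " absent from the Ct table")
  }
  genes <- setdiff(unique(dt$gene), reference_gene)
  if (length(genes) == 0) input_error("no target genes in the Ct table")
  eff <- resolve_efficiencies(efficiencies, c(genes, reference_gene))

  stat <- dt[, list(mean_ct = mean(ct), var_ct = stats::var(ct), n = .N),
             by = c("gene", "condition")]
  get_stat <- function(g, cond) {
    row <- stat[gene == g & condition == cond]
    if (nrow(row) != 1) input_error("missing Cts for gene ", g, ", condition ", cond)
    row
  }
  out <- lapply(genes, function(g) {
    tc <- get_stat(g, "control"); tk <- get_stat(g, "knockdown")
    rc <- get_stat(reference_gene, "control"); rk <- get_stat(reference_gene, "knockdown")
    ratio <- pfaffl_ratio(tc$mean_ct, tk$mean_ct, rc$mean_ct, rk$mean_ct,
                          e_target = eff[[g]], e_ref = eff[[reference_gene]])
    # delta method on log2 ratio from the replicate Ct variances
    vterm <- function(s, e) (log2(e))^2 * (ifelse(is.na(s$var_ct), 0, s$var_ct) / s$n)
    se <- sqrt(vterm(tc, eff[[g]]) + vterm(tk, eff[[g]]) +
                 vterm(rc, eff[[reference_gene]]) + vterm(rk, eff[[reference_gene]]))
    data.frame(gene = g, ratio = ratio, n_control = tc$n, n_knockdown = tk$n,
               se_log2_ratio = se, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p values; monotone in
#' rank order, capped at 1, input order preserved.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    input_error("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Filter a differential-expression table at the screen's cutoffs
#'
#' Up-regulated: `log2fc > lfc_cutoff` and adjusted p `< alpha`;
#' down-regulated: `log2fc < -lfc_cutoff` and adjusted p `< alpha`.
#' Both inequalities are strict, so a gene exactly at the fold-change
#' cutoff is excluded. Supplied adjusted p values take precedence; when
#' absent they are computed from the raw p values with [bh_adjust()].
#'
#' @param de_table data.frame with `gene_id`, `log2fc`, and `adj_p`
#'   and/or `p`.
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 0.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return list: `up` and `down` (character vectors of gene ids) and
#'   `adjustment` (`"supplied"` or `"bh_recomputed"`).
#' @export
de_filter <- function(de_table, lfc_cutoff = 0.5, alpha = 0.05) {
  if (!all(c("gene_id", "log2fc") %in% names(de_table))) {
    input_error("DE table needs gene_id and log2fc columns")
  }
  if (any(!is.finite(de_table$log2fc))) input_error("log2fc must be finite")
  if (!is.null(de_table$adj_p) && (nrow(de_table) == 0 || !all(is.na(de_table$adj_p)))) {
    adj <- de_table$adj_p
    if (any(!is.finite(adj)) || any(adj < 0) || any(adj > 1)) {
      input_error("adjusted p values must lie in [0, 1]")
    }
    provenance <- "supplied"
  } else if (!is.null(de_table$p)) {
    adj <- bh_adjust(de_table$p)
    provenance <- "bh_recomputed"
  } else {
    input_error("DE table needs an adj_p or p column")
  }
  sig <- adj < alpha
  list(up = de_table$gene_id[sig & de_table$log2fc > lfc_cutoff],
       down = de_table$gene_id[sig & de_table$log2fc < -lfc_cutoff],
       adjustment = provenance)
}

#' Overlap counts between two regulated-gene signatures
#'
#' Exact set-intersection counts of up- and down-regulated genes between
#' two signatures, plus the per-signature totals (the numbers behind a
#' two-signature Venn diagram).
#'
#' @param up_a,down_a,up_b,down_b Character vectors of gene ids.
#' @return list of class `overlap_counts`: `up_a`, `down_a`, `up_b`,
#'   `down_b`, `shared_up`, `shared_down`, and the shared id sets
#'   `shared_up_genes`, `shared_down_genes`.
#' @export
venn_overlap <- function(up_a, down_a, up_b, down_b) {
  up_a <- unique(as.character(up_a)); down_a <- unique(as.character(down_a))
  up_b <- unique(as.character(up_b)); down_b <- unique(as.character(down_b))
  shared_up <- intersect(up_a, up_b)
  shared_down <- intersect(down_a, down_b)
  structure(list(
    up_a = length(up_a), down_a = length(down_a),
    up_b = length(up_b), down_b = length(down_b),
    shared_up = length(shared_up), shared_down = length(shared_down),
    shared_up_genes = sort(shared_up), shared_down_genes = sort(shared_down)
  ), class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("Signature overlap\n")
  cat(sprintf("  up:   %d vs %d, shared %d\n", x$up_a, x$up_b, x$shared_up))
  cat(sprintf("  down: %d vs %d, shared %d\n", x$down_a, x$down_b, x$shared_down))
  invisible(x)
}
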
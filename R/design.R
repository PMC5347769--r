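#' Screen design parameters
#'
#' Describes the physical layout of an arrayed shRNA differentiation screen:
#' how many genes are targeted, how many independent constructs per gene, how
#' many replicate wells per construct, plate capacity, and the per-plate
#' control complement. Defaults reproduce the published screen scale: 420
#' targeted kinases, 4-10 shRNA constructs per gene, triplicate wells seeded
#' at 1200 cells/well on 384-well plates carrying 56 vector-control wells
#' plus MCF7/MCF10A gating-control wells.
#'
#' @param n_genes Number of targeted genes.
#' @param constructs_per_gene Integer range `c(low, high)`; the number of
#'   shRNA constructs per gene is drawn uniformly from this range.
#' @param replicates_per_construct Replicate wells per construct.
#' @param cells_per_well_mean Mean seeded (measurable) cells per well.
#' @param controls_per_plate Vector-control wells per plate (empty,
#'   non-specific, GFP), forming the null pool for hit calling.
#' @param wells_per_plate Physical plate capacity.
#' @param gating_wells_per_line Wells per plate seeded with each
#'   immunofluorescence gating-control line (MCF7-like and MCF10A-like).
#' @return A `screen_design` list, validated.
#' @export
#' @examples
#' screen_design(n_genes = 10, cells_per_well_mean = 100)
screen_design <- function(n_genes = 420L,
                          constructs_per_gene = c(4L, 10L),
                          replicates_per_construct = 3L,
                          cells_per_well_mean = 1200,
                          controls_per_plate = 56L,
                          wells_per_plate = 384L,
                          gating_wells_per_line = 4L) {
  d <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    constructs_per_gene = constructs_per_gene,
    replicates_per_construct = assert_count(replicates_per_construct, "replicates_per_construct"),
    cells_per_well_mean = assert_positive(cells_per_well_mean, "cells_per_well_mean"),
    controls_per_plate = assert_count(controls_per_plate, "controls_per_plate"),
    wells_per_plate = assert_count(wells_per_plate, "wells_per_plate"),
    gating_wells_per_line = assert_count(gating_wells_per_line, "gating_wells_per_line")
  )
  cpg <- constructs_per_gene
  if (length(cpg) == 1) cpg <- c(cpg, cpg)
  if (length(cpg) != 2 || any(!is.finite(cpg)) || any(cpg != as.integer(cpg)) ||
      cpg[1] < 1 || cpg[2] < cpg[1]) {
    config_error("constructs_per_gene must be an integer range c(low, high) with low >= 1 and high >= low")
  }
  d$constructs_per_gene <- as.integer(cpg)
  if (d$wells_per_plate < d$controls_per_plate) {
    config_error("wells_per_plate (", d$wells_per_plate,
                 ") must be >= controls_per_plate (", d$controls_per_plate, ")")
  }
  treat_slots <- d$wells_per_plate - d$controls_per_plate - 2L * d$gating_wells_per_line
  if (treat_slots < d$replicates_per_construct) {
    config_error("plate layout leaves no room for treatment wells: ",
                 d$wells_per_plate, " wells minus ", d$controls_per_plate,
                 " controls minus ", 2L * d$gating_wells_per_line,
                 " gating wells < ", d$replicates_per_construct, " replicate slots")
  }
  structure(d, class = "screen_design")
}

#' Planted biological effects for a synthetic screen
#'
#' Specifies what the generator plants: which genes act as differentiators
#' (their knockdown shifts cells from the double-positive K5+K8+ pool to the
#' luminal K5-K8+ population), with what per-construct penetrance, and which
#' constructs are cytotoxic (yielding too few cells to pass well QC). The
#' default shift emulates the published effect size: the K5-K8+ fraction
#' rising from 4% at baseline to 24% in responding wells.
#'
#' The three non-shifted baseline population fractions (double-positive,
#' K5+K8-, double-negative) are generator choices: the screened line is
#' predominantly double-positive, so the double-positive pool donates the
#' shifted mass.
#'
#' @param baseline_k5neg_k8pos_fraction Baseline K5-K8+ (luminal) fraction.
#' @param effect_k5neg_k8pos_fraction K5-K8+ fraction in wells of responding
#'   differentiator constructs.
#' @param differentiator_genes Either a count (genes sampled at generation
#'   time) or a character vector of gene ids.
#' @param per_construct_effect_penetrance Probability that any one construct
#'   of a differentiator gene produces the shift (independent shRNAs differ
#'   in knockdown strength).
#' @param cytotoxic_constructs Either a count or a character vector of
#'   construct ids whose wells receive `cytotoxic_cell_count_mean` cells.
#' @param cytotoxic_cell_count_mean Mean cell count of cytotoxic wells;
#'   below the 200-cell QC threshold by default.
#' @param well_to_well_cv Multiplicative coefficient of variation of the
#'   per-well expected cell count.
#' @param baseline_dp_fraction Baseline double-positive (K5+K8+) fraction.
#' @param baseline_k5pos_k8neg_fraction Baseline K5+K8- fraction.
#' @return An `effect_model` list, validated.
#' @export
effect_model <- function(baseline_k5neg_k8pos_fraction = 0.04,
                         effect_k5neg_k8pos_fraction = 0.24,
                         differentiator_genes = 0L,
                         per_construct_effect_penetrance = 0.8,
                         cytotoxic_constructs = 0L,
                         cytotoxic_cell_count_mean = 100,
                         well_to_well_cv = 0.10,
                         baseline_dp_fraction = 0.78,
                         baseline_k5pos_k8neg_fraction = 0.03) {
  e <- list(
    baseline_k5neg_k8pos_fraction = assert_proportion(baseline_k5neg_k8pos_fraction, "baseline_k5neg_k8pos_fraction"),
    effect_k5neg_k8pos_fraction = assert_proportion(effect_k5neg_k8pos_fraction, "effect_k5neg_k8pos_fraction"),
    differentiator_genes = differentiator_genes,
    per_construct_effect_penetrance = assert_proportion(per_construct_effect_penetrance, "per_construct_effect_penetrance"),
    cytotoxic_constructs = cytotoxic_constructs,
    cytotoxic_cell_count_mean = assert_positive(cytotoxic_cell_count_mean, "cytotoxic_cell_count_mean"),
    well_to_well_cv = assert_proportion(well_to_well_cv, "well_to_well_cv"),
    baseline_dp_fraction = assert_proportion(baseline_dp_fraction, "baseline_dp_fraction"),
    baseline_k5pos_k8neg_fraction = assert_proportion(baseline_k5pos_k8neg_fraction, "baseline_k5pos_k8neg_fraction")
  )
  if (e$effect_k5neg_k8pos_fraction < e$baseline_k5neg_k8pos_fraction) {
    config_error("effect_k5neg_k8pos_fraction must be >= baseline_k5neg_k8pos_fraction")
  }
  base_sum <- e$baseline_dp_fraction + e$baseline_k5pos_k8neg_fraction +
    e$baseline_k5neg_k8pos_fraction
  if (base_sum > 1) {
    config_error("baseline population fractions exceed 1 (sum ", signif(base_sum, 4), ")")
  }
  shift <- e$effect_k5neg_k8pos_fraction - e$baseline_k5neg_k8pos_fraction
  if (shift > e$baseline_dp_fraction) {
    config_error("effect shift (", shift, ") exceeds the baseline double-positive pool (",
                 e$baseline_dp_fraction, ")")
  }
  structure(e, class = "effect_model")
}

#' Per-population intensity, pyknosis and cell-area model
#'
#' Distributional stand-in for the immunofluorescence readout: each of the
#' four K5/K8 populations draws channel intensities log-normally, with the
#' marker-positive distribution well above the marker-negative one in the
#' corresponding channel. Cell areas are a two-component log-normal mixture
#' straddling the 830 um^2 size cutoff; a fixed fraction of cells is flagged
#' pyknotic.
#'
#' @param k5_neg_meanlog,k5_neg_sdlog,k5_pos_meanlog,k5_pos_sdlog Log-scale
#'   parameters of the K5-channel intensity for K5-negative and K5-positive
#'   populations (linear fluorescence units).
#' @param k8_neg_meanlog,k8_neg_sdlog,k8_pos_meanlog,k8_pos_sdlog Same for
#'   the K8 channel.
#' @param pyknotic_fraction Fraction of cells flagged pyknotic (excluded
#'   before gating).
#' @param area_log_mean_small,area_log_mean_big Log-mean areas (log um^2) of
#'   the small- and big-cell mixture components.
#' @param area_log_sd Log-scale SD shared by both area components.
#' @param big_cell_fraction_baseline,big_cell_fraction_effect Big-cell
#'   mixture weight in baseline vs responding wells.
#' @return An `intensity_model` list, validated.
#' @export
intensity_model <- function(k5_neg_meanlog = log(100), k5_neg_sdlog = 0.25,
                            k5_pos_meanlog = log(1000), k5_pos_sdlog = 0.35,
                            k8_neg_meanlog = log(100), k8_neg_sdlog = 0.25,
                            k8_pos_meanlog = log(1000), k8_pos_sdlog = 0.35,
                            pyknotic_fraction = 0.05,
                            area_log_mean_small = log(600),
                            area_log_mean_big = log(1100),
                            area_log_sd = 0.35,
                            big_cell_fraction_baseline = 0.25,
                            big_cell_fraction_effect = 0.50) {
  im <- list(
    k5_neg_meanlog = k5_neg_meanlog, k5_neg_sdlog = assert_positive(k5_neg_sdlog, "k5_neg_sdlog"),
    k5_pos_meanlog = k5_pos_meanlog, k5_pos_sdlog = assert_positive(k5_pos_sdlog, "k5_pos_sdlog"),
    k8_neg_meanlog = k8_neg_meanlog, k8_neg_sdlog = assert_positive(k8_neg_sdlog, "k8_neg_sdlog"),
    k8_pos_meanlog = k8_pos_meanlog, k8_pos_sdlog = assert_positive(k8_pos_sdlog, "k8_pos_sdlog"),
    pyknotic_fraction = assert_proportion(pyknotic_fraction, "pyknotic_fraction", open_upper = TRUE),
    area_log_mean_small = area_log_mean_small,
    area_log_mean_big = area_log_mean_big,
    area_log_sd = assert_positive(area_log_sd, "area_log_sd"),
    big_cell_fraction_baseline = assert_proportion(big_cell_fraction_baseline, "big_cell_fraction_baseline"),
    big_cell_fraction_effect = assert_proportion(big_cell_fraction_effect, "big_cell_fraction_effect")
  )
  if (im$k5_pos_meanlog <= im$k5_neg_meanlog) {
    config_error("k5_pos_meanlog must exceed k5_neg_meanlog")
  }
  if (im$k8_pos_meanlog <= im$k8_neg_meanlog) {
    config_error("k8_pos_meanlog must exceed k8_neg_meanlog")
  }
  structure(im, class = "intensity_model")
}
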
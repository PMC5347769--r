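#' Generate a seeded synthetic differentiation screen
#'
#' Produces a per-cell measurement table, a well annotation table, and the
#' ground truth of planted effects, with the statistical structure the
#' downstream analysis assumes: log-normal two-channel intensities per
#' K5/K8 population, Poisson cell counts with multiplicative well-to-well
#' noise, planted differentiator genes shifting cells from K5+K8+ to K5-K8+
#' with per-construct penetrance, cytotoxic constructs yielding low-count
#' wells, and per-plate vector-control and gating-control complements.
#'
#' Treatment constructs are assigned to plates round-robin (all replicate
#' wells of a construct share a plate); every plate carries the full control
#' complement. Control wells are grouped into pseudo-constructs of
#' `replicates_per_construct` wells within plate and role so that control
#' and treatment constructs are scored identically downstream.
#'
#' @param design A [screen_design()].
#' @param effects An [effect_model()].
#' @param intensity An [intensity_model()].
#' @param seed Non-negative integer; identical inputs and seed give
#'   identical tables. The caller's RNG state is restored on exit.
#' @return A list of class `synthetic_screen` with elements
#'   `cells` (data.frame: `cell_id`, `well_id`, `intensity_k5`,
#'   `intensity_k8`, `cell_area`, `pyknotic`),
#'   `annotations` (data.frame: `well_id`, `plate_id`, `role`,
#'   `construct_id`, `gene_id`, `replicate_index`), and
#'   `truth` (list: `differentiator_genes`, `cytotoxic_constructs`,
#'   `wells` with the true and realized per-well population composition).
#' @export
#' @examples
#' scr <- generate_screen(
#'   screen_design(n_genes = 4, constructs_per_gene = c(2, 3),
#'                 cells_per_well_mean = 50),
#'   effect_model(differentiator_genes = 1),
#'   intensity_model(), seed = 7)
#' head(scr$cells)
generate_screen <- function(design, effects = effect_model(),
                            intensity = intensity_model(), seed = 1L) {
  if (!inherits(design, "screen_design")) config_error("design must be a screen_design object")
  if (!inherits(effects, "effect_model")) config_error("effects must be an effect_model object")
  if (!inherits(intensity, "intensity_model")) config_error("intensity must be an intensity_model object")
  with_seed(seed, generate_screen_impl(design, effects, intensity))
}

generate_screen_impl <- function(d, e, im) {
  reps <- d$replicates_per_construct
  lo <- d$constructs_per_gene[1]; hi <- d$constructs_per_gene[2]

  gene_ids <- sprintf("gene_%04d", seq_len(d$n_genes))
  ncg <- if (lo == hi) rep.int(lo, d$n_genes) else
    sample(seq.int(lo, hi), d$n_genes, replace = TRUE)
  construct_gene <- rep(gene_ids, ncg)
  construct_ids <- sprintf("%s_sh%02d", construct_gene, sequence(ncg))
  n_constructs <- length(construct_ids)

  diff_genes <- resolve_planted(e$differentiator_genes, gene_ids, "differentiator_genes")
  tox_constructs <- resolve_planted(e$cytotoxic_constructs, construct_ids, "cytotoxic_constructs")
  is_diff <- construct_gene %in% diff_genes
  affected <- logical(n_constructs)
  if (any(is_diff)) {
    affected[is_diff] <- stats::runif(sum(is_diff)) < e$per_construct_effect_penetrance
  }

  # plate layout: round-robin over treatment constructs, full controls everywhere
  treat_slots <- d$wells_per_plate - d$controls_per_plate - 2L * d$gating_wells_per_line
  cap <- max(1L, treat_slots %/% reps)
  n_plates <- max(1L, as.integer(ceiling(n_constructs / cap)))
  plate_ids <- sprintf("plate_%03d", seq_len(n_plates))
  construct_plate <- plate_ids[((seq_len(n_constructs) - 1L) %% n_plates) + 1L]

  ann_treat <- data.table::data.table(
    plate_id = rep(construct_plate, each = reps),
    role = "treatment",
    construct_id = rep(construct_ids, each = reps),
    gene_id = rep(construct_gene, each = reps),
    replicate_index = rep.int(seq_len(reps), n_constructs)
  )

  ctrl_roles <- rep(CONTROL_ROLES, length.out = d$controls_per_plate)
  ann_ctrl <- data.table::data.table(
    plate_id = rep(plate_ids, each = d$controls_per_plate),
    role = rep(ctrl_roles, times = n_plates)
  )
  ann_ctrl[, idx := seq_len(.N), by = c("plate_id", "role")]
  ann_ctrl[, construct_id := sprintf("ctrl_%s_%s_g%02d", sub("^control_", "", role),
                                     sub("^plate_", "p", plate_id),
                                     as.integer(ceiling(idx / reps)))]
  ann_ctrl[, replicate_index := ((idx - 1L) %% reps) + 1L]
  ann_ctrl[, gene_id := NA_character_]
  ann_ctrl[, idx := NULL]

  g <- d$gating_wells_per_line
  ann_gate <- data.table::data.table(
    plate_id = rep(plate_ids, each = 2L * g),
    role = rep(rep(GATING_ROLES, each = g), times = n_plates),
    construct_id = NA_character_,
    gene_id = NA_character_,
    replicate_index = rep.int(seq_len(g), 2L * n_plates)
  )

  ann <- data.table::rbindlist(list(ann_treat, ann_ctrl, ann_gate), use.names = TRUE)
  data.table::setorder(ann, plate_id, role, construct_id, replicate_index, na.last = TRUE)
  ann[, well_id := sprintf("well_%06d", seq_len(.N))]
  data.table::setcolorder(ann, c("well_id", "plate_id", "role", "construct_id",
                                 "gene_id", "replicate_index"))
  n_wells <- nrow(ann)

  # per-well expected counts and population composition
  ci <- match(ann$construct_id, construct_ids)      # NA for controls/gating
  well_affected <- !is.na(ci) & affected[ci]
  well_tox <- !is.na(ann$construct_id) & ann$construct_id %in% tox_constructs

  base_k8 <- e$baseline_k5neg_k8pos_fraction
  eff_k8 <- e$effect_k5neg_k8pos_fraction
  shift <- eff_k8 - base_k8
  f_dp <- ifelse(well_affected, e$baseline_dp_fraction - shift, e$baseline_dp_fraction)
  f_k5 <- rep.int(e$baseline_k5pos_k8neg_fraction, n_wells)
  f_k8 <- ifelse(well_affected, eff_k8, base_k8)
  is_mcf7 <- ann$role == "gating_mcf7"      # luminal line: pure K5-K8+
  is_mcf10a <- ann$role == "gating_mcf10a"  # basal line: pure K5+K8-
  f_dp[is_mcf7 | is_mcf10a] <- 0
  f_k5[is_mcf7] <- 0; f_k8[is_mcf7] <- 1
  f_k5[is_mcf10a] <- 1; f_k8[is_mcf10a] <- 0
  f_dn <- pmax(0, 1 - f_dp - f_k5 - f_k8)

  cvsd <- sqrt(log(1 + e$well_to_well_cv^2))
  mult <- if (cvsd > 0) exp(stats::rnorm(n_wells, -cvsd^2 / 2, cvsd)) else rep.int(1, n_wells)
  lambda <- ifelse(well_tox, e$cytotoxic_cell_count_mean, d$cells_per_well_mean) * mult
  n_cells_w <- stats::rpois(n_wells, lambda)

  big_frac <- ifelse(well_affected, im$big_cell_fraction_effect, im$big_cell_fraction_baseline)

  total <- sum(n_cells_w)
  widx <- rep.int(seq_len(n_wells), n_cells_w)
  cum1 <- f_dp; cum2 <- f_dp + f_k5; cum3 <- cum2 + f_k8
  u <- stats::runif(total)
  pop <- 1L + (u > cum1[widx]) + (u > cum2[widx]) + (u > cum3[widx]) # 1 DP 2 K5_only 3 K8_only 4 DN
  k5pos <- pop <= 2L
  k8pos <- pop == 1L | pop == 3L

  k5_meanlog <- im$k5_neg_meanlog + (im$k5_pos_meanlog - im$k5_neg_meanlog) * k5pos
  k5_sdlog <- im$k5_neg_sdlog + (im$k5_pos_sdlog - im$k5_neg_sdlog) * k5pos
  k8_meanlog <- im$k8_neg_meanlog + (im$k8_pos_meanlog - im$k8_neg_meanlog) * k8pos
  k8_sdlog <- im$k8_neg_sdlog + (im$k8_pos_sdlog - im$k8_neg_sdlog) * k8pos
  int_k5 <- stats::rlnorm(total, k5_meanlog, k5_sdlog)
  int_k8 <- stats::rlnorm(total, k8_meanlog, k8_sdlog)
  pyk <- stats::runif(total) < im$pyknotic_fraction
  big <- stats::runif(total) < big_frac[widx]
  area_meanlog <- im$area_log_mean_small + (im$area_log_mean_big - im$area_log_mean_small) * big
  area <- stats::rlnorm(total, area_meanlog, im$area_log_sd)

  cells <- data.table::setDT(list(
    cell_id = seq_len(total),
    well_id = ann$well_id[widx],
    intensity_k5 = int_k5,
    intensity_k8 = int_k8,
    cell_area = area,
    pyknotic = pyk
  ))

  realized <- matrix(tabulate((widx - 1L) * 4L + pop, nbins = 4L * n_wells),
                     ncol = 4L, byrow = TRUE)
  truth_wells <- data.table::data.table(
    well_id = ann$well_id, plate_id = ann$plate_id, role = ann$role,
    construct_id = ann$construct_id, gene_id = ann$gene_id,
    affected = well_affected, cytotoxic = well_tox,
    frac_dp = f_dp, frac_k5_only = f_k5, frac_k8_only = f_k8, frac_dn = f_dn,
    n_cells = n_cells_w,
    n_dp_true = realized[, 1], n_k5_only_true = realized[, 2],
    n_k8_only_true = realized[, 3], n_dn_true = realized[, 4]
  )

  structure(list(
    cells = data.table::setDF(cells),
    annotations = data.table::setDF(ann),
    truth = list(
      differentiator_genes = diff_genes,
      cytotoxic_constructs = tox_constructs,
      affected_constructs = construct_ids[affected],
      wells = data.table::setDF(truth_wells)
    )
  ), class = "synthetic_screen")
}

# Planted-id argument: a count (sampled from the pool) or explicit ids.
resolve_planted <- function(x, pool, name) {
  if (is.null(x) || length(x) == 0) return(character(0))
  if (is.numeric(x) && length(x) == 1) {
    n <- assert_count(x, name, min = 0)
    if (n > length(pool)) config_error(name, " count (", n, ") exceeds pool size (", length(pool), ")")
    if (n == 0) return(character(0))
    return(sort(sample(pool, n)))
  }
  if (is.character(x)) {
    bad <- setdiff(x, pool)
    if (length(bad)) config_error(name, " ids not in the generated pool: ", paste(utils::head(bad, 3), collapse = ", "))
    return(sort(unique(x)))
  }
  config_error(name, " must be a count or a character vector of ids")
}

#' Generate a synthetic qPCR Ct table
#'
#' Fixture generator for efficiency-corrected relative quantification: for
#' each target gene a planted knockdown/control expression ratio is encoded
#' in the target-gene Ct difference, with the reference gene (HPRT1 by
#' default) held constant across conditions. With `noise_sd = 0`,
#' [pfaffl_from_table()] recovers the planted ratios exactly.
#'
#' @param n_samples Replicates per condition.
#' @param true_ratios Named numeric vector of planted knockdown/control
#'   expression ratios, one per target gene.
#' @param efficiencies Amplification efficiencies in fold/cycle, in (1, 2]:
#'   either a single value for all genes or a named vector covering each
#'   target and the reference gene.
#' @param noise_sd SD (cycles) of Gaussian noise added to every Ct.
#' @param seed RNG seed.
#' @param reference_gene Normalization control gene name.
#' @param base_ct_target,base_ct_reference Control-condition mean Cts.
#' @return data.frame with columns `sample_id`, `condition`, `gene`, `ct`.
#' @export
generate_qpcr_table <- function(n_samples = 3L, true_ratios = c(ERN1 = 0.34),
                                efficiencies = 2.0, noise_sd = 0, seed = 1L,
                                reference_gene = "HPRT1",
                                base_ct_target = 24, base_ct_reference = 20) {
  n_samples <- assert_count(n_samples, "n_samples")
  if (is.null(names(true_ratios)) || any(!nzchar(names(true_ratios)))) {
    config_error("true_ratios must be a named vector (one ratio per target gene)")
  }
  if (any(!is.finite(true_ratios)) || any(true_ratios <= 0)) {
    config_error("true_ratios must be positive and finite")
  }
  if (length(noise_sd) != 1 || !is.finite(noise_sd) || noise_sd < 0) {
    config_error("noise_sd must be a single number >= 0")
  }
  genes <- c(names(true_ratios), reference_gene)
  eff <- resolve_efficiencies(efficiencies, genes)

  with_seed(seed, {
    rows <- list()
    for (g in names(true_ratios)) {
      # ratio = E_t^(Ct_t,ctrl - Ct_t,kd) / E_ref^(Ct_ref,ctrl - Ct_ref,kd); ref held flat
      dct <- log(true_ratios[[g]]) / log(eff[[g]])
      for (cond in c("control", "knockdown")) {
        ct_t <- if (cond == "control") base_ct_target else base_ct_target - dct
        rows[[length(rows) + 1L]] <- data.table::data.table(
          sample_id = sprintf("%s_%s_%d", g, cond, seq_len(n_samples)),
          condition = cond, gene = g,
          ct = ct_t + stats::rnorm(n_samples, 0, noise_sd)
        )
        rows[[length(rows) + 1L]] <- data.table::data.table(
          sample_id = sprintf("%s_%s_%d", g, cond, seq_len(n_samples)),
          condition = cond, gene = reference_gene,
          ct = base_ct_reference + stats::rnorm(n_samples, 0, noise_sd)
        )
      }
    }
    data.table::setDF(data.table::rbindlist(rows))
  })
}

resolve_efficiencies <- function(efficiencies, genes) {
  if (length(efficiencies) == 1 && is.null(names(efficiencies))) {
    efficiencies <- stats::setNames(rep.int(as.numeric(efficiencies), length(genes)), genes)
  }
  missing <- setdiff(genes, names(efficiencies))
  if (length(missing)) config_error("no efficiency supplied for: ", paste(missing, collapse = ", "))
  eff <- efficiencies[genes]
  if (any(!is.finite(eff)) || any(eff <= 1) || any(eff > 2)) {
    config_error("amplification efficiencies must lie in (1, 2] fold/cycle")
  }
  as.list(eff)
}

#' Generate paired synthetic differential-expression tables
#'
#' Fixture generator for the DE filter/overlap stage: two gene-level DE
#' tables (e.g. two knockdown signatures against a common control) with
#' planted shared up-/down-regulated genes and per-table unique genes, all
#' placed strictly beyond the filtering cutoffs; the remaining genes are
#' null (small fold changes, large p values).
#'
#' @param n_genes Total genes per table.
#' @param n_shared_up,n_shared_down Genes regulated in both tables.
#' @param n_unique_each Genes up-regulated in only one table (applied to
#'   each table symmetrically unless the per-table arguments are given).
#' @param seed RNG seed.
#' @param n_unique_up,n_unique_down Optional length-2 integer vectors
#'   giving per-table unique up-/down-regulated gene counts
#'   (overrides `n_unique_each`).
#' @param lfc_cutoff,alpha Cutoffs the planted effects must clear.
#' @return list with data.frames `table_a`, `table_b` (columns `gene_id`,
#'   `log2fc`, `p`, `adj_p`) and `truth` (planted id sets).
#' @export
generate_de_tables <- function(n_genes = 2000L, n_shared_up = 5L, n_shared_down = 3L,
                               n_unique_each = 4L, seed = 1L,
                               n_unique_up = NULL, n_unique_down = NULL,
                               lfc_cutoff = 0.5, alpha = 0.05) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_shared_up <- assert_count(n_shared_up, "n_shared_up", min = 0)
  n_shared_down <- assert_count(n_shared_down, "n_shared_down", min = 0)
  n_unique_each <- assert_count(n_unique_each, "n_unique_each", min = 0)
  n_up <- if (is.null(n_unique_up)) c(n_unique_each, n_unique_each) else as.integer(n_unique_up)
  n_dn <- if (is.null(n_unique_down)) c(0L, 0L) else as.integer(n_unique_down)
  if (length(n_up) != 2 || length(n_dn) != 2 || any(n_up < 0) || any(n_dn < 0)) {
    config_error("n_unique_up / n_unique_down must be length-2 non-negative integer vectors")
  }
  planted_total <- n_shared_up + n_shared_down + sum(n_up) + sum(n_dn)
  if (planted_total > n_genes) {
    config_error("planted gene counts (", planted_total, ") exceed n_genes (", n_genes, ")")
  }

  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    picked <- sample(gene_ids, planted_total)
    take <- function(n) { out <- picked[seq_len(n)]; picked <<- picked[-seq_len(n)]; if (n) out else character(0) }
    shared_up <- take(n_shared_up); shared_down <- take(n_shared_down)
    uniq_up_a <- take(n_up[1]); uniq_up_b <- take(n_up[2])
    uniq_dn_a <- take(n_dn[1]); uniq_dn_b <- take(n_dn[2])

    make_table <- function(up, down) {
      lfc <- stats::runif(n_genes, -0.9 * lfc_cutoff, 0.9 * lfc_cutoff)
      p <- stats::runif(n_genes, 0.30, 1)
      iu <- match(up, gene_ids); idn <- match(down, gene_ids)
      lfc[iu] <- stats::runif(length(iu), lfc_cutoff + 0.5, lfc_cutoff + 2)
      lfc[idn] <- -stats::runif(length(idn), lfc_cutoff + 0.5, lfc_cutoff + 2)
      # small enough that the BH-adjusted value stays strictly below alpha
      # even at rank 1 (p * m < alpha / 10)
      p[c(iu, idn)] <- stats::runif(length(iu) + length(idn), 1e-12, alpha / (10 * n_genes))
      data.frame(gene_id = gene_ids, log2fc = lfc, p = p,
                 adj_p = bh_adjust(p), stringsAsFactors = FALSE)
    }
    list(
      table_a = make_table(c(shared_up, uniq_up_a), c(shared_down, uniq_dn_a)),
      table_b = make_table(c(shared_up, uniq_up_b), c(shared_down, uniq_dn_b)),
      truth = list(shared_up = sort(shared_up), shared_down = sort(shared_down),
                   unique_up_a = sort(uniq_up_a), unique_up_b = sort(uniq_up_b),
                   unique_down_a = sort(uniq_dn_a), unique_down_b = sort(uniq_dn_b))
    )
  })
}
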
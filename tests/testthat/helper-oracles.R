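# Independent brute-force oracles: plain per-row loops, written without any
# of the package's vectorized internals, used to verify the pipeline on
# small inputs.

oracle_class_one <- function(k5, k8, pyk, th5, th8) {
  if (pyk) return("excluded_pyknotic")
  k5p <- k5 > th5
  k8p <- k8 > th8
  if (k5p && k8p) "DP" else if (k5p) "K5_only" else if (k8p) "K8_only" else "DN"
}

oracle_summarize_well <- function(cells, th5, th8, min_cells) {
  counts <- c(DP = 0, K5_only = 0, K8_only = 0, DN = 0)
  n_pyk <- 0
  for (i in seq_len(nrow(cells))) {
    cl <- oracle_class_one(cells$intensity_k5[i], cells$intensity_k8[i],
                           cells$pyknotic[i], th5, th8)
    if (cl == "excluded_pyknotic") n_pyk <- n_pyk + 1 else counts[cl] <- counts[cl] + 1
  }
  n <- sum(counts)
  pct <- if (n > 0) 100 * counts / n else counts * 0
  list(n_analyzable = n, n_pyknotic_excluded = n_pyk, counts = counts,
       pct = pct, qc_pass = n >= min_cells)
}

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Whole-pipeline oracle: raw cell table + annotations -> gene calls and
# screen frequencies, all by explicit enumeration.
oracle_pipeline <- function(cells, ann, z = 2.5, min_cells = 200,
                            z_cutoff = 2.5, min_constructs = 2) {
  grab <- function(role, channel) {
    vals <- c()
    for (i in seq_len(nrow(cells))) {
      w <- cells$well_id[i]
      r <- ann$role[ann$well_id == w]
      if (r == role && !cells$pyknotic[i]) vals <- c(vals, cells[[channel]][i])
    }
    vals
  }
  v5 <- grab("gating_mcf7", "intensity_k5")
  v8 <- grab("gating_mcf10a", "intensity_k8")
  th5 <- mean(v5) + z * oracle_sd(v5)
  th8 <- mean(v8) + z * oracle_sd(v8)

  wells <- list()
  for (w in ann$well_id) {
    wells[[w]] <- oracle_summarize_well(cells[cells$well_id == w, , drop = FALSE],
                                        th5, th8, min_cells)
  }

  con_ids <- sort(unique(ann$construct_id[!is.na(ann$construct_id)]))
  scores <- list()
  for (cid in con_ids) {
    wids <- ann$well_id[!is.na(ann$construct_id) & ann$construct_id == cid]
    pk8 <- pk5 <- nk8 <- c()
    for (w in wids) {
      if (wells[[w]]$qc_pass) {
        pk8 <- c(pk8, wells[[w]]$pct[["K8_only"]])
        pk5 <- c(pk5, wells[[w]]$pct[["K5_only"]])
        nk8 <- c(nk8, wells[[w]]$counts[["K8_only"]])
      }
    }
    scores[[cid]] <- list(
      role = ann$role[ann$well_id == wids[1]],
      gene = ann$gene_id[ann$well_id == wids[1]],
      scored = length(pk8) > 0, n_used = length(pk8),
      pct_k8 = if (length(pk8)) mean(pk8) else NA_real_,
      pct_k5 = if (length(pk5)) mean(pk5) else NA_real_,
      count_k8 = if (length(nk8)) mean(nk8) else NA_real_
    )
  }

  ctrl_k8 <- ctrl_k5 <- c()
  for (cid in con_ids) {
    s <- scores[[cid]]
    if (s$scored && s$role %in% c("control_empty", "control_nonspecific", "control_gfp")) {
      ctrl_k8 <- c(ctrl_k8, s$pct_k8)
      ctrl_k5 <- c(ctrl_k5, s$pct_k5)
    }
  }
  m8 <- mean(ctrl_k8); s8 <- oracle_sd(ctrl_k8)
  m5 <- mean(ctrl_k5); s5 <- oracle_sd(ctrl_k5)
  zof <- function(x, m, s) if (s > 0) (x - m) / s else (if (x > m) Inf else if (x < m) -Inf else 0)

  hits <- list()
  n_ctrl_scored <- 0; n_ctrl_hit <- 0
  for (cid in con_ids) {
    s <- scores[[cid]]
    if (!s$scored) { hits[[cid]] <- list(scored = FALSE); next }
    z8 <- zof(s$pct_k8, m8, s8); z5 <- zof(s$pct_k5, m5, s5)
    h8 <- z8 >= z_cutoff; h5 <- z5 >= z_cutoff
    hits[[cid]] <- list(scored = TRUE, z8 = z8, z5 = z5, h8 = h8, h5 = h5,
                        role = s$role, gene = s$gene)
    if (s$role != "treatment") {
      n_ctrl_scored <- n_ctrl_scored + 1
      if (h8 || h5) n_ctrl_hit <- n_ctrl_hit + 1
    }
  }

  genes <- sort(unique(ann$gene_id[!is.na(ann$gene_id)]))
  gene_hits <- character(0)
  for (g in genes) {
    cids <- unique(ann$construct_id[!is.na(ann$gene_id) & ann$gene_id == g])
    n8 <- n5 <- 0
    for (cid in cids) {
      h <- hits[[cid]]
      if (isTRUE(h$scored)) {
        if (h$h8) n8 <- n8 + 1
        if (h$h5) n5 <- n5 + 1
      }
    }
    if (n8 >= min_constructs || n5 >= min_constructs) gene_hits <- c(gene_hits, g)
  }

  p <- n_ctrl_hit / n_ctrl_scored
  list(th5 = th5, th8 = th8, wells = wells, scores = scores, hits = hits,
       gene_hits = gene_hits,
       freq = list(p = p, chance = p^2,
                   gene_freq = length(gene_hits) / length(genes)))
}

# Exhaustive step-up BH: adj_i = min(1, min_{j >= i} p_(j) * m / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in i:m) best <- min(best, ranked[j] * m / j)
    adj[i] <- best
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch statistic from first principles.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# -- fixture builders ---------------------------------------------------------

make_cells <- function(well_id, k5, k8, area = 500, pyknotic = FALSE) {
  n <- max(length(well_id), length(k5), length(k8))
  data.frame(cell_id = seq_len(n), well_id = rep_len(well_id, n),
             intensity_k5 = rep_len(k5, n), intensity_k8 = rep_len(k8, n),
             cell_area = rep_len(area, n), pyknotic = rep_len(pyknotic, n),
             stringsAsFactors = FALSE)
}

fixed_thresholds <- function(k5 = 150, k8 = 150) {
  structure(list(k5_threshold = k5, k8_threshold = k8, z_multiplier = 2.5,
                 n_mcf7_cells = 2L, n_mcf10a_cells = 2L),
            class = "gate_thresholds")
}

tiny_design <- function(n_genes = 4, cpg = c(2, 3), cells = 60,
                        controls = 6, wells = 60, gating = 2, reps = 3) {
  screen_design(n_genes = n_genes, constructs_per_gene = cpg,
                replicates_per_construct = reps, cells_per_well_mean = cells,
                controls_per_plate = controls, wells_per_plate = wells,
                gating_wells_per_line = gating)
}

# Shared analysis chain used by several tests (package route).
run_screen_calls <- function(scr, min_cells = 200, z = 2.5, z_cutoff = 2.5,
                             min_constructs = 2) {
  ann <- scr$annotations
  mcf7 <- scr$cells[scr$cells$well_id %in% ann$well_id[ann$role == "gating_mcf7"], ]
  mcf10a <- scr$cells[scr$cells$well_id %in% ann$well_id[ann$role == "gating_mcf10a"], ]
  th <- calibrate_thresholds(mcf7, mcf10a, z_multiplier = z)
  ws <- summarize_wells(scr$cells, th, min_cells = min_cells, all_well_ids = ann$well_id)
  sc <- score_constructs(ws, ann)
  cs <- control_statistics(sc)
  hc <- call_hits(sc, cs, z_cutoff = z_cutoff)
  gc <- call_genes(hc, min_constructs = min_constructs)
  fr <- screen_frequencies(hc, gc, length(unique(ann$gene_id[!is.na(ann$gene_id)])))
  list(thresholds = th, well_summaries = ws, scores = sc, control = cs,
       hits = hc, genes = gc, freq = fr)
}
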
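test_that("identical seed and parameters give identical tables", {
  d <- tiny_design()
  e <- effect_model(differentiator_genes = 1)
  a <- generate_screen(d, e, intensity_model(), seed = 11)
  b <- generate_screen(d, e, intensity_model(), seed = 11)
  expect_identical(a, b)
  c2 <- generate_screen(d, e, intensity_model(), seed = 12)
  expect_false(identical(a$cells, c2$cells))
})

test_that("generator restores the caller's RNG state", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_screen(tiny_design(), effect_model(), intensity_model(), seed = 5))
  expect_identical(runif(3), before)
})

test_that("no planted effects means empty ground truth", {
  scr <- generate_screen(tiny_design(), effect_model(), intensity_model(), seed = 1)
  expect_identical(scr$truth$differentiator_genes, character(0))
  expect_identical(scr$truth$cytotoxic_constructs, character(0))
  expect_false(any(scr$truth$wells$affected))
})

test_that("paper-scale defaults produce the stated layout", {
  # default design counts; few cells per well so only the layout is exercised
  scr <- generate_screen(screen_design(cells_per_well_mean = 5),
                         effect_model(), intensity_model(), seed = 3)
  ann <- scr$annotations
  treat <- ann[ann$role == "treatment", ]
  expect_equal(length(unique(treat$gene_id)), 420)
  cpg <- tapply(treat$construct_id, treat$gene_id, function(x) length(unique(x)))
  expect_true(all(cpg >= 4 & cpg <= 10))
  expect_true(all(table(treat$construct_id) == 3))
  ctrl <- ann[startsWith(ann$role, "control_"), ]
  expect_true(all(table(ctrl$plate_id) == 56))
  gat <- ann[startsWith(ann$role, "gating_"), ]
  expect_setequal(unique(gat$plate_id), unique(ann$plate_id))
  expect_true(all(table(gat$plate_id, gat$role) == 4))
  # annotation invariants
  expect_true(all(!is.na(treat$construct_id) & !is.na(treat$gene_id)))
  expect_true(all(is.na(gat$construct_id) & is.na(gat$gene_id)))
  expect_true(all(ann$replicate_index >= 1))
})

test_that("planted effects and toxic constructs are recorded and realized", {
  d <- tiny_design(n_genes = 6, cells = 400)
  e <- effect_model(differentiator_genes = 2, per_construct_effect_penetrance = 1,
                    cytotoxic_constructs = 1, cytotoxic_cell_count_mean = 30)
  scr <- generate_screen(d, e, intensity_model(), seed = 21)
  expect_length(scr$truth$differentiator_genes, 2)
  expect_length(scr$truth$cytotoxic_constructs, 1)
  tw <- scr$truth$wells
  # full penetrance: every well of a differentiator construct is affected
  diff_wells <- tw$gene_id %in% scr$truth$differentiator_genes & tw$role == "treatment"
  expect_true(all(tw$affected[diff_wells]))
  expect_true(all(tw$frac_k8_only[diff_wells] == 0.24))
  # toxic wells draw far fewer cells
  expect_lt(mean(tw$n_cells[tw$cytotoxic]), 100)
})

test_that("realized composition matches the effect model within 3 binomial SEs", {
  d <- tiny_design(n_genes = 5, cpg = c(7, 7), cells = 400, wells = 130,
                   controls = 6, gating = 2)
  scr <- generate_screen(d, effect_model(), intensity_model(), seed = 8)
  tw <- scr$truth$wells
  base <- tw[tw$role == "treatment", ]
  expect_gte(nrow(base), 100)
  for (pop in list(c("n_k8_only_true", 0.04), c("n_dp_true", 0.78),
                   c("n_k5_only_true", 0.03))) {
    frac <- sum(base[[pop[[1]]]]) / sum(base$n_cells)
    p <- as.numeric(pop[[2]])
    se <- sqrt(p * (1 - p) / sum(base$n_cells))
    expect_lt(abs(frac - p), 3 * se)
  }
})

test_that("null screens leave treatment and control wells exchangeable", {
  d <- tiny_design(n_genes = 8, cpg = c(3, 3), cells = 300,
                   controls = 12, wells = 100, gating = 2)
  nonsig <- 0
  for (s in 1:20) {
    scr <- generate_screen(d, effect_model(), intensity_model(), seed = 100 + s)
    res <- run_screen_calls(scr, min_cells = 100)
    ann <- scr$annotations
    ws <- res$well_summaries
    tr <- ws$pct_k8_only[ws$well_id %in% ann$well_id[ann$role == "treatment"] & ws$qc_pass]
    ct <- ws$pct_k8_only[ws$well_id %in% ann$well_id[startsWith(ann$role, "control_")] & ws$qc_pass]
    if (t.test(tr, ct)$p.value > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 19)
})

test_that("inconsistent designs raise configuration errors naming the invariant", {
  expect_error(screen_design(wells_per_plate = 40, controls_per_plate = 56),
               class = "bilinscreen_config_error")
  expect_error(screen_design(constructs_per_gene = c(5, 3)),
               class = "bilinscreen_config_error")
  expect_error(screen_design(n_genes = 0), class = "bilinscreen_config_error")
  expect_error(effect_model(baseline_k5neg_k8pos_fraction = 0.3,
                            effect_k5neg_k8pos_fraction = 0.2),
               class = "bilinscreen_config_error")
  expect_error(intensity_model(k5_pos_meanlog = log(50)),
               class = "bilinscreen_config_error")
  expect_error(generate_screen(tiny_design(), effect_model(differentiator_genes = 99),
                               intensity_model(), seed = 1),
               class = "bilinscreen_config_error")
})

test_that("qPCR generator round-trips planted ratios through the Pfaffl method", {
  for (r in c(1.0, 0.34, 2.7)) {
    tab <- generate_qpcr_table(n_samples = 3, true_ratios = c(GENE = r),
                               noise_sd = 0, seed = 4)
    res <- pfaffl_from_table(tab)
    expect_equal(res$ratio, r, tolerance = 1e-12)
  }
  # non-default efficiencies round-trip too when passed consistently
  eff <- c(GENE = 1.87, HPRT1 = 1.92)
  tab <- generate_qpcr_table(true_ratios = c(GENE = 0.42), efficiencies = eff,
                             noise_sd = 0, seed = 4)
  expect_equal(pfaffl_from_table(tab, efficiencies = eff)$ratio, 0.42,
               tolerance = 1e-12)
})

test_that("a planted two-fold ratio at perfect efficiency shifts the target Ct one cycle", {
  tab <- generate_qpcr_table(n_samples = 2, true_ratios = c(G = 2), efficiencies = 2,
                             noise_sd = 0, seed = 1)
  ct_ctrl <- unique(tab$ct[tab$gene == "G" & tab$condition == "control"])
  ct_kd <- unique(tab$ct[tab$gene == "G" & tab$condition == "knockdown"])
  expect_equal(ct_ctrl - ct_kd, 1)
  ref <- tab$ct[tab$gene == "HPRT1"]
  expect_equal(length(unique(ref)), 1)
})

test_that("qPCR generator rejects impossible efficiencies", {
  expect_error(generate_qpcr_table(true_ratios = c(G = 1), efficiencies = 1),
               class = "bilinscreen_config_error")
  expect_error(generate_qpcr_table(true_ratios = c(G = 1), efficiencies = 2.3),
               class = "bilinscreen_config_error")
})

test_that("DE table generator plants recoverable regulated sets", {
  de <- generate_de_tables(n_genes = 500, n_shared_up = 5, n_shared_down = 3,
                           n_unique_each = 4, seed = 9)
  fa <- de_filter(de$table_a)
  fb <- de_filter(de$table_b)
  ov <- venn_overlap(fa$up, fa$down, fb$up, fb$down)
  expect_setequal(intersect(fa$up, fb$up), de$truth$shared_up)
  expect_equal(ov$shared_up, 5)
  expect_equal(ov$shared_down, 3)
  expect_equal(ov$up_a, 5 + 4)
  expect_equal(ov$up_b, 5 + 4)

  none <- generate_de_tables(n_genes = 50, n_shared_up = 0, n_shared_down = 0,
                             n_unique_each = 0, seed = 2)
  f0 <- de_filter(none$table_a)
  expect_length(f0$up, 0)
  expect_length(f0$down, 0)

  expect_error(generate_de_tables(n_genes = 5, n_shared_up = 4, n_shared_down = 4),
               class = "bilinscreen_config_error")
})
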
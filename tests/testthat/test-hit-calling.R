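# Well-summary fixture: one row per well in the summarize_wells() schema.
make_ws <- function(well_id, pct_k8 = 4, pct_k5 = 3, n = 300, qc = TRUE) {
  k8_cnt <- round(n * pct_k8 / 100)
  data.frame(well_id = well_id, n_analyzable = n, n_pyknotic_excluded = 0L,
             n_dp = n - k8_cnt, n_k5_only = 0L, n_k8_only = k8_cnt, n_dn = 0L,
             pct_dp = 100 - pct_k8 - pct_k5, pct_k5_only = pct_k5,
             pct_k8_only = pct_k8, pct_dn = 0, qc_pass = qc,
             stringsAsFactors = FALSE)
}

make_ann <- function(well_id, role, construct_id, gene_id = NA_character_) {
  data.frame(well_id = well_id, plate_id = "plate_001", role = role,
             construct_id = construct_id, gene_id = gene_id,
             replicate_index = 1L, stringsAsFactors = FALSE)
}

test_that("construct scores average QC-passing replicate wells only", {
  ws <- rbind(make_ws("w1", pct_k8 = 10), make_ws("w2", pct_k8 = 12),
              make_ws("w3", pct_k8 = 14),
              make_ws("w4", pct_k8 = 50, qc = FALSE, n = 30),
              make_ws("w5", pct_k8 = 10), make_ws("w6", pct_k8 = 14),
              make_ws("w7", pct_k8 = 99, qc = FALSE, n = 10),
              make_ws("w8", pct_k8 = 99, qc = FALSE, n = 10),
              make_ws("w9", pct_k8 = 99, qc = FALSE, n = 10))
  ann <- make_ann(paste0("w", 1:9), "treatment",
                  rep(c("c1", "c2", "c3"), each = 3),
                  rep(c("gA", "gA", "gB"), each = 3))
  sc <- score_constructs(ws, ann)
  expect_equal(sc$pct_k8_only[sc$construct_id == "c1"], 12)
  expect_equal(sc$n_wells_used[sc$construct_id == "c1"], 3)
  # one replicate QC-fails: mean over the two passing wells
  expect_equal(sc$pct_k8_only[sc$construct_id == "c2"], 12)
  expect_equal(sc$n_wells_used[sc$construct_id == "c2"], 2)
  # all replicates below the cell cutoff: not scored, not dropped
  expect_equal(sc$status[sc$construct_id == "c3"], "not_scored")
  expect_true(is.na(sc$pct_k8_only[sc$construct_id == "c3"]))

  bad_ann <- ann
  bad_ann$gene_id[3] <- "gZ" # c1 now maps to two genes
  expect_error(score_constructs(ws, bad_ann), class = "bilinscreen_input_error")
})

test_that("control statistics pool scored vector controls and exclude gating wells", {
  ws <- rbind(make_ws("w1", pct_k8 = 2), make_ws("w2", pct_k8 = 4),
              make_ws("w3", pct_k8 = 6), make_ws("w4", pct_k8 = 90))
  ann <- rbind(make_ann("w1", "control_empty", "ce1"),
               make_ann("w2", "control_gfp", "cg1"),
               make_ann("w3", "control_nonspecific", "cn1"),
               make_ann("w4", "gating_mcf7", NA_character_))
  cs <- control_statistics(score_constructs(ws, ann))
  expect_equal(cs$pct_k8_only$mean, 4)
  expect_equal(cs$pct_k8_only$sd, 2)
  expect_equal(cs$n, 3) # the gating well never enters the null pool

  flat <- control_statistics(score_constructs(
    rbind(make_ws("w1", pct_k8 = 4), make_ws("w2", pct_k8 = 4), make_ws("w3", pct_k8 = 4)),
    rbind(make_ann("w1", "control_empty", "ce1"),
          make_ann("w2", "control_empty", "ce2"),
          make_ann("w3", "control_gfp", "cg1"))))
  expect_equal(flat$pct_k8_only$sd, 0)

  expect_error(control_statistics(score_constructs(
    make_ws("w1"), make_ann("w1", "control_empty", "ce1"))),
    class = "bilinscreen_calibration_error")
})

test_that("hits clear z >= 2.5 against the control distribution, inclusively", {
  ws <- rbind(make_ws("w1", pct_k8 = 2), make_ws("w2", pct_k8 = 4),
              make_ws("w3", pct_k8 = 6),
              make_ws("t1", pct_k8 = 10), make_ws("t2", pct_k8 = 4),
              make_ws("t3", pct_k8 = 9), make_ws("t4", pct_k8 = 24))
  ann <- rbind(make_ann("w1", "control_empty", "ce1"),
               make_ann("w2", "control_gfp", "cg1"),
               make_ann("w3", "control_nonspecific", "cn1"),
               make_ann(c("t1", "t2", "t3", "t4"), "treatment",
                        c("c1", "c2", "c3", "c4"), c("g1", "g2", "g3", "g4")))
  sc <- score_constructs(ws, ann)
  hc <- call_hits(sc, control_statistics(sc))
  # control mean 4, SD 2: 10 -> z = 3 (hit); 4 -> z = 0; 9 -> z = 2.5 exactly (hit)
  expect_equal(hc$z_k8_only[hc$construct_id == "c1"], 3)
  expect_true(hc$hit_k8_only[hc$construct_id == "c1"])
  expect_equal(hc$z_k8_only[hc$construct_id == "c2"], 0)
  expect_false(hc$is_hit[hc$construct_id == "c2"])
  expect_true(hc$hit_k8_only[hc$construct_id == "c3"]) # the threshold itself is a hit
  # the published strongest effect, 24% against a 4% control mean, is a clear hit
  expect_true(hc$is_hit[hc$construct_id == "c4"])
  expect_equal(hc$direction[hc$construct_id == "c4"], "toward_K8_only")
})

test_that("zero control SD makes any strict exceedance an infinite-z hit", {
  ws <- rbind(make_ws("w1", pct_k8 = 4), make_ws("w2", pct_k8 = 4),
              make_ws("t1", pct_k8 = 4.5), make_ws("t2", pct_k8 = 4))
  ann <- rbind(make_ann("w1", "control_empty", "ce1"),
               make_ann("w2", "control_gfp", "cg1"),
               make_ann(c("t1", "t2"), "treatment", c("c1", "c2"), c("g1", "g2")))
  sc <- score_constructs(ws, ann)
  hc <- call_hits(sc, control_statistics(sc))
  expect_equal(hc$z_k8_only[hc$construct_id == "c1"], Inf)
  expect_true(hc$hit_k8_only[hc$construct_id == "c1"])
  expect_equal(hc$z_k8_only[hc$construct_id == "c2"], 0)
  expect_false(hc$is_hit[hc$construct_id == "c2"])
})

test_that("genes need hits from at least two distinct constructs in one direction", {
  hc <- data.frame(
    construct_id = c("a1", "a2", "a3", "b1", "b2", "c1", "c2", "d1", "d2"),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gC", "gC", "gD", "gD"),
    role = "treatment",
    status = c(rep("scored", 7), "not_scored", "not_scored"),
    z_k8_only = c(3, 4, 1, 3, 1, 3, 1, NA, NA),
    hit_k8_only = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, NA, NA),
    z_k5_only = c(0, 0, 0, 0, 0, 3, 1, NA, NA),
    hit_k5_only = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, NA, NA),
    is_hit = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, NA, NA),
    direction = c("toward_K8_only", "toward_K8_only", NA, "toward_K8_only", NA,
                  "toward_K5_only", NA, NA, NA),
    stringsAsFactors = FALSE)
  gc <- call_genes(hc)
  expect_true(gc$is_gene_hit[gc$gene_id == "gA"])   # two hit constructs
  expect_false(gc$is_gene_hit[gc$gene_id == "gB"])  # one hit construct
  expect_false(gc$is_gene_hit[gc$gene_id == "gC"])  # one per direction, not two in one
  expect_equal(gc$status[gc$gene_id == "gD"], "not_scored")
  expect_false(gc$is_gene_hit[gc$gene_id == "gD"])
  expect_equal(gc$direction[gc$gene_id == "gA"], "toward_K8_only")
})

test_that("the chance double-hit probability is exactly p squared", {
  expect_equal(signif(chance_double_hit(0.0237), 2), 0.00056)
  expect_identical(chance_double_hit(0.0237), 0.0237^2)
  grid <- seq(0, 1, by = 0.01)
  expect_identical(chance_double_hit(grid) - grid^2, rep(0, length(grid)))
  expect_equal(chance_double_hit(0), 0)
  expect_equal(chance_double_hit(1), 1)
  expect_error(chance_double_hit(1.2), class = "bilinscreen_input_error")
})

test_that("the screen frequency report reproduces the published arithmetic", {
  f <- screen_frequency_report(n_control_hits = 9, n_controls_scored = 380,
                               n_gene_hits = 11, n_genes_targeted = 420)
  expect_equal(f$chance_double_hit_probability, (9 / 380)^2)
  expect_equal(signif(f$gene_hit_frequency, 2), 0.026)
  expect_equal(f$gene_hit_frequency, 11 / 420)
  expect_error(screen_frequency_report(0, 0, 0, 420),
               class = "bilinscreen_config_error")
})

test_that("the binomial multi-construct diagnostic differs from the p^2 default", {
  p <- 0.0237
  bin5 <- double_hit_prob_binomial(p, 5)
  expect_equal(bin5, pbinom(1, 5, p, lower.tail = FALSE))
  expect_gt(bin5, chance_double_hit(p)) # 5 chances to pair exceed a single pair
})

test_that("absolute-count annotation is strict and independent of the hit call", {
  # a construct can raise the K8-only percentage while losing absolute cells
  ws <- rbind(make_ws("w1", pct_k8 = 2, n = 2500), make_ws("w2", pct_k8 = 4, n = 2500),
              make_ws("w3", pct_k8 = 6, n = 2500),
              make_ws("t1", pct_k8 = 15, n = 300))
  ann <- rbind(make_ann("w1", "control_empty", "ce1"),
               make_ann("w2", "control_gfp", "cg1"),
               make_ann("w3", "control_nonspecific", "cn1"),
               make_ann("t1", "treatment", "c1", "g1"))
  sc <- score_constructs(ws, ann)
  cs <- control_statistics(sc)
  hc <- call_hits(sc, cs)
  ac <- absolute_count_check(sc, cs)
  expect_true(hc$is_hit[hc$construct_id == "c1"])
  expect_false(ac$absolute_count_increased[ac$construct_id == "c1"])
  # strict inequality: equal counts are not an increase
  sc_eq <- sc
  sc_eq$mean_count_k8_only[sc_eq$construct_id == "c1"] <- cs$mean_count_k8_only
  expect_false(absolute_count_check(sc_eq, cs)$absolute_count_increased[
    sc_eq$construct_id == "c1"])
  expect_true(absolute_count_check(
    transform(sc, mean_count_k8_only = cs$mean_count_k8_only + 1), cs
  )$absolute_count_increased[1])
})
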
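test_that("network generation honours requested class counts and determinism", {
  spec <- simulation_spec(n_tf = 5, n_mirna = 5, n_gene = 50,
                          n_tfout = 40, n_mirout = 40, n_bitt = 3,
                          n_bitm = 3, cohorts = "C1")
  sim <- generate_grn(spec, seed = 12)
  expect_equal(nrow(sim$grn$edges), 40 + 40 + 6 + 6)
  cls <- table(sim$grn$edges$class)
  expect_equal(as.integer(cls[c("TFout", "miRout", "BiTT", "BiTM")]),
               c(40L, 40L, 6L, 6L))
  # classification is consistent under re-running classify_edges
  re <- classify_edges(sim$grn)
  expect_equal(re$edges$class, sim$grn$edges$class)
  # byte-identical for the same seed
  sim2 <- generate_grn(spec, seed = 12)
  expect_identical(sim2$grn$edges, sim$grn$edges)
  # different seed gives a different network
  sim3 <- generate_grn(spec, seed = 13)
  expect_false(identical(sim3$grn$edges, sim$grn$edges))
  # infeasible requests are named
  expect_error(generate_grn(simulation_spec(n_tf = 2, n_bitt = 5)),
               "n_bitt")
})

test_that("every scoring unit of a generated network has a truth entry", {
  sim <- random_grn(6)
  e <- sim$grn$edges
  keys <- unique(ifelse(e$class %in% c("BiTT", "BiTM"),
                        canonical_pair_key(e$regulator_id, e$target_id),
                        paste(e$regulator_id, e$target_id, sep = ">")))
  expect_setequal(keys, sim$truth$pairs$pair_key)
  expect_false(anyDuplicated(sim$truth$pairs$pair_key) > 0)
})

test_that("planted correlations are recovered at Monte-Carlo tolerance", {
  spec <- simulation_spec(n_tf = 2, n_mirna = 2, n_gene = 2, n_tfout = 1,
                          n_mirout = 0, n_bitt = 0, n_bitm = 1,
                          cohorts = "C1", n_normal = 200, n_tumor = 200,
                          mirna_overlap = 1,
                          class_rho = list(TFout = c(0.8, 0.8),
                                           miRout = c(0, 0),
                                           BiTT = c(0, 0),
                                           BiTM = c(0, 0)))
  sim <- generate_grn(spec, seed = 3)
  rhos <- vapply(1:20, function(s) {
    ex <- generate_expression(sim, "C1", seed = s)
    rec <- score_network(sim$grn, ex$mrna, ex$mirna, ex$sheet, "C1",
                         "normal")
    rec$rho[rec$class == "TFout"]
  }, 0)
  # planted Spearman 0.8: batch mean within 3 SE (SE ~ 0.03/sqrt(20))
  expect_equal(mean(rhos), 0.8, tolerance = 0.03)
})

test_that("unplanted edges stay null and monotone maps preserve Spearman", {
  spec <- simulation_spec(n_tf = 10, n_mirna = 2, n_gene = 100,
                          n_tfout = 150, n_mirout = 0, n_bitt = 0,
                          n_bitm = 0, cohorts = "C1",
                          n_normal = 50, n_tumor = 4,
                          class_rho = list(TFout = c(0, 0),
                                           miRout = c(0, 0),
                                           BiTT = c(0, 0),
                                           BiTM = c(0, 0)))
  sim <- generate_grn(spec, seed = 9)
  ex <- generate_expression(sim, "C1", seed = 10)
  rec <- score_network(sim$grn, ex$mrna, ex$mirna, ex$sheet, "C1", "normal")
  expect_lte(mean(abs(rec$rho)), 2 / sqrt(50))
  # Spearman computed on the abundance scale equals Spearman on log2 scale
  m <- ex$mrna
  a <- unname(m[1, ]); b <- unname(m[2, ])
  expect_equal(spearman_rho(a, b), spearman_rho(log2(a), log2(b)))
})

test_that("miRNA sample overlap is exact by construction", {
  spec <- simulation_spec(n_tf = 3, n_mirna = 3, n_gene = 10, n_tfout = 5,
                          n_mirout = 5, n_bitt = 0, n_bitm = 1,
                          cohorts = "C1", n_normal = 40, n_tumor = 40,
                          mirna_overlap = 0.5)
  sim <- generate_grn(spec, seed = 4)
  ex <- generate_expression(sim, "C1", seed = 4)
  tum <- ex$sheet$sample_id[ex$sheet$condition == "tumor"]
  shared <- intersect(intersect(colnames(ex$mrna), colnames(ex$mirna)), tum)
  expect_length(shared, 20)
})

test_that("the planted loop rewires as specified and shifts its TF", {
  spec <- simulation_spec(cohorts = c("C1", "C2"))
  sim <- plant_dc_loop(generate_grn(spec, seed = 21))
  key <- sim$truth$planted_pair
  i <- which(sim$truth$pairs$pair_key == key)
  expect_equal(sim$truth$pairs$rho_normal[i], 0)
  expect_equal(sim$truth$pairs$rho_tumor[i], 0.8)
  tf <- sim$truth$planted_tf
  expect_equal(unname(sim$truth$tumor_shift[tf]), 1)

  ex <- generate_expression(sim, "C1", seed = 22)
  # the TF's tumour up-shift of +1 log2 unit is recovered by de_test
  d <- de_test(ex$mrna[tf, ex$sheet$sample_id[ex$sheet$condition ==
                                                "normal"]],
               ex$mrna[tf, ex$sheet$sample_id[ex$sheet$condition ==
                                                "tumor"]])
  expect_equal(d$log2fc, 1, tolerance = 0.6)
  expect_lt(d$p, 0.05)
  # the planted pair is strongly correlated in tumor, not in normal
  recT <- score_network(sim$grn, ex$mrna, ex$mirna, ex$sheet, "C1", "tumor")
  recN <- score_network(sim$grn, ex$mrna, ex$mirna, ex$sheet, "C1",
                        "normal")
  expect_gt(recT$z[recT$pair_key == key], 2.5)
  expect_lt(abs(recN$z[recN$pair_key == key]), 2.5)

  # negative control: no planting means no systematic rewiring of the pair
  sim0 <- generate_grn(spec, seed = 21)
  ex0 <- generate_expression(sim0, "C1", seed = 22)
  r0T <- score_network(sim0$grn, ex0$mrna, ex0$mirna, ex0$sheet, "C1",
                       "tumor")
  r0N <- score_network(sim0$grn, ex0$mrna, ex0$mirna, ex0$sheet, "C1",
                       "normal")
  D0 <- abs(r0N$z[r0N$pair_key == key] - r0T$z[r0T$pair_key == key])
  expect_lt(D0, 4)  # |difference of two unit-variance z's|, no offset

  # planting requires a BiTM pair
  no_bitm <- generate_grn(simulation_spec(n_bitm = 0, n_tfout = 20,
                                          n_mirout = 20, cohorts = "C1"),
                          seed = 1)
  expect_error(plant_dc_loop(no_bitm), "no BiTM")
})

test_that("annotation fixtures carry their ground truth", {
  sim <- plant_dc_loop(generate_grn(simulation_spec(), seed = 31))
  ann <- generate_annotations(sim, seed = 31)
  # forced planted endpoints are annotated
  ends <- strsplit(sim$truth$planted_pair, "|", fixed = TRUE)[[1]]
  kinds <- setNames(sim$grn$nodes$kind, sim$grn$nodes$id)
  for (id in ends) {
    if (kinds[[id]] == "miRNA") {
      expect_true(id %in% ann$cancer_mirnas)
    } else {
      expect_true(id %in% ann$cancer_genes)
    }
  }
  # planted module is the planted TF's unidirectional target set
  e <- sim$grn$edges
  expect_setequal(ann$genesets$planted_module,
                  e$target_id[e$regulator_id == sim$truth$planted_tf &
                                e$class == "TFout"])
  # drug fixture classes match the amplitude rule, including the
  # strict-boundary case t = 2c -> neutral
  cl <- classify_signatures(ann$drug_signatures)
  expect_equal(cl$class, ann$drug_signatures$truth_class)
  expect_true(any(ann$drug_signatures$t == 2 * ann$drug_signatures$c &
                    ann$drug_signatures$truth_class == "neutral"))
  # generator is deterministic
  ann2 <- generate_annotations(sim, seed = 31)
  expect_identical(ann2$cancer_genes, ann$cancer_genes)
  # forcing arbitrary DC pairs annotates their targets
  dc <- sim$truth$pairs[1:5, ]
  ann3 <- generate_annotations(sim, seed = 31, force_pairs = dc)
  tgt <- dc$v
  expect_true(all(tgt %in% c(ann3$cancer_genes, ann3$cancer_mirnas)))
})
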
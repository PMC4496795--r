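# hypergeometric enumeration oracle over all tables with the observed
# margins; used to pin down fisher_exact and geneset_enrichment
enum_fisher <- function(a, b, c, d, alternative) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  obs <- probs[xs == a]
  switch(alternative,
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]),
         two_sided = sum(probs[probs <= obs * (1 + 1e-7)]))
}

test_that("fisher_exact reproduces hand-enumerated tables", {
  expect_equal(fisher_exact(c(3, 1, 1, 3), "greater"), 17 / 70,
               tolerance = 1e-10)
  expect_equal(fisher_exact(c(5, 0, 0, 5), "greater"), 1 / 252,
               tolerance = 1e-10)
  expect_equal(fisher_exact(c(0, 5, 5, 0), "greater"), 1.0)
  expect_error(fisher_exact(c(-1, 1, 1, 1)), "negative")
})

test_that("fisher_exact agrees with full enumeration on random tables", {
  set.seed(17)
  for (i in 1:60) {
    x <- as.vector(rmultinom(1, sample(4:30, 1), runif(4, 0.1, 1)))
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(fisher_exact(x, alt),
                   enum_fisher(x[1], x[2], x[3], x[4], alt),
                   tolerance = 1e-9)
    }
  }
})

test_that("gene-set enrichment is the hypergeometric upper tail", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(s1 = universe[1:10])
  query <- c(universe[1:5], universe[90:94])
  res <- geneset_enrichment(query, sets, universe)
  manual <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(res$p, manual, tolerance = 1e-12)
  expect_equal(res$k, 5)
  expect_equal(res$direction, "over")
  # equivalence with the 2x2 exact test, greater
  expect_equal(res$p, fisher_exact(c(5, 5, 5, 85), "greater"),
               tolerance = 1e-10)
  # degenerate: query = set = universe has a single outcome
  expect_equal(geneset_enrichment(universe, list(all = universe),
                                  universe)$p, 1.0)
  # zero overlap: upper tail at k = 0 is 1
  res0 <- geneset_enrichment(universe[11:20], list(s1 = universe[1:10]),
                             universe)
  expect_equal(res0$p, 1.0)
  expect_equal(res0$direction, "under")
  expect_error(geneset_enrichment("g1", list(a = "g1"), character(0)),
               "empty universe")
})

test_that("Fisher's combined test matches its closed forms", {
  expect_equal(fisher_combined(c(1, 1)), 1.0)
  expect_equal(fisher_combined(0.3), 0.3)          # df 2 identity
  expect_equal(fisher_combined(c(0.05, 0.05)), 0.01747, tolerance = 1e-3)
  # closed form for two p-values: q(1 - log q), q = p1 p2
  for (q2 in list(c(0.2, 0.7), c(0.01, 0.5), c(0.9, 0.9))) {
    q <- prod(q2)
    expect_equal(fisher_combined(q2), q * (1 - log(q)), tolerance = 1e-12)
  }
  # combining k identical small p-values grows more significant with k
  ps <- vapply(1:5, function(k) fisher_combined(rep(0.05, k)), 0)
  expect_true(all(diff(ps) < 0))
  expect_error(fisher_combined(numeric(0)))
  expect_error(fisher_combined(c(0.5, 0)), "0, 1")
})

test_that("the DE substitute combines rank-sum p with log2 fold-change", {
  x <- c(100, 200, 300, 400, 150)
  same <- de_test(x, x)
  expect_equal(same$log2fc, 0)
  expect_equal(same$p, 1.0)
  # exact doubling at large values: log2fc ~ 1 (pseudocount bias bounded)
  d <- de_test(x, 2 * x)
  expect_equal(d$log2fc, 1, tolerance = 0.01)
  # complete separation at 3 vs 3: exact p = 2/C(6,3)
  expect_equal(de_test(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  # p is rank-based, invariant under monotone transforms
  set.seed(4)
  a <- rlnorm(10, 5); b <- rlnorm(10, 6)
  expect_equal(de_test(a, b)$p, de_test(sqrt(a), sqrt(b))$p)
  # small groups are skipped, not errors
  expect_false(de_test(c(1, 2), c(3, 4, 5))$ok)
})

test_that("regulator modules need positive correlation AND up-regulation", {
  rec <- make_records(c("TF1>g1", "TF1>g2", "TF1>g3", "TF1|m1"),
                      z = c(3.0, -3.0, 3.0, 4.0),
                      class = c("TFout", "TFout", "TFout", "BiTM"),
                      condition = "tumor")
  de <- data.frame(feature = c("g1", "g2", "g3", "m1"),
                   log2fc = c(1, 1, -0.5, 1),
                   p = c(0.01, 0.01, 0.01, 0.01),
                   stringsAsFactors = FALSE)
  mod <- regulator_module("TF1", rec, de)
  expect_true("g1" %in% mod)          # z > 2.5 and up-regulated
  expect_false("g2" %in% mod)         # negatively correlated, excluded
  expect_false("g3" %in% mod)         # down-regulated, excluded
  expect_true("m1" %in% mod)          # bidirectional partner included
  expect_warning(empty <- regulator_module("TF9", rec, de), "absent")
  expect_length(empty, 0)
})

test_that("cancer-association enrichment detects planted labels", {
  kinds <- setNames(c(rep("TF", 10), rep("gene", 200), rep("miRNA", 10)),
                    c(sprintf("T%02d", 1:10), sprintf("g%03d", 1:200),
                      sprintf("m%02d", 1:10)))
  set.seed(8)
  bg <- data.frame(pair_key = sprintf("e%03d", 1:200),
                   regulator = sample(sprintf("T%02d", 1:10), 200, TRUE),
                   target = sprintf("g%03d", 1:200),
                   class = "TFout", stringsAsFactors = FALSE)
  dc <- bg[1:20, ]
  # annotate every DC target plus ~50% of the remaining targets
  cancer_genes <- c(dc$target, sample(bg$target[21:200], 90))
  res <- cancer_assoc_enrichment(dc, bg, cancer_genes, character(0), kinds)
  expect_lt(res$overall$p, 0.05)
  expect_equal(res$overall$proportion_dc, 1)
  # oracle: hypergeometric tail for the same 2x2
  K <- sum(bg$target %in% cancer_genes)
  expect_equal(res$overall$p,
               phyper(20 - 1, K, 200 - K, 20, lower.tail = FALSE),
               tolerance = 1e-10)
  # a DC set drawn from the background carries no signal
  dc2 <- bg[sample.int(200, 20), ]
  res2 <- cancer_assoc_enrichment(dc2, bg, sample(bg$target, 100),
                                  character(0), kinds)
  expect_gt(res2$overall$p, 1e-4)
  expect_error(cancer_assoc_enrichment(dc, bg[0, ], cancer_genes,
                                       character(0), kinds), "empty")
})

test_that("BiTM pairs split into CN/NC/CC categories with two-sided reporting", {
  kinds <- setNames(c("TF", "TF", "miRNA", "miRNA"),
                    c("T1", "T2", "m1", "m2"))
  bg <- data.frame(
    pair_key = c("T1|m1", "T1|m2", "T2|m1", "T2|m2"),
    regulator = c("T1", "T1", "T2", "T2"),
    target = c("m1", "m2", "m1", "m2"),
    class = "BiTM", stringsAsFactors = FALSE)
  res <- cancer_assoc_enrichment(bg[1, ], bg, "T1", "m2", kinds)
  cats <- res$categories
  expect_equal(cats$category, c("CN", "NC", "CC"))
  # T1|m1 is CN (TF annotated, miRNA not): the DC pair falls in CN
  expect_equal(cats$dc_count[cats$category == "CN"], 1)
  expect_equal(cats$background_count[cats$category == "CC"], 1)  # T1|m2
  expect_true(all(cats$p_over >= 0 & cats$p_over <= 1))
  expect_true(all(cats$p_under >= 0 & cats$p_under <= 1))
})

test_that("GMT collections round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g9"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sets.gmt")
  write_gmt(sets, p)
  expect_equal(read_gmt(p), sets)
})
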
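# fixture builders shared across test files; everything is generated in
# code so tests carry no data files

# build a grn from compact edge strings ("A>B") and a kinds vector
make_grn <- function(edges, kinds) {
  parts <- strsplit(edges, ">", fixed = TRUE)
  df <- data.frame(regulator_id = vapply(parts, `[[`, "", 1),
                   target_id = vapply(parts, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  kdf <- data.frame(id = names(kinds), kind = unname(kinds),
                    stringsAsFactors = FALSE)
  grn(df, kdf)
}

# write edge + kind TSVs for load_grn tests; returns the two paths
write_grn_files <- function(edges, kinds, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  parts <- strsplit(edges, ">", fixed = TRUE)
  ep <- file.path(dir, "edges.tsv")
  np <- file.path(dir, "nodes.tsv")
  write.table(data.frame(regulator_id = vapply(parts, `[[`, "", 1),
                         target_id = vapply(parts, `[[`, "", 2)),
              ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = names(kinds), kind = unname(kinds)),
              np, sep = "\t", quote = FALSE, row.names = FALSE)
  c(edges = ep, nodes = np)
}

# minimal scored-record table for selection/rewiring tests
make_records <- function(pair_key, z, class = "TFout",
                         regulator = NULL, target = NULL,
                         n = 60, condition = "normal", cohort = "C1") {
  if (is.null(regulator)) {
    sp <- strsplit(pair_key, "[>|]")
    regulator <- vapply(sp, `[[`, "", 1)
    target <- vapply(sp, `[[`, "", 2)
  }
  data.frame(pair_key = pair_key, regulator = regulator, target = target,
             class = class, cohort = cohort, condition = condition,
             n = n, rho = tanh(z / sqrt(n - 3)), z = z,
             clamped = FALSE, stringsAsFactors = FALSE)
}

# random classified grn for property tests
random_grn <- function(seed, n_tf = 6, n_mirna = 6, n_gene = 20,
                       n_tfout = 15, n_mirout = 12, n_bitt = 2,
                       n_bitm = 3) {
  spec <- simulation_spec(n_tf = n_tf, n_mirna = n_mirna, n_gene = n_gene,
                          n_tfout = n_tfout, n_mirout = n_mirout,
                          n_bitt = n_bitt, n_bitm = n_bitm,
                          cohorts = "C1", n_normal = 10, n_tumor = 10)
  generate_grn(spec, seed = seed)
}

# small expression fixture: matrix with given feature/sample names
make_expr <- function(features, samples, modality = "mRNA", seed = 1) {
  set.seed(seed)
  m <- matrix(2^(8 + rnorm(length(features) * length(samples))),
              nrow = length(features),
              dimnames = list(features, samples))
  attr(m, "modality") <- modality
  m
}

make_sheet <- function(samples, condition = "tumor", cohort = "C1") {
  data.frame(sample_id = samples,
             patient_id = paste0("P", seq_along(samples)),
             condition = condition, cohort = cohort,
             stringsAsFactors = FALSE)
}
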
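#' Simulation specification for synthetic cohorts
#'
#' Defines the study conditions for the synthetic generator: a typed
#' regulatory network with unidirectional and reciprocal (feedback) edges,
#' matched tumor/normal expression cohorts with planted per-class Spearman
#' correlations, tumor mean shifts, partial mRNA/miRNA sample overlap, and
#' annotation fractions. Defaults describe a desk-scale analogue of a
#' seven-cohort tumor/normal study: 60 normal + 60 tumor samples per
#' cohort and 250 directed regulations.
#'
#' @param n_tf,n_mirna,n_gene node counts.
#' @param n_tfout,n_mirout numbers of unidirectional edges.
#' @param n_bitt,n_bitm numbers of reciprocal TF-TF and TF-miRNA pairs
#'   (each contributes two directed edges).
#' @param cohorts cohort names.
#' @param n_normal,n_tumor samples per condition per cohort (>= 4).
#' @param mirna_overlap fraction of mRNA sample ids also profiled for
#'   miRNA, per condition.
#' @param class_rho named list class -> `c(normal, tumor)` planted Spearman
#'   correlations, each in (-1, 1). Defaults encode predominantly
#'   activating TF regulation and repressive miRNA regulation, identical
#'   in the two conditions (no rewiring unless planted).
#' @param tumor_shift named numeric vector feature -> tumor mean shift in
#'   log2 units.
#' @param cancer_fraction fraction of genes/TFs and of miRNAs labelled
#'   cancer-associated by [generate_annotations()].
#' @param base_log2 baseline log2 abundance (values are `2^(base + latent)`
#'   so downstream `log2(x + 1)` pseudocounts are negligible).
#' @return object of class `sim_spec`.
#' @export
simulation_spec <- function(n_tf = 15, n_mirna = 15, n_gene = 120,
                            n_tfout = 120, n_mirout = 100,
                            n_bitt = 5, n_bitm = 10,
                            cohorts = c("BRCA", "HNSC", "KIRC", "LUAD",
                                        "LUSC", "THCA", "UCEC"),
                            n_normal = 60, n_tumor = 60,
                            mirna_overlap = 0.8,
                            class_rho = list(
                              TFout = c(normal = 0.4, tumor = 0.4),
                              miRout = c(normal = -0.3, tumor = -0.3),
                              BiTT = c(normal = 0.5, tumor = 0.5),
                              BiTM = c(normal = 0.5, tumor = 0.5)),
                            tumor_shift = c(),
                            cancer_fraction = 0.15,
                            base_log2 = 8) {
  rhos <- unlist(class_rho)
  stopifnot(all(rhos > -1 & rhos < 1),
            n_normal >= 4, n_tumor >= 4,
            mirna_overlap >= 0, mirna_overlap <= 1,
            cancer_fraction >= 0, cancer_fraction <= 1)
  structure(list(n_tf = n_tf, n_mirna = n_mirna, n_gene = n_gene,
                 n_tfout = n_tfout, n_mirout = n_mirout,
                 n_bitt = n_bitt, n_bitm = n_bitm,
                 cohorts = cohorts, n_normal = n_normal, n_tumor = n_tumor,
                 mirna_overlap = mirna_overlap, class_rho = class_rho,
                 tumor_shift = tumor_shift,
                 cancer_fraction = cancer_fraction,
                 base_log2 = base_log2),
            class = "sim_spec")
}

#' Generate a typed regulatory network with ground truth
#'
#' Constructs the requested numbers of TFout and miRout edges and
#' reciprocal BiTT/BiTM pairs, with regulator out-degrees drawn by
#' preferential attachment (heavy-tailed, as regulatory networks are), no
#' self-loops, no duplicate edges, and no accidental reciprocal pairs
#' (candidate edges whose reverse already exists are rejected so the class
#' partition matches the request exactly). Deterministic for a fixed seed.
#'
#' The truth record holds one row per scoring unit (pair level for
#' bidirectional classes) with the planted Spearman correlations per
#' condition taken from `spec$class_rho`.
#'
#' @param spec a `sim_spec`.
#' @param seed integer seed.
#' @return list of class `regrewire_sim` with elements `grn` (classified),
#'   `truth` (list: `pairs`, `tumor_shift`, `planted_pair`) and `spec`.
#' @export
generate_grn <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  tfs <- sprintf("TF%02d", seq_len(spec$n_tf))
  mirs <- sprintf("miR%03d", seq_len(spec$n_mirna))
  genes <- sprintf("G%04d", seq_len(spec$n_gene))

  if (spec$n_bitt > choose(spec$n_tf, 2)) {
    stop("infeasible: n_bitt exceeds the number of distinct TF pairs",
         call. = FALSE)
  }
  if (spec$n_bitm > spec$n_tf * spec$n_mirna) {
    stop("infeasible: n_bitm exceeds the number of TF-miRNA pairs",
         call. = FALSE)
  }

  reg <- character(0); tgt <- character(0)
  has_edge <- function(u, v) any(reg == u & tgt == v)
  add <- function(u, v) { reg <<- c(reg, u); tgt <<- c(tgt, v) }

  if (spec$n_bitt > 0) {
    cmb <- t(utils::combn(tfs, 2))
    sel <- cmb[sample.int(nrow(cmb), spec$n_bitt), , drop = FALSE]
    for (i in seq_len(nrow(sel))) { add(sel[i, 1], sel[i, 2])
                                    add(sel[i, 2], sel[i, 1]) }
  }
  if (spec$n_bitm > 0) {
    grid <- expand.grid(tf = tfs, mir = mirs, stringsAsFactors = FALSE)
    sel <- grid[sample.int(nrow(grid), spec$n_bitm), , drop = FALSE]
    for (i in seq_len(nrow(sel))) { add(sel$tf[i], sel$mir[i])
                                    add(sel$mir[i], sel$tf[i]) }
  }
  draw_unidirectional <- function(n_edges, regulators, target_pool) {
    outdeg <- stats::setNames(rep(0, length(regulators)), regulators)
    made <- 0; tries <- 0
    while (made < n_edges) {
      tries <- tries + 1
      if (tries > 50 * n_edges + 1000) {
        stop("infeasible: cannot place ", n_edges,
             " unidirectional edges without duplicates/reciprocals",
             call. = FALSE)
      }
      u <- sample(regulators, 1, prob = outdeg + 1)
      v <- sample(target_pool, 1)
      if (u == v || has_edge(u, v) || has_edge(v, u)) next
      add(u, v)
      outdeg[u] <- outdeg[u] + 1
      made <- made + 1
    }
  }
  if (spec$n_tfout > 0) {
    draw_unidirectional(spec$n_tfout, tfs, c(genes, mirs))
  }
  if (spec$n_mirout > 0) {
    draw_unidirectional(spec$n_mirout, mirs, c(genes, tfs))
  }

  kinds <- data.frame(
    id = c(tfs, mirs, genes),
    kind = c(rep("TF", length(tfs)), rep("miRNA", length(mirs)),
             rep("gene", length(genes))),
    stringsAsFactors = FALSE)
  g <- classify_edges(grn(data.frame(regulator_id = reg, target_id = tgt,
                                     stringsAsFactors = FALSE), kinds))

  e <- g$edges
  pk <- edge_pair_key(e$regulator_id, e$target_id, e$class)
  ord <- radix_order(pk, e$regulator_id)
  e <- e[ord, , drop = FALSE]; pk <- pk[ord]
  units <- e[!duplicated(pk), , drop = FALSE]
  ukeys <- pk[!duplicated(pk)]
  rho_n <- vapply(units$class, function(cl) spec$class_rho[[cl]][1], 0)
  rho_t <- vapply(units$class, function(cl) spec$class_rho[[cl]][2], 0)
  pairs <- data.frame(pair_key = ukeys, u = units$regulator_id,
                      v = units$target_id, class = units$class,
                      rho_normal = unname(rho_n), rho_tumor = unname(rho_t),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(grn = g,
                 truth = list(pairs = pairs,
                              tumor_shift = spec$tumor_shift,
                              planted_pair = NULL),
                 spec = spec),
            class = "regrewire_sim")
}

#' Plant a consistently rewired TF-miRNA feedback loop
#'
#' Overrides one BiTM pair to be uncorrelated in normal and strongly
#' positively correlated in tumor in every cohort, and adds a tumor
#' up-shift to its TF - the pattern of a feedback loop whose equilibrium
#' is lost in tumor. The pair chosen is the one whose TF has the largest
#' unidirectional out-degree (ties broken by pair key), emulating a hub
#' regulator with a sizeable downstream program; the TF's overexpression
#' then propagates to that target module in tumor. The pair is marked in
#' the truth record as the expected rank-1 differentially co-expressed
#' BiTM regulation.
#'
#' @param sim a `regrewire_sim` from [generate_grn()].
#' @param rho_normal,rho_tumor planted Spearman correlations (defaults 0
#'   and 0.8).
#' @param tf_shift tumor mean shift of the TF in log2 units (default +1).
#' @return the modified `regrewire_sim`.
#' @export
plant_dc_loop <- function(sim, rho_normal = 0, rho_tumor = 0.8,
                          tf_shift = 1) {
  stopifnot(inherits(sim, "regrewire_sim"))
  pairs <- sim$truth$pairs
  bitm <- which(pairs$class == "BiTM")
  if (length(bitm) == 0) stop("no BiTM pair to plant", call. = FALSE)
  kinds0 <- stats::setNames(sim$grn$nodes$kind, sim$grn$nodes$id)
  e <- sim$grn$edges
  outdeg <- table(e$regulator_id[e$class == "TFout"])
  tf_of <- ifelse(kinds0[pairs$u[bitm]] == "TF", pairs$u[bitm],
                  pairs$v[bitm])
  deg <- as.integer(outdeg[tf_of])
  deg[is.na(deg)] <- 0L
  sel <- bitm[radix_order(-deg, pairs$pair_key[bitm])[1]]
  key <- pairs$pair_key[sel]
  i <- sel
  pairs$rho_normal[i] <- rho_normal
  pairs$rho_tumor[i] <- rho_tumor
  kinds <- stats::setNames(sim$grn$nodes$kind, sim$grn$nodes$id)
  tf <- if (kinds[[pairs$u[i]]] == "TF") pairs$u[i] else pairs$v[i]
  shift <- sim$truth$tumor_shift
  shift[tf] <- tf_shift
  sim$truth$pairs <- pairs
  sim$truth$tumor_shift <- shift
  sim$truth$planted_pair <- key
  sim$truth$planted_tf <- tf
  sim
}

#' Generate matched tumor/normal expression for one cohort
#'
#' Per condition, every feature starts as an independent standard normal
#' latent variable on the log2 scale. Planted correlations are induced by
#' rewriting the dependent endpoint of each truth pair as
#' `r * latent(src) + sqrt(1 - r^2) * noise`, where `r = 2 sin(pi rho_S / 6)`
#' converts the planted Spearman value to the Gaussian Pearson parameter,
#' so the population Spearman correlation equals the spec value. The
#' dependent endpoint is the target for unidirectional edges, the miRNA of
#' a BiTM pair, and the later-sorting TF of a BiTT pair; pairs are planted
#' in priority order (planted loop, then BiTT, BiTM, TFout, miRout, each by
#' pair key) so upstream regulators are finalized before they are used as
#' sources. A pair whose dependent endpoint was already planted, or already
#' used as a source, is left unplanted and recorded as a conflict (the same
#' resolution in both conditions). Features regulated by the same regulator
#' share its latent factor, so residual target-target correlations exist by
#' construction. Tumor mean shifts are added on the latent (log2) scale
#' before planting, so a shifted regulator's overexpression propagates to
#' its activated targets; values are then mapped to the abundance scale by
#' `2^(base_log2 + latent)` - a monotone map, so sample Spearman
#' correlations are untouched. miRNA sample ids are the first
#' `round(overlap * n)` mRNA sample ids of each condition.
#'
#' @param sim a `regrewire_sim`.
#' @param cohort cohort name.
#' @param seed integer seed.
#' @return list with `mrna`, `mirna` (matrices), `sheet` (sample sheet for
#'   this cohort) and `conflicts` (pair keys left unplanted).
#' @export
generate_expression <- function(sim, cohort, seed = 1) {
  stopifnot(inherits(sim, "regrewire_sim"))
  spec <- sim$spec
  set.seed(seed)
  nodes <- sim$grn$nodes
  feats <- nodes$id
  kinds <- stats::setNames(nodes$kind, nodes$id)
  mirna_feats <- nodes$id[nodes$kind == "miRNA"]
  mrna_feats <- setdiff(feats, mirna_feats)
  pairs <- sim$truth$pairs
  shift <- sim$truth$tumor_shift

  # planting plan: dependent endpoint and order, resolved once so both
  # conditions share the same conflict resolution
  plan <- pairs
  bidir <- is_bidirectional(plan$class)
  swap <- bidir & ((plan$class == "BiTM" & kinds[plan$u] == "miRNA") |
                     (plan$class == "BiTT" & plan$u > plan$v))
  src <- ifelse(swap, plan$v, plan$u)
  dep <- ifelse(swap, plan$u, plan$v)
  prio <- match(plan$class, c("BiTT", "BiTM", "TFout", "miRout"))
  if (!is.null(sim$truth$planted_pair)) {
    prio[plan$pair_key == sim$truth$planted_pair] <- 0L
  }
  ord <- radix_order(prio, plan$pair_key)
  plan <- data.frame(pair_key = plan$pair_key, src = src, dep = dep,
                     rho_normal = plan$rho_normal,
                     rho_tumor = plan$rho_tumor,
                     stringsAsFactors = FALSE)[ord, , drop = FALSE]
  active <- plan$rho_normal != 0 | plan$rho_tumor != 0
  planted_dep <- character(0); used_src <- character(0)
  conflict <- logical(nrow(plan))
  for (i in which(active)) {
    if (plan$dep[i] %in% planted_dep || plan$dep[i] %in% used_src) {
      conflict[i] <- TRUE
      next
    }
    planted_dep <- c(planted_dep, plan$dep[i])
    used_src <- c(used_src, plan$src[i])
  }
  plant <- plan[active & !conflict, , drop = FALSE]
  conflicts <- plan$pair_key[conflict]

  one_condition <- function(condition, n_s) {
    Z <- matrix(stats::rnorm(length(feats) * n_s), nrow = length(feats),
                dimnames = list(feats, NULL))
    # shifts first, so a shifted regulator's overexpression propagates to
    # its planted targets (the targets become activated in tumor)
    if (condition == "tumor" && length(shift)) {
      hit <- intersect(names(shift), feats)
      Z[hit, ] <- Z[hit, , drop = FALSE] + shift[hit]
    }
    rho <- if (condition == "normal") plant$rho_normal else plant$rho_tumor
    for (i in seq_len(nrow(plant))) {
      if (rho[i] == 0) next
      r <- 2 * sin(pi * rho[i] / 6)
      Z[plant$dep[i], ] <- r * Z[plant$src[i], ] +
        sqrt(1 - r^2) * Z[plant$dep[i], ]
    }
    2^(spec$base_log2 + Z)
  }

  nrm <- one_condition("normal", spec$n_normal)
  tmr <- one_condition("tumor", spec$n_tumor)
  ids_n <- sprintf("%s_N%02d", cohort, seq_len(spec$n_normal))
  ids_t <- sprintf("%s_T%02d", cohort, seq_len(spec$n_tumor))
  colnames(nrm) <- ids_n
  colnames(tmr) <- ids_t
  all_vals <- cbind(nrm, tmr)

  mrna <- all_vals[mrna_feats, , drop = FALSE]
  attr(mrna, "modality") <- "mRNA"
  n_mir_n <- round(spec$mirna_overlap * spec$n_normal)
  n_mir_t <- round(spec$mirna_overlap * spec$n_tumor)
  mir_samples <- c(ids_n[seq_len(n_mir_n)], ids_t[seq_len(n_mir_t)])
  mirna <- all_vals[mirna_feats, mir_samples, drop = FALSE]
  attr(mirna, "modality") <- "miRNA"

  sheet <- data.frame(
    sample_id = c(ids_n, ids_t),
    patient_id = sprintf("%s_P%03d", cohort,
                         c(seq_len(spec$n_normal), seq_len(spec$n_tumor))),
    condition = c(rep("normal", spec$n_normal),
                  rep("tumor", spec$n_tumor)),
    cohort = cohort, stringsAsFactors = FALSE)
  list(mrna = mrna, mirna = mirna, sheet = sheet, conflicts = conflicts)
}

#' Generate annotation and drug fixtures with ground truth
#'
#' Draws cancer-associated gene and miRNA labels at the spec fraction
#' (optionally forcing the planted feedback-loop endpoints to be
#' annotated, which creates the expected enrichment of cancer-associated
#' regulations among DC feedback loops), builds a gene-set collection in
#' which one set is the planted regulator's target module, and emits a
#' small drug-signature and drug-gene interaction fixture with known
#' amplitude classes.
#'
#' @param sim a `regrewire_sim`.
#' @param seed integer seed.
#' @param force_planted force planted-loop endpoints (and the planted
#'   module's TF) to be cancer-associated (default TRUE).
#' @param force_pairs optional data.frame with `regulator`/`target` (or
#'   `u`/`v`) columns: every listed pair is made cancer-associated by
#'   annotating its target endpoint (targets have low degree, so the
#'   planted association stays local to the listed pairs).
#' @param n_random_sets,set_size random gene sets in the GMT collection.
#' @return list with `cancer_genes`, `cancer_mirnas`, `genesets` (named
#'   list; `planted_module` is the planted TF's target set),
#'   `drug_signatures` (with `truth_class`), `drug_interactions`, and
#'   `truth` (planted TF and module).
#' @export
generate_annotations <- function(sim, seed = 1, force_planted = TRUE,
                                 force_pairs = NULL,
                                 n_random_sets = 10, set_size = 15) {
  stopifnot(inherits(sim, "regrewire_sim"))
  spec <- sim$spec
  set.seed(seed)
  nodes <- sim$grn$nodes
  gene_pool <- nodes$id[nodes$kind %in% c("TF", "gene")]
  mir_pool <- nodes$id[nodes$kind == "miRNA"]
  cancer_genes <- sample(gene_pool,
                         round(spec$cancer_fraction * length(gene_pool)))
  cancer_mirnas <- sample(mir_pool,
                          round(spec$cancer_fraction * length(mir_pool)))
  kinds <- stats::setNames(nodes$kind, nodes$id)
  planted <- sim$truth$planted_pair
  if (force_planted && !is.null(planted)) {
    ends <- strsplit(planted, "|", fixed = TRUE)[[1]]
    for (id in ends) {
      if (kinds[[id]] == "miRNA") {
        cancer_mirnas <- union(cancer_mirnas, id)
      } else {
        cancer_genes <- union(cancer_genes, id)
      }
    }
  }
  if (!is.null(force_pairs)) {
    tgt <- force_pairs$target %||% force_pairs$v
    cancer_mirnas <- union(cancer_mirnas, tgt[kinds[tgt] == "miRNA"])
    cancer_genes <- union(cancer_genes, tgt[kinds[tgt] != "miRNA"])
  }

  # planted functional module: the planted TF's unidirectional targets
  e <- sim$grn$edges
  tf <- sim$truth$planted_tf %||% nodes$id[nodes$kind == "TF"][1]
  module <- radix_sort(unique(e$target_id[e$regulator_id == tf &
                                      e$class == "TFout"]))
  universe <- gene_pool
  sets <- list(planted_module = module)
  for (i in seq_len(n_random_sets)) {
    sets[[sprintf("random_set_%02d", i)]] <-
      radix_sort(sample(universe, min(set_size, length(universe))))
  }

  # drug fixture: known (t, c) patterns covering up, down, neutral and the
  # strict-cutoff boundary (t = 2c gives a = 2/3, not > 0.67)
  base <- data.frame(
    t = c(3, 4, 1, 0.5, 2, 1, 1.2),
    c = c(1, -1, 3, 2, 1, 1, 1),
    truth_class = c("up", "up", "down", "down", "neutral", "neutral",
                    "neutral"),
    stringsAsFactors = FALSE)
  reps <- 3
  sig <- base[rep(seq_len(nrow(base)), reps), , drop = FALSE]
  sig$drug_id <- sprintf("drug%02d", seq_len(nrow(sig)))
  sig <- sig[, c("drug_id", "t", "c", "truth_class")]
  rownames(sig) <- NULL
  inter <- data.frame(
    drug_id = rep(sig$drug_id, each = 2),
    gene_id = sample(gene_pool, 2 * nrow(sig), replace = TRUE),
    source = "synthetic", stringsAsFactors = FALSE)
  list(cancer_genes = radix_sort(cancer_genes),
       cancer_mirnas = radix_sort(cancer_mirnas),
       genesets = sets,
       drug_signatures = sig,
       drug_interactions = inter,
       truth = list(planted_tf = tf, planted_module = module,
                    universe = universe))
}
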
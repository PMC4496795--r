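#' Build a pipeline configuration
#'
#' Collects the analysis thresholds (defaults are the conventional ones:
#' `|z| >= 2.5` significance, top 10% D(z) for DC selection, top-k grid
#' 5/10/15/20%, amplitude cutoff 0.67, DE alpha 0.05) together with the
#' simulation spec, seed and output directory. A YAML or JSON file with
#' the same field names can be read via `config_path`.
#'
#' @param spec a [simulation_spec()] (defaults to the package default).
#' @param seed master seed; every stage derives its own substream from it.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param z_thresh,top_k,dc_fraction,amplitude_cutoff,de_alpha thresholds.
#' @param plant_loop plant the rewired feedback loop (default TRUE).
#' @param config_path optional YAML/JSON file overriding the scalar fields.
#' @return list of class `rewire_config`.
#' @export
pipeline_config <- function(spec = simulation_spec(), seed = 1,
                            out_dir = NULL, z_thresh = 2.5,
                            top_k = c(0.05, 0.10, 0.15, 0.20),
                            dc_fraction = 0.10, amplitude_cutoff = 0.67,
                            de_alpha = 0.05, plant_loop = TRUE,
                            config_path = NULL) {
  cfg <- list(spec = spec, seed = seed, out_dir = out_dir,
              z_thresh = z_thresh, top_k = top_k,
              dc_fraction = dc_fraction,
              amplitude_cutoff = amplitude_cutoff,
              de_alpha = de_alpha, plant_loop = plant_loop)
  if (!is.null(config_path)) {
    override <- yaml::read_yaml(config_path)
    scalar <- intersect(names(override),
                        c("seed", "z_thresh", "top_k", "dc_fraction",
                          "amplitude_cutoff", "de_alpha", "plant_loop",
                          "out_dir"))
    cfg[scalar] <- override[scalar]
    if (!is.null(override$spec)) {
      cfg$spec <- do.call(simulation_spec, override$spec)
    }
  }
  stopifnot(cfg$z_thresh > 0, all(cfg$top_k > 0 & cfg$top_k <= 1),
            cfg$dc_fraction > 0, cfg$dc_fraction <= 1,
            cfg$amplitude_cutoff > 0, cfg$de_alpha > 0, cfg$de_alpha < 1)
  class(cfg) <- "rewire_config"
  cfg
}

#' Run the full rewiring analysis end to end
#'
#' Stages: simulate (network, cohorts, annotations, drug fixtures) ->
#' correlate (per-cohort, per-condition scored networks; top-k selections;
#' sign-activity tables) -> rewire (overlap statistics and rewiring-type
#' tables per cohort and k; cross-cohort overlap comparison) -> dc-rank
#' (D(z), DC flags, cross-cohort BiTM feedback-loop ranking) -> enrich
#' (cancer-association enrichment; activated regulator module, gene-set
#' enrichment, Fisher's combined p) -> drugnet (signature classification
#' and subnetwork). All randomness derives from the single config seed
#' through per-stage substreams, so outputs are reproducible byte for
#' byte. When `out_dir` is set, TSV/GMT/GraphML outputs plus a JSON
#' manifest (parameters, per-stage counts, output digests) are written.
#'
#' @param config a [pipeline_config()].
#' @return object of class `rewire_run` (invisibly if files are written):
#'   a list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "rewire_config"))
  spec <- config$spec
  seed <- config$seed
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  save <- function(df, name) {
    if (!is.null(out)) write_tsv(df, file.path(out, name))
  }

  # -- simulate ----------------------------------------------------------
  sim <- generate_grn(spec, seed = derive_seed(seed, 1))
  if (config$plant_loop) sim <- plant_dc_loop(sim)
  cohorts <- spec$cohorts
  expr <- lapply(seq_along(cohorts), function(i) {
    generate_expression(sim, cohorts[i], seed = derive_seed(seed, 10 + i))
  })
  names(expr) <- cohorts
  ann <- generate_annotations(sim, seed = derive_seed(seed, 2))
  kinds <- stats::setNames(sim$grn$nodes$kind, sim$grn$nodes$id)
  if (!is.null(out)) {
    export_network(sim$grn, file.path(out, "grn_edges.tsv"), "tsv",
                   nodes_path = file.path(out, "grn_nodes.tsv"))
    save(sim$truth$pairs, "truth_pairs.tsv")
    writeLines(ann$cancer_genes, file.path(out, "cancer_genes.txt"))
    writeLines(ann$cancer_mirnas, file.path(out, "cancer_mirnas.txt"))
    write_gmt(ann$genesets, file.path(out, "genesets.gmt"))
  }

  # -- correlate ---------------------------------------------------------
  scored <- lapply(cohorts, function(co) {
    lapply(c(normal = "normal", tumor = "tumor"), function(cond) {
      score_network(sim$grn, expr[[co]]$mrna, expr[[co]]$mirna,
                    expr[[co]]$sheet, co, cond)
    })
  })
  names(scored) <- cohorts
  activity <- lapply(cohorts, function(co) {
    lapply(stats::setNames(config$top_k, paste0("k", config$top_k)),
           function(k) {
             lapply(scored[[co]], function(rec) {
               sign_activity(top_percent(rec, k), rec)
             })
           })
  })
  names(activity) <- cohorts
  if (!is.null(out)) {
    for (co in cohorts) {
      for (cond in c("normal", "tumor")) {
        save(scored[[co]][[cond]],
             sprintf("scored_%s_%s.tsv", co, cond))
      }
    }
  }

  # -- rewire ------------------------------------------------------------
  rewiring <- lapply(stats::setNames(config$top_k,
                                     paste0("k", config$top_k)),
                     function(k) {
    per_cohort <- lapply(cohorts, function(co) {
      nN <- top_percent(significant_edges(scored[[co]]$normal,
                                          config$z_thresh), k)
      nT <- top_percent(significant_edges(scored[[co]]$tumor,
                                          config$z_thresh), k)
      list(overlap = overlap_stats(nN, nT),
           rewired = classify_rewiring(nN, nT))
    })
    names(per_cohort) <- cohorts
    inter_actor <- vapply(per_cohort,
                          function(x) x$overlap$jaccard_interactors, 0)
    inter_action <- vapply(per_cohort,
                           function(x) x$overlap$jaccard_interactions, 0)
    list(per_cohort = per_cohort,
         overlap_p = compare_overlap_across_cohorts(inter_actor,
                                                    inter_action))
  })
  if (!is.null(out)) {
    for (kname in names(rewiring)) {
      for (co in cohorts) {
        save(rewiring[[kname]]$per_cohort[[co]]$rewired,
             sprintf("rewiring_%s_%s.tsv", co, kname))
      }
    }
  }

  # -- dc-rank -----------------------------------------------------------
  dc <- lapply(cohorts, function(co) {
    dc_select(dz(scored[[co]]$normal, scored[[co]]$tumor,
                 config$z_thresh), config$dc_fraction)
  })
  names(dc) <- cohorts
  bitm_ranking <- rank_bitm_across_cohorts(dc)
  if (!is.null(out)) {
    for (co in cohorts) save(dc[[co]], sprintf("dc_%s.tsv", co))
    save(bitm_ranking, "bitm_ranking.tsv")
  }

  # -- enrich ------------------------------------------------------------
  cancer_enrich <- lapply(cohorts, function(co) {
    d <- dc[[co]]
    cancer_assoc_enrichment(d[d$dc_flag, , drop = FALSE], d,
                            ann$cancer_genes, ann$cancer_mirnas, kinds)
  })
  names(cancer_enrich) <- cohorts
  tf <- ann$truth$planted_tf
  module_tabs <- lapply(cohorts, function(co) {
    de <- de_table(expr[[co]]$mrna, expr[[co]]$sheet, co)
    mod <- suppressWarnings(
      regulator_module(tf, scored[[co]]$tumor, de,
                       z_thresh = config$z_thresh,
                       de_alpha = config$de_alpha))
    geneset_enrichment(mod, ann$genesets, ann$truth$universe)
  })
  names(module_tabs) <- cohorts
  set_ids <- names(ann$genesets)
  combined <- vapply(set_ids, function(sid) {
    ps <- vapply(module_tabs, function(tab) tab$p[tab$set_id == sid], 0)
    fisher_combined(ps)
  }, 0)
  module_summary <- data.frame(set_id = set_ids,
                               combined_p = unname(combined),
                               stringsAsFactors = FALSE)
  module_summary <- module_summary[radix_order(module_summary$combined_p,
                                         module_summary$set_id), ]
  rownames(module_summary) <- NULL
  if (!is.null(out)) {
    for (co in cohorts) save(module_tabs[[co]],
                             sprintf("module_enrichment_%s.tsv", co))
    save(module_summary, "module_combined.tsv")
  }

  # -- drugnet -----------------------------------------------------------
  sigs <- classify_signatures(ann$drug_signatures,
                              cutoff = config$amplitude_cutoff)
  subnet <- build_subnetwork(sigs, ann$drug_interactions)
  if (!is.null(out)) {
    save(sigs, "drug_signatures.tsv")
    export_subnetwork(subnet, file.path(out, "drug_subnetwork.graphml"),
                      "graphml")
    export_subnetwork(subnet, file.path(out, "drug_subnetwork.sif"), "sif")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("regrewire")),
    seed = seed,
    parameters = config[c("z_thresh", "top_k", "dc_fraction",
                          "amplitude_cutoff", "de_alpha", "plant_loop")],
    cohorts = cohorts,
    stages = list(
      simulate = list(nodes = nrow(sim$grn$nodes),
                      edges = nrow(sim$grn$edges),
                      planted_pair = sim$truth$planted_pair),
      correlate = list(scored_units = nrow(scored[[1]]$normal)),
      dc_rank = list(ranked_bitm = nrow(bitm_ranking)),
      drugnet = list(drugs = sum(sigs$class != "neutral"),
                     interactions = igraph::ecount(subnet))))
  if (!is.null(out)) {
    files <- list.files(out, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$output_digests <- as.list(tools::md5sum(files))
    names(manifest$output_digests) <- basename(files)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  res <- structure(list(sim = sim, annotations = ann, scored = scored,
                        activity = activity, rewiring = rewiring, dc = dc,
                        bitm_ranking = bitm_ranking,
                        cancer_enrichment = cancer_enrich,
                        module_enrichment = module_tabs,
                        module_combined = module_summary,
                        drug_signatures = sigs, drug_subnetwork = subnet,
                        manifest = manifest),
                   class = "rewire_run")
  if (is.null(out)) res else invisible(res)
}

#' @export
print.rewire_run <- function(x, ...) {
  cat("regrewire pipeline run\n")
  cat("  cohorts:", paste(x$manifest$cohorts, collapse = ", "), "\n")
  cat("  network:", x$manifest$stages$simulate$edges, "edges,",
      x$manifest$stages$simulate$nodes, "nodes\n")
  if (!is.null(x$sim$truth$planted_pair)) {
    cat("  planted feedback loop:", x$sim$truth$planted_pair, "\n")
  }
  if (nrow(x$bitm_ranking)) {
    cat("  top BiTM by mean D(z):", x$bitm_ranking$pair_key[1],
        sprintf("(mean D = %.2f over %d cohorts)\n",
                x$bitm_ranking$mean_D[1], x$bitm_ranking$n_cohorts[1]))
  }
  top_mod <- x$module_combined$set_id[1]
  cat(sprintf("  top functional module: %s (combined p = %.3g)\n",
              top_mod, x$module_combined$combined_p[1]))
  cat("  drug subnetwork:", x$manifest$stages$drugnet$drugs, "drugs,",
      x$manifest$stages$drugnet$interactions, "interactions\n")
  invisible(x)
}
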
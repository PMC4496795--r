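#' Connectivity-Map-style signature amplitude
#'
#' `a = 2 * (t - c) / (|t| + |c|)` for a treatment value `t` and control
#' value `c`: `a = 0` means no differential expression, `a > 0` increased
#' and `a < 0` decreased expression upon treatment. `a = 2/3` corresponds
#' to a two-fold change (`t = 2c`, `c > 0`), which is why the conventional
#' up/down cutoff sits at 0.67. Bounded: `|a| <= 2`.
#'
#' @param t,c numeric vectors (recycled).
#' @return amplitude(s); `NA` with a warning where `t = c = 0` (the
#'   signature carries no information and should be dropped).
#' @export
amplitude <- function(t, c) {
  denom <- abs(t) + abs(c)
  a <- 2 * (t - c) / denom
  if (any(denom == 0)) {
    warning(sum(denom == 0), " signature(s) with t = c = 0 dropped (NA)",
            call. = FALSE)
    a[denom == 0] <- NA_real_
  }
  a
}

#' Classify drug signatures as up / down / neutral
#'
#' Adds amplitude and class columns: `a > cutoff` is `up`, `a < -cutoff` is
#' `down`, anything else (including `a` exactly at the cutoff, which is a
#' strict comparison, and `NA` amplitudes) is `neutral`.
#'
#' @param signatures data.frame with columns `drug_id`, `t`, `c`.
#' @param cutoff amplitude cutoff (default 0.67, applied literally).
#' @return `signatures` with added `a` and `class` columns.
#' @export
classify_signatures <- function(signatures, cutoff = 0.67) {
  stopifnot(all(c("drug_id", "t", "c") %in% names(signatures)))
  signatures$a <- amplitude(signatures$t, signatures$c)
  signatures$class <- ifelse(is.na(signatures$a), "neutral",
                             ifelse(signatures$a > cutoff, "up",
                                    ifelse(signatures$a < -cutoff, "down",
                                           "neutral")))
  signatures
}

#' Collapse multiple signatures per drug
#'
#' Keeps, for each drug, the single signature with the largest `|a|`
#' (ties broken by row order). Useful when several instrument instances
#' exist per drug.
#'
#' @param signatures classified signatures (from [classify_signatures()]).
#' @return one row per drug.
#' @export
collapse_signatures <- function(signatures) {
  stopifnot("a" %in% names(signatures))
  ord <- radix_order(signatures$drug_id, -abs(signatures$a))
  s <- signatures[ord, , drop = FALSE]
  out <- s[!duplicated(s$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble an annotated drug-gene subnetwork
#'
#' Builds a bipartite graph over the drugs classified `up` or `down` and
#' the genes they interact with. Duplicated drug-gene pairs are removed;
#' interactions referencing drugs absent from the classified signatures
#' are dropped with a warning. Node attributes: `role` (`drug`/`gene`),
#' `reg_class` (drug up/down), `target_status` (gene annotation, default
#' `non-target`), `atc` (drug annotation, default `unclassified`).
#'
#' @param classed classified signatures (one row per drug; see
#'   [collapse_signatures()]).
#' @param interactions data.frame with `drug_id`, `gene_id` (optional
#'   `source`).
#' @param target_annotation optional named vector gene_id -> status (e.g.
#'   `validated`, `predicted`).
#' @param drug_annotation optional named vector drug_id -> ATC class.
#' @return an igraph graph.
#' @export
build_subnetwork <- function(classed, interactions,
                             target_annotation = NULL,
                             drug_annotation = NULL) {
  stopifnot(all(c("drug_id", "gene_id") %in% names(interactions)))
  interactions <- interactions[!duplicated(
    interactions[, c("drug_id", "gene_id")]), , drop = FALSE]
  keep_drugs <- classed$drug_id[classed$class %in% c("up", "down")]
  unknown <- setdiff(interactions$drug_id, classed$drug_id)
  if (length(unknown)) {
    warning("dropping ", sum(interactions$drug_id %in% unknown),
            " interaction(s) referencing unknown drug(s): ",
            paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  inter <- interactions[interactions$drug_id %in% keep_drugs, , drop = FALSE]
  drugs <- radix_sort(unique(inter$drug_id))
  genes <- radix_sort(unique(inter$gene_id))
  reg_class <- stats::setNames(classed$class, classed$drug_id)
  verts <- data.frame(
    name = c(drugs, genes),
    role = c(rep("drug", length(drugs)), rep("gene", length(genes))),
    reg_class = c(unname(reg_class[drugs]), rep(NA_character_,
                                                length(genes))),
    target_status = c(rep(NA_character_, length(drugs)),
                      unname((target_annotation[genes]) %||%
                               rep(NA_character_, length(genes)))),
    atc = c(unname((drug_annotation[drugs]) %||%
                     rep(NA_character_, length(drugs))),
            rep(NA_character_, length(genes))),
    stringsAsFactors = FALSE)
  verts$target_status[verts$role == "gene" &
                        is.na(verts$target_status)] <- "non-target"
  verts$atc[verts$role == "drug" & is.na(verts$atc)] <- "unclassified"
  igraph::graph_from_data_frame(
    d = data.frame(from = inter$drug_id, to = inter$gene_id,
                   source = inter$source %||% rep("interaction",
                                                  nrow(inter)),
                   stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
}

#' Export a drug-gene subnetwork
#'
#' @param g igraph graph from [build_subnetwork()].
#' @param path output path.
#' @param format `"graphml"` or `"sif"`.
#' @return invisibly, `path`.
#' @export
export_subnetwork <- function(g, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ga <- g
    # graphml writer rejects NA attribute values
    for (at in igraph::vertex_attr_names(ga)) {
      v <- igraph::vertex_attr(ga, at)
      if (is.character(v)) {
        v[is.na(v)] <- ""
        ga <- igraph::set_vertex_attr(ga, at, value = v)
      }
    }
    igraph::write_graph(ga, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    writeLines(paste(el[, 1], "interacts", el[, 2], sep = "\t"), path)
  }
  invisible(path)
}
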
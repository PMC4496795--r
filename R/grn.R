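#' Construct a typed regulatory network
#'
#' Builds a `grn` object from an edge table and a node-kind annotation.
#' Self-loops are removed and duplicate directed edges collapsed; both are
#' counted in the object's log. Nodes are typed as `TF`, `miRNA` or `gene`;
#' an id has exactly one kind.
#'
#' @param edges data.frame with columns `regulator_id`, `target_id`.
#' @param node_kinds data.frame with columns `id`, `kind` covering every id
#'   that appears in `edges`.
#' @return An object of class `grn`: a list with `nodes` (id, kind) and
#'   `edges` (regulator_id, target_id, class). `class` is `NA` until
#'   [classify_edges()] is called. The removal log is in `attr(x, "log")`.
#' @seealso [load_grn()], [classify_edges()], [export_network()]
#' @export
grn <- function(edges, node_kinds) {
  stopifnot(is.data.frame(edges), is.data.frame(node_kinds))
  edges <- edges[, c("regulator_id", "target_id"), drop = FALSE]
  edges$regulator_id <- as.character(edges$regulator_id)
  edges$target_id <- as.character(edges$target_id)
  node_kinds$id <- as.character(node_kinds$id)
  node_kinds$kind <- as.character(node_kinds$kind)

  bad_kind <- !node_kinds$kind %in% NODE_KINDS
  if (any(bad_kind)) {
    stop("unknown node kind '", node_kinds$kind[bad_kind][1], "' for id '",
         node_kinds$id[bad_kind][1], "' (expected TF, miRNA or gene)",
         call. = FALSE)
  }
  if (anyDuplicated(node_kinds$id)) {
    dup <- node_kinds$id[duplicated(node_kinds$id)][1]
    conflicting <- unique(node_kinds$kind[node_kinds$id == dup])
    if (length(conflicting) > 1) {
      stop("node '", dup, "' annotated with more than one kind: ",
           paste(conflicting, collapse = ", "), call. = FALSE)
    }
    node_kinds <- node_kinds[!duplicated(node_kinds$id), , drop = FALSE]
  }

  ids <- unique(c(edges$regulator_id, edges$target_id))
  missing <- setdiff(ids, node_kinds$id)
  if (length(missing)) {
    stop("no kind annotation for node id '", missing[1], "'", call. = FALSE)
  }

  self <- edges$regulator_id == edges$target_id
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  dup <- duplicated(edges[, c("regulator_id", "target_id")])
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  edges$class <- rep(NA_character_, nrow(edges))
  rownames(edges) <- NULL

  ids <- unique(c(edges$regulator_id, edges$target_id))
  nodes <- node_kinds[node_kinds$id %in% ids, c("id", "kind"), drop = FALSE]
  rownames(nodes) <- NULL

  log <- sprintf("%d duplicate, %d self-loop removed", n_dup, n_self)
  if (n_dup + n_self > 0) message("grn: ", log)
  structure(list(nodes = nodes, edges = edges), class = "grn", log = log)
}

#' Load a regulatory network from edge-list and node-kind files
#'
#' @param path TSV with header columns `regulator_id`, `target_id`
#'   (extra columns such as `evidence` are ignored).
#' @param node_kinds_path TSV with header columns `id`, `kind`.
#' @inherit grn return
#' @export
load_grn <- function(path, node_kinds_path) {
  kinds <- read_tsv_checked(node_kinds_path, c("id", "kind"), "node-kind")
  edges <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(edges) == 0 && ncol(edges) <= 1) {
    # empty edge file (possibly header-less): empty network
    return(grn(data.frame(regulator_id = character(), target_id = character()),
               kinds))
  }
  miss <- setdiff(c("regulator_id", "target_id"), names(edges))
  if (length(miss)) {
    stop("edge file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("regulator_id", "target_id")) {
    bad <- which(is.na(edges[[col]]) | edges[[col]] == "")
    if (length(bad)) {
      stop("edge file ", path, ": malformed row at line ", bad[1] + 1L,
           " (empty ", col, ")", call. = FALSE)
    }
  }
  grn(edges, kinds)
}

#' Assign regulation classes to every edge
#'
#' Each directed edge gets one of four mutually exclusive classes:
#' * `BiTT` - the reverse edge exists and both endpoints are TFs;
#' * `BiTM` - the reverse edge exists and the endpoints are one TF and one
#'   miRNA (a TF-miRNA feedback loop);
#' * `TFout` - any other edge with a TF regulator;
#' * `miRout` - any other edge with a miRNA regulator.
#'
#' Both directed edges of a reciprocal pair carry the same bidirectional
#' class. A reciprocal miRNA-miRNA pair falls outside the bidirectional
#' taxonomy (which requires a TF): each direction is classified `miRout`
#' and a warning is emitted.
#'
#' @param x a `grn`.
#' @return `x` with `edges$class` filled in.
#' @export
classify_edges <- function(x) {
  stopifnot(inherits(x, "grn"))
  e <- x$edges
  if (nrow(e) == 0) return(x)
  kind <- stats::setNames(x$nodes$kind, x$nodes$id)
  rk <- unname(kind[e$regulator_id])
  tk <- unname(kind[e$target_id])
  if (any(rk == "gene")) {
    bad <- e$regulator_id[rk == "gene"][1]
    stop("node '", bad, "' has kind 'gene' but appears as a regulator",
         call. = FALSE)
  }
  fwd <- directed_key(e$regulator_id, e$target_id)
  rev <- directed_key(e$target_id, e$regulator_id)
  recip <- rev %in% fwd

  cls <- ifelse(rk == "TF", "TFout", "miRout")
  cls[recip & rk == "TF" & tk == "TF"] <- "BiTT"
  cls[recip & ((rk == "TF" & tk == "miRNA") |
               (rk == "miRNA" & tk == "TF"))] <- "BiTM"
  mimi <- recip & rk == "miRNA" & tk == "miRNA"
  if (any(mimi)) {
    warning("reciprocal miRNA-miRNA edge(s) found (e.g. ",
            e$regulator_id[mimi][1], " <-> ", e$target_id[mimi][1],
            "); classified as miRout", call. = FALSE)
  }
  x$edges$class <- cls
  x
}

#' Export a regulatory network
#'
#' TSV export writes the edge list plus a companion node-kind file and is
#' round-trip safe through [load_grn()]. SIF uses the regulation class as
#' the relation label. GraphML (via igraph) carries node attribute `kind`
#' and edge attribute `class`.
#'
#' @param x a `grn`.
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param nodes_path companion node-kind TSV path (TSV format only);
#'   defaults to `<path without extension>_nodes.tsv`.
#' @return invisibly, the path(s) written.
#' @export
export_network <- function(x, path, format = c("tsv", "sif", "graphml"),
                           nodes_path = NULL) {
  stopifnot(inherits(x, "grn"))
  format <- match.arg(format)
  e <- x$edges
  if (format == "tsv") {
    nodes_path <- nodes_path %||%
      paste0(tools::file_path_sans_ext(path), "_nodes.tsv")
    write_tsv(e[, c("regulator_id", "target_id")], path)
    write_tsv(x$nodes, nodes_path)
    return(invisible(c(path, nodes_path)))
  }
  if (format == "sif") {
    rel <- ifelse(is.na(e$class), "regulates", e$class)
    writeLines(paste(e$regulator_id, rel, e$target_id, sep = "\t"), path)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$regulator_id, to = e$target_id,
                   class = ifelse(is.na(e$class), "unclassified", e$class),
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = x$nodes$id, kind = x$nodes$kind,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
print.grn <- function(x, ...) {
  cat("Typed regulatory network (grn)\n")
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(table(x$nodes$kind)),
                            as.integer(table(x$nodes$kind))), collapse = ", ")))
  cat(sprintf("  directed edges: %d\n", nrow(x$edges)))
  if (nrow(x$edges) && !all(is.na(x$edges$class))) {
    tab <- table(factor(x$edges$class, levels = REGULATION_CLASSES))
    cat("  classes:", paste(sprintf("%s %d", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
  } else if (nrow(x$edges)) {
    cat("  classes: unassigned (run classify_edges())\n")
  }
  invisible(x)
}

#' @export
summary.grn <- function(object, ...) {
  e <- object$edges
  cls <- table(factor(e$class, levels = REGULATION_CLASSES))
  pairs <- sum(is_bidirectional(e$class), na.rm = TRUE) / 2
  out <- list(n_nodes = nrow(object$nodes),
              kinds = table(object$nodes$kind),
              n_edges = nrow(e),
              classes = cls,
              n_bidirectional_pairs = pairs,
              log = attr(object, "log"))
  class(out) <- "summary.grn"
  out
}

#' @export
print.summary.grn <- function(x, ...) {
  cat("grn summary:", x$n_edges, "edges among", x$n_nodes, "nodes\n")
  print(x$classes)
  cat("bidirectional pairs:", x$n_bidirectional_pairs, "\n")
  if (!is.null(x$log)) cat("load log:", x$log, "\n")
  invisible(x)
}
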
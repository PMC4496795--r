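#' Overlap between two condition-specific networks
#'
#' Quantifies how much of a correlated network is conserved between normal
#' and tumor: the Jaccard index of the interactor sets (nodes touching at
#' least one retained regulation) and of the interaction sets (pair keys).
#' Jaccard (`|intersection| / |union|`) is used because it is symmetric and
#' bounded in `[0, 1]`.
#'
#' @param net_N,net_T record data.frames (same cohort, same selection rule),
#'   e.g. from [top_percent()].
#' @return object of class `overlap_stats`: a list with
#'   `jaccard_interactors`, `jaccard_interactions` and the underlying
#'   shared/total counts.
#' @export
overlap_stats <- function(net_N, net_T) {
  nodes_N <- unique(c(net_N$regulator, net_N$target))
  nodes_T <- unique(c(net_T$regulator, net_T$target))
  edges_N <- unique(net_N$pair_key)
  edges_T <- unique(net_T$pair_key)
  if (length(edges_N) == 0 && length(edges_T) == 0) {
    warning("both networks are empty; overlap reported as 0", call. = FALSE)
  }
  jacc <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0) return(0)
    length(intersect(a, b)) / length(u)
  }
  structure(list(
    jaccard_interactors = jacc(nodes_N, nodes_T),
    jaccard_interactions = jacc(edges_N, edges_T),
    n_shared_nodes = length(intersect(nodes_N, nodes_T)),
    n_total_nodes = length(union(nodes_N, nodes_T)),
    n_shared_edges = length(intersect(edges_N, edges_T)),
    n_total_edges = length(union(edges_N, edges_T))
  ), class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap: interactors %.3f (%d/%d), interactions %.3f (%d/%d)\n",
              x$jaccard_interactors, x$n_shared_nodes, x$n_total_nodes,
              x$jaccard_interactions, x$n_shared_edges, x$n_total_edges))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' For combined sample size at most 12 the null distribution of the
#' rank-sum is enumerated exactly over all group assignments of the pooled
#' values (average ranks for ties; two-sided p is twice the smaller tail,
#' capped at 1). Larger samples use the normal approximation with tie and
#' continuity correction via `stats::wilcox.test`.
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
ranksum_test <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both samples must be non-empty", call. = FALSE)
  if (m + n <= 12) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(m)])
    idx <- utils::combn(m + n, m)
    ws <- colSums(matrix(r[idx], nrow = m))
    return(min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))))
  }
  suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

#' Compare interactor vs interaction overlap across cohorts
#'
#' Tests whether the per-cohort interactor-overlap fractions differ from the
#' interaction-overlap fractions (two-sided Wilcoxon rank-sum).
#'
#' @param interactor_fracs,interaction_fracs one overlap fraction per cohort.
#' @return two-sided p-value.
#' @export
compare_overlap_across_cohorts <- function(interactor_fracs,
                                           interaction_fracs) {
  ranksum_test(interactor_fracs, interaction_fracs)
}

#' Classify gained and lost regulations by rewiring type
#'
#' Every regulation in the symmetric difference of the two networks is
#' labelled `lost` (present in normal only) or `gained` (tumor only) and
#' assigned a rewiring type by how many of its two endpoints remain
#' interactors (touch any retained regulation) in the other condition's
#' network: both endpoints retained -> type I, one -> type II, neither ->
#' type III.
#'
#' @param net_N,net_T record data.frames selected under the same rule.
#' @return data.frame with `pair_key`, `regulator`, `target`, `direction`
#'   (`gained`/`lost`), `type` (`I`/`II`/`III`).
#' @export
classify_rewiring <- function(net_N, net_T) {
  nodes_N <- unique(c(net_N$regulator, net_N$target))
  nodes_T <- unique(c(net_T$regulator, net_T$target))
  uniq_N <- net_N[!duplicated(net_N$pair_key), , drop = FALSE]
  uniq_T <- net_T[!duplicated(net_T$pair_key), , drop = FALSE]
  lost <- uniq_N[!uniq_N$pair_key %in% uniq_T$pair_key, , drop = FALSE]
  gained <- uniq_T[!uniq_T$pair_key %in% uniq_N$pair_key, , drop = FALSE]
  typ <- function(df, other_nodes) {
    if (nrow(df) == 0) return(character(0))
    cnt <- (df$regulator %in% other_nodes) + (df$target %in% other_nodes)
    c("III", "II", "I")[cnt + 1L]
  }
  out <- rbind(
    data.frame(pair_key = lost$pair_key, regulator = lost$regulator,
               target = lost$target,
               direction = rep("lost", nrow(lost)),
               type = typ(lost, nodes_T), stringsAsFactors = FALSE),
    data.frame(pair_key = gained$pair_key, regulator = gained$regulator,
               target = gained$target,
               direction = rep("gained", nrow(gained)),
               type = typ(gained, nodes_N), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Differential co-expression D(z) between normal and tumor
#'
#' For every regulation scored in both conditions and significantly
#' correlated (`|z| >= z_thresh`) in at least one of them, computes
#' `D = |z_N - z_T|`. Requiring significance in only one condition keeps
#' exactly the regulations that are gained or lost between conditions.
#' Omitted regulations are returned in `attr(, "omitted")` with reasons
#' (`missing_condition`, `not_significant`).
#'
#' @param records_N,records_T scored records for the two conditions of one
#'   cohort (from [score_network()]).
#' @param z_thresh significance threshold on `|z|` (default 2.5).
#' @return data.frame with `pair_key`, `regulator`, `target`, `class`,
#'   `z_normal`, `z_tumor`, `D`.
#' @export
dz <- function(records_N, records_T, z_thresh = 2.5) {
  a <- records_N[, c("pair_key", "regulator", "target", "class", "z")]
  b <- records_T[, c("pair_key", "z")]
  names(a)[names(a) == "z"] <- "z_normal"
  names(b)[names(b) == "z"] <- "z_tumor"
  only <- c(setdiff(a$pair_key, b$pair_key), setdiff(b$pair_key, a$pair_key))
  m <- merge(a, b, by = "pair_key")
  finite <- is.finite(m$z_normal) & is.finite(m$z_tumor)
  eligible <- finite &
    (abs(m$z_normal) >= z_thresh | abs(m$z_tumor) >= z_thresh)
  omitted <- rbind(
    data.frame(pair_key = only,
               reason = rep("missing_condition", length(only)),
               stringsAsFactors = FALSE),
    data.frame(pair_key = m$pair_key[!eligible],
               reason = rep("not_significant", sum(!eligible)),
               stringsAsFactors = FALSE))
  out <- m[eligible, , drop = FALSE]
  out$D <- abs(out$z_normal - out$z_tumor)
  out <- out[radix_order(out$pair_key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Flag differentially co-expressed (DC) regulations
#'
#' Flags the `ceiling(top_fraction * N)` records with largest `D` as
#' differentially co-expressed; ties broken by (`D` descending, pair key
#' ascending).
#'
#' @param records data.frame from [dz()].
#' @param top_fraction fraction of records to flag (default 0.10).
#' @return `records` with a logical `dc_flag` column.
#' @export
dc_select <- function(records, top_fraction = 0.10) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  records$dc_flag <- logical(nrow(records))
  if (nrow(records) == 0) return(records)
  m <- as.integer(ceiling(top_fraction * nrow(records)))
  ord <- radix_order(-records$D, records$pair_key)
  records$dc_flag[ord[seq_len(m)]] <- TRUE
  records
}

#' Rank TF-miRNA feedback loops by average D(z) across cohorts
#'
#' Considers only BiTM-class pair keys with a D value in every supplied
#' cohort and ranks them by mean D, descending. Pairs covered in only some
#' cohorts are excluded from the ranking and reported in
#' `attr(, "partial")`.
#'
#' @param per_cohort named list (cohort -> data.frame from [dz()] or
#'   [dc_select()]).
#' @return data.frame with `pair_key`, `mean_D`, `n_cohorts`, `rank`.
#' @export
rank_bitm_across_cohorts <- function(per_cohort) {
  stopifnot(is.list(per_cohort), length(per_cohort) >= 1)
  bitm <- lapply(per_cohort, function(d) d[d$class == "BiTM",
                                           c("pair_key", "D"), drop = FALSE])
  keys <- unlist(lapply(bitm, `[[`, "pair_key"), use.names = FALSE)
  cover <- table(keys)
  complete <- names(cover)[cover == length(per_cohort)]
  partial <- names(cover)[cover < length(per_cohort)]
  if (length(complete) == 0) {
    warning("no BiTM pair has a D value in every cohort; empty ranking",
            call. = FALSE)
    out <- data.frame(pair_key = character(), mean_D = numeric(),
                      n_cohorts = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "partial") <- partial
    return(out)
  }
  dmat <- vapply(bitm, function(d) {
    stats::setNames(d$D, d$pair_key)[complete]
  }, numeric(length(complete)))
  dmat <- matrix(dmat, nrow = length(complete))
  mean_D <- rowMeans(dmat)
  ord <- radix_order(-mean_D, complete)
  out <- data.frame(pair_key = complete[ord], mean_D = mean_D[ord],
                    n_cohorts = length(per_cohort),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "partial") <- partial
  out
}
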
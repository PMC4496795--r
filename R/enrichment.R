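#' Fisher's exact test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @return exact p-value.
#' @export
fisher_exact <- function(table, alternative = c("greater", "less",
                                                "two_sided")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, byrow = TRUE)
  if (any(table < 0)) stop("negative count in contingency table",
                           call. = FALSE)
  alt <- if (alternative == "two_sided") "two.sided" else alternative
  stats::fisher.test(table, alternative = alt)$p.value
}

#' Cancer-association enrichment of DC regulations
#'
#' A regulation is cancer-associated if at least one endpoint is annotated
#' (miRNA endpoints against the cancer-miRNA list, TF/gene endpoints
#' against the cancer-gene list). Tests (i) over-representation of
#' cancer-associated regulations among the DC set versus the rest of the
#' background, and (ii) for BiTM pairs, each association category -
#' CN (only the TF annotated), NC (only the miRNA), CC (both) - for over-
#' and under-representation among DC BiTM pairs versus background BiTM
#' pairs. One-sided Fisher's exact tests, raw p-values.
#'
#' @param dc_pairs,background_pairs data.frames with `pair_key`,
#'   `regulator`, `target`, `class`; `dc_pairs` is a subset of
#'   `background_pairs` (matched by `pair_key`).
#' @param cancer_genes,cancer_mirnas character vectors of annotated ids.
#' @param kinds named character vector id -> kind (e.g.
#'   `setNames(g$nodes$kind, g$nodes$id)`).
#' @return list with `overall` (p, counts, proportions) and `categories`
#'   (per-category counts and one-sided p-values over/under).
#' @export
cancer_assoc_enrichment <- function(dc_pairs, background_pairs,
                                    cancer_genes, cancer_mirnas, kinds) {
  if (nrow(background_pairs) == 0) stop("empty background", call. = FALSE)
  annotated <- function(id) {
    ifelse(kinds[id] == "miRNA", id %in% cancer_mirnas, id %in% cancer_genes)
  }
  bg <- background_pairs[!duplicated(background_pairs$pair_key), ,
                         drop = FALSE]
  bg$assoc <- annotated(bg$regulator) | annotated(bg$target)
  bg$dc <- bg$pair_key %in% dc_pairs$pair_key

  a <- sum(bg$dc & bg$assoc); b <- sum(bg$dc & !bg$assoc)
  c_ <- sum(!bg$dc & bg$assoc); d <- sum(!bg$dc & !bg$assoc)
  overall <- list(
    p = fisher_exact(c(a, b, c_, d), "greater"),
    n_dc = sum(bg$dc), n_background = nrow(bg),
    proportion_dc = if (sum(bg$dc)) a / sum(bg$dc) else NA_real_,
    proportion_background = mean(bg$assoc))

  bit <- bg[bg$class == "BiTM", , drop = FALSE]
  categories <- NULL
  if (nrow(bit)) {
    tf_id <- ifelse(kinds[bit$regulator] == "TF", bit$regulator, bit$target)
    mir_id <- ifelse(kinds[bit$regulator] == "miRNA", bit$regulator,
                     bit$target)
    tf_c <- tf_id %in% cancer_genes
    mir_c <- mir_id %in% cancer_mirnas
    cat <- ifelse(tf_c & mir_c, "CC",
                  ifelse(tf_c, "CN", ifelse(mir_c, "NC", "NN")))
    categories <- do.call(rbind, lapply(c("CN", "NC", "CC"), function(cc) {
      k <- sum(bit$dc & cat == cc); b2 <- sum(bit$dc & cat != cc)
      c2 <- sum(!bit$dc & cat == cc); d2 <- sum(!bit$dc & cat != cc)
      data.frame(category = cc, dc_count = k, background_count = k + c2,
                 p_over = fisher_exact(c(k, b2, c2, d2), "greater"),
                 p_under = fisher_exact(c(k, b2, c2, d2), "less"),
                 stringsAsFactors = FALSE)
    }))
  }
  list(overall = overall, categories = categories)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, "", 1))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Gene-set (functional-module) enrichment
#'
#' One-sided hypergeometric over-representation test of a query gene set
#' against each collection set, all intersected with the universe first.
#' Raw p-values are the primary output; Benjamini-Hochberg q-values are
#' reported alongside.
#'
#' @param query character vector of gene ids (subset of `universe`).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all assayable gene ids.
#' @return data.frame sorted by p with `set_id`, `k` (overlap), `K` (set
#'   size in universe), `n` (query size), `N` (universe size), `p`, `q`,
#'   `direction` (`over`/`under` relative to expectation).
#' @export
geneset_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- intersect(unique(query), universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s); k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = nm, k = k, K = K, n = n, N = N, p = p,
               direction = if (k >= n * K / N) "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[radix_order(out$p, out$set_id), c("set_id", "k", "K", "n", "N",
                                         "p", "q", "direction")]
  rownames(out) <- NULL
  out
}

#' Fisher's combined probability test
#'
#' Combines independent p-values as `X = -2 * sum(log(p))` referred to a
#' chi-square distribution with `2k` degrees of freedom.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
fisher_combined <- function(pvalues) {
  if (length(pvalues) == 0) stop("no p-values to combine", call. = FALSE)
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  X <- -2 * sum(log(pvalues))
  stats::pchisq(X, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Rank-based differential-expression test
#'
#' Self-contained substitute for a count-model DE test: the log2
#' fold-change is the difference of group means of `log2(x + 1)` and the
#' p-value a two-sided Wilcoxon rank-sum test (exact for small untied
#' samples), so it is invariant under monotone transforms of the values.
#'
#' @param values_normal,values_tumor numeric vectors (group size >= 3).
#' @return list with `log2fc` (tumor minus normal) and `p`; both `NA` with
#'   `ok = FALSE` if a group is too small, so callers can skip the feature.
#' @export
de_test <- function(values_normal, values_tumor) {
  if (length(values_normal) < 3 || length(values_tumor) < 3) {
    return(list(log2fc = NA_real_, p = NA_real_, ok = FALSE))
  }
  log2fc <- mean(log2(values_tumor + 1)) - mean(log2(values_normal + 1))
  p <- suppressWarnings(
    stats::wilcox.test(values_tumor, values_normal)$p.value)
  list(log2fc = log2fc, p = p, ok = TRUE)
}

#' Differential expression table for one cohort
#'
#' Applies [de_test()] to every feature of an expression matrix, splitting
#' samples by condition from the sample sheet.
#'
#' @param expr expression matrix (features x samples).
#' @param sheet sample sheet.
#' @param cohort cohort name.
#' @return data.frame `feature`, `log2fc`, `p` (features with a group
#'   smaller than 3 are dropped).
#' @export
de_table <- function(expr, sheet, cohort) {
  sheet <- validate_sample_sheet(sheet)
  s_n <- intersect(sheet$sample_id[sheet$cohort == cohort &
                                     sheet$condition == "normal"],
                   colnames(expr))
  s_t <- intersect(sheet$sample_id[sheet$cohort == cohort &
                                     sheet$condition == "tumor"],
                   colnames(expr))
  rows <- lapply(rownames(expr), function(f) {
    r <- de_test(expr[f, s_n], expr[f, s_t])
    if (!r$ok) return(NULL)
    data.frame(feature = f, log2fc = r$log2fc, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(feature = character(),
                                      log2fc = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Activated target-gene module of a regulator
#'
#' Selects the partners of a regulator that it plausibly activates in
#' tumor: tumor-condition correlation `z > z_thresh` (positive, one-sided)
#' and tumor up-regulation (`p < de_alpha` and `log2fc > 0`). Bidirectional
#' pairs are included via their canonical record regardless of stored
#' orientation. The resulting set feeds [geneset_enrichment()] per cohort
#' and [fisher_combined()] across cohorts.
#'
#' @param regulator_id the regulator (e.g. a TF id).
#' @param tumor_records tumor-condition records from [score_network()].
#' @param de data.frame from [de_table()] (tumor vs normal).
#' @param z_thresh positive-correlation threshold on `z` (default 2.5).
#' @param de_alpha DE significance level (default 0.05).
#' @return character vector of activated partner ids (empty, with a
#'   warning, if the regulator is absent from the records).
#' @export
regulator_module <- function(regulator_id, tumor_records, de,
                             z_thresh = 2.5, de_alpha = 0.05) {
  hit <- tumor_records$regulator == regulator_id |
    (is_bidirectional(tumor_records$class) &
       tumor_records$target == regulator_id)
  if (!any(hit)) {
    warning("regulator '", regulator_id, "' absent from scored records",
            call. = FALSE)
    return(character(0))
  }
  rec <- tumor_records[hit, , drop = FALSE]
  partner <- ifelse(rec$regulator == regulator_id, rec$target, rec$regulator)
  partner <- partner[is.finite(rec$z) & rec$z > z_thresh]
  up <- de$feature[!is.na(de$p) & de$p < de_alpha & de$log2fc > 0]
  radix_sort(unique(intersect(partner, up)))
}
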
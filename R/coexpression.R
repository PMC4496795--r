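#' Spearman rank correlation
#'
#' Thin wrapper around `stats::cor(method = "spearman")` (average ranks for
#' ties) that signals undefined correlations with `NA` instead of a warning,
#' so scoring code can skip and log the edge.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Spearman's rho in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Standardized Fisher-transformed correlation
#'
#' Computes `z = arctanh(rho) * sqrt(n - 3)`, the Fisher transformation of a
#' correlation standardized by the matched-sample count, which removes the
#' sample-number bias when comparing correlations across cohorts of
#' different size. `|rho|` is clamped to `1 - 1e-7` before `arctanh` so
#' perfect correlations stay finite (ranking is preserved).
#'
#' @param rho correlation(s) in `[-1, 1]`.
#' @param n matched-sample count(s); `z` is `NA` for `n < 4`.
#' @return numeric vector of z scores; antisymmetric in `rho`.
#' @export
fisher_z <- function(rho, n) {
  stopifnot(all(abs(rho) <= 1, na.rm = TRUE))
  clamp <- 1 - 1e-7
  r <- pmax(pmin(rho, clamp), -clamp)
  z <- atanh(r) * sqrt(n - 3)
  z[n < 4] <- NA_real_
  z
}

#' Score every regulation of a network by expression correlation
#'
#' For each scorable regulation, computes Spearman's rho between regulator
#' and target expression over the matched samples of one cohort and
#' condition, and its standardized Fisher z. Bidirectional (BiTT/BiTM)
#' pairs are scored once per pair under the canonical pair key (Spearman is
#' symmetric); unidirectional edges are scored per directed edge.
#' Unscorable edges (feature missing, fewer than `min_n` matched samples,
#' constant expression) are skipped and collected with reasons in
#' `attr(result, "skipped")`.
#'
#' @param x a classified `grn`.
#' @param mrna,mirna expression matrices.
#' @param sheet sample sheet.
#' @param cohort,condition cohort name and `"normal"`/`"tumor"`.
#' @param min_n minimum matched-sample count for a finite z (default 4, the
#'   smallest n for which `sqrt(n - 3)` is positive).
#' @return data.frame with columns `pair_key`, `regulator`, `target`,
#'   `class`, `cohort`, `condition`, `n`, `rho`, `z`, `clamped`.
#' @export
score_network <- function(x, mrna, mirna, sheet, cohort, condition,
                          min_n = 4) {
  stopifnot(inherits(x, "grn"))
  if (any(is.na(x$edges$class))) {
    stop("edges are unclassified; run classify_edges() first", call. = FALSE)
  }
  sheet <- validate_sample_sheet(sheet)
  if (!any(sheet$cohort == cohort & sheet$condition == condition)) {
    stop("no samples for cohort '", cohort, "', condition '", condition, "'",
         call. = FALSE)
  }
  e <- x$edges
  kind <- stats::setNames(x$nodes$kind, x$nodes$id)
  pk <- edge_pair_key(e$regulator_id, e$target_id, e$class)
  # one scoring unit per pair key; for bidirectional pairs keep the
  # canonical orientation (lexicographically smaller regulator)
  ord <- radix_order(pk, e$regulator_id)
  e <- e[ord, , drop = FALSE]
  pk <- pk[ord]
  units <- e[!duplicated(pk), , drop = FALSE]
  ukeys <- pk[!duplicated(pk)]

  n_u <- nrow(units)
  res_n <- integer(n_u); res_rho <- rep(NA_real_, n_u)
  skipped_reason <- character(n_u)
  for (i in seq_len(n_u)) {
    mv <- matched_vectors(units$regulator_id[i], kind[[units$regulator_id[i]]],
                          units$target_id[i], kind[[units$target_id[i]]],
                          mrna, mirna, sheet, cohort, condition)
    if (!mv$ok) { skipped_reason[i] <- mv$reason; next }
    if (mv$n < min_n) { skipped_reason[i] <- "n_lt_4"; res_n[i] <- mv$n; next }
    rho <- spearman_rho(mv$x, mv$y)
    if (is.na(rho)) { skipped_reason[i] <- "constant_vector"; next }
    res_n[i] <- mv$n
    res_rho[i] <- rho
  }
  keep <- skipped_reason == ""
  out <- data.frame(pair_key = ukeys[keep],
                    regulator = units$regulator_id[keep],
                    target = units$target_id[keep],
                    class = units$class[keep],
                    cohort = rep(cohort, sum(keep)),
                    condition = rep(condition, sum(keep)),
                    n = res_n[keep], rho = res_rho[keep],
                    stringsAsFactors = FALSE)
  out$z <- fisher_z(out$rho, out$n)
  out$clamped <- abs(out$rho) >= 1 - 1e-7
  rownames(out) <- NULL
  skipped <- data.frame(pair_key = ukeys[!keep],
                        reason = skipped_reason[!keep],
                        stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Significantly correlated regulations
#'
#' Keeps scored regulations with `|z| >= z_thresh` (inclusive). The default
#' threshold 2.5 corresponds to one-sided normal-tail P < 0.01; the z value
#' itself is the working statistic and is never converted to a p-value.
#'
#' @param records data.frame from [score_network()].
#' @param z_thresh threshold on `|z|` (default 2.5).
#' @return subset of `records`.
#' @export
significant_edges <- function(records, z_thresh = 2.5) {
  records[is.finite(records$z) & abs(records$z) >= z_thresh, , drop = FALSE]
}

#' Top-k% correlated network
#'
#' Retains the `ceiling(k * N)` scored regulations with largest `|z|`.
#' Ranking is by `|z|` (not `|rho|`) because standardization is the
#' correction for sample-number bias; ties at the cut are broken by
#' (`|z|` descending, pair key ascending) for determinism.
#'
#' @param records data.frame from [score_network()].
#' @param k fraction in (0, 1].
#' @return the retained subset, with the selection rule recorded in
#'   `attr(, "rule")`.
#' @export
top_percent <- function(records, k) {
  stopifnot(k > 0, k <= 1)
  if (nrow(records) == 0) {
    attr(records, "rule") <- list(type = "top_fraction", k = k)
    return(records)
  }
  m <- as.integer(ceiling(k * nrow(records)))
  ord <- radix_order(-abs(records$z), records$pair_key)
  out <- records[ord[seq_len(m)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rule") <- list(type = "top_fraction", k = k)
  out
}

#' Regulation-activity sign summary with enrichment
#'
#' Per regulation class, counts positively (`z >= 0`; exact zeros are
#' counted as positive) and negatively correlated regulations in a selected
#' (top-k) set and tests, one-sided Fisher's exact test per sign, whether
#' that sign is over-represented relative to the background set (normally
#' the 100% correlated network from the same scoring run). No multiplicity
#' correction is applied; each class/sign is reported with its raw p.
#'
#' @param top selected records (e.g. from [top_percent()]).
#' @param background background records from the same scoring run
#'   (a superset of `top`).
#' @return data.frame with `class`, `n_pos`, `n_neg`, `p_pos`, `p_neg`.
#' @export
sign_activity <- function(top, background) {
  classes <- intersect(REGULATION_CLASSES, unique(background$class))
  rows <- lapply(classes, function(cl) {
    tp <- top[top$class == cl, , drop = FALSE]
    bg <- background[background$class == cl, , drop = FALSE]
    a_pos <- sum(tp$z >= 0); a_neg <- sum(tp$z < 0)
    K_pos <- sum(bg$z >= 0); K_neg <- sum(bg$z < 0)
    if (nrow(tp) == 0) {
      return(data.frame(class = cl, n_pos = 0L, n_neg = 0L,
                        p_pos = 1, p_neg = 1, stringsAsFactors = FALSE))
    }
    p_pos <- stats::fisher.test(
      matrix(c(a_pos, a_neg, K_pos - a_pos, K_neg - a_neg), nrow = 2,
             byrow = TRUE), alternative = "greater")$p.value
    p_neg <- stats::fisher.test(
      matrix(c(a_neg, a_pos, K_neg - a_neg, K_pos - a_pos), nrow = 2,
             byrow = TRUE), alternative = "greater")$p.value
    data.frame(class = cl, n_pos = a_pos, n_neg = a_neg,
               p_pos = p_pos, p_neg = p_neg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
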
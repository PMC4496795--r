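# shared internal helpers

REGULATION_CLASSES <- c("TFout", "miRout", "BiTT", "BiTM")
NODE_KINDS <- c("TF", "miRNA", "gene")
BIDIRECTIONAL <- c("BiTT", "BiTM")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical pair key for an unordered node pair
#'
#' Bidirectional regulations (BiTT, BiTM) are handled at the pair level;
#' the canonical key puts the lexicographically smaller id first so the two
#' directed edges of a reciprocal pair share one key.
#'
#' @param a,b character vectors of node ids.
#' @return character vector of keys, `"<min>|<max>"`.
#' @export
canonical_pair_key <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  swap <- vapply(seq_len(n), function(i) {
    sort(c(a[i], b[i]), method = "radix")[1] != a[i]
  }, logical(1))
  ifelse(swap, paste(b, a, sep = "|"), paste(a, b, sep = "|"))
}

# locale-independent (C collation) ordering helpers, so pair-key ties and
# canonical orientations never depend on the session locale
radix_order <- function(...) order(..., method = "radix")
radix_sort <- function(x) sort(x, method = "radix")

# key for a directed edge
directed_key <- function(regulator, target) paste(regulator, target, sep = ">")

# pair-level key used throughout for scoring units: unordered for
# bidirectional classes, ordered for unidirectional ones
edge_pair_key <- function(regulator, target, class) {
  ifelse(class %in% BIDIRECTIONAL,
         canonical_pair_key(regulator, target),
         directed_key(regulator, target))
}

is_bidirectional <- function(class) class %in% BIDIRECTIONAL

# deterministic substream seeds derived from one user seed (kept < 2^31)
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483629 + 1
}

# read a TSV with required columns, reporting the offending line on failure
read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in required) {
    bad <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(bad)) {
      stop(what, " file ", path, ": malformed row at line ", bad[1] + 1L,
           " (empty ", col, ")", call. = FALSE)
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
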
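#' Load an expression matrix
#'
#' Reads a features-by-samples TSV (first column = feature id, header row =
#' sample ids) into a numeric matrix. Values are abundances on their
#' original scale; the package applies no internal normalization (the
#' differential-expression substitute log-transforms internally).
#'
#' @param path TSV file path.
#' @param modality `"mRNA"` or `"miRNA"`; stored as attribute `modality`.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
load_expression <- function(path, modality = c("mRNA", "miRNA")) {
  modality <- match.arg(modality)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("expression file ", path, " is empty", call. = FALSE)
  }
  feat <- as.character(df[[1]])
  if (anyDuplicated(feat)) {
    stop("duplicated feature id '", feat[duplicated(feat)][1], "' in ", path,
         call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) || anyNA(v)) {
      i <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop("non-numeric value in ", path, " at row ", i, ", column '",
           names(vals)[j], "'", call. = FALSE)
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- feat
  attr(m, "modality") <- modality
  m
}

#' Read and validate a sample sheet
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `condition`
#'   (`normal` or `tumor`) and `cohort`.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "patient_id", "condition",
                                 "cohort"), "sample sheet")
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data.frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  stopifnot(is.data.frame(sheet))
  need <- c("sample_id", "patient_id", "condition", "cohort")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample_id '",
         sheet$sample_id[duplicated(sheet$sample_id)][1], "'", call. = FALSE)
  }
  bad <- !sheet$condition %in% c("normal", "tumor")
  if (any(bad)) stop("condition must be 'normal' or 'tumor' (got '",
                     sheet$condition[bad][1], "')", call. = FALSE)
  if (any(sheet$cohort == "" | is.na(sheet$cohort))) {
    stop("empty cohort in sample sheet", call. = FALSE)
  }
  sheet
}

# matrix holding a feature of this kind: miRNAs live in the miRNA matrix,
# TFs and genes in the mRNA matrix
matrix_for_kind <- function(kind, mrna, mirna) {
  if (kind == "miRNA") mirna else mrna
}

#' Matched regulator/target expression vectors
#'
#' Restricts to samples of the requested cohort and condition that are
#' present in both relevant matrices (miRNA features are looked up in the
#' miRNA matrix, TFs and genes in the mRNA matrix), matched by sample id.
#' `n` is the number of matched samples between regulator and target.
#'
#' @param regulator,target feature ids.
#' @param regulator_kind,target_kind node kinds (`TF`, `miRNA`, `gene`).
#' @param mrna,mirna expression matrices from [load_expression()].
#' @param sheet sample sheet data.frame.
#' @param cohort,condition cohort name and `"normal"`/`"tumor"`.
#' @return If both features are present: a list with `ok = TRUE`, `n`,
#'   `x` (regulator values), `y` (target values) and `samples`. Otherwise
#'   `ok = FALSE` with a `reason` (`"feature_missing"`), so callers can skip
#'   the edge and log it rather than fail.
#' @export
matched_vectors <- function(regulator, regulator_kind, target, target_kind,
                            mrna, mirna, sheet, cohort, condition) {
  m1 <- matrix_for_kind(regulator_kind, mrna, mirna)
  m2 <- matrix_for_kind(target_kind, mrna, mirna)
  if (!(regulator %in% rownames(m1))) {
    return(list(ok = FALSE, reason = "feature_missing", feature = regulator))
  }
  if (!(target %in% rownames(m2))) {
    return(list(ok = FALSE, reason = "feature_missing", feature = target))
  }
  keep <- sheet$cohort == cohort & sheet$condition == condition
  s <- sheet$sample_id[keep]
  s <- intersect(intersect(s, colnames(m1)), colnames(m2))
  list(ok = TRUE, n = length(s),
       x = unname(m1[regulator, s]), y = unname(m2[target, s]),
       samples = s)
}
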
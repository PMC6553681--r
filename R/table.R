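# Subjects x features tables with labels and cleaning provenance.

#' Construct a feature table
#'
#' @param matrix numeric subjects x features matrix.
#' @param row_ids subject ids (unique).
#' @param col_info data.frame with columns `name`, `sequence`, `tissue`,
#'   `feature` describing each column (names unique).
#' @param labels integer 0/1 per subject.
#' @param provenance per-column removal reason; "none" for retained columns.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(matrix, row_ids, col_info, labels,
                          provenance = NULL) {
  matrix <- as.matrix(matrix)
  if (anyDuplicated(row_ids)) rt_error("duplicated row ids", "radtex_assembly_error")
  if (anyDuplicated(col_info$name)) rt_error("duplicated column ids", "radtex_assembly_error")
  if (length(row_ids) != nrow(matrix) || nrow(col_info) != ncol(matrix))
    rt_error("dimension mismatch", "radtex_assembly_error")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    rt_error("labels must be 0/1", "radtex_assembly_error")
  if (length(labels) != nrow(matrix))
    rt_error("one label per subject required", "radtex_assembly_error")
  if (is.null(provenance))
    provenance <- stats::setNames(rep("none", ncol(matrix)), col_info$name)
  dimnames(matrix) <- list(row_ids, col_info$name)
  structure(list(matrix = matrix, row_ids = row_ids, col_info = col_info,
                 labels = labels, provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$matrix), "subjects x", ncol(x$matrix),
      "features;", sum(x$labels == 1L), "positive labels\n")
  invisible(x)
}

#' Assemble per-subject feature vectors into a feature table
#'
#' One row per subject, one column per (sequence, tissue, feature). A
#' (subject, sequence, tissue) combination missing from `vectors` leaves its
#' 114 cells `NA` (they fall to the invalid-column path in [clean_table()]).
#'
#' @param vectors list of entries, each a list with `subject`, `sequence`,
#'   `tissue` and `fv` (a `feature_vector` from [extract_volume_features()]).
#' @param labels named integer vector (names = subject ids) or a vector in
#'   subject order.
#' @return a [feature_table()].
#' @export
assemble_table <- function(vectors, labels) {
  if (length(vectors) == 0L) rt_error("no feature vectors", "radtex_assembly_error")
  subs <- vapply(vectors, function(v) v$subject, character(1))
  seqs <- vapply(vectors, function(v) v$sequence, character(1))
  tiss <- vapply(vectors, function(v) v$tissue, character(1))
  key <- paste(subs, seqs, tiss, sep = "|")
  if (anyDuplicated(key))
    rt_error("duplicate (subject, sequence, tissue)", "radtex_assembly_error")
  row_ids <- unique(subs)
  combos <- unique(data.frame(sequence = seqs, tissue = tiss,
                              stringsAsFactors = FALSE))
  fn <- feature_names()
  col_info <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    data.frame(name = paste(combos$sequence[i], combos$tissue[i], fn, sep = "."),
               sequence = combos$sequence[i], tissue = combos$tissue[i],
               feature = fn, stringsAsFactors = FALSE)
  }))
  M <- matrix(NA_real_, length(row_ids), nrow(col_info),
              dimnames = list(row_ids, col_info$name))
  for (v in vectors) {
    cols <- paste(v$sequence, v$tissue, fn, sep = ".")
    M[v$subject, cols] <- unname(v$fv$values)
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(row_ids))
      rt_error("every subject needs a label", "radtex_assembly_error")
    labels <- stats::setNames(as.integer(labels), row_ids)
  }
  if (!all(row_ids %in% names(labels)))
    rt_error("every subject needs a label", "radtex_assembly_error")
  feature_table(M, row_ids, col_info, labels[row_ids])
}

#' Remove invalid and near-zero-variance columns
#'
#' Drops every column containing a non-finite cell (reason "invalid"), then
#' every zero-variance or near-zero-variance column (reason
#' "near_zero_variance"): most-common / second-most-common value frequency
#' ratio above `nzv_freq_ratio` AND distinct-value percentage below
#' `nzv_unique_pct`. Defaults are the common caret-style 95/5 and 10.
#' Idempotent.
#'
#' @param t a [feature_table()].
#' @param nzv_freq_ratio frequency-ratio cutoff (default 95/5 = 19).
#' @param nzv_unique_pct distinct-value percentage cutoff (default 10).
#' @return the cleaned [feature_table()]; `provenance` records every removal.
#' @export
clean_table <- function(t, nzv_freq_ratio = 95 / 5, nzv_unique_pct = 10) {
  M <- t$matrix
  reason <- t$provenance
  invalid <- colSums(!is.finite(M)) > 0L
  reason[invalid] <- "invalid"
  nzv <- vapply(seq_len(ncol(M)), function(j) {
    if (invalid[j]) return(FALSE)
    v <- M[, j]
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1L) return(TRUE)              # zero variance
    ratio <- tab[1] / tab[2]
    upct <- 100 * length(tab) / length(v)
    ratio > nzv_freq_ratio && upct < nzv_unique_pct
  }, logical(1))
  reason[nzv] <- "near_zero_variance"
  keep <- !(invalid | nzv)
  if (!any(keep)) rt_error("all columns removed by cleaning", "radtex_empty_table")
  out <- feature_table(M[, keep, drop = FALSE], t$row_ids,
                       t$col_info[keep, , drop = FALSE], t$labels,
                       reason[keep])
  attr(out, "removed") <- reason[!keep]
  out
}

#' Standardize to zero mean and unit variance using training statistics
#'
#' Column means and sample SDs (n - 1) are estimated on `train` only and
#' applied to both tables; `apply_to` rows never influence the parameters.
#'
#' @param train cleaned [feature_table()] whose rows define the statistics.
#' @param apply_to optional second [feature_table()] with the same columns.
#' @return list with `train`, `apply_to` (transformed tables) and `center`,
#'   `scale` (the per-column statistics).
#' @export
standardize <- function(train, apply_to = NULL) {
  mu <- colMeans(train$matrix)
  sdv <- apply(train$matrix, 2L, stats::sd)
  if (any(sdv <= 0 | !is.finite(sdv)))
    rt_error("zero-SD column reached standardization", "radtex_contract_violation")
  tr <- train
  tr$matrix <- sweep(sweep(train$matrix, 2L, mu), 2L, sdv, "/")
  ap <- NULL
  if (!is.null(apply_to)) {
    if (!identical(colnames(apply_to$matrix), colnames(train$matrix)))
      rt_error("column mismatch between tables", "radtex_contract_violation")
    ap <- apply_to
    ap$matrix <- sweep(sweep(apply_to$matrix, 2L, mu), 2L, sdv, "/")
  }
  list(train = tr, apply_to = ap, center = mu, scale = sdv)
}

# row subset helper used by cross-validation
subset_rows <- function(t, idx) {
  feature_table(t$matrix[idx, , drop = FALSE], t$row_ids[idx], t$col_info,
                t$labels[idx], t$provenance)
}
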
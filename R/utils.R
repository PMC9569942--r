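#' @keywords internal
"_PACKAGE"

# Derive a reproducible per-stage seed from one global seed. Kept below
# 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Validate an integer count matrix
#'
#' Checks the container contract shared by all count inputs: a nonnegative
#' integer-valued matrix with unique feature (row) and sample (column)
#' identifiers.
#'
#' @param counts numeric matrix, features in rows, samples in columns, with
#'   `rownames` and `colnames` set.
#' @return the validated matrix (invisibly unchanged).
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("feature and sample identifiers must be unique")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integer-valued")
  }
  counts
}

# Internal: check a sample metadata table against a count matrix.
validate_meta <- function(meta, sample_ids = NULL,
                          groups = c("BCR", "BRF")) {
  if (!is.data.frame(meta) || !all(c("sample_id", "group") %in% names(meta))) {
    stop("meta must be a data.frame with columns 'sample_id' and 'group'")
  }
  if (!all(meta$group %in% groups)) {
    stop("meta$group must only contain: ", paste(groups, collapse = ", "))
  }
  if (!is.null(sample_ids)) {
    if (!setequal(meta$sample_id, sample_ids)) {
      stop("meta sample_ids do not match the count matrix columns")
    }
    meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  }
  meta
}

# Internal: TSV writers/readers used for all file-based stage handoff.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' Expects features as rows (first column = feature id) and a header of
#' sample identifiers, the layout written by [write_count_matrix()].
#'
#' @param path TSV file path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_counts(m)
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
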
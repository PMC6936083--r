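#' Construct a validated expression matrix
#'
#' An expression matrix holds one observation per column: `m` features
#' (genes) in rows and `n` samples in columns, the orientation in which
#' subspace-clustering methods consume the data (each sample is a point in
#' feature space). The constructor validates finiteness, dimensions and
#' identifier uniqueness and returns a plain numeric matrix with feature IDs
#' as row names and sample IDs as column names.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#' @param feature_ids Character vector of unique feature identifiers
#'   (default: existing row names, or `feature_1..m`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: existing column names, or `sample_1..n`).
#' @return A numeric matrix with validated dimnames.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4))
#' dim(x)
#' @export
expression_matrix <- function(values, feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (m < 1L || n < 2L) {
    stop("an expression matrix needs at least 1 feature and 2 samples, got ",
         m, " x ", n, call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at feature row %d, sample column %d",
                 bad[[1L]], bad[[2L]]), call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- rownames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(m))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != m) stop("feature_ids length != nrow", call. = FALSE)
  if (length(sample_ids) != n) stop("sample_ids length != ncol", call. = FALSE)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' The delimiter (tab or comma) is auto-detected from the header line.
#' Every data cell must parse as a finite number; the first offending cell
#' is reported with its feature and sample coordinates.
#'
#' @param path Path to a TSV or CSV file.
#' @param transpose If `TRUE` the file holds samples in rows and features in
#'   columns and is transposed after reading.
#' @return A validated expression matrix (features x samples).
#' @seealso [write_expression_matrix()], [expression_matrix()]
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expected at least one ID column and one data column in ",
                           path, call. = FALSE)
  ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L] # before subsetting: `[.data.frame` dedupes names
  body <- as.matrix(raw[, -1L, drop = FALSE])
  colnames(body) <- sample_ids
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num) || !all(is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at row ID '%s', column '%s' in %s",
                 body[bad[[1L]], bad[[2L]]], ids[bad[[1L]]],
                 colnames(body)[bad[[2L]]], path), call. = FALSE)
  }
  x <- expression_matrix(num, feature_ids = ids, sample_ids = colnames(body))
  if (transpose) x <- expression_matrix(t(x)) else x
}

#' Write an expression matrix as TSV
#'
#' Full-precision writer producing the same layout [read_expression_matrix()]
#' reads: header row of sample IDs, first column of feature IDs.
#'
#' @param x Expression matrix (features x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- expression_matrix(x)
  df <- data.frame(feature_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample labels from a two-column CSV/TSV
#'
#' @param path File with columns `sample_id,label` (header optional when the
#'   first field is literally `sample_id`).
#' @return Named vector of labels, names are sample IDs.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  has_header <- grepl("^sample_id", header)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs two columns (sample_id, label)",
                          call. = FALSE)
  stats::setNames(df[[2L]], as.character(df[[1L]]))
}

#' Write cluster labels as a two-column CSV
#'
#' @param labels Vector of labels; names taken as sample IDs when present.
#' @param path Output path.
#' @param sample_ids Sample IDs used when `labels` is unnamed.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, sample_ids = names(labels)) {
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_along(labels))
  df <- data.frame(sample_id = sample_ids, cluster = as.vector(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# normalizations offered by the pipeline; expression matrices often need one
# even though the method itself makes no preprocessing assumption
normalize_expression <- function(x, method = c("none", "per_sample_l2", "log2p1")) {
  method <- match.arg(method)
  switch(method,
    none = x,
    per_sample_l2 = {
      nrm <- sqrt(colSums(x^2))
      nrm[nrm == 0] <- 1
      sweep(x, 2L, nrm, "/")
    },
    log2p1 = {
      if (any(x < 0)) stop("log2p1 normalization requires nonnegative values",
                           call. = FALSE)
      log2(x + 1)
    })
}
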
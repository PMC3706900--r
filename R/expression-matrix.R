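#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix (features in rows, samples
#' in columns) with unique feature and sample identifiers and a `feature_kind`
#' attribute (`"miRNA"` or `"mRNA"`). Values are continuous expression
#' measurements, either raw intensities or normalized scores; missing values
#' are only tolerated before normalization and must be flagged explicitly via
#' `allow_missing`.
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param feature_kind `"miRNA"` or `"mRNA"`.
#' @param allow_missing logical; permit `NA` cells (pre-normalization data).
#' @return the validated matrix, classed `"expr_matrix"`, with attributes
#'   `feature_kind` and `n_missing`.
#' @export
expression_matrix <- function(values, feature_kind = c("miRNA", "mRNA"),
                              allow_missing = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  n_missing <- sum(is.na(values))
  if (n_missing > 0 && !allow_missing)
    stop(n_missing, " missing value(s) present; use allow_missing = TRUE ",
         "for pre-normalization data")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite expression values")
  structure(values, class = c("expr_matrix", class(values)),
            feature_kind = feature_kind, n_missing = n_missing)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d features x %d samples (%d missing)\n",
              attr(x, "feature_kind"), nrow(x), ncol(x), attr(x, "n_missing")))
  invisible(x)
}

feature_kind <- function(x) attr(x, "feature_kind") %||% "miRNA"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an expression matrix from tab-separated text
#'
#' Expected layout: first column feature id, header row of sample ids,
#' tab-separated, `.` decimal, no quoting. Row and column order are preserved.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, feature_kind = c("miRNA", "mRNA"),
                                   allow_missing = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           na.strings = character(0))
  if (nrow(tab) == 0 || ncol(tab) < 2)
    stop("expression file needs a feature-id column and >= 1 sample column: ",
         path)
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  expression_matrix(num, feature_kind, allow_missing = allow_missing)
}

#' Write an expression matrix as tab-separated text
#'
#' Canonical dialect: UTF-8, tab-separated, `.` decimal, no quoting; numbers
#' printed with full precision (round-trips through
#' [read_expression_matrix()]).
#'
#' @param x expression matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  header <- paste(c("feature_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i],
            format(x[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Impute missing expression values by feature median
#'
#' Missing cells (allowed only in pre-normalization matrices) are replaced by
#' the median of the feature's observed values; the number imputed is
#' reported via a message.
#'
#' @param x expression matrix possibly containing `NA`.
#' @return matrix with no missing values.
#' @export
impute_missing <- function(x) {
  n_na <- sum(is.na(x))
  if (n_na == 0) return(x)
  for (i in which(rowSums(is.na(x)) > 0)) {
    med <- stats::median(x[i, ], na.rm = TRUE)
    if (is.na(med)) stop("feature '", rownames(x)[i], "' entirely missing")
    x[i, is.na(x[i, ])] <- med
  }
  message("imputed ", n_na, " missing value(s) by feature median")
  attr(x, "n_missing") <- 0L
  x
}
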
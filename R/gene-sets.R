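#' Construct a miRNA target-set collection
#'
#' Named gene-identifier sets, one per miRNA (a miRNA may appear under several
#' prediction sources; entries are keyed `"<miRNA>|<source>"` when a source is
#' given). Gene sets are unordered, duplicate-free, non-empty.
#'
#' @param sets named list of character vectors (gene ids).
#' @param source character vector of source labels (e.g. `"miRanda"`,
#'   `"TargetScan"`, `"PITA"`), recycled.
#' @return object of class `"target_sets"`: a named list with elements
#'   `genes` (character vector) and `source`.
#' @export
target_sets <- function(sets, source = "unknown") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every target set needs a miRNA name")
  source <- rep_len(as.character(source), length(sets))
  out <- lapply(seq_along(sets), function(i) {
    g <- as.character(sets[[i]])
    if (anyDuplicated(g)) {
      warning("duplicated gene ids in set '", names(sets)[i], "' removed")
      g <- unique(g)
    }
    if (!length(g)) stop("empty target set: ", names(sets)[i])
    list(mirna = names(sets)[i], genes = g, source = source[i])
  })
  names(out) <- names(sets)
  structure(out, class = "target_sets")
}

#' @export
print.target_sets <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1))
  cat(sprintf("<target_sets> %d sets, %d-%d genes each\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' Read miRNA target sets from a GMT file
#'
#' Standard GMT: one set per line, `set-name TAB description TAB gene ...`.
#' The set name is taken as the miRNA id and the description as the target
#' prediction source label.
#'
#' @param path GMT file path.
#' @return a [target_sets()] collection.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  target_sets(sets, source = vapply(fields, `[[`, character(1), 2L))
}

#' Write target sets as GMT
#' @param x target_sets collection.
#' @param path output path.
#' @export
write_gene_sets <- function(x, path) {
  lines <- vapply(x, function(s)
    paste(c(s$mirna, s$source, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Intersect target sets with the measured gene universe
#'
#' All set-level statistics operate on post-intersection sets; sets falling
#' below `min_size` after intersection are dropped with a message.
#'
#' @param x target_sets collection.
#' @param gene_ids measured gene identifiers.
#' @param min_size minimum post-intersection set size (default 5).
#' @return filtered target_sets collection with intersected gene sets.
#' @export
intersect_target_sets <- function(x, gene_ids, min_size = 5) {
  out <- lapply(x, function(s) {
    s$genes <- intersect(s$genes, gene_ids)
    s
  })
  keep <- vapply(out, function(s) length(s$genes) >= min_size, logical(1))
  if (any(!keep))
    message(sum(!keep), " set(s) below min_size ", min_size,
            " after intersection, skipped")
  structure(out[keep], class = "target_sets")
}
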
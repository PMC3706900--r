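#' Validate a clinical annotation table
#'
#' Canonical columns: `sample_id`, `specimen_type` (`biopsy`/`resection`),
#' `pair_id` (optional, links a biopsy to its post-chemotherapy resection),
#' `rfs_time`/`rfs_event`, `os_time`/`os_event` (months, strictly positive;
#' event flags 0/1), `necrosis_pct` (0-100, optional), `chemoresponse`
#' (`suboptimal`/`optimal`), `metastasis_dx` (0/1), `regimen` (free text,
#' e.g. `"MAP"`). Unknown columns are kept but flagged with a warning.
#'
#' @param tab data.frame with the columns above.
#' @return the table, classed `"clinical_table"`.
#' @export
clinical_table <- function(tab) {
  required <- c("sample_id", "specimen_type", "rfs_time", "rfs_event",
                "os_time", "os_event")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  known <- c(required, "pair_id", "necrosis_pct", "chemoresponse",
             "metastasis_dx", "regimen")
  extra <- setdiff(names(tab), known)
  if (length(extra))
    warning("ignoring unknown clinical column(s): ", paste(extra, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  if (!all(tab$specimen_type %in% c("biopsy", "resection")))
    stop("specimen_type must be 'biopsy' or 'resection'")
  for (tm in c("rfs_time", "os_time")) {
    v <- tab[[tm]]
    if (!is.numeric(v) || any(is.na(v)) || any(v <= 0))
      stop(tm, " must be strictly positive")
  }
  for (ev in c("rfs_event", "os_event")) {
    v <- tab[[ev]]
    if (!all(v %in% c(0, 1))) stop(ev, " flags must be 0 or 1")
  }
  if (any(tab$os_time < tab$rfs_time - 1e-9))
    stop("os_time must be >= rfs_time for every sample")
  if (!is.null(tab$necrosis_pct)) {
    v <- tab$necrosis_pct
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop("necrosis_pct must lie in [0, 100]")
  }
  if (!is.null(tab$chemoresponse)) {
    tab$chemoresponse <- as_chemoresponse(tab$chemoresponse)
  }
  if (!is.null(tab$metastasis_dx) &&
      !all(tab$metastasis_dx %in% c(0, 1, NA)))
    stop("metastasis_dx must be 0 or 1")
  if (!is.null(tab$pair_id)) {
    tab$pair_id <- as.character(tab$pair_id)
    tab$pair_id[tab$pair_id %in% c("", "NA")] <- NA_character_
    counts <- table(tab$pair_id)
    broken <- names(counts)[counts != 2]
    # a usable pair links exactly one biopsy to one resection
    for (p in setdiff(names(counts)[counts == 2], broken)) {
      rows <- tab[!is.na(tab$pair_id) & tab$pair_id == p, ]
      if (!setequal(rows$specimen_type, c("biopsy", "resection")))
        broken <- c(broken, p)
    }
    if (length(broken)) {
      warning("pair id(s) not linking one biopsy to one resection, dropped ",
              "from paired analyses: ", paste(broken, collapse = ", "))
      tab$pair_id[tab$pair_id %in% broken] <- NA_character_
    }
  }
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

as_chemoresponse <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% c("suboptimal", "optimal", NA)))
    stop("chemoresponse must be 'suboptimal' or 'optimal'")
  factor(x, levels = c("suboptimal", "optimal"), ordered = TRUE)
}

#' Read a clinical annotation table from tab-separated text
#'
#' @param path file path.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  clinical_table(tab)
}

#' Write a clinical table as tab-separated text
#' @param tab clinical table.
#' @param path output path.
#' @export
write_clinical_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$chemoresponse <- as.character(out$chemoresponse)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v)
    format(v, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Usable biopsy/resection pairs
#'
#' @param tab clinical table.
#' @return data.frame with `pair_id`, `biopsy`, `resection` sample ids.
#' @export
clinical_pairs <- function(tab) {
  if (is.null(tab$pair_id)) return(data.frame(pair_id = character(),
                                              biopsy = character(),
                                              resection = character()))
  ok <- !is.na(tab$pair_id)
  pieces <- split(tab[ok, c("sample_id", "specimen_type")], tab$pair_id[ok])
  rows <- lapply(names(pieces), function(p) {
    pc <- pieces[[p]]
    data.frame(pair_id = p,
               biopsy = pc$sample_id[pc$specimen_type == "biopsy"],
               resection = pc$sample_id[pc$specimen_type == "resection"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame()
}
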
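# Binary isolate x KO gene-content matrices: construction, I/O and the
# column filters applied ahead of clustering.

#' Construct a binary isolate-by-KO gene-content matrix
#'
#' The central object of the gene-content analysis: rows are isolates,
#' columns are KEGG Orthology (KO) identifiers, and entry 1 records that the
#' KO was annotated in the isolate's genome.
#'
#' @param x A matrix (or data frame) of 0/1 values with isolate ids as row
#'   names and KO ids as column names.
#' @return An integer matrix of class `ko_matrix`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
#'             dimnames = list(c("iso1", "iso2"), c("K00001", "K00002", "K00003")))
#' ko_matrix(m)
ko_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) abort("`x` must be a matrix or data frame")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("`x` needs isolate row names and KO column names")
  }
  if (anyDuplicated(rownames(x))) abort("duplicate isolate ids")
  if (anyDuplicated(colnames(x))) abort("duplicate KO ids")
  if (anyNA(x)) abort("missing entries are not allowed")
  if (!all(x %in% c(0, 1))) abort("entries must all be 0 or 1")
  storage.mode(x) <- "integer"
  class(x) <- c("ko_matrix", class(x))
  x
}

#' @export
print.ko_matrix <- function(x, ...) {
  cat(sprintf("<ko_matrix> %d isolates x %d KOs (%.1f%% present)\n",
              nrow(x), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' Read a binary KO presence/absence matrix from a TSV file
#'
#' Expects a tab-delimited file with a header row and a leading id column.
#' Orientation (isolates in rows or columns) is auto-detected from which
#' dimension's ids look like KO identifiers (`K` followed by digits), or can
#' be forced.
#'
#' @param path Path to the TSV file.
#' @param isolates `"auto"`, `"rows"`, or `"columns"`: where isolates live in
#'   the file.
#' @param truthy,falsy Character vectors of cell values mapped to presence
#'   and absence before validation; anything else is rejected.
#' @return A [ko_matrix()].
#' @export
read_ko_matrix <- function(path, isolates = c("auto", "rows", "columns"),
                           truthy = c("1", "TRUE"), falsy = c("0", "FALSE")) {
  isolates <- match.arg(isolates)
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(tb) < 2) abort("expected an id column plus at least one data column")
  ids <- tb[[1]]
  if (anyNA(ids) || anyDuplicated(ids)) abort("row ids must be present and unique")
  vals <- as.matrix(tb[, -1, drop = FALSE])
  rownames(vals) <- ids
  num <- matrix(NA_integer_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  num[vals %in% truthy] <- 1L
  num[vals %in% falsy] <- 0L
  if (anyNA(num)) {
    bad <- unique(vals[is.na(num)])
    abort(sprintf("non-binary cell values: %s", paste(head(bad, 5), collapse = ", ")))
  }
  if (isolates == "auto") {
    ko_like <- function(v) mean(grepl("^K\\d+$", v))
    isolates <- if (ko_like(colnames(num)) >= ko_like(rownames(num))) "rows" else "columns"
  }
  if (isolates == "columns") num <- t(num)
  ko_matrix(num)
}

#' Remove zero-variance KO columns
#'
#' Drops KOs that are present in every isolate or absent from every isolate;
#' such columns carry no information for clustering.
#'
#' @param m A [ko_matrix()].
#' @return A list with `matrix` (the filtered [ko_matrix()], column order
#'   preserved) and `removed` (character vector of dropped KO ids).
#' @export
filter_zero_variance <- function(m) {
  stopifnot(inherits(m, "ko_matrix"))
  cs <- colSums(m)
  constant <- cs == 0L | cs == nrow(m)
  list(
    matrix = ko_matrix(unclass(m)[, !constant, drop = FALSE]),
    removed = colnames(m)[constant]
  )
}

#' Collapse KOs with identical presence/absence profiles
#'
#' KO columns that are exact duplicates of one another contribute identical
#' information to the isolate distance matrix; each distinct profile is
#' reduced to a single representative (the first column in file order), and
#' the membership of every collapsed group is recorded so that enrichment
#' scores can later be propagated back to the collapsed KOs.
#'
#' @param m A [ko_matrix()], normally after [filter_zero_variance()].
#' @return A list with `matrix` (one column per distinct profile) and
#'   `duplicates` (a tibble with columns `representative_ko`, `member_ko`
#'   listing each collapsed KO under its retained representative).
#' @export
collapse_duplicate_kos <- function(m) {
  stopifnot(inherits(m, "ko_matrix"))
  key <- apply(m, 2, paste0, collapse = "")
  first_idx <- !duplicated(key)
  rep_for <- colnames(m)[first_idx][match(key, key[first_idx])]
  dup <- tibble::tibble(
    representative_ko = rep_for[!first_idx],
    member_ko = colnames(m)[!first_idx]
  )
  list(
    matrix = ko_matrix(unclass(m)[, first_idx, drop = FALSE]),
    duplicates = dup
  )
}

#' Expand a collapsed matrix back to its original column multiset
#'
#' Inverse of [collapse_duplicate_kos()]; used mainly to verify that the
#' collapse is lossless.
#'
#' @param m A collapsed [ko_matrix()].
#' @param duplicates The `duplicates` tibble from [collapse_duplicate_kos()].
#' @return A [ko_matrix()] containing representative and member columns.
#' @export
expand_duplicate_kos <- function(m, duplicates) {
  stopifnot(inherits(m, "ko_matrix"))
  if (nrow(duplicates) == 0) return(m)
  extra <- unclass(m)[, duplicates$representative_ko, drop = FALSE]
  colnames(extra) <- duplicates$member_ko
  ko_matrix(cbind(unclass(m), extra))
}
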
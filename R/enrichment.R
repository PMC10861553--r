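# Per-cluster KO enrichment: 2x2 contingency odds ratios with the
# Haldane-Anscombe zero-cell correction, ranked by log10(OR).

#' Contingency counts for one cluster/KO pair
#'
#' For cluster i and KO j: `a` isolates in i carrying j, `b` in i without j,
#' `c` outside i carrying j, `d` outside i without j. Isolates with cluster
#' label 0 (unassigned) are excluded from both margins.
#'
#' @param assignment Tibble with columns `isolate`, `cluster`.
#' @param m A [ko_matrix()] sharing isolate ids with `assignment`.
#' @param cluster_id Cluster label (> 0).
#' @param ko_id KO column id.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
contingency_counts <- function(assignment, m, cluster_id, ko_id) {
  stopifnot(inherits(m, "ko_matrix"))
  if (!ko_id %in% colnames(m)) abort(sprintf("unknown KO id '%s'", ko_id))
  keep <- assignment[assignment$cluster > 0, ]
  if (!cluster_id %in% keep$cluster) abort(sprintf("unknown cluster %s", cluster_id))
  if (!all(keep$isolate %in% rownames(m))) abort("assignment isolates missing from matrix")
  present <- unclass(m)[keep$isolate, ko_id] == 1L
  inside <- keep$cluster == cluster_id
  c(a = sum(inside & present), b = sum(inside & !present),
    c = sum(!inside & present), d = sum(!inside & !present))
}

#' Odds ratio for a 2x2 contingency table
#'
#' Computes `or = a*d / (b*c)` and its log10. With the default correction,
#' 0.5 is added to cells that are zero (and only to those), keeping the
#' ratio finite; `"all_cells"` applies the classical correction of adding
#' 0.5 everywhere, and `"none"` applies no correction.
#'
#' @param a,b,c,d Non-negative counts, not all zero.
#' @param correction `"zero_cells"` (default), `"all_cells"`, or `"none"`.
#' @return A one-row tibble with the (possibly corrected) cells, `odds_ratio`
#'   and `log10_or`.
#' @export
#' @examples
#' odds_ratio(3, 0, 0, 3) # or = 36, log10 ~ 1.556
odds_ratio <- function(a, b, c, d, correction = c("zero_cells", "all_cells", "none")) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) abort("counts must be non-negative")
  if (all(cells == 0)) abort("all four cells are zero")
  cells <- switch(correction,
    zero_cells = ifelse(cells == 0, 0.5, cells),
    all_cells = cells + 0.5,
    none = cells
  )
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  tibble::tibble(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 odds_ratio = or, log10_or = log10(or))
}

#' Rank KOs by cluster enrichment
#'
#' Scores every (cluster, KO) pair with the log10 odds ratio of the 2x2
#' membership-by-presence table and ranks KOs within each cluster by
#' descending score (ties broken by KO id). KOs collapsed as duplicate
#' profiles inherit the score of their representative.
#'
#' @inheritParams contingency_counts
#' @param duplicates Optional duplicates tibble from
#'   [collapse_duplicate_kos()]; collapsed members are appended with their
#'   representative's score.
#' @param correction Passed to [odds_ratio()].
#' @return A tibble with columns `cluster`, `ko`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `log10_or`, `duplicate_of` (NA for scored columns) and
#'   `rank` (within cluster).
#' @export
rank_cluster_kos <- function(assignment, m, duplicates = NULL,
                             correction = c("zero_cells", "all_cells", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(m, "ko_matrix"))
  keep <- assignment[assignment$cluster > 0, , drop = FALSE]
  if (nrow(keep) == 0) abort("no assigned isolates")
  if (!all(keep$isolate %in% rownames(m))) abort("assignment isolates missing from matrix")
  mm <- unclass(m)[keep$isolate, , drop = FALSE]
  clusters <- sort(unique(keep$cluster))
  n_total <- nrow(mm)
  ko_totals <- colSums(mm)

  per_cluster <- purrr::map(clusters, function(ci) {
    inside <- keep$cluster == ci
    n_in <- sum(inside)
    if (n_in == 0) {
      warn(sprintf("cluster %d empty after excluding unassigned isolates", ci))
      return(NULL)
    }
    a <- colSums(mm[inside, , drop = FALSE])
    b <- n_in - a
    cc <- ko_totals - a
    dd <- (n_total - n_in) - cc
    corr <- function(v) switch(correction,
      zero_cells = ifelse(v == 0, 0.5, v),
      all_cells = v + 0.5,
      none = v
    )
    ca <- corr(a); cb <- corr(b); ccc <- corr(cc); cd <- corr(dd)
    or <- ca * cd / (cb * ccc)
    tibble::tibble(
      cluster = ci, ko = colnames(mm),
      a = ca, b = cb, c = ccc, d = cd,
      odds_ratio = or, log10_or = log10(or),
      duplicate_of = NA_character_
    )
  })
  scores <- dplyr::bind_rows(per_cluster)

  if (!is.null(duplicates) && nrow(duplicates) > 0) {
    extra <- dplyr::inner_join(
      scores,
      dplyr::rename(duplicates, ko = "representative_ko"),
      by = "ko"
    )
    extra$duplicate_of <- extra$ko
    extra$ko <- extra$member_ko
    extra$member_ko <- NULL
    scores <- dplyr::bind_rows(scores, extra)
  }

  scores |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$log10_or), .data$ko) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
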
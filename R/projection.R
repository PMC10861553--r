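# Projection of community abundances onto isolate gene content: the
# per-sample "functional potential" proxy for expected metabolic capacity.

#' Distribute OTU abundances onto mapped isolates
#'
#' Each OTU's relative abundance is split equally among the isolates it
#' maps to at or above the chosen identity bin (or weighted by identity).
#' Abundance of OTUs with no admissible hit is reported as an unmapped
#' fraction rather than renormalised, so projected values stay comparable
#' across samples.
#'
#' @param abundance Samples-by-OTUs relative-abundance matrix (rows should
#'   sum to at most 1; raw counts are accepted and row-normalised).
#' @param hits Tibble from [map_otus_to_isolates()].
#' @param min_bin Lowest admissible identity bin: `">=99"` (default),
#'   `"97-99"`, or `"95-97"`.
#' @param weights `"equal"` splits an OTU's abundance evenly across its
#'   admissible isolates; `"identity"` weights the split by percent
#'   identity.
#' @return A list with `abundance` (samples x isolates matrix) and
#'   `unmapped` (tibble `sample`, `unmapped_fraction`).
#' @export
abundance_to_isolates <- function(abundance, hits,
                                  min_bin = c(">=99", "97-99", "95-97"),
                                  weights = c("equal", "identity")) {
  min_bin <- match.arg(min_bin)
  weights <- match.arg(weights)
  m <- as_count_matrix(abundance, "abundance")
  if (any(rowSums(m) > 1 + 1e-8)) m <- m / rowSums(m)
  min_code <- match(min_bin, c("95-97", "97-99", ">=99"))
  adm <- hits[as.integer(hits$bin) >= min_code, , drop = FALSE]
  isolates <- sort(unique(hits$isolate))
  out <- matrix(0, nrow(m), length(isolates),
                dimnames = list(rownames(m), isolates))
  if (nrow(adm) == 0) {
    warn("no admissible hits; projection is all zero")
    return(list(abundance = out,
                unmapped = tibble::tibble(sample = rownames(m),
                                          unmapped_fraction = rowSums(m))))
  }
  split <- split(adm, adm$otu)
  mapped_otus <- intersect(colnames(m), names(split))
  for (otu in mapped_otus) {
    h <- split[[otu]]
    w <- if (weights == "equal") rep(1, nrow(h)) else h$percent_identity
    w <- w / sum(w)
    out[, h$isolate] <- out[, h$isolate, drop = FALSE] +
      outer(m[, otu], w)
  }
  mapped_mass <- rowSums(m[, mapped_otus, drop = FALSE])
  list(
    abundance = out,
    unmapped = tibble::tibble(sample = rownames(m),
                              unmapped_fraction = unname(rowSums(m) - mapped_mass))
  )
}

#' Project isolate abundances onto KO content
#'
#' Matrix product `F = A %*% K`: `A` is the samples-by-isolates abundance
#' matrix, `K` the binary isolate-by-KO matrix, so `F[s, j]` is the summed
#' abundance of isolates carrying KO j in sample s - a proxy for the
#' community's capacity for the function j indexes.
#'
#' @param abundance Samples-by-isolates matrix (e.g. from
#'   [abundance_to_isolates()]); isolate ids must all be rows of `ko`.
#' @param ko A [ko_matrix()].
#' @param ko_subset Optional character vector restricting the projection to
#'   a KO panel (e.g. metabolite-linked KOs).
#' @return A samples-by-KOs numeric matrix.
#' @export
#' @examples
#' k <- ko_matrix(matrix(c(1, 1, 0, 1, 1, 0), 2, byrow = TRUE,
#'                dimnames = list(c("i1", "i2"), c("K1", "K2", "K3"))))
#' a <- matrix(c(2, 1), 1, dimnames = list("s1", c("i1", "i2")))
#' project_functional_potential(a, k)
project_functional_potential <- function(abundance, ko, ko_subset = NULL) {
  stopifnot(inherits(ko, "ko_matrix"))
  a <- as_count_matrix(abundance, "abundance")
  if (!all(colnames(a) %in% rownames(ko))) {
    abort("isolate ids in `abundance` missing from the KO matrix")
  }
  k <- unclass(ko)[colnames(a), , drop = FALSE]
  if (!is.null(ko_subset)) {
    missing <- setdiff(ko_subset, colnames(k))
    if (length(missing) > 0) abort("unknown KO ids in `ko_subset`")
    k <- k[, ko_subset, drop = FALSE]
  }
  a %*% k
}
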
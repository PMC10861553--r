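# Mapping OTU representative 16S sequences onto isolate-derived 16S genes
# by semi-global pairwise percent identity, with the binned "barcode"
# representation used to discriminate closely related taxa.

# 5x5 DNA scoring matrix; N is always a mismatch (conservative identity).
identity_scoring_matrix <- function(match = 1, mismatch = -1) {
  bases <- c("A", "C", "G", "T", "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(sm) <- match
  sm["N", "N"] <- mismatch
  sm
}

as_dna_set <- function(x, arg) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  if (is.character(x)) {
    if (any(!grepl("^[ACGTNacgtn]+$", x))) {
      abort(sprintf("`%s` contains characters outside {A,C,G,T,N}", arg))
    }
    s <- Biostrings::DNAStringSet(toupper(x))
    if (!is.null(names(x))) names(s) <- names(x)
    return(s)
  }
  abort(sprintf("`%s` must be sequences or a FASTA path", arg))
}

#' Percent identity of two 16S sequences
#'
#' Semi-global (overlap) dynamic-programming alignment with free end gaps,
#' match +1, mismatch -1, and a linear gap penalty of -2 per gap column by
#' default. Identity is the number of identical aligned bases divided by
#' the number of alignment columns; `N` never counts as a match.
#'
#' @param a,b Sequences (character, `DNAString`) over `{A,C,G,T,N}`.
#' @param match,mismatch,gap Alignment scores (gap is the per-column
#'   penalty, given as a negative number).
#' @return A list with `percent_identity` (0-100) and `alignment_length`
#'   (alignment columns).
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGA")
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as_dna_set(a, "a")[[1]]
  b <- as_dna_set(b, "b")[[1]]
  if (length(a) == 0 || length(b) == 0) abort("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap",
    substitutionMatrix = identity_scoring_matrix(match, mismatch),
    gapOpening = 0, gapExtension = -gap
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  len <- length(pa)
  matches <- sum(pa == pb & pa %in% c("A", "C", "G", "T"))
  list(percent_identity = 100 * matches / len, alignment_length = len)
}

#' Bin a percent identity into the barcode classes
#'
#' Half-open boundaries: `[95, 97)` is "95-97", `[97, 99)` is "97-99",
#' `[99, 100]` is ">=99"; identities below `min_identity` get `NA`.
#'
#' @param percent_identity Numeric vector in `[0, 100]`.
#' @param min_identity Lower bound of the lowest bin.
#' @return A factor with levels `"95-97"`, `"97-99"`, `">=99"`.
#' @export
bin_identity <- function(percent_identity, min_identity = 95) {
  cut(percent_identity,
      breaks = c(min_identity, 97, 99, 100.000001),
      labels = c("95-97", "97-99", ">=99"),
      right = FALSE, include.lowest = TRUE)
}

#' Map OTU sequences onto isolate 16S genes
#'
#' Scores every OTU-isolate pair with [pairwise_identity()] and keeps hits
#' with identity of at least `min_identity` and alignment length of at
#' least `min_length`. One OTU may hit many isolates and vice versa; all
#' surviving hits are reported.
#'
#' @param otus,isolates Named character vectors, `DNAStringSet`s, or FASTA
#'   file paths of OTU representative and isolate 16S sequences.
#' @param min_identity Minimum percent identity (default 95).
#' @param min_length Minimum alignment length in columns (default 206, a
#'   V4-amplicon-scale floor standing in for an e-value filter).
#' @param ... Scores passed to [pairwise_identity()].
#' @return A tibble with columns `otu`, `isolate`, `percent_identity`,
#'   `alignment_length`, `bin`.
#' @export
map_otus_to_isolates <- function(otus, isolates, min_identity = 95,
                                 min_length = 206, ...) {
  otus <- as_dna_set(otus, "otus")
  isolates <- as_dna_set(isolates, "isolates")
  if (is.null(names(otus))) names(otus) <- paste0("otu_", seq_along(otus))
  if (is.null(names(isolates))) names(isolates) <- paste0("isolate_", seq_along(isolates))
  if (min_identity < 0 || min_identity > 100) abort("`min_identity` out of range")
  hits <- purrr::map(seq_along(otus), function(i) {
    purrr::map(seq_along(isolates), function(j) {
      pid <- pairwise_identity(otus[[i]], isolates[[j]], ...)
      tibble::tibble(otu = names(otus)[i], isolate = names(isolates)[j],
                     percent_identity = pid$percent_identity,
                     alignment_length = pid$alignment_length)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  hits <- hits[hits$percent_identity >= min_identity &
                 hits$alignment_length >= min_length, , drop = FALSE]
  hits$bin <- bin_identity(hits$percent_identity, min_identity)
  hits
}

#' OTU-by-isolate barcode matrix of identity bins
#'
#' Encodes hits as 0 (no hit), 1 (95-97%), 2 (97-99%), 3 (>= 99%); the
#' per-row patterns act as "barcodes" that can separate taxa sharing
#' near-identical 16S sequences.
#'
#' @param hits Tibble from [map_otus_to_isolates()].
#' @param otus,isolates Optional ordered id vectors fixing the matrix
#'   layout; default to the ids present in `hits`.
#' @return An integer matrix (OTUs x isolates).
#' @export
barcode_matrix <- function(hits, otus = NULL, isolates = NULL) {
  otus <- otus %||% unique(hits$otu)
  isolates <- isolates %||% unique(hits$isolate)
  if (!all(hits$otu %in% otus) || !all(hits$isolate %in% isolates)) {
    abort("`hits` reference ids missing from `otus`/`isolates`")
  }
  m <- matrix(0L, length(otus), length(isolates),
              dimnames = list(otus, isolates))
  if (nrow(hits) > 0) {
    code <- as.integer(hits$bin)
    m[cbind(match(hits$otu, otus), match(hits$isolate, isolates))] <- code
  }
  m
}

#' Heatmap of a barcode matrix
#'
#' @param m Matrix from [barcode_matrix()].
#' @return A ggplot object.
#' @export
plot_barcode_matrix <- function(m) {
  df <- tibble::as_tibble(m, rownames = "otu") |>
    tidyr::pivot_longer(-"otu", names_to = "isolate", values_to = "code")
  df$bin <- factor(df$code, levels = 0:3,
                   labels = c("none", "95-97", "97-99", ">=99"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$isolate, y = .data$otu,
                                   fill = .data$bin)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::scale_fill_manual(values = c(none = "white", `95-97` = "#bdd7e7",
                                          `97-99` = "#6baed6", `>=99` = "#2171b5")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
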
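# OTU table preparation (read/prevalence filtering, biomass-correlation
# contaminant flagging, rarefaction) and the diversity statistics used in
# the dysbiosis analysis.

#' Filter low-count, low-prevalence OTUs
#'
#' Removes OTUs whose total read count across all samples falls below
#' `min_total_reads` or that are detected in fewer than
#' `min_prevalence` of samples. The two thresholds come from a single
#' filtering rule stated jointly in low-biomass amplicon practice; by
#' default an OTU failing either one is removed.
#'
#' @param counts Samples-by-OTUs count matrix (or data frame with a sample
#'   id first column).
#' @param min_total_reads Minimum total reads summed over samples.
#' @param min_prevalence Minimum fraction of samples with a non-zero count.
#' @return A list with `counts` (filtered matrix) and `removed` (tibble with
#'   columns `otu`, `total_reads`, `prevalence`).
#' @export
filter_low_count_otus <- function(counts, min_total_reads = 20,
                                  min_prevalence = 0.02) {
  if (min_total_reads < 0 || min_prevalence < 0) abort("thresholds must be non-negative")
  m <- as_count_matrix(counts)
  totals <- colSums(m)
  prev <- colMeans(m > 0)
  drop <- totals < min_total_reads | prev < min_prevalence
  list(
    counts = m[, !drop, drop = FALSE],
    removed = tibble::tibble(otu = colnames(m)[drop],
                             total_reads = unname(totals[drop]),
                             prevalence = unname(prev[drop]))
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, monotone in the sorted order and capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag putative contaminant OTUs by biomass correlation
#'
#' In low-biomass airway samples, reagent contaminants contribute a roughly
#' constant absolute input, so their *relative* abundance falls as true
#' bacterial biomass rises. Each OTU's per-sample relative abundance is
#' Spearman-correlated with qPCR biomass; OTUs with a Benjamini-Hochberg
#' adjusted p-value below `fdr` and `|rho|` above `rho_threshold` in the
#' contaminant direction (negative, by default) are flagged.
#'
#' @param counts Samples-by-OTUs count matrix.
#' @param biomass Numeric vector of per-sample biomass (16S copies), in
#'   sample order (or named by sample).
#' @param rho_threshold Minimum correlation magnitude.
#' @param fdr Adjusted p-value threshold.
#' @param direction `"negative"` flags only negative correlations (the
#'   dilution mechanism); `"both"` flags either sign.
#' @return A tibble with columns `otu`, `rho`, `p_value`, `p_adjusted`,
#'   `contaminant`.
#' @export
flag_biomass_contaminants <- function(counts, biomass, rho_threshold = 0.2,
                                      fdr = 0.05,
                                      direction = c("negative", "both")) {
  direction <- match.arg(direction)
  m <- as_count_matrix(counts)
  if (!is.null(names(biomass))) biomass <- biomass[rownames(m)]
  if (length(biomass) != nrow(m)) abort("`biomass` must have one value per sample")
  if (anyNA(biomass) || any(biomass <= 0)) abort("biomass must be positive and complete")
  if (length(unique(biomass)) < 2) abort("biomass is constant; correlation undefined")
  if (nrow(m) < 10) warn("fewer than 10 samples; biomass correlations are unstable")
  rel <- m / rowSums(m)
  res <- purrr::map(colnames(rel), function(otu) {
    x <- rel[, otu]
    if (sd(x) == 0) {
      # constant relative abundance (e.g. never observed): no evidence
      return(tibble::tibble(otu = otu, rho = NA_real_, p_value = 1))
    }
    ct <- suppressWarnings(cor.test(x, biomass, method = "spearman",
                                    exact = FALSE))
    tibble::tibble(otu = otu, rho = unname(ct$estimate),
                   p_value = ifelse(is.na(ct$p.value), 1, ct$p.value))
  }) |> dplyr::bind_rows()
  res$p_adjusted <- bh_adjust(res$p_value)
  res$contaminant <- !is.na(res$rho) & res$p_adjusted < fdr &
    if (direction == "negative") res$rho <= -rho_threshold else abs(res$rho) >= rho_threshold
  res
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, after discarding samples whose total falls below
#' `min_sample_reads`. Per-OTU counts after rarefaction follow the
#' multivariate hypergeometric distribution.
#'
#' @param counts Samples-by-OTUs count matrix of non-negative integers.
#' @param depth Target depth, or `"min"` for the smallest retained sample
#'   total.
#' @param seed Integer seed making the draw reproducible.
#' @param min_sample_reads Samples with fewer total reads are dropped first.
#' @return A list with `counts` (rarefied integer matrix, every row summing
#'   to `depth`), `depth`, and `discarded` (character vector of dropped
#'   sample ids).
#' @export
rarefy_counts <- function(counts, depth = "min", seed = 1,
                          min_sample_reads = 1000) {
  m <- as_count_matrix(counts)
  if (any(m != round(m))) abort("counts must be integers")
  totals <- rowSums(m)
  discarded <- rownames(m)[totals < min_sample_reads]
  m <- m[totals >= min_sample_reads, , drop = FALSE]
  if (nrow(m) == 0) abort("no samples left after the minimum-reads filter")
  if (identical(depth, "min")) depth <- min(rowSums(m))
  if (!is.numeric(depth) || depth <= 0) abort("`depth` must be a positive number")
  if (any(rowSums(m) < depth)) abort("`depth` exceeds a retained sample's total")
  out <- with_seed(seed, {
    t(apply(m, 1, function(x) {
      drawn <- sample(rep.int(seq_along(x), x), depth)
      tabulate(drawn, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(m)
  storage.mode(out) <- "integer"
  list(counts = out, depth = as.integer(depth), discarded = discarded)
}

#' Alpha diversity: Shannon index, richness and Pielou evenness
#'
#' Shannon entropy `H = -sum p_i log(p_i)` (natural log by default),
#' richness `S` (OTUs with non-zero count), and evenness `J = H / log(S)`
#' (undefined, `NA`, when `S <= 1`).
#'
#' @param counts Samples-by-OTUs count matrix; every sample must have at
#'   least one read.
#' @param base Logarithm base for the Shannon index.
#' @return A tibble with columns `sample`, `shannon`, `richness`, `evenness`.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  m <- as_count_matrix(counts)
  if (any(rowSums(m) == 0)) abort("all-zero samples have undefined diversity")
  res <- apply(m, 1, function(x) {
    p <- x[x > 0] / sum(x)
    h <- -sum(p * log(p, base = base))
    s <- length(p)
    c(h, s, if (s > 1) h / log(s, base = base) else NA_real_)
  })
  tibble::tibble(sample = rownames(m), shannon = unname(res[1, ]),
                 richness = as.integer(res[2, ]), evenness = unname(res[3, ]))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`: 0 for identical samples,
#' 1 for samples with disjoint support. Computed on relative abundances by
#' default so that sequencing depth does not dominate.
#'
#' @param counts Samples-by-OTUs matrix with at least two samples.
#' @param transform `"relative"` (rows scaled to sum 1) or `"none"`.
#' @return A [stats::dist] object.
#' @export
bray_curtis <- function(counts, transform = c("relative", "none")) {
  transform <- match.arg(transform)
  m <- as_count_matrix(counts)
  if (nrow(m) < 2) abort("need at least two samples")
  if (any(rowSums(m) == 0)) abort("zero-sum samples have undefined dissimilarity")
  if (transform == "relative") m <- m / rowSums(m)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and returns coordinates on the
#' axes with positive eigenvalues in decreasing order. Negative eigenvalues
#' (possible for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported but contribute no coordinates.
#'
#' @param d A [stats::dist] object or distance matrix.
#' @param n_axes Number of axes requested.
#' @return An object of class `pcoa_result`: list with `coordinates` (tibble
#'   `sample`, `axis_1`, ...), `eigenvalues`, and `variance_explained`
#'   (fractions of the positive-eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- validate_distance(d)
  n <- attr(d, "Size")
  n_pos_max <- n - 1
  res <- suppressWarnings(cmdscale(d, k = min(n_axes, n_pos_max), eig = TRUE))
  eig <- res$eig
  pos <- sum(eig > 1e-8)
  if (n_axes > pos) {
    warn(sprintf("only %d positive axes available; returning those", pos))
  }
  k <- min(n_axes, pos)
  coords <- if (k > 0) {
    res$points[, seq_len(k), drop = FALSE]
  } else {
    matrix(0, n, n_axes) # degenerate configuration: everything at the origin
  }
  colnames(coords) <- paste0("axis_", seq_len(ncol(coords)))
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  ct <- dplyr::bind_cols(tibble::tibble(sample = ids),
                         tibble::as_tibble(as.data.frame(coords)))
  pos_total <- sum(pmax(eig, 0))
  ve <- if (pos_total > 0) pmax(eig, 0)[seq_len(ncol(coords))] / pos_total
        else rep(0, ncol(coords))
  structure(
    list(coordinates = ct, eigenvalues = eig, variance_explained = ve),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d axes (%.1f%% variance on axis 1)\n",
              nrow(x$coordinates), ncol(x$coordinates) - 1,
              100 * x$variance_explained[1]))
  invisible(x)
}

#' Ordination plot of a PCoA result
#'
#' @param object A `pcoa_result`.
#' @param colour Optional vector (in sample order) mapped to point colour,
#'   e.g. community types or disease status.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) abort("need at least two axes to plot")
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis_1, y = .data$axis_2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$variance_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
    ggplot2::labs(colour = NULL)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based pseudo-F test of compositional differences between groups,
#' with the p-value computed by label permutation as
#' `(1 + #{permuted F >= observed}) / (1 + n_perm)`.
#'
#' @param d A [stats::dist] object or distance matrix.
#' @param groups Grouping vector (at least two groups, each with at least
#'   two samples).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @return A one-row tibble: `pseudo_f`, `r_squared`, `df`, `p_value`,
#'   `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- validate_distance(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) abort("`groups` must match the distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least two groups")
  if (any(tab < 2)) abort("every group needs at least two samples")
  df <- data.frame(groups = groups)
  fit <- with_seed(seed, vegan::adonis2(d ~ groups, data = df, permutations = n_perm))
  tibble::tibble(
    pseudo_f = fit$F[1],
    r_squared = fit$R2[1],
    df = fit$Df[1],
    p_value = fit$`Pr(>F)`[1],
    n_perm = n_perm
  )
}
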
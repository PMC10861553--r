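# Independent oracles used by the tests. These deliberately share no code
# with the package implementation.

# Naive O(n^3) complete-linkage agglomeration: repeatedly merge the two
# clusters whose maximum pairwise distance is smallest; returns the sorted
# merge heights.
naive_complete_linkage_heights <- function(dm) {
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d_ij <- max(dm[clusters[[i]], clusters[[j]]])
        if (d_ij < best_d) {
          best_d <- d_ij
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Brute-force enrichment scoring that never collapses duplicates: loops
# over every (cluster, KO) pair, tallies the 2x2 table by explicit
# counting, and applies the zero-cell correction by hand.
brute_force_ko_scores <- function(labels, mat) {
  keep <- labels > 0
  labels <- labels[keep]
  mat <- mat[keep, , drop = FALSE]
  out <- list()
  for (ci in sort(unique(labels))) {
    for (ko in colnames(mat)) {
      a <- b <- cc <- dd <- 0
      for (i in seq_len(nrow(mat))) {
        inside <- labels[i] == ci
        present <- mat[i, ko] == 1
        if (inside && present) a <- a + 1
        else if (inside) b <- b + 1
        else if (present) cc <- cc + 1
        else dd <- dd + 1
      }
      cells <- c(a, b, cc, dd)
      cells[cells == 0] <- 0.5
      out[[length(out) + 1]] <- data.frame(
        cluster = ci, ko = ko,
        log10_or = log10(cells[1] * cells[4] / (cells[2] * cells[3]))
      )
    }
  }
  do.call(rbind, out)
}

# All compositions of n reads over J taxa (for exhaustive DM normalisation).
all_compositions <- function(n, J) {
  if (J == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (first in 0:n) {
    rest <- all_compositions(n - first, J - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Hand-rolled Shannon/evenness for cross-checking.
oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}
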
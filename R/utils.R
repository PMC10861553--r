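# Shared internal helpers plus a couple of small exported utilities.

#' Derive a reproducible sub-seed for a named random substream
#'
#' All generators in the package draw their randomness from a substream seed
#' derived deterministically from a user-facing seed and the generator name.
#' Adding a new generator therefore never perturbs the draws of existing ones
#' run under the same master seed.
#'
#' @param seed Integer master seed.
#' @param name Character scalar naming the substream (usually the generator).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "ko_matrix")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Evaluate code with a local RNG state seeded from `seed`; restores the
# caller's .Random.seed afterwards so library functions stay side-effect free.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used throughout the package to quantify recovery of planted clusters.
#'
#' @param a,b Vectors of cluster labels (any atomic type) of equal length.
#' @return A numeric scalar; 1 for identical partitions, approximately 0 for
#'   independent ones.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Coerce a samples-x-features table (matrix, or data frame whose first column
# holds sample ids) to a numeric matrix with rownames.
as_count_matrix <- function(x, arg = "counts") {
  if (is.data.frame(x)) {
    first <- x[[1]]
    if (is.character(first) || is.factor(first)) {
      ids <- as.character(first)
      m <- as.matrix(x[, -1, drop = FALSE])
      rownames(m) <- ids
    } else {
      m <- as.matrix(x)
    }
    storage.mode(m) <- "double"
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
  } else {
    abort(sprintf("`%s` must be a matrix or data frame", arg))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("sample_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("feature_", seq_len(ncol(m)))
  if (anyNA(m)) abort(sprintf("`%s` contains missing values", arg))
  if (any(m < 0)) abort(sprintf("`%s` contains negative values", arg))
  m
}
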
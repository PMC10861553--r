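# Dirichlet-multinomial mixture (DMM) community typing: likelihood, EM
# fitting, model selection, sample assignment and congruence testing.
# This is a from-scratch implementation of the mixture model used to define
# airway community types ("pulmotypes"), analogous to gut enterotyping.

#' Dirichlet-multinomial log-likelihood of a count vector
#'
#' With `n = sum(x)` and `A = sum(alpha)`:
#' `log P(x | alpha) = lgamma(n+1) - sum lgamma(x_j+1) + lgamma(A) -
#'  lgamma(n+A) + sum(lgamma(x_j+alpha_j) - lgamma(alpha_j))`.
#' Everything is computed in log space, so counts up to about 1e6 pose no
#' overflow problem.
#'
#' @param x Non-negative integer count vector.
#' @param alpha Positive Dirichlet parameter vector, same length as `x`.
#' @return The log probability (a scalar).
#' @export
#' @examples
#' exp(dm_log_likelihood(c(1, 0), c(1, 1))) # = 1/2
dm_log_likelihood <- function(x, alpha) {
  if (length(x) != length(alpha)) abort("`x` and `alpha` must have equal length")
  if (any(alpha <= 0)) abort("`alpha` must be positive")
  if (any(x < 0) || any(x != round(x))) abort("`x` must be non-negative integers")
  n <- sum(x)
  A <- sum(alpha)
  lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(A) - lgamma(n + A) +
    sum(lgamma(x + alpha) - lgamma(alpha))
}

# Vectorised DM log-likelihood: counts matrix (n x J) against one alpha
# vector -> n log-probabilities. lfact_rows = precomputed
# lgamma(n_s+1) - rowSums(lgamma(x+1)).
dm_ll_rows <- function(x, n_s, lfact_rows, alpha) {
  A <- sum(alpha)
  lfact_rows + lgamma(A) - lgamma(n_s + A) +
    rowSums(lgamma(sweep(x, 2, alpha, "+"))) - sum(lgamma(alpha))
}

# Responsibility-weighted DM maximum-likelihood fit of one component's
# alpha, by L-BFGS-B on log(alpha) with the analytic digamma gradient.
fit_weighted_dm <- function(x, n_s, w, alpha0, alpha_min = 1e-8) {
  negll <- function(la) {
    alpha <- exp(la)
    A <- sum(alpha)
    -sum(w * (lgamma(A) - lgamma(n_s + A) +
                rowSums(lgamma(sweep(x, 2, alpha, "+"))) - sum(lgamma(alpha))))
  }
  grad <- function(la) {
    alpha <- exp(la)
    A <- sum(alpha)
    g <- colSums(w * digamma(sweep(x, 2, alpha, "+"))) -
      sum(w) * digamma(alpha) +
      sum(w) * digamma(A) - sum(w * digamma(n_s + A))
    -g * alpha
  }
  o <- optim(log(alpha0), negll, grad, method = "L-BFGS-B",
             lower = log(alpha_min), upper = log(1e8),
             control = list(maxit = 250))
  exp(o$par)
}

#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Samples are modelled as draws from `k` Dirichlet-multinomial components
#' with weights `pi`. The E-step computes responsibilities
#' `z_sk` proportional to `pi_k P(x_s | alpha_k)`; the M-step sets `pi` to mean
#' responsibility and maximises each component's responsibility-weighted DM
#' likelihood over `log(alpha)` by bounded quasi-Newton. Responsibilities
#' are initialised from k-means on the proportion vectors; the best of
#' `n_restarts` runs by log-likelihood is returned, components ordered by
#' decreasing weight.
#'
#' @param counts Samples-by-taxa count matrix (genus-binned in the airway
#'   typing application); every retained sample must have at least one read.
#' @param k Number of mixture components.
#' @param seed Integer seed (initialisation).
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of seeded restarts.
#' @param alpha_min Lower bound for the alpha optimisation.
#' @return An object of class `dmm_fit`: list with `k`, `pi`, `alpha`
#'   (k x J, rownames `type_1`...), `z` (responsibilities), `loglik`,
#'   `loglik_trace`, `criteria` (`laplace`, `bic`, `aic`), `n_iter`,
#'   `converged`, `seed`, and the input dimensions.
#' @export
#' @examples
#' sim <- simulate_dmm_counts(k = 2, pi = c(0.5, 0.5),
#'                            alpha = rbind(c(8, 1, 1), c(1, 8, 1)),
#'                            n_samples = 60, depth = 500, seed = 1)
#' fit <- fit_dmm(sim$counts, k = 2, seed = 1, n_restarts = 2)
#' glance(fit)
fit_dmm <- function(counts, k, seed = 1, tol = 1e-6, max_iter = 200,
                    n_restarts = 5, alpha_min = 1e-8) {
  x <- as_count_matrix(counts)
  if (any(x != round(x))) abort("counts must be integers")
  n <- nrow(x)
  J <- ncol(x)
  if (k < 1) abort("`k` must be at least 1")
  if (n <= k) abort("need more samples than components")
  n_s <- rowSums(x)
  if (any(n_s == 0)) abort("every sample needs at least one read")
  lfact_rows <- lgamma(n_s + 1) - rowSums(lgamma(x + 1))
  props <- x / n_s

  run_once <- function(rseed) {
    assign0 <- with_seed(rseed, {
      if (k == 1) {
        rep(1L, n)
      } else if (nrow(unique(props)) < k) {
        sample.int(k, n, replace = TRUE)
      } else {
        kmeans(props, centers = k, nstart = 3)$cluster
      }
    })
    z <- matrix(1e-6, n, k)
    z[cbind(seq_len(n), assign0)] <- 1
    z <- z / rowSums(z)
    alpha <- matrix(0, k, J)
    for (kk in seq_len(k)) {
      mp <- colSums(z[, kk] * props) / sum(z[, kk])
      alpha[kk, ] <- pmax(mp, 1e-6) * 10
    }
    pi_k <- colMeans(z)
    loglik_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      for (kk in seq_len(k)) {
        alpha[kk, ] <- fit_weighted_dm(x, n_s, z[, kk], alpha[kk, ], alpha_min)
      }
      pi_k <- colMeans(z)
      lmat <- vapply(seq_len(k), function(kk) {
        dm_ll_rows(x, n_s, lfact_rows, alpha[kk, ])
      }, numeric(n))
      lpost <- sweep(matrix(lmat, n, k), 2, log(pi_k), "+")
      lse <- row_logsumexp(lpost)
      z <- exp(lpost - lse)
      loglik <- sum(lse)
      trace <- c(trace, loglik)
      if (it > 1 && loglik - loglik_prev < tol) {
        converged <- TRUE
        break
      }
      loglik_prev <- loglik
    }
    list(alpha = alpha, pi = pi_k, z = z, loglik = loglik,
         trace = trace, converged = converged, n_iter = it)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    cand <- run_once(substream_seed(seed, paste0("dmm_restart_", r)))
    # degenerate component: responsibility mass below one sample
    if (any(colSums(cand$z) < 1) && r < n_restarts) next
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  if (is.null(best)) best <- run_once(substream_seed(seed, "dmm_restart_final"))

  ord <- order(best$pi, decreasing = TRUE)
  alpha <- best$alpha[ord, , drop = FALSE]
  dimnames(alpha) <- list(paste0("type_", seq_len(k)), colnames(x))
  z <- best$z[, ord, drop = FALSE]
  dimnames(z) <- list(rownames(x), paste0("type_", seq_len(k)))

  fit <- structure(
    list(k = k, pi = unname(best$pi[ord]), alpha = alpha, z = z,
         loglik = best$loglik, loglik_trace = best$trace,
         n_iter = best$n_iter, converged = best$converged,
         seed = seed, n_samples = n, n_taxa = J),
    class = "dmm_fit"
  )
  fit$criteria <- list(
    laplace = laplace_criterion(fit, x, n_s),
    bic = -2 * fit$loglik + (k * J + k - 1) * log(n),
    aic = -2 * fit$loglik + 2 * (k * J + k - 1)
  )
  fit
}

# Laplace-approximation negative log model evidence at the EM optimum.
# The Hessian over log(alpha) is approximated block-diagonally per component
# using responsibility-weighted second derivatives (a rank-one update of a
# diagonal, so the determinant is cheap); the mixture-weight block is
# penalised at BIC rate. Known to be anti-conservative for k; see the
# methods vignette.
laplace_criterion <- function(fit, x, n_s) {
  logdet <- 0
  for (kk in seq_len(fit$k)) {
    w <- fit$z[, kk]
    alpha <- fit$alpha[kk, ]
    A <- sum(alpha)
    b <- sum(w * (trigamma(A) - trigamma(n_s + A)))
    a <- colSums(w * trigamma(sweep(x, 2, alpha, "+"))) - sum(w) * trigamma(alpha)
    na <- pmax(-a, 1e-10)
    logdet <- logdet + sum(log(na)) + log(max(1 - sum(b / na), 1e-10))
  }
  d_alpha <- fit$k * fit$n_taxa
  -(fit$loglik + 0.5 * d_alpha * log(2 * pi) - 0.5 * logdet) +
    0.5 * (fit$k - 1) * log(fit$n_samples)
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf("<dmm_fit> k = %d, %d samples x %d taxa, loglik = %.1f (%s)\n",
              x$k, x$n_samples, x$n_taxa, x$loglik,
              if (x$converged) "converged" else "not converged"))
  cat("weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of community types
#'
#' Fits the mixture for each `k` in `k_range` and returns the fit that
#' minimises the chosen information criterion. The whole criterion curve is
#' attached so the shape of the evidence can be inspected.
#'
#' @inheritParams fit_dmm
#' @param k_range Integer vector of component numbers to try.
#' @param criterion `"bic"` (default), `"laplace"`, or `"aic"`;
#'   lower is better for all three.
#' @return The best `dmm_fit`, with `$criterion_curve` (tibble `k`,
#'   `laplace`, `bic`, `aic`, `converged`) and `$criterion` recording the
#'   rule used.
#' @export
select_k <- function(counts, k_range = 1:5,
                     criterion = c("bic", "laplace", "aic"),
                     seed = 1, ...) {
  criterion <- match.arg(criterion)
  if (length(k_range) == 0) abort("`k_range` is empty")
  fits <- purrr::map(k_range, function(k) fit_dmm(counts, k, seed = seed, ...))
  if (!any(purrr::map_lgl(fits, "converged"))) abort("no fit converged")
  curve <- tibble::tibble(
    k = as.integer(k_range),
    laplace = purrr::map_dbl(fits, ~ .x$criteria$laplace),
    bic = purrr::map_dbl(fits, ~ .x$criteria$bic),
    aic = purrr::map_dbl(fits, ~ .x$criteria$aic),
    converged = purrr::map_lgl(fits, "converged")
  )
  best <- fits[[which.min(curve[[criterion]])]]
  best$criterion_curve <- curve
  best$criterion <- criterion
  best
}

#' Assign samples to community types
#'
#' Hard assignment by maximum responsibility; posterior ties go to the
#' lower-numbered component and are flagged.
#'
#' @param fit A `dmm_fit`.
#' @return A tibble with columns `sample`, `type` (integer), `posterior`,
#'   `tied`.
#' @export
assign_types <- function(fit) {
  stopifnot(inherits(fit, "dmm_fit"))
  z <- fit$z
  type <- max.col(z, ties.method = "first")
  posterior <- z[cbind(seq_len(nrow(z)), type)]
  tied <- apply(z, 1, function(r) sum(abs(r - max(r)) < 1e-12) > 1)
  if (any(tied)) warn(sprintf("%d sample(s) had tied posteriors", sum(tied)))
  tibble::tibble(sample = rownames(z) %||% as.character(seq_len(nrow(z))),
                 type = as.integer(type), posterior = posterior, tied = tied)
}

#' Top driver taxa of each community type
#'
#' Taxa ranked by each component's fitted expected proportion
#' `alpha_j / sum(alpha)` - the "main drivers" of a community type.
#'
#' @param fit A `dmm_fit`.
#' @param n Number of taxa per type.
#' @return A tibble with columns `type`, `rank`, `taxon`,
#'   `expected_proportion`.
#' @export
top_drivers <- function(fit, n = 5) {
  stopifnot(inherits(fit, "dmm_fit"))
  ep <- fit$alpha / rowSums(fit$alpha)
  purrr::map(seq_len(fit$k), function(kk) {
    ord <- order(ep[kk, ], decreasing = TRUE)[seq_len(min(n, ncol(ep)))]
    tibble::tibble(type = kk, rank = seq_along(ord),
                   taxon = colnames(ep)[ord],
                   expected_proportion = unname(ep[kk, ord]))
  }) |> dplyr::bind_rows()
}

#' Congruence of community-type assignment with a sample grouping
#'
#' Pearson chi-square test (no continuity correction) on the contingency
#' table of a metadata factor (donor, site, study, disease status) against
#' assigned community type; used to ask whether samples from the same donor
#' or site receive consistent types.
#'
#' @param types Integer/character vector of community-type labels.
#' @param groups Factor-like vector of the same length.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, plus the level
#'   counts dropped (levels with zero samples are removed with a warning).
#' @export
congruence_test <- function(types, groups) {
  if (length(types) != length(groups)) abort("inputs must have equal length")
  groups <- droplevels(as.factor(groups))
  empties <- setdiff(levels(as.factor(groups)), unique(as.character(groups)))
  if (length(empties) > 0) warn("dropping empty factor levels")
  tab <- table(groups, types)
  if (any(dim(tab) < 2)) abort("need at least two levels and two types")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' @method tidy dmm_fit
#' @export
tidy.dmm_fit <- function(x, ...) {
  ep <- x$alpha / rowSums(x$alpha)
  purrr::map(seq_len(x$k), function(kk) {
    tibble::tibble(type = kk, weight = x$pi[kk],
                   taxon = colnames(x$alpha),
                   alpha = unname(x$alpha[kk, ]),
                   expected_proportion = unname(ep[kk, ]))
  }) |> dplyr::bind_rows()
}

#' @method glance dmm_fit
#' @export
glance.dmm_fit <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik,
                 laplace = x$criteria$laplace, bic = x$criteria$bic,
                 aic = x$criteria$aic,
                 n_iter = x$n_iter, converged = x$converged,
                 n_samples = x$n_samples, n_taxa = x$n_taxa)
}

#' Plot a fitted mixture: criterion curve and expected type profiles
#'
#' When the fit carries a criterion curve (from [select_k()]) the curve is
#' drawn; otherwise the per-type expected taxon proportions are shown.
#'
#' @param object A `dmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dmm_fit
#' @export
autoplot.dmm_fit <- function(object, ...) {
  if (!is.null(object$criterion_curve)) {
    crit <- object$criterion %||% "bic"
    df <- object$criterion_curve
    ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data[[crit]])) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "number of community types", y = crit) +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon,
                                     y = .data$expected_proportion)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~type) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "expected proportion") +
      ggplot2::theme_minimal()
  }
}
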
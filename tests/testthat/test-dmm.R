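# Dirichlet-multinomial likelihood, EM fitting and congruence testing.

test_that("the DM log-likelihood matches closed forms and normalises", {
  # single outcome: probability 1
  expect_equal(dm_log_likelihood(5, 2.3), 0)
  # uniform prior symmetry
  expect_equal(exp(dm_log_likelihood(c(1, 0), c(1, 1))), 1 / 2, tolerance = 1e-12)
  expect_equal(exp(dm_log_likelihood(c(2, 0), c(1, 1))), 1 / 3, tolerance = 1e-12)
  # normalisation over all compositions at n = 2, J = 2, alpha = (1, 1)
  probs2 <- vapply(0:2, function(x1) {
    exp(dm_log_likelihood(c(x1, 2 - x1), c(1, 1)))
  }, numeric(1))
  expect_equal(sum(probs2), 1, tolerance = 1e-12)

  expect_error(dm_log_likelihood(c(1, 0), c(1, -1)), "positive")
  expect_error(dm_log_likelihood(c(-1, 0), c(1, 1)), "non-negative")
  expect_error(dm_log_likelihood(c(1, 0, 0), c(1, 1)), "equal length")
})

test_that("exhaustive enumeration sums to one for random alphas", {
  withr::local_seed(17)
  for (rep in 1:5) {
    alpha <- rgamma(3, 2) + 0.1
    for (n in 1:4) {
      comps <- all_compositions(n, 3)
      total <- sum(apply(comps, 1, function(x) exp(dm_log_likelihood(x, alpha))))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("a k = 1 fit collapses to the single-component ML estimate", {
  sim <- simulate_dmm_counts(1, 1, rbind(c(5, 3, 2, 1)), n_samples = 50,
                             depth = 400, seed = 5)
  fit <- fit_dmm(sim$counts, k = 1, seed = 1, n_restarts = 1)
  expect_true(fit$converged)
  expect_equal(fit$pi, 1)
  expect_true(all(abs(fit$z - 1) < 1e-12))
  # the fitted expected proportions should be close to the generating ones
  ep <- fit$alpha[1, ] / sum(fit$alpha)
  expect_lt(max(abs(ep - c(5, 3, 2, 1) / 11)), 0.05)
})

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  sim <- simulate_dmm_counts(2, c(0.5, 0.5),
                             rbind(c(10, 1, 1, 1), c(1, 10, 1, 1)),
                             n_samples = 80, depth = 500, seed = 6)
  fit <- fit_dmm(sim$counts, k = 2, seed = 2, n_restarts = 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("fits are equivariant under taxon column permutation", {
  sim <- simulate_dmm_counts(2, c(0.5, 0.5),
                             rbind(c(10, 1, 1, 1), c(1, 10, 1, 1)),
                             n_samples = 60, depth = 500, seed = 7)
  fit <- fit_dmm(sim$counts, k = 2, seed = 3, n_restarts = 1)
  perm <- c(3, 1, 4, 2)
  fit_p <- fit_dmm(sim$counts[, perm], k = 2, seed = 3, n_restarts = 1)
  expect_equal(unname(fit_p$alpha), unname(fit$alpha[, perm]), tolerance = 1e-3)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("select_k reports the whole criterion curve and handles degeneracy", {
  sim <- simulate_dmm_counts(1, 1, rbind(c(6, 3, 1)), n_samples = 40,
                             depth = 300, seed = 8)
  best <- select_k(sim$counts, k_range = 1:3, seed = 1, n_restarts = 1)
  expect_equal(nrow(best$criterion_curve), 3)
  expect_equal(best$k, 1)

  # identical compositions: no mixture support, k = 1 wins
  x <- matrix(rep(c(500L, 300L, 200L), each = 30), 30, 3)
  rownames(x) <- paste0("s", 1:30)
  colnames(x) <- paste0("t", 1:3)
  best_id <- select_k(x, k_range = 1:3, seed = 2, n_restarts = 1)
  expect_equal(best_id$k, 1)
})

test_that("type assignment is argmax with ties going to the lower index", {
  fit <- structure(list(
    k = 2,
    z = rbind(s1 = c(0.9, 0.1), s2 = c(0.5, 0.5)),
    alpha = matrix(1, 2, 3, dimnames = list(c("type_1", "type_2"),
                                            c("a", "b", "c"))),
    pi = c(0.5, 0.5)
  ), class = "dmm_fit")
  types <- suppressWarnings(assign_types(fit))
  expect_equal(types$type, c(1L, 1L))
  expect_equal(types$posterior[1], 0.9)
  expect_true(types$tied[2])
  expect_false(types$tied[1])
})

test_that("congruence chi-square matches hand computation", {
  # [[10, 0], [0, 10]]: expected 5 per cell, chi-square = 20, df = 1
  res <- congruence_test(rep(1:2, each = 10), rep(c("x", "y"), each = 10))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)

  # identical type proportions per level -> statistic 0
  types <- rep(c(1, 2), 10)
  groups <- rep(c("x", "y"), each = 10)
  res0 <- congruence_test(types, groups)
  expect_equal(res0$statistic, 0)

  expect_error(congruence_test(rep(1, 10), rep(c("x", "y"), 5)), "two levels")
})

test_that("driver taxa rank by fitted expected proportion", {
  sim <- simulate_dmm_counts(2, c(0.5, 0.5),
                             rbind(c(20, 5, 1, 1), c(1, 1, 20, 5)),
                             n_samples = 100, depth = 800, seed = 9)
  fit <- fit_dmm(sim$counts, k = 2, seed = 4, n_restarts = 2)
  drivers <- top_drivers(fit, n = 2)
  # component-wise driver order should match the generating alphas
  # (components are weight-ordered, so match them to truth by top taxon)
  for (kk in 1:2) {
    top <- drivers$taxon[drivers$type == kk & drivers$rank == 1]
    second <- drivers$taxon[drivers$type == kk & drivers$rank == 2]
    truth_row <- if (top == "taxon_01") c(1, 2) else c(3, 4)
    expect_equal(top, colnames(sim$counts)[truth_row[1]])
    expect_equal(second, colnames(sim$counts)[truth_row[2]])
  }
})

test_that("tidy and glance expose the fit in broom style", {
  sim <- simulate_dmm_counts(1, 1, rbind(c(4, 2, 1)), n_samples = 30,
                             depth = 200, seed = 10)
  fit <- fit_dmm(sim$counts, k = 1, seed = 1, n_restarts = 1)
  td <- tidy(fit)
  expect_setequal(names(td), c("type", "weight", "taxon", "alpha",
                               "expected_proportion"))
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$expected_proportion), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$k, 1)
  expect_true(all(c("laplace", "bic", "aic") %in% names(gl)))
})
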
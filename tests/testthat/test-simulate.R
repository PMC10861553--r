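# The synthetic-data generators: determinism, construction guarantees, and
# round-trip recovery of planted truth.

test_that("all generators are pure functions of (parameters, seed)", {
  expect_identical(simulate_ko_matrix(2, 5, 30, 10, 0.1, seed = 3),
                   simulate_ko_matrix(2, 5, 30, 10, 0.1, seed = 3))
  expect_identical(
    simulate_dmm_counts(2, c(0.4, 0.6), rbind(c(5, 1), c(1, 5)), 20, 100, seed = 4),
    simulate_dmm_counts(2, c(0.4, 0.6), rbind(c(5, 1), c(1, 5)), 20, 100, seed = 4)
  )
  expect_identical(simulate_contaminated_community(n_samples = 10, seed = 5),
                   simulate_contaminated_community(n_samples = 10, seed = 5))
  s <- random_16s(1, 60, seed = 6)
  expect_identical(s, random_16s(1, 60, seed = 6))
  expect_identical(mutate_16s(s[[1]], 3, seed = 7), mutate_16s(s[[1]], 3, seed = 7))
  # different seeds give different draws
  expect_false(identical(random_16s(1, 60, seed = 6), random_16s(1, 60, seed = 8)))
})

test_that("substream seeds are stable, name-dependent and in range", {
  expect_identical(substream_seed(1, "a"), substream_seed(1, "a"))
  expect_false(substream_seed(1, "a") == substream_seed(1, "b"))
  expect_false(substream_seed(1, "a") == substream_seed(2, "a"))
  seeds <- vapply(1:50, function(s) substream_seed(s, "generator"), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
})

test_that("noiseless KO signatures are cluster-pure and separate blocks", {
  sim <- simulate_ko_matrix(n_clusters = 3, isolates_per_cluster = 10,
                            n_background_kos = 100, signature_size = 30,
                            flip_rate = 0, seed = 9)
  m <- unclass(sim$matrix)
  labels <- sim$truth$labels$cluster
  for (k in 1:3) {
    sig <- sim$truth$signature_kos[[k]]
    expect_true(all(m[labels == k, sig] == 1))
    expect_true(all(m[labels != k, sig] == 0))
  }
  # between-cluster distances exceed within-cluster by ~2 * signature_size
  d <- as.matrix(ko_distance(sim$matrix))
  within <- d[labels == 1, labels == 1][upper.tri(diag(10))]
  between <- d[labels == 1, labels == 2]
  expect_gte(min(between) - max(within), 0)
  expect_gt(mean(between) - mean(within), 2 * 30 * 0.8)

  expect_error(simulate_ko_matrix(flip_rate = 0.6), "flip_rate")
  expect_error(simulate_ko_matrix(isolates_per_cluster = c(3, 3)),
               "length 1 or")
})

test_that("uneven cluster sizes are honoured", {
  sim <- simulate_ko_matrix(n_clusters = 3, isolates_per_cluster = c(8, 5, 3),
                            n_background_kos = 20, signature_size = 5,
                            flip_rate = 0, seed = 10)
  expect_equal(as.integer(table(sim$truth$labels$cluster)), c(8, 5, 3))
  expect_equal(nrow(sim$matrix), 16)
})

test_that("k = 1 Dirichlet(1,...,1) draws approach uniform mean proportions", {
  J <- 5
  sim <- simulate_dmm_counts(1, 1, rbind(rep(1, J)), n_samples = 500,
                             depth = 2000, seed = 11)
  props <- sim$counts / rowSums(sim$counts)
  # mean proportion per taxon ~ 1/J; SE of the mean of a Dirichlet(1) marginal
  se <- sqrt((1 / J) * (1 - 1 / J) / (J + 1)) / sqrt(500)
  expect_true(all(abs(colMeans(props) - 1 / J) < 3 * se))

  expect_error(simulate_dmm_counts(2, c(0.7, 0.7), rbind(c(1, 1), c(1, 1)), 10),
               "sum to 1")
  expect_error(simulate_dmm_counts(1, 1, rbind(c(-1, 1)), 10), "positive")
})

test_that("the contamination model plants a strong negative rank correlation", {
  cc <- simulate_contaminated_community(n_samples = 60, biomass_range = 100,
                                        seed = 12)
  rel <- cc$counts / rowSums(cc$counts)
  rho <- suppressWarnings(
    cor(rel[, "contaminant_1"], cc$metadata$biomass, method = "spearman"))
  expect_lte(rho, -0.8)

  expect_error(simulate_contaminated_community(biomass_range = 1), "exceed 1")
})

test_that("without contaminant input the flagging rule stays quiet", {
  false_positives <- vapply(1:100, function(s) {
    cc <- simulate_contaminated_community(n_samples = 30, n_otus = 15,
                                          contaminant_input = 0, seed = s)
    flags <- flag_biomass_contaminants(cc$counts, cc$metadata$biomass)
    any(flags$contaminant)
  }, logical(1))
  expect_gte(mean(!false_positives), 0.95)
})

test_that("mutation counts translate exactly into identity", {
  s <- random_16s(1, 250, seed = 13)[[1]]
  expect_identical(mutate_16s(s, 0, seed = 1), s)
  m <- mutate_16s(s, 5, seed = 14)
  expect_equal(sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]]), 5)
  expect_error(mutate_16s(s, 251, seed = 1), "more substitutions")
})

test_that("airway cohort samples share types within donors", {
  cohort <- simulate_airway_cohort(n_samples = 60, seed = 15)
  expect_equal(nrow(cohort$counts), 60)
  joined <- dplyr::inner_join(cohort$metadata, cohort$truth$labels, by = "sample")
  per_donor <- tapply(joined$component, joined$donor, function(x) length(unique(x)))
  expect_true(all(per_donor == 1))
  expect_setequal(unique(cohort$metadata$site), c("ptOP", "LLL", "LUL"))
})

test_that("the adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::local_seed(30)
  for (rep in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 5:1), 1) # both all-singletons
})
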
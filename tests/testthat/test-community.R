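# OTU filtering, contaminant flagging, rarefaction and diversity.

test_that("low-count/low-prevalence OTUs are removed at the stated thresholds", {
  counts <- matrix(0L, 100, 4,
                   dimnames = list(sprintf("s%03d", 1:100),
                                   c("rare19", "rare1sample", "common", "boundary20")))
  counts[1:19, "rare19"] <- 1L          # total 19 < 20 -> removed
  counts[1, "rare1sample"] <- 100L      # 1% prevalence < 2% -> removed
  counts[, "common"] <- 10L             # everywhere -> kept
  counts[1:10, "boundary20"] <- 2L      # total 20, prevalence 10% -> kept
  res <- filter_low_count_otus(counts)
  expect_setequal(colnames(res$counts), c("common", "boundary20"))
  expect_setequal(res$removed$otu, c("rare19", "rare1sample"))

  # planted rare OTUs are exactly the ones removed
  withr::local_seed(21)
  base <- matrix(rpois(100 * 30, 30), 100, 30)
  rare <- matrix(0L, 100, 10)
  for (j in 1:10) rare[sample(100, 3), j] <- 5L # totals 15 < 20
  m <- cbind(base, rare)
  colnames(m) <- c(sprintf("otu%02d", 1:30), sprintf("rare%02d", 1:10))
  rownames(m) <- sprintf("s%03d", 1:100)
  res2 <- filter_low_count_otus(m)
  expect_setequal(res2$removed$otu, sprintf("rare%02d", 1:10))

  expect_error(filter_low_count_otus(m, min_total_reads = -1), "non-negative")
})

test_that("Benjamini-Hochberg adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # monotone in sorted order, never below the raw p, capped at 1
  withr::local_seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12 & adj <= 1))
  # a flat tie block is a fixed point of the adjustment
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("constant-input contaminants are flagged and genuine taxa are not", {
  cc <- simulate_contaminated_community(n_samples = 60, biomass_range = 100,
                                        seed = 4)
  flags <- flag_biomass_contaminants(cc$counts, cc$metadata$biomass)
  expect_true(flags$contaminant[flags$otu == "contaminant_1"])
  expect_lte(flags$rho[flags$otu == "contaminant_1"], -0.8)
  # genuine taxa keep near-zero correlations; none should be flagged here
  genuine <- flags[flags$otu != "contaminant_1", ]
  expect_false(any(genuine$contaminant))

  expect_error(
    flag_biomass_contaminants(cc$counts, rep(1e6, 60)),
    "constant"
  )
})

test_that("a perfectly monotone decreasing abundance gives rho = -1", {
  n <- 12
  biomass <- 2^(1:n) # no ties
  counts <- cbind(
    target = seq(1200, 100, length.out = n),
    filler = rep(1000, n)
  )
  rownames(counts) <- sprintf("s%02d", 1:n)
  flags <- flag_biomass_contaminants(counts, biomass, rho_threshold = 0.2)
  expect_equal(flags$rho[flags$otu == "target"], -1)
  expect_true(flags$contaminant[flags$otu == "target"])
})

test_that("rarefaction conserves totals and matches the hypergeometric mean", {
  counts <- rbind(
    keep1 = c(800L, 200L),
    keep2 = c(150L, 50L),
    tiny = c(5L, 3L)
  )
  colnames(counts) <- c("otu1", "otu2")
  res <- rarefy_counts(counts, depth = "min", seed = 1, min_sample_reads = 100)
  expect_equal(res$discarded, "tiny")
  expect_equal(res$depth, 200L)
  expect_true(all(rowSums(res$counts) == 200))

  # a sample whose total equals the depth is unchanged
  res2 <- rarefy_counts(counts[1:2, ], depth = 200, seed = 2,
                        min_sample_reads = 100)
  expect_equal(res2$counts["keep2", ], c(otu1 = 150L, otu2 = 50L))

  # hypergeometric expectation: (800, 200) rarefied to 100 -> mean 80
  draws <- vapply(1:1000, function(s) {
    rarefy_counts(matrix(c(800L, 200L), 1, dimnames = list("s", c("a", "b"))),
                  depth = 100, seed = s, min_sample_reads = 1)$counts[1, "a"]
  }, numeric(1))
  se <- sqrt(100 * 0.8 * 0.2 * (1000 - 100) / (1000 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - 80), 3 * se)

  expect_error(rarefy_counts(counts, depth = 0, min_sample_reads = 1), "positive")
  expect_error(rarefy_counts(counts, depth = 1e6, min_sample_reads = 1), "exceeds")
})

test_that("alpha diversity matches the closed-form values", {
  counts <- rbind(
    uniform4 = c(25, 25, 25, 25),
    single = c(40, 0, 0, 0),
    skew = c(50, 25, 25, 0)
  )
  colnames(counts) <- paste0("otu", 1:4)
  div <- alpha_diversity(counts)
  expect_equal(div$shannon[div$sample == "uniform4"], log(4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(div$richness[div$sample == "uniform4"], 4L)
  expect_equal(div$evenness[div$sample == "uniform4"], 1, tolerance = 1e-12)

  expect_equal(div$shannon[div$sample == "single"], 0)
  expect_equal(div$richness[div$sample == "single"], 1L)
  expect_true(is.na(div$evenness[div$sample == "single"]))

  expect_equal(div$shannon[div$sample == "skew"], 1.0397, tolerance = 1e-4)
  expect_equal(div$shannon[div$sample == "skew"],
               oracle_shannon(c(0.5, 0.25, 0.25)), tolerance = 1e-12)

  expect_error(alpha_diversity(rbind(c(0, 0))), "all-zero")
})

test_that("Bray-Curtis takes its closed-form values and stays in [0, 1]", {
  counts <- rbind(x = c(6, 2, 0), y = c(2, 2, 0), same = c(6, 2, 0),
                  disjoint = c(0, 0, 5))
  colnames(counts) <- c("a", "b", "c")
  d <- as.matrix(bray_curtis(counts, transform = "none"))
  expect_equal(d["x", "y"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["x", "same"], 0)
  expect_equal(d["disjoint", "x"], 1)

  withr::local_seed(14)
  m <- matrix(rpois(20 * 10, 5) + 1, 20, 10)
  rownames(m) <- paste0("s", 1:20)
  dr <- bray_curtis(m)
  expect_true(all(dr >= 0 & dr <= 1))
  expect_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "zero-sum")
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # all-zero distances -> all-zero coordinates
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  p0 <- suppressWarnings(pcoa(d0))
  expect_true(all(abs(as.matrix(p0$coordinates[, -1])) < 1e-10))

  # three collinear points: one positive eigenvalue, unit spacing on axis 1
  d3 <- matrix(c(0, 1, 2,
                 1, 0, 1,
                 2, 1, 0), 3, 3, dimnames = list(1:3, 1:3))
  p3 <- suppressWarnings(pcoa(d3, n_axes = 2))
  expect_equal(sum(p3$eigenvalues > 1e-8), 1)
  ax1 <- sort(p3$coordinates$axis_1)
  expect_equal(diff(ax1), c(1, 1), tolerance = 1e-8)

  # Euclidean round trip for random 2-D points
  withr::local_seed(31)
  pts <- matrix(runif(16), 8, 2)
  d <- dist(pts)
  pr <- pcoa(d, n_axes = 2)
  rec <- as.matrix(pr$coordinates[, c("axis_1", "axis_2")])
  expect_equal(as.matrix(dist(rec)), as.matrix(d), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("PERMANOVA separates planted groups and respects invariances", {
  withr::local_seed(8)
  g1 <- matrix(rpois(10 * 6, c(50, 5, 5, 5, 5, 5)), 10, 6, byrow = TRUE)
  g2 <- matrix(rpois(10 * 6, c(5, 50, 5, 5, 5, 5)), 10, 6, byrow = TRUE)
  m <- rbind(g1, g2)
  rownames(m) <- paste0("s", 1:20)
  groups <- rep(c("a", "b"), each = 10)
  d <- bray_curtis(m)
  res <- permanova(d, groups, n_perm = 99, seed = 1)
  expect_equal(res$p_value, 0.01) # minimum attainable with 99 permutations

  # permuting samples and labels together leaves F unchanged
  perm <- sample(20)
  dm <- as.matrix(d)[perm, perm]
  res_perm <- permanova(as.dist(dm), groups[perm], n_perm = 99, seed = 1)
  expect_equal(res_perm$pseudo_f, res$pseudo_f, tolerance = 1e-12)

  expect_error(permanova(d, rep("a", 20)), "two groups")
  expect_error(permanova(d, c("b", rep("a", 19))), "at least two samples")
})
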
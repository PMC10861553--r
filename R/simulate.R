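# Seeded synthetic-data generators with known ground truth for every
# pipeline stage. Each generator draws from its own named substream of the
# master seed (see substream_seed()), so outputs are exactly reproducible
# and adding a generator never perturbs another's draws.

#' Simulate a binary KO matrix with planted isolate clusters
#'
#' Background KOs are present independently with probability 0.5; each
#' cluster additionally carries a disjoint block of signature KOs present
#' only in its members. Every cell is then flipped independently with
#' probability `flip_rate` (annotation noise).
#'
#' @param n_clusters Number of planted clusters.
#' @param isolates_per_cluster Scalar, or vector of per-cluster sizes.
#' @param n_background_kos Number of unstructured background KOs.
#' @param signature_size Signature KOs per cluster.
#' @param flip_rate Per-cell flip probability in `[0, 0.5)`.
#' @param seed Master seed.
#' @return A list with `matrix` (a [ko_matrix()]) and `truth` (list with
#'   `labels` tibble, `signature_kos`, `flip_rate`, `seed`).
#' @export
simulate_ko_matrix <- function(n_clusters = 3, isolates_per_cluster = 10,
                               n_background_kos = 100, signature_size = 30,
                               flip_rate = 0, seed = 1) {
  if (n_clusters < 1 || n_background_kos < 0 || signature_size < 0) {
    abort("simulation sizes must be positive")
  }
  if (flip_rate < 0 || flip_rate >= 0.5) abort("`flip_rate` must be in [0, 0.5)")
  sizes <- if (length(isolates_per_cluster) == 1) {
    rep(isolates_per_cluster, n_clusters)
  } else {
    if (length(isolates_per_cluster) != n_clusters) {
      abort("`isolates_per_cluster` must have length 1 or `n_clusters`")
    }
    isolates_per_cluster
  }
  n <- sum(sizes)
  labels <- rep(seq_len(n_clusters), sizes)
  m <- with_seed(substream_seed(seed, "ko_matrix"), {
    bg <- matrix(rbinom(n * n_background_kos, 1, 0.5), n, n_background_kos)
    if (signature_size > 0) {
      sig <- matrix(0L, n, n_clusters * signature_size)
      for (k in seq_len(n_clusters)) {
        cols <- ((k - 1) * signature_size + 1):(k * signature_size)
        sig[labels == k, cols] <- 1L
      }
      full <- cbind(bg, sig)
    } else {
      full <- bg
    }
    if (flip_rate > 0) {
      full <- abs(full - matrix(rbinom(length(full), 1, flip_rate), nrow(full)))
    }
    full
  })
  iso_ids <- sprintf("iso_%03d", seq_len(n))
  ko_ids <- sprintf("K%05d", seq_len(ncol(m)))
  dimnames(m) <- list(iso_ids, ko_ids)
  sig_kos <- if (signature_size > 0) {
    lapply(seq_len(n_clusters), function(k) {
      ko_ids[n_background_kos + ((k - 1) * signature_size + 1):(k * signature_size)]
    })
  } else {
    list()
  }
  list(
    matrix = ko_matrix(m),
    truth = list(
      labels = tibble::tibble(isolate = iso_ids, cluster = labels),
      signature_kos = sig_kos,
      flip_rate = flip_rate,
      seed = seed
    )
  )
}

#' Simulate counts from a Dirichlet-multinomial mixture
#'
#' Per sample: a component is drawn from `pi`, taxon proportions from
#' `Dirichlet(alpha[component, ])`, and counts from
#' `Multinomial(depth, proportions)`. Depth is either fixed or drawn
#' log-uniformly from a range.
#'
#' @param k Number of components.
#' @param pi Mixture weights (length `k`, summing to 1).
#' @param alpha `k` x J matrix of positive Dirichlet parameters.
#' @param n_samples Number of samples.
#' @param depth Fixed sequencing depth, or a length-2 vector giving a
#'   log-uniform depth range.
#' @param seed Master seed.
#' @return A list with `counts` (samples x taxa integer matrix) and `truth`
#'   (list with `labels`, `pi`, `alpha`, `seed`).
#' @export
simulate_dmm_counts <- function(k, pi, alpha, n_samples, depth = 1000, seed = 1) {
  if (length(pi) != k || abs(sum(pi) - 1) > 1e-8 || any(pi <= 0)) {
    abort("`pi` must be positive and sum to 1")
  }
  alpha <- rbind(alpha)
  if (nrow(alpha) != k || any(alpha <= 0)) abort("`alpha` must be k x J and positive")
  J <- ncol(alpha)
  out <- with_seed(substream_seed(seed, "dmm_counts"), {
    labels <- sample.int(k, n_samples, replace = TRUE, prob = pi)
    depths <- if (length(depth) == 2) {
      round(exp(runif(n_samples, log(depth[1]), log(depth[2]))))
    } else {
      rep(depth, n_samples)
    }
    counts <- t(vapply(seq_len(n_samples), function(s) {
      g <- rgamma(J, alpha[labels[s], ])
      as.numeric(rmultinom(1, depths[s], g / sum(g)))
    }, numeric(J)))
    list(labels = labels, counts = counts)
  })
  counts <- out$counts
  storage.mode(counts) <- "integer"
  taxa <- colnames(alpha) %||% sprintf("taxon_%02d", seq_len(J))
  dimnames(counts) <- list(sprintf("sample_%04d", seq_len(n_samples)), taxa)
  list(
    counts = counts,
    truth = list(
      labels = tibble::tibble(sample = rownames(counts), component = out$labels),
      pi = pi, alpha = alpha, seed = seed
    )
  )
}

#' Canonical two-type genus profiles for airway cohort simulations
#'
#' Dirichlet parameters for two community types sharing their two dominant
#' genera but differing in the third driver, mirroring the structure of
#' airway community types in which one type carries an anaerobe-leaning
#' third driver and the other a proteobacterial one. Taxa are named
#' generically (`genus_01`...), with the four drivers first.
#'
#' @param n_taxa Total number of genus bins (>= 6).
#' @param theta Dirichlet precision (sum of alpha) per type.
#' @return A 2 x `n_taxa` matrix of Dirichlet parameters.
#' @export
airway_type_profiles <- function(n_taxa = 20, theta = 50) {
  if (n_taxa < 6) abort("need at least 6 taxa")
  minor <- rep(0.5, n_taxa - 4)
  p1 <- c(10, 8, 5, 0.5, minor)   # type 1: drivers g1, g2, g3
  p2 <- c(10, 8, 0.5, 5, minor)   # type 2: drivers g1, g2, g4
  p1 <- p1 / sum(p1)
  p2 <- p2 / sum(p2)
  a <- rbind(p1, p2) * theta
  dimnames(a) <- list(c("type_1", "type_2"), sprintf("genus_%02d", seq_len(n_taxa)))
  a
}

#' Simulate an airway-style cohort with two community types
#'
#' Donors each contribute one to three samples (emulating one throat swab
#' plus up to two bronchial brushings); all samples of a donor share the
#' donor's latent community type, so type assignment should be congruent
#' with donor. Counts are drawn from the two-type Dirichlet-multinomial of
#' [airway_type_profiles()].
#'
#' @param n_samples Target number of samples.
#' @param pi Type weights over donors.
#' @param n_taxa,theta Passed to [airway_type_profiles()].
#' @param depth Sequencing depth (fixed, or length-2 log-uniform range).
#' @param seed Master seed.
#' @return A list with `counts`, `metadata` (tibble `sample`, `donor`,
#'   `site`), and `truth` (per-sample component labels and parameters).
#' @export
simulate_airway_cohort <- function(n_samples = 888, pi = c(410, 478) / 888,
                                   n_taxa = 20, theta = 50,
                                   depth = c(2000, 20000), seed = 1) {
  alpha <- airway_type_profiles(n_taxa, theta)
  plan <- with_seed(substream_seed(seed, "cohort_plan"), {
    per_donor <- integer(0)
    while (sum(per_donor) < n_samples) {
      per_donor <- c(per_donor, sample(1:3, 1))
    }
    per_donor[length(per_donor)] <- per_donor[length(per_donor)] -
      (sum(per_donor) - n_samples)
    donor_type <- sample.int(2, length(per_donor), replace = TRUE, prob = pi)
    list(per_donor = per_donor, donor_type = donor_type)
  })
  labels <- rep(plan$donor_type, plan$per_donor)
  donors <- rep(sprintf("donor_%03d", seq_along(plan$per_donor)), plan$per_donor)
  sites <- unlist(lapply(plan$per_donor, function(ns) c("ptOP", "LLL", "LUL")[seq_len(ns)]))
  counts <- with_seed(substream_seed(seed, "cohort_counts"), {
    depths <- if (length(depth) == 2) {
      round(exp(runif(n_samples, log(depth[1]), log(depth[2]))))
    } else {
      rep(depth, n_samples)
    }
    t(vapply(seq_len(n_samples), function(s) {
      g <- rgamma(ncol(alpha), alpha[labels[s], ])
      as.numeric(rmultinom(1, depths[s], g / sum(g)))
    }, numeric(ncol(alpha))))
  })
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sprintf("sample_%04d", seq_len(n_samples)), colnames(alpha))
  list(
    counts = counts,
    metadata = tibble::tibble(sample = rownames(counts), donor = donors, site = sites),
    truth = list(labels = tibble::tibble(sample = rownames(counts), component = labels),
                 pi = pi, alpha = alpha, seed = seed)
  )
}

#' Simulate a low-biomass community with a constant-input contaminant
#'
#' True community DNA scales with per-sample biomass (log-uniform over a
#' `biomass_range`-fold gradient), while the contaminant contributes a
#' constant absolute input. The contaminant's expected share of reads in
#' sample s is therefore `c / (c + biomass_s)`, falling as biomass rises -
#' the signature the biomass-correlation contaminant rule detects.
#'
#' @param n_samples Number of samples.
#' @param n_otus Number of genuine OTUs.
#' @param contaminant_input Constant absolute contaminant input, on the
#'   same scale as biomass (16S copies).
#' @param biomass_min Smallest biomass; the largest is
#'   `biomass_min * biomass_range`.
#' @param biomass_range Fold range of the biomass gradient (> 1).
#' @param depth Sequencing depth per sample (independent of biomass).
#' @param base_alpha Dirichlet parameters of the genuine community
#'   (default: mild realistic unevenness).
#' @param seed Master seed.
#' @return A list with `counts` (samples x OTUs, contaminant in column
#'   `contaminant_1`), `metadata` (tibble `sample`, `biomass`,
#'   `sample_class`), and `truth`.
#' @export
simulate_contaminated_community <- function(n_samples = 60, n_otus = 30,
                                            contaminant_input = 1e4,
                                            biomass_min = 1e5,
                                            biomass_range = 100,
                                            depth = 20000,
                                            base_alpha = NULL,
                                            seed = 1) {
  if (biomass_range <= 1) abort("`biomass_range` must exceed 1")
  if (contaminant_input < 0 || biomass_min <= 0 || depth <= 0) {
    abort("inputs must be positive")
  }
  base_alpha <- base_alpha %||% (c(10, 8, 5, 3, rep(0.8, n_otus - 4)) / 2)
  if (length(base_alpha) != n_otus) abort("`base_alpha` must have length `n_otus`")
  out <- with_seed(substream_seed(seed, "contaminated_community"), {
    biomass <- exp(runif(n_samples, log(biomass_min),
                         log(biomass_min * biomass_range)))
    counts <- t(vapply(seq_len(n_samples), function(s) {
      g <- rgamma(n_otus, base_alpha)
      p_true <- g / sum(g)
      f <- contaminant_input / (contaminant_input + biomass[s])
      as.numeric(rmultinom(1, depth, c((1 - f) * p_true, f)))
    }, numeric(n_otus + 1)))
    list(biomass = biomass, counts = counts)
  })
  counts <- out$counts
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                           c(sprintf("otu_%03d", seq_len(n_otus)), "contaminant_1"))
  list(
    counts = counts,
    metadata = tibble::tibble(sample = rownames(counts),
                              biomass = out$biomass,
                              sample_class = "sample"),
    truth = list(contaminant = "contaminant_1",
                 contaminant_input = contaminant_input, seed = seed)
  )
}

#' Random 16S-like sequences
#'
#' Uniform random sequences over `{A,C,G,T}`; no attempt is made to mimic
#' real 16S phylogenetic structure - divergence between sequences is
#' planted explicitly with [mutate_16s()].
#'
#' @param n_seqs Number of sequences.
#' @param length Sequence length (V4 amplicon scale by default).
#' @param seed Master seed.
#' @param prefix Name prefix.
#' @return A named character vector.
#' @export
random_16s <- function(n_seqs = 1, length = 250, seed = 1, prefix = "seq") {
  if (length < 1) abort("`length` must be positive")
  seqs <- with_seed(substream_seed(seed, "random_16s"), {
    vapply(seq_len(n_seqs), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, character(1))
  })
  setNames(seqs, sprintf("%s_%02d", prefix, seq_len(n_seqs)))
}

#' Substitute a fixed number of bases in a sequence
#'
#' Exactly `n_substitutions` distinct positions are changed to a different
#' base, so the identity of the mutant to its parent is exactly
#' `(L - n) / L * 100` (no indels are introduced).
#'
#' @param seq A single sequence (character scalar over `{A,C,G,T,N}`).
#' @param n_substitutions Number of positions to substitute.
#' @param seed Master seed.
#' @return The mutated sequence (character scalar).
#' @export
mutate_16s <- function(seq, n_substitutions, seed = 1) {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(seq, "")[[1]]
  if (n_substitutions > length(chars)) abort("more substitutions than positions")
  if (n_substitutions == 0) return(seq)
  with_seed(substream_seed(seed, "mutate_16s"), {
    pos <- sample(length(chars), n_substitutions)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  })
  paste(chars, collapse = "")
}
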
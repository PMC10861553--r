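# Isolate clustering: Manhattan distances on binary KO profiles, complete
# linkage, and an adaptive (dynamic-tree-cut style) extraction of clusters
# from the dendrogram.

#' Manhattan distance between isolate KO profiles
#'
#' For binary profiles the Manhattan distance equals the Hamming distance:
#' the number of KO columns on which two isolates disagree.
#'
#' @param m A [ko_matrix()] with at least two isolates.
#' @return A [stats::dist] object.
#' @export
ko_distance <- function(m) {
  stopifnot(inherits(m, "ko_matrix"))
  if (nrow(m) < 2) abort("need at least two isolates to compute distances")
  dist(unclass(m), method = "manhattan")
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the maximum pairwise distance between their members; merge heights are
#' therefore non-decreasing.
#'
#' @param d A [stats::dist] object or a symmetric non-negative matrix with a
#'   zero diagonal.
#' @return A [stats::hclust] tree.
#' @export
complete_linkage <- function(d) {
  d <- validate_distance(d)
  hclust(d, method = "complete")
}

validate_distance <- function(d) {
  if (inherits(d, "dist")) {
    if (any(d < 0)) abort("distances must be non-negative")
    return(d)
  }
  if (!is.matrix(d)) abort("`d` must be a dist object or matrix")
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    abort("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) abort("distance matrix must have a zero diagonal")
  if (any(d < 0)) abort("distances must be non-negative")
  as.dist(d)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are differences between successive merge heights, so leaf
#' depth equals the height at which each isolate was absorbed.
#'
#' @param hc A [stats::hclust] tree.
#' @param path Optional file path; when given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the ape package is required for Newick export")
  }
  tr <- ape::as.phylo(hc)
  txt <- ape::write.tree(tr)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# deep-split level -> criterion constants (0 = most conservative splitting,
# 4 = most aggressive). Scatter/gap fractions follow the usual dynamic
# tree-cut interpolation between the 5th-percentile and maximum merge
# heights; the separation z-score floor is this implementation's own
# addition (see the methods vignette).
cut_params <- function(deep_split, heights, cut_height) {
  stopifnot(deep_split %in% 0:4)
  ref_height <- unname(quantile(heights, 0.05))
  mcs_frac <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  list(
    ref_height = ref_height,
    max_abs_scatter = ref_height + mcs_frac * (cut_height - ref_height),
    min_abs_gap = (1 - mcs_frac) * 3 / 4 * (cut_height - ref_height),
    sep_min = c(5, 4.25, 3.5, 2.75, 2)[deep_split + 1]
  )
}

#' Adaptive cluster extraction from a complete-linkage dendrogram
#'
#' A dynamic-hybrid-style tree cut: instead of slicing the dendrogram at one
#' fixed height, branches are examined bottom-up and declared clusters when
#' they are large enough, internally cohesive, and clearly separated from
#' the branch they merge with. Members of small branches that never qualify
#' are assigned to the nearest cluster when they fall within its radius and
#' are otherwise left unassigned (label 0).
#'
#' A branch merging at height h qualifies as a cluster when
#' (i) it has at least `min_cluster_size` members,
#' (ii) its core scatter (mean attachment height of its earliest-joining
#' core) stays below a deep-split-dependent ceiling,
#' (iii) the gap `h - r` above its own root height r exceeds a
#' deep-split-dependent floor, and
#' (iv) the separation z-score between the two merging branches,
#' `(mean between-branch distance - mean within-branch distance) / sd(within)`,
#' exceeds a deep-split-dependent threshold. The z-score is invariant to
#' additive offsets in the distances, which keeps the criterion usable when
#' profiles share a large common background.
#'
#' @param hc A [stats::hclust] tree built from `d`.
#' @param d The distance object or matrix the tree was built from.
#' @param min_cluster_size Minimum number of members for a cluster.
#' @param deep_split Integer 0-4; larger values split more finely.
#' @param cut_height Merges above this height are never performed; defaults
#'   to the maximum merge height (the whole tree is considered).
#' @return A tibble with columns `isolate` and `cluster` (integer labels,
#'   numbered by decreasing cluster size, 0 = unassigned).
#' @export
cut_tree_dynamic <- function(hc, d, min_cluster_size = 3, deep_split = 2,
                             cut_height = NULL) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  if (min_cluster_size > n) abort("`min_cluster_size` exceeds the number of objects")
  dm <- as.matrix(d)
  if (nrow(dm) != n) abort("`d` does not match the tree")
  heights <- hc$height
  merge <- hc$merge
  cut_height <- cut_height %||% max(heights)
  par <- cut_params(deep_split, heights, cut_height)

  new_branch <- function(members, attach, root) {
    list(members = members, attach = attach, root = root,
         composite = FALSE, clusters = list(), loose = integer(0))
  }
  core_scatter <- function(b) {
    sz <- length(b$members)
    core <- min(sz, min_cluster_size + floor(sqrt(max(0, sz - min_cluster_size))))
    mean(sort(b$attach)[seq_len(core)])
  }
  is_candidate <- function(b, h) {
    if (b$composite) return(FALSE)
    if (length(b$members) < min_cluster_size) return(FALSE)
    if (core_scatter(b) > par$max_abs_scatter) return(FALSE)
    h - b$root >= par$min_abs_gap
  }
  # separation z-score of the two-group partition {m1, m2}
  split_sep <- function(m1, m2) {
    btw <- dm[m1, m2, drop = FALSE]
    win <- c(
      if (length(m1) > 1) dm[m1, m1][lower.tri(diag(length(m1)))],
      if (length(m2) > 1) dm[m2, m2][lower.tri(diag(length(m2)))]
    )
    if (length(win) < 2) return(Inf)
    s <- sd(win)
    delta <- mean(btw) - mean(win)
    if (s < 1e-12) return(if (delta > 1e-12) Inf else 0)
    delta / s
  }

  branches <- vector("list", n - 1)
  get_node <- function(id, h) if (id < 0) new_branch(-id, h, 0) else branches[[id]]
  finalized <- list()
  loose_top <- integer(0)

  for (i in seq_len(n - 1)) {
    h <- heights[i]
    b1 <- get_node(merge[i, 1], h)
    b2 <- get_node(merge[i, 2], h)
    if (h > cut_height) {
      # merge suppressed: flush both sides as independent subtrees
      for (b in list(b1, b2)) {
        if (b$composite) {
          finalized <- c(finalized, b$clusters)
          loose_top <- c(loose_top, b$loose)
        } else if (length(b$members) >= min_cluster_size &&
                   core_scatter(b) <= par$max_abs_scatter) {
          finalized <- c(finalized, list(b$members))
        } else {
          loose_top <- c(loose_top, b$members)
        }
      }
      branches[[i]] <- new_branch(integer(0), numeric(0), h)
      next
    }
    if (!b1$composite && !b2$composite) {
      if (is_candidate(b1, h) && is_candidate(b2, h) &&
          split_sep(b1$members, b2$members) >= par$sep_min) {
        comp <- new_branch(c(b1$members, b2$members), c(b1$attach, b2$attach), h)
        comp$composite <- TRUE
        comp$clusters <- list(b1$members, b2$members)
        branches[[i]] <- comp
      } else {
        branches[[i]] <- new_branch(c(b1$members, b2$members),
                                    c(b1$attach, b2$attach), h)
      }
    } else {
      comp <- new_branch(c(b1$members, b2$members), c(b1$attach, b2$attach), h)
      comp$composite <- TRUE
      for (side in 1:2) {
        b <- list(b1, b2)[[side]]
        other <- list(b2, b1)[[side]]
        if (b$composite) {
          comp$clusters <- c(comp$clusters, b$clusters)
          comp$loose <- c(comp$loose, b$loose)
        } else {
          # compare the incoming branch against the nearest established
          # cluster on the other side, not against pooled cross-cluster
          # distances
          pool <- if (other$composite) other$clusters else list(other$members)
          mean_d <- vapply(pool, function(mm) mean(dm[b$members, mm]), numeric(1))
          nearest <- pool[[which.min(mean_d)]]
          if (is_candidate(b, h) && split_sep(b$members, nearest) >= par$sep_min) {
            comp$clusters <- c(comp$clusters, list(b$members))
          } else {
            comp$loose <- c(comp$loose, b$members)
          }
        }
      }
      branches[[i]] <- comp
    }
  }

  top <- branches[[n - 1]]
  loose <- loose_top
  if (top$composite) {
    finalized <- c(finalized, top$clusters)
    loose <- c(loose, top$loose)
  } else if (length(top$members) >= min_cluster_size) {
    finalized <- c(finalized, list(top$members))
  } else {
    loose <- c(loose, top$members)
  }

  labels <- integer(n)
  for (ci in seq_along(finalized)) labels[finalized[[ci]]] <- ci
  if (length(finalized) > 0 && length(loose) > 0) {
    radii <- vapply(finalized, function(mem) {
      if (length(mem) < 2) return(0)
      max(vapply(mem, function(mi) mean(dm[mi, setdiff(mem, mi)]), numeric(1)))
    }, numeric(1))
    for (o in loose) {
      avgd <- vapply(finalized, function(mem) mean(dm[o, mem]), numeric(1))
      j <- which.min(avgd)
      if (avgd[j] <= radii[j] * 1.2 + 1e-12) labels[o] <- j
    }
  }
  # renumber by decreasing size
  tab <- sort(table(labels[labels > 0]), decreasing = TRUE)
  if (length(tab) > 0) {
    remap <- setNames(seq_along(tab), names(tab))
    labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  }
  ids <- hc$labels %||% as.character(seq_len(n))
  tibble::tibble(isolate = ids, cluster = as.integer(labels))
}

#' Split one cluster into two
#'
#' Used to refine an automatically detected cluster with external evidence
#' (for example 16S similarity splitting one streptococcal gene-content
#' cluster in two). All other labels are preserved; the two parts receive
#' fresh labels at the end of the label range.
#'
#' @param assignment A tibble with columns `isolate`, `cluster`.
#' @param cluster_id The cluster to split.
#' @param partition Named vector (names = isolate ids of that cluster,
#'   values in `c(1, 2)`) covering exactly the cluster's members, with both
#'   parts non-empty.
#' @return A new assignment tibble with one more cluster.
#' @export
split_cluster <- function(assignment, cluster_id, partition) {
  stopifnot(all(c("isolate", "cluster") %in% names(assignment)))
  members <- assignment$isolate[assignment$cluster == cluster_id]
  if (length(members) == 0) abort(sprintf("cluster %s does not exist", cluster_id))
  if (!setequal(names(partition), members)) {
    abort("`partition` must cover exactly the members of the cluster")
  }
  if (!all(partition %in% 1:2) || length(unique(partition)) < 2) {
    abort("`partition` must place members in two non-empty parts")
  }
  new_labels <- max(assignment$cluster) + 1:2
  out <- assignment
  out$cluster[match(names(partition), out$isolate)] <-
    new_labels[as.integer(partition)]
  out
}

#' Cluster a KO gene-content matrix end to end
#'
#' Runs the full chain: zero-variance filtering, duplicate-profile collapse,
#' Manhattan distances, complete linkage, and the adaptive tree cut.
#'
#' @inheritParams cut_tree_dynamic
#' @param m A [ko_matrix()].
#' @return An object of class `ko_clustering`: a list with the filtered and
#'   collapsed matrices, removed/collapsed KO records, the distance object,
#'   the `hclust` tree, and the `clusters` assignment tibble.
#' @export
#' @examples
#' sim <- simulate_ko_matrix(n_clusters = 3, isolates_per_cluster = 8,
#'                           n_background_kos = 60, signature_size = 25,
#'                           flip_rate = 0.05, seed = 1)
#' fit <- cluster_ko_profiles(sim$matrix)
#' table(fit$clusters$cluster)
cluster_ko_profiles <- function(m, min_cluster_size = 3, deep_split = 2,
                                cut_height = NULL) {
  zv <- filter_zero_variance(m)
  dd <- collapse_duplicate_kos(zv$matrix)
  d <- ko_distance(dd$matrix)
  hc <- complete_linkage(d)
  clusters <- cut_tree_dynamic(hc, d, min_cluster_size = min_cluster_size,
                               deep_split = deep_split, cut_height = cut_height)
  structure(
    list(
      matrix = zv$matrix,
      collapsed_matrix = dd$matrix,
      removed_zero_variance = zv$removed,
      duplicates = dd$duplicates,
      distance = d,
      tree = hc,
      clusters = clusters,
      params = list(min_cluster_size = min_cluster_size, deep_split = deep_split)
    ),
    class = "ko_clustering"
  )
}

#' @export
print.ko_clustering <- function(x, ...) {
  k <- max(x$clusters$cluster)
  cat(sprintf(
    "<ko_clustering> %d isolates, %d informative KOs (%d distinct profiles), %d clusters (%d unassigned)\n",
    nrow(x$matrix), ncol(x$matrix), ncol(x$collapsed_matrix), k,
    sum(x$clusters$cluster == 0)))
  invisible(x)
}
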
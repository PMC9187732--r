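#' Split cluster gene sets into cell-type-specific and shared genes
#'
#' A gene belonging to exactly one cluster of the collection is specific to
#' that cluster; a gene appearing in two or more clusters is non-specific in
#' every cluster that carries it. The contrast between the two groups is what
#' lets the cluster score cancel signal that is common to many cell types.
#'
#' @param clusters Named list of gene sets (e.g. from [read_gene_sets()]).
#' @return A named list of partitions, one per cluster, each a list with
#'   `cluster_id`, `specific_genes`, `nonspecific_genes`.
#' @export
partition_cluster_genes <- function(clusters) {
  stopifnot(length(clusters) >= 1L)
  membership <- table(unlist(lapply(clusters, unique)))
  out <- lapply(names(clusters), function(nm) {
    genes <- unique(clusters[[nm]])
    shared <- membership[genes] >= 2L
    list(cluster_id = nm,
         specific_genes = genes[!shared],
         nonspecific_genes = genes[shared])
  })
  names(out) <- names(clusters)
  out
}

#' Cluster enrichment score from differential-expression p-values
#'
#' The score is the mean of -log10 p over the cluster's cell-type-specific
#' genes minus the mean of -log10 p over its non-specific genes, using the
#' unadjusted differential-expression p-values. Denominators count only genes
#' actually present in the table; a message reports any shrinkage. When
#' either side has no gene in the table the score is undefined (`NA` with a
#' warning).
#'
#' @param de Differential-expression table with columns `gene`, `p_value`.
#' @param part One partition from [partition_cluster_genes()].
#' @return The score (numeric scalar), with attributes `n_specific` and
#'   `n_nonspecific` giving the denominators used.
#' @export
compute_cellscore <- function(de, part) {
  p <- stats::setNames(de$p_value, de$gene)
  sp <- p[part$specific_genes[part$specific_genes %in% names(p)]]
  ns <- p[part$nonspecific_genes[part$nonspecific_genes %in% names(p)]]
  if (!length(sp) || !length(ns)) {
    warning("cluster '", part$cluster_id, "': no ",
            if (!length(sp)) "specific" else "non-specific",
            " gene present in the differential-expression table",
            call. = FALSE)
    return(structure(NA_real_, n_specific = length(sp),
                     n_nonspecific = length(ns)))
  }
  if (length(sp) < length(part$specific_genes) ||
      length(ns) < length(part$nonspecific_genes)) {
    message("cluster '", part$cluster_id, "': ", length(sp), "/",
            length(part$specific_genes), " specific and ", length(ns), "/",
            length(part$nonspecific_genes),
            " non-specific genes present in the table")
  }
  structure(mean(-log10(sp)) - mean(-log10(ns)),
            n_specific = length(sp), n_nonspecific = length(ns))
}

#' Draw one pseudo-case permutation of the group labels
#'
#' Pseudo-cases are a uniform without-replacement draw of `n_case` samples
#' from the actual control samples only; all real cases plus the remaining
#' controls become pseudo-controls. Label counts therefore match the observed
#' design while the null never mixes genuine case samples into the pseudo-case
#' group.
#'
#' @param sheet Sample sheet.
#' @return Character vector of permuted labels (`case`/`control`) named by
#'   sample id, in sheet order.
#' @export
draw_permutation <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  ctrl <- sheet$sample_id[sheet$group == "control"]
  n_case <- sum(sheet$group == "case")
  if (length(ctrl) < n_case) {
    stop("pseudo-case scheme inapplicable: ", length(ctrl),
         " controls cannot supply ", n_case, " pseudo-cases")
  }
  pseudo <- sample(ctrl, n_case)
  labels <- stats::setNames(rep("control", nrow(sheet)), sheet$sample_id)
  labels[pseudo] <- "case"
  labels
}

# All C(n_ctrl, n_case) pseudo-case assignments as a list of label vectors.
.enumerate_permutations <- function(sheet) {
  ctrl <- sheet$sample_id[sheet$group == "control"]
  n_case <- sum(sheet$group == "case")
  combos <- utils::combn(ctrl, n_case, simplify = FALSE)
  lapply(combos, function(pseudo) {
    labels <- stats::setNames(rep("control", nrow(sheet)), sheet$sample_id)
    labels[pseudo] <- "case"
    labels
  })
}

#' Permutation null distribution of cluster scores
#'
#' For each permutation the per-gene regressions are refit with the permuted
#' labels (the covariate, by default the first principal component, is
#' computed once from the observed matrix and reused, since relabelling does
#' not change the expression values) and the cluster score is recomputed.
#' All clusters share the same label draws, so their empirical p-values are
#' comparable. When the number of distinct pseudo-case assignments
#' `choose(n_control, n_case)` does not exceed `n_perm`, the null is built by
#' exhaustive enumeration instead of sampling.
#'
#' @param m Gene-by-sample normalized expression matrix.
#' @param sheet Sample sheet.
#' @param partitions A single partition or list of partitions from
#'   [partition_cluster_genes()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed (ignored in enumeration mode).
#' @param covariates As in [fit_differential_expression()].
#' @param enumerate Switch to exhaustive enumeration when feasible (default
#'   TRUE).
#' @return Object of class `permutation_null`: `null_scores` (matrix,
#'   permutations x clusters), `n_permutations`, `seed`, `enumerated`,
#'   `scheme` (n_case and control pool ids).
#' @export
build_null_distribution <- function(m, sheet, partitions, n_perm = 1000L,
                                    seed = 1L, covariates = "pc1",
                                    enumerate = TRUE) {
  sheet <- validate_sample_sheet(sheet)
  if (!is.null(partitions$cluster_id)) partitions <- list(partitions)
  m <- m[, sheet$sample_id, drop = FALSE]
  if (identical(covariates, "pc1")) {
    covariates <- compute_pca(m, 1L)$scores[, 1L, drop = FALSE]
  }
  ctrl <- sheet$sample_id[sheet$group == "control"]
  n_case <- sum(sheet$group == "case")
  if (length(ctrl) < n_case) {
    stop("pseudo-case scheme inapplicable: fewer controls than cases")
  }
  n_exhaustive <- choose(length(ctrl), n_case)
  enumerated <- isTRUE(enumerate) && n_exhaustive <= n_perm
  if (enumerated) {
    draws <- .enumerate_permutations(sheet)
  } else {
    set.seed(seed)
    draws <- replicate(n_perm, draw_permutation(sheet), simplify = FALSE)
  }
  genes <- rownames(m)
  idx <- lapply(partitions, function(pp) {
    list(sp = which(genes %in% pp$specific_genes),
         ns = which(genes %in% pp$nonspecific_genes))
  })
  null_scores <- matrix(NA_real_, length(draws), length(partitions),
                        dimnames = list(NULL, names(partitions)))
  for (i in seq_along(draws)) {
    g <- as.numeric(draws[[i]][sheet$sample_id] == "case")
    fit <- tryCatch(.ols_group_test(m, .design_matrix(g, covariates)),
                    error = function(e) {
                      stop("permutation ", i, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    nl <- -log10(fit$p_value)
    null_scores[i, ] <- vapply(idx, function(jj) {
      if (!length(jj$sp) || !length(jj$ns)) return(NA_real_)
      mean(nl[jj$sp]) - mean(nl[jj$ns])
    }, 0)
  }
  structure(list(null_scores = null_scores,
                 n_permutations = length(draws),
                 seed = if (enumerated) NA_integer_ else as.integer(seed),
                 enumerated = enumerated,
                 scheme = list(n_case = n_case, control_pool = ctrl)),
            class = "permutation_null")
}

#' One-sided empirical p-value against a permutation null
#'
#' `p = #\{null >= observed\} / n_permutations`: large scores indicate
#' perturbation. When no null score reaches the observed value the p-value is
#' at the resolution floor of the null and is reported as the bound
#' `1 / n_permutations` with `at_floor = TRUE` (rendered as e.g. `<1e-06` by
#' [write_results_table()]).
#'
#' @param observed Observed score.
#' @param null A `permutation_null` (single-cluster), or numeric vector of
#'   null scores.
#' @return List: `p_empirical`, `at_floor`, `n_permutations`.
#' @export
empirical_pvalue <- function(observed, null) {
  scores <- if (inherits(null, "permutation_null")) {
    stopifnot(ncol(null$null_scores) == 1L)
    null$null_scores[, 1L]
  } else as.numeric(null)
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (!n) stop("empty null distribution")
  k <- sum(scores >= observed)
  list(p_empirical = if (k == 0L) 1 / n else k / n,
       at_floor = k == 0L, n_permutations = n)
}

#' Bonferroni family-wise threshold
#'
#' @param n_tests Number of hypotheses (e.g. clusters tested).
#' @param level Family-wise error level in (0, 1).
#' @return `level / n_tests`; e.g. 10 clusters at 0.05 give 0.005.
#' @export
fwer_threshold <- function(n_tests, level = 0.05) {
  stopifnot(is.numeric(n_tests), n_tests >= 1, n_tests == round(n_tests),
            is.numeric(level), level > 0, level < 1)
  level / n_tests
}

#' Score-weighted combination of two datasets' empirical p-values
#'
#' Combines the evidence from two cohorts (e.g. organoids and post-mortem
#' tissue) for one cluster: the -log10 p-values are averaged with weights
#' proportional to the absolute cluster scores, so the dataset with the
#' stronger signal dominates.
#'
#' @param score_a,score_b Cluster scores in the two datasets.
#' @param p_a,p_b Empirical p-values in (0, 1].
#' @return List: `neglog10` (the weighted average on the -log10 scale) and
#'   `p` (its back-transform `10^-neglog10`, for convenience). Both `NA` when
#'   both scores are zero.
#' @export
combine_dataset_pvalues <- function(score_a, p_a, score_b, p_b) {
  stopifnot(p_a > 0, p_a <= 1, p_b > 0, p_b <= 1)
  denom <- abs(score_a) + abs(score_b)
  if (denom == 0) {
    warning("both scores are zero; combined p undefined", call. = FALSE)
    return(list(neglog10 = NA_real_, p = NA_real_))
  }
  w <- abs(score_a) / denom
  v <- w * (-log10(p_a)) + (1 - w) * (-log10(p_b))
  list(neglog10 = v, p = 10^(-v))
}

#' Directional pairwise percentage overlaps between gene sets
#'
#' Entry (A, B) is `100 * |A intersect B| / |A|` — the share of A's genes
#' found in B — so the matrix is asymmetric for unequal set sizes. Diagonal
#' is 100. Empty sets give `NA` rows.
#'
#' @param sets Named list of gene sets.
#' @return Square numeric matrix of percentages.
#' @export
pairwise_overlap_matrix <- function(sets) {
  stopifnot(length(sets) >= 2L)
  sets <- lapply(sets, unique)
  n <- length(sets)
  out <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    if (!length(sets[[i]])) next
    for (j in seq_len(n)) {
      out[i, j] <- 100 * length(intersect(sets[[i]], sets[[j]])) /
        length(sets[[i]])
    }
  }
  out
}

#' Merge redundant clusters by percentage overlap
#'
#' Two clusters are joined when either directional overlap reaches the
#' threshold (default 50%); the unique cluster groups are the connected
#' components of that graph, so chains of pairwise-overlapping clusters
#' collapse into one group. Each group's gene set is the union of its
#' members.
#'
#' @param overlaps Matrix from [pairwise_overlap_matrix()].
#' @param sets The gene sets the matrix was computed from (for the unions).
#' @param threshold Percentage overlap threshold in (0, 100].
#' @return List: `groups` (list of member-name vectors), `membership` (named
#'   integer vector cluster -> group), `union_sets` (named list of merged
#'   gene sets, named after each group's first member).
#' @export
deduplicate_clusters <- function(overlaps, sets, threshold = 50) {
  stopifnot(threshold > 0, threshold <= 100,
            nrow(overlaps) == ncol(overlaps))
  adj <- (!is.na(overlaps) & overlaps >= threshold)
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  groups <- split(names(comp), comp)
  names(groups) <- vapply(groups, `[[`, "", 1L)
  union_sets <- lapply(groups, function(members) {
    unique(unlist(sets[members]))
  })
  list(groups = unname(groups),
       membership = stats::setNames(match(comp, unique(comp)), names(comp)),
       union_sets = union_sets)
}

#' Overlap profile of a cluster against a reference atlas
#'
#' For each atlas cell type, the mean of the two directional percentage
#' overlaps between the cluster's genes and the atlas set's genes. The
#' profile is the cluster's fingerprint over the atlas and is what gets
#' correlated between cluster systems for fine-mapping cluster identities.
#'
#' @param cluster Character vector of gene symbols.
#' @param atlas Named list of atlas gene sets.
#' @return Named numeric vector, atlas cell type -> mean overlap percentage.
#' @export
atlas_overlap_profile <- function(cluster, atlas) {
  stopifnot(length(atlas) >= 1L)
  cluster <- unique(cluster)
  if (!length(cluster)) {
    return(stats::setNames(rep(NA_real_, length(atlas)), names(atlas)))
  }
  vapply(atlas, function(a) {
    a <- unique(a)
    if (!length(a)) return(NA_real_)
    k <- length(intersect(cluster, a))
    mean(c(100 * k / length(cluster), 100 * k / length(a)))
  }, 0)
}

#' Pearson correlation between two atlas overlap profiles
#'
#' @param profile_a,profile_b Numeric vectors over the identical atlas
#'   (length >= 3).
#' @return List: `r`, `p_value` (two-sided); both `NA` when either profile
#'   has zero variance.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  stopifnot(length(profile_a) == length(profile_b), length(profile_a) >= 3L)
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0) {
    warning("zero-variance profile; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(profile_a, profile_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Full critical-cell-type analysis
#'
#' Observed differential expression (with the PC1 covariate), cluster scores
#' for every partition, a shared permutation null, one-sided empirical
#' p-values and Bonferroni family-wise flags across the clusters tested.
#'
#' @param m Normalized gene-by-sample matrix.
#' @param sheet Sample sheet.
#' @param clusters Named list of cluster gene sets.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param fwer_levels Family-wise error levels to flag.
#' @param covariates As in [fit_differential_expression()].
#' @param enumerate Use exhaustive enumeration when feasible.
#' @return List: `results` (data.frame cluster, score, n_specific,
#'   n_nonspecific, p_empirical, at_floor, one `fwer_*` flag column per
#'   level), `null` (the `permutation_null`), `de` (observed table).
#' @export
run_cellscore <- function(m, sheet, clusters, n_perm = 1000L, seed = 1L,
                          fwer_levels = c(0.05, 0.1), covariates = "pc1",
                          enumerate = TRUE) {
  sheet <- validate_sample_sheet(sheet)
  parts <- partition_cluster_genes(clusters)
  de <- fit_differential_expression(m, sheet, covariates = covariates)
  obs <- lapply(parts, function(pp) compute_cellscore(de, pp))
  null <- build_null_distribution(m, sheet, parts, n_perm = n_perm,
                                  seed = seed, covariates = covariates,
                                  enumerate = enumerate)
  res <- data.frame(cluster = names(parts),
                    score = vapply(obs, as.numeric, 0),
                    n_specific = vapply(obs, attr, 0L, "n_specific"),
                    n_nonspecific = vapply(obs, attr, 0L, "n_nonspecific"),
                    row.names = NULL, stringsAsFactors = FALSE)
  ep <- lapply(seq_along(parts), function(j) {
    if (is.na(res$score[j])) {
      return(list(p_empirical = NA_real_, at_floor = NA))
    }
    empirical_pvalue(res$score[j], null$null_scores[, j])
  })
  res$p_empirical <- vapply(ep, `[[`, 0, "p_empirical")
  res$at_floor <- vapply(ep, `[[`, NA, "at_floor")
  for (lv in fwer_levels) {
    res[[paste0("fwer_", lv)]] <-
      !is.na(res$p_empirical) &
      res$p_empirical <= fwer_threshold(length(parts), lv)
  }
  list(results = res, null = null, de = de)
}
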
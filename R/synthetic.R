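#' Generate a synthetic case/control organoid cohort with planted truth
#'
#' Expression follows a log-normal model: on the log2 scale each value is a
#' gene baseline plus a donor random effect plus replicate noise, then
#' exponentiated to the FPKM scale. Donor effects are drawn per (gene, donor),
#' which makes replicates from one donor more alike than samples from
#' different donors — the intra- over inter-individual concordance structure
#' real cohorts show. Two perturbations can be planted in case donors only:
#' a multiplicative dosage fold change on a set of locus genes (emulating
#' copy-number dosage, e.g. 0.5 for a hemizygous deletion or 1.5 for a
#' duplication), and an additive log2 shift on a designated gene set
#' (emulating a perturbed cell-type program). Everything planted is recorded
#' in the returned truth record.
#'
#' @param n_case_donors,n_ctrl_donors Donor counts (defaults 13 and 12,
#'   a cohort shape typical of this assay).
#' @param reps_per_donor Replicates per donor: a scalar, or a length-2 range
#'   sampled uniformly per donor (default `c(1, 3)`).
#' @param n_genes Number of genes.
#' @param locus_size Number of locus (dosage) genes.
#' @param dosage_fc Multiplicative fold change on locus genes in cases
#'   (default 1 = none).
#' @param perturbed_genes Gene ids (or count, drawn from non-locus genes) to
#'   receive the additive case shift.
#' @param perturbed_effect Additive log2 shift in case samples for the
#'   perturbed genes (default 0).
#' @param n_expressed Number of genes planted above the expression filter;
#'   the remainder get baselines far below 2 FPKM (default all expressed).
#' @param donor_sd SD of the per-(gene, donor) effect on the log2 scale
#'   (default 0.35).
#' @param rep_sd SD of replicate noise on the log2 scale (default 0.25).
#' @param global_factor_sd SD of a per-sample global factor (default 0.5),
#'   added on the log2 scale with per-gene loadings drawn from N(1, 0.3).
#'   This emulates the dominant technical axis real organoid cohorts show —
#'   a single principal component carrying most of the expression variance —
#'   and is what the pipeline's PC1 covariate is meant to absorb. Set to 0
#'   for fully exchangeable samples.
#' @param baseline_log2_range Range of expressed-gene baselines on the log2
#'   scale (default `c(1.5, 6)`, i.e. roughly 3-64 FPKM).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List: `expression` (gene-by-sample FPKM matrix), `samples`
#'   (sample sheet), `truth` (planted parameters: locus genes, dosage fold
#'   change, perturbed genes and effect, noise SDs, expressed genes, seed).
#' @export
generate_cohort <- function(n_case_donors = 13L, n_ctrl_donors = 12L,
                            reps_per_donor = c(1L, 3L), n_genes = 2000L,
                            locus_size = 20L, dosage_fc = 1,
                            perturbed_genes = NULL, perturbed_effect = 0,
                            n_expressed = n_genes, donor_sd = 0.35,
                            rep_sd = 0.25, global_factor_sd = 0.5,
                            baseline_log2_range = c(1.5, 6), seed = 1L) {
  stopifnot(n_case_donors >= 1, n_ctrl_donors >= 1, n_genes >= 1,
            locus_size >= 0, dosage_fc > 0, n_expressed <= n_genes)
  if (locus_size > n_genes) stop("locus_size exceeds n_genes")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  donors <- c(sprintf("case%02d", seq_len(n_case_donors)),
              sprintf("ctrl%02d", seq_len(n_ctrl_donors)))
  donor_group <- rep(c("case", "control"), c(n_case_donors, n_ctrl_donors))
  reps <- if (length(reps_per_donor) == 2L) {
    sample(seq(reps_per_donor[1L], reps_per_donor[2L]), length(donors),
           replace = TRUE)
  } else rep(reps_per_donor, length(donors))
  sheet <- data.frame(
    sample_id = unlist(lapply(seq_along(donors), function(d) {
      paste0(donors[d], "_r", seq_len(reps[d]))
    })),
    donor_id = rep(donors, reps),
    replicate_index = unlist(lapply(reps, seq_len)),
    group = rep(donor_group, reps),
    stringsAsFactors = FALSE)

  expressed <- genes[seq_len(n_expressed)]
  baseline <- c(stats::runif(n_expressed, baseline_log2_range[1L],
                             baseline_log2_range[2L]),
                stats::runif(n_genes - n_expressed, -4, -1))
  names(baseline) <- genes
  locus <- if (locus_size > 0) sample(expressed, locus_size) else character()
  if (is.numeric(perturbed_genes) && length(perturbed_genes) == 1L) {
    perturbed_genes <- sample(setdiff(expressed, locus), perturbed_genes)
  }
  perturbed_genes <- as.character(perturbed_genes)

  donor_eff <- matrix(stats::rnorm(n_genes * length(donors), 0, donor_sd),
                      n_genes, dimnames = list(genes, donors))
  log2m <- baseline + donor_eff[, sheet$donor_id] +
    matrix(stats::rnorm(n_genes * nrow(sheet), 0, rep_sd), n_genes)
  if (global_factor_sd > 0) {
    factor_score <- stats::rnorm(nrow(sheet), 0, global_factor_sd)
    loading <- stats::rnorm(n_genes, 1, 0.3)
    log2m <- log2m + outer(loading, factor_score)
  }
  colnames(log2m) <- sheet$sample_id
  is_case <- sheet$group == "case"
  if (length(locus) && dosage_fc != 1) {
    log2m[locus, is_case] <- log2m[locus, is_case] + log2(dosage_fc)
  }
  if (length(perturbed_genes) && perturbed_effect != 0) {
    log2m[perturbed_genes, is_case] <-
      log2m[perturbed_genes, is_case] + perturbed_effect
  }
  list(expression = 2^log2m, samples = sheet,
       truth = list(locus_genes = locus, dosage_fc = dosage_fc,
                    perturbed_genes = perturbed_genes,
                    perturbed_effect = perturbed_effect,
                    expressed_genes = expressed, donor_sd = donor_sd,
                    rep_sd = rep_sd, global_factor_sd = global_factor_sd,
                    seed = seed))
}

#' Generate cluster gene sets with known specific/shared structure
#'
#' Each cluster receives its own disjoint block of cell-type-specific genes
#' plus a draw from a common shared pool. Any shared-pool gene that ends up
#' in only one cluster is added to a second random cluster, so that by
#' construction every shared gene is genuinely non-specific and the expected
#' partition is exact.
#'
#' @param n_clusters Number of clusters (default 10).
#' @param specific_per_cluster Specific genes per cluster: a scalar, a
#'   per-cluster vector, or a length-2 range sampled per cluster (default
#'   `c(47, 266)`, the spread seen in curated organoid cluster lists).
#' @param shared_per_cluster Shared-pool draws per cluster, same conventions
#'   (default `c(12, 49)`).
#' @param shared_pool_size Size of the shared pool (default 60).
#' @param gene_pool Optional character vector to draw all gene names from
#'   (e.g. a cohort's gene universe); synthetic names are minted otherwise.
#' @param seed Integer seed.
#' @return List: `sets` (named list of cluster gene sets, GMT-compatible)
#'   and `expected_partition` (the planted specific/non-specific split, same
#'   shape as [partition_cluster_genes()] output).
#' @export
generate_cluster_sets <- function(n_clusters = 10L,
                                  specific_per_cluster = c(47L, 266L),
                                  shared_per_cluster = c(12L, 49L),
                                  shared_pool_size = 60L, gene_pool = NULL,
                                  seed = 1L) {
  stopifnot(n_clusters >= 1)
  set.seed(seed)
  expand <- function(x) {
    if (length(x) == 2L && n_clusters != 2L) {
      sample(seq(x[1L], x[2L]), n_clusters, replace = TRUE)
    } else rep(x, length.out = n_clusters)
  }
  n_spec <- expand(specific_per_cluster)
  n_shared <- pmin(expand(shared_per_cluster), shared_pool_size)
  if (n_clusters == 1L) n_shared[] <- 0L
  total <- sum(n_spec) + shared_pool_size
  if (is.null(gene_pool)) {
    gene_pool <- sprintf("SYN%05d", seq_len(total))
  } else if (length(gene_pool) < total) {
    stop("gene_pool exhausted: need ", total, " genes, have ",
         length(gene_pool))
  }
  pool <- sample(gene_pool, total)
  shared_pool <- pool[seq_len(shared_pool_size)]
  rest <- if (shared_pool_size > 0) pool[-seq_len(shared_pool_size)] else pool
  offsets <- cumsum(c(0L, n_spec))
  cluster_ids <- sprintf("c%d", seq_len(n_clusters))
  specific <- lapply(seq_len(n_clusters), function(i) {
    rest[(offsets[i] + 1L):offsets[i + 1L]]
  })
  shared <- lapply(seq_len(n_clusters), function(i) {
    if (n_shared[i] > 0L) sample(shared_pool, n_shared[i]) else character()
  })
  # promote singly-drawn shared genes into a second cluster
  if (n_clusters >= 2L) {
    counts <- table(unlist(shared))
    for (g in names(counts)[counts == 1L]) {
      owner <- which(vapply(shared, function(s) g %in% s, NA))
      extra <- sample(setdiff(seq_len(n_clusters), owner), 1L)
      shared[[extra]] <- c(shared[[extra]], g)
    }
  }
  sets <- lapply(seq_len(n_clusters), function(i) {
    c(specific[[i]], shared[[i]])
  })
  names(sets) <- cluster_ids
  attr(sets, "description") <- stats::setNames(
    rep("synthetic cluster", n_clusters), cluster_ids)
  expected <- lapply(seq_len(n_clusters), function(i) {
    list(cluster_id = cluster_ids[i], specific_genes = specific[[i]],
         nonspecific_genes = shared[[i]])
  })
  names(expected) <- cluster_ids
  list(sets = sets, expected_partition = expected)
}

#' Generate a reference co-expression compendium with correlated blocks
#'
#' Emulates the role of a large post-mortem expression compendium: genes are
#' organized into blocks with a target exchangeable within-block correlation
#' rho (single-factor construction, `x = sqrt(rho) * f + sqrt(1 - rho) * e`),
#' genes outside any block are independent. Passing gene names that coincide
#' with a cohort's cluster genes lets tests plant a driver gene whose
#' connectivity block overlaps a perturbed cluster.
#'
#' @param n_genes Number of compendium genes (ignored beyond
#'   `length(gene_names)` when names are given).
#' @param n_samples Number of compendium samples.
#' @param block_spec List of blocks, each a list with `genes` (character
#'   vector of gene names, or an integer count taken from the unassigned
#'   pool) and `rho` (target within-block correlation in [0, 1)).
#' @param gene_names Optional character vector of gene names (length
#'   `n_genes`).
#' @param mean_log2,sd_log2 Location and scale of the values (default 5, 1).
#' @param seed Integer seed.
#' @return List: `expression` (gene-by-sample matrix) and `truth` (`blocks`:
#'   realized gene lists and rho per block).
#' @export
generate_reference_compendium <- function(n_genes = 200L, n_samples = 100L,
                                          block_spec = list(),
                                          gene_names = NULL, mean_log2 = 5,
                                          sd_log2 = 1, seed = 1L) {
  stopifnot(n_samples >= 3L)
  set.seed(seed)
  if (is.null(gene_names)) {
    gene_names <- sprintf("R%05d", seq_len(n_genes))
  }
  n_genes <- length(gene_names)
  unassigned <- gene_names
  blocks <- lapply(seq_along(block_spec), function(b) {
    spec <- block_spec[[b]]
    rho <- spec$rho
    if (!is.numeric(rho) || rho < 0 || rho >= 1) {
      stop("block ", b, ": rho must lie in [0, 1) for a ",
           "positive-definite exchangeable block")
    }
    g <- spec$genes
    if (is.numeric(g) && length(g) == 1L) {
      if (g > length(unassigned)) stop("block ", b, ": pool exhausted")
      g <- utils::head(unassigned, g)
    }
    missing <- setdiff(g, gene_names)
    if (length(missing)) {
      stop("block ", b, " names genes outside the compendium: ",
           paste(missing, collapse = ", "))
    }
    unassigned <<- setdiff(unassigned, g)
    list(genes = g, rho = rho)
  })
  m <- matrix(stats::rnorm(n_genes * n_samples), n_genes,
              dimnames = list(gene_names, sprintf("S%04d",
                                                  seq_len(n_samples))))
  for (bl in blocks) {
    f <- stats::rnorm(n_samples)
    m[bl$genes, ] <- sqrt(bl$rho) * rep(f, each = length(bl$genes)) +
      sqrt(1 - bl$rho) * m[bl$genes, , drop = FALSE]
  }
  m <- mean_log2 + sd_log2 * m
  list(expression = m, truth = list(blocks = blocks, seed = seed))
}
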
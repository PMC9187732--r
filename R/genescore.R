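#' Co-expression connectivity of locus genes against a reference compendium
#'
#' For each gene of interest (e.g. the genes spanned by a copy-number
#' variant) the squared Pearson correlation of its expression profile with
#' every other gene's profile across the reference compendium samples is the
#' proxy for co-expression connectivity. Self-correlations are excluded;
#' locus genes absent from the compendium are dropped with a message;
#' zero-variance reference genes yield undefined correlations and do not
#' count toward the per-locus-gene denominator.
#'
#' @param locus_genes Character vector of gene symbols.
#' @param compendium Gene-by-sample reference expression matrix (>= 3
#'   samples).
#' @return List of class `connectivity_table`: `r_squared` (locus gene x
#'   reference gene matrix, `NA` for self/undefined pairs), `locus_genes`,
#'   `reference_genes`, `num_available` (named count of defined correlations
#'   per locus gene), `dropped` (locus genes absent from the compendium).
#' @export
compute_connectivity <- function(locus_genes, compendium) {
  if (ncol(compendium) < 3L) stop("compendium needs at least 3 samples")
  locus_genes <- unique(locus_genes)
  present <- locus_genes[locus_genes %in% rownames(compendium)]
  dropped <- setdiff(locus_genes, present)
  if (length(dropped)) {
    message("locus gene(s) absent from the compendium, excluded: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(present)) stop("no locus gene found in the compendium")
  r <- suppressWarnings(stats::cor(t(compendium[present, , drop = FALSE]),
                                   t(compendium)))
  r2 <- r^2
  for (g in present) r2[g, g] <- NA_real_
  structure(list(r_squared = r2, locus_genes = present,
                 reference_genes = colnames(r2),
                 num_available = rowSums(!is.na(r2)), dropped = dropped),
            class = "connectivity_table")
}

#' Genomic-control inflation factor of a p-value distribution
#'
#' P-values are mapped to upper-tail one-degree-of-freedom chi-square
#' statistics; lambda is the ratio of their observed median to the median
#' expected under uniformity, `qchisq(0.5, 1)`. Lambda near 1 indicates a
#' well-calibrated test-statistic distribution; lambda > 1 global inflation.
#'
#' @param p_values Numeric vector in (0, 1].
#' @return Lambda (numeric scalar).
#' @export
genomic_control_lambda <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(stats) / stats::qchisq(0.5, df = 1)
}

#' Connectivity-weighted driver-gene score
#'
#' For locus gene x, the sum over reference genes y of
#' `-log10(p_y) * r2(x, y)`, divided by the number of genes entering the sum
#' and scaled by `1 / log10(lambda)`, where lambda is the genomic-control
#' factor of the run's full differential-expression p-value vector. Because
#' each permutation run relabels different samples, every run (observed or
#' permuted) is normalized by its own lambda so that runs are comparable.
#' When a gene subset is given (a cluster's specific plus non-specific
#' genes), the sum is restricted to it, yielding the cell-type-specific
#' score.
#'
#' When lambda <= 1 the prefactor is undefined or would flip the ranking;
#' the raw (unnormalized) score is returned with `normalized = FALSE` and a
#' warning instead.
#'
#' @param x Locus gene symbol.
#' @param conn A `connectivity_table` from [compute_connectivity()].
#' @param de Differential-expression table (columns `gene`, `p_value`).
#' @param gene_subset Optional character vector restricting the reference
#'   genes.
#' @param lambda Optional precomputed lambda (otherwise taken from
#'   `de$p_value`).
#' @return List: `score`, `raw_score`, `lambda`, `normalized`, `num_y`.
#' @export
compute_genescore <- function(x, conn, de, gene_subset = NULL,
                              lambda = NULL) {
  stopifnot(inherits(conn, "connectivity_table"))
  if (!x %in% conn$locus_genes) {
    stop("gene '", x, "' not in the connectivity table")
  }
  if (is.null(lambda)) lambda <- genomic_control_lambda(de$p_value)
  r2 <- conn$r_squared[x, ]
  p <- stats::setNames(de$p_value, de$gene)
  y <- intersect(names(r2)[!is.na(r2)], names(p))
  if (!is.null(gene_subset)) y <- intersect(y, gene_subset)
  num_y <- length(y)
  if (!num_y) {
    warning("no reference gene available for '", x, "'", call. = FALSE)
    return(list(score = NA_real_, raw_score = NA_real_, lambda = lambda,
                normalized = FALSE, num_y = 0L))
  }
  raw <- sum(-log10(p[y]) * r2[y]) / num_y
  if (!is.finite(log10(lambda)) || log10(lambda) <= 0) {
    warning("lambda <= 1 (", format(lambda),
            "); returning the unnormalized score", call. = FALSE)
    return(list(score = raw, raw_score = raw, lambda = lambda,
                normalized = FALSE, num_y = num_y))
  }
  list(score = raw / log10(lambda), raw_score = raw, lambda = lambda,
       normalized = TRUE, num_y = num_y)
}

# Scores for all locus genes and scopes of one run. `scopes` is a named list
# scope_name -> gene subset (NULL = all reference genes).
.genescores_one_run <- function(conn, de, scopes, lambda = NULL) {
  if (is.null(lambda)) lambda <- genomic_control_lambda(de$p_value)
  out <- matrix(NA_real_, length(conn$locus_genes), length(scopes),
                dimnames = list(conn$locus_genes, names(scopes)))
  for (x in conn$locus_genes) {
    for (s in names(scopes)) {
      gs <- suppressWarnings(compute_genescore(x, conn, de,
                                               gene_subset = scopes[[s]],
                                               lambda = lambda))
      out[x, s] <- gs$score
    }
  }
  out
}

#' Permutation p-values for driver-gene scores
#'
#' Uses the same pseudo-case permutation scheme as the cluster analysis:
#' each permutation refits the per-gene regressions (PC1 covariate computed
#' once from the observed matrix), recomputes that run's genomic-control
#' lambda from its full p-value vector, and rescores every locus gene in
#' every scope. The one-sided empirical p-value is the proportion of
#' permuted scores at or above the observed score, with the floor reported
#' as `1 / n_perm`.
#'
#' @param m Normalized gene-by-sample matrix (the case/control cohort).
#' @param sheet Sample sheet.
#' @param conn A `connectivity_table` against the reference compendium.
#' @param clusters Optional named list of partitions (from
#'   [partition_cluster_genes()]); each adds a per-cluster scope (specific
#'   plus non-specific genes) next to the global `all` scope.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param covariates As in [fit_differential_expression()].
#' @param enumerate Use exhaustive label enumeration when feasible.
#' @return List: `results` (data.frame gene, scope, score, lambda,
#'   p_empirical, at_floor), `null_scores` (3-d array permutation x gene x
#'   scope), `de` (observed table).
#' @export
genescore_permutation_pvalues <- function(m, sheet, conn, clusters = NULL,
                                          n_perm = 1000L, seed = 1L,
                                          covariates = "pc1",
                                          enumerate = TRUE) {
  sheet <- validate_sample_sheet(sheet)
  m <- m[, sheet$sample_id, drop = FALSE]
  if (identical(covariates, "pc1")) {
    covariates <- compute_pca(m, 1L)$scores[, 1L, drop = FALSE]
  }
  scopes <- list(all = NULL)
  if (!is.null(clusters)) {
    if (!is.null(clusters$cluster_id)) clusters <- list(clusters)
    for (pp in clusters) {
      scopes[[pp$cluster_id]] <- c(pp$specific_genes, pp$nonspecific_genes)
    }
  }
  g_obs <- as.numeric(sheet$group == "case")
  X <- .design_matrix(g_obs, covariates)
  fit <- .ols_group_test(m, X)
  de_obs <- data.frame(gene = rownames(m), p_value = fit$p_value,
                       stringsAsFactors = FALSE)
  obs_lambda <- genomic_control_lambda(de_obs$p_value)
  obs <- .genescores_one_run(conn, de_obs, scopes, lambda = obs_lambda)

  ctrl <- sheet$sample_id[sheet$group == "control"]
  n_case <- sum(sheet$group == "case")
  if (length(ctrl) < n_case) {
    stop("pseudo-case scheme inapplicable: fewer controls than cases")
  }
  enumerated <- isTRUE(enumerate) && choose(length(ctrl), n_case) <= n_perm
  if (enumerated) {
    draws <- .enumerate_permutations(sheet)
  } else {
    set.seed(seed)
    draws <- replicate(n_perm, draw_permutation(sheet), simplify = FALSE)
  }
  null_scores <- array(NA_real_,
                       dim = c(length(draws), length(conn$locus_genes),
                               length(scopes)),
                       dimnames = list(NULL, conn$locus_genes,
                                       names(scopes)))
  for (i in seq_along(draws)) {
    g <- as.numeric(draws[[i]][sheet$sample_id] == "case")
    fit_i <- .ols_group_test(m, .design_matrix(g, covariates))
    de_i <- data.frame(gene = rownames(m), p_value = fit_i$p_value,
                       stringsAsFactors = FALSE)
    null_scores[i, , ] <- .genescores_one_run(conn, de_i, scopes)
  }
  rows <- expand.grid(gene = conn$locus_genes, scope = names(scopes),
                      stringsAsFactors = FALSE)
  ep <- lapply(seq_len(nrow(rows)), function(r) {
    o <- obs[rows$gene[r], rows$scope[r]]
    if (is.na(o)) return(list(p_empirical = NA_real_, at_floor = NA))
    empirical_pvalue(o, null_scores[, rows$gene[r], rows$scope[r]])
  })
  res <- data.frame(gene = rows$gene, scope = rows$scope,
                    score = obs[cbind(rows$gene, rows$scope)],
                    lambda = obs_lambda,
                    p_empirical = vapply(ep, `[[`, 0, "p_empirical"),
                    at_floor = vapply(ep, `[[`, NA, "at_floor"),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(results = res, null_scores = null_scores, de = de_obs)
}

#' Percentile-based false-discovery thresholds for pooled score p-values
#'
#' The p-values of the cell-type-specific scores from all clusters of one
#' locus are pooled and sorted; the 5th percentile (nearest-rank, lower) is
#' the FDR 0.05 threshold and the 10th percentile the FDR 0.1 threshold. A
#' level whose nearest rank would fall below the first order statistic (fewer
#' than `100 / percentile` values) is undefined (`NA`).
#'
#' @param pooled_p Numeric vector of p-values pooled across clusters.
#' @param percentiles Percentile levels (default `c(5, 10)`).
#' @return Named numeric vector, `fdr_<percentile/100>` -> p threshold.
#' @export
percentile_fdr_thresholds <- function(pooled_p, percentiles = c(5, 10)) {
  stopifnot(length(pooled_p) >= 1L, all(percentiles > 0),
            all(percentiles <= 100))
  s <- sort(pooled_p)
  n <- length(s)
  out <- vapply(percentiles, function(pc) {
    k <- floor(pc / 100 * n)
    if (k < 1L) NA_real_ else s[k]
  }, 0)
  names(out) <- paste0("fdr_", percentiles / 100)
  out
}
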
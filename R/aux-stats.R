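#' Two-by-two overlap enrichment between model systems
#'
#' Compares hit rates between two conditions, e.g. the fraction of shared
#' expressed genes that replicate differential expression in one companion
#' model system versus another. The point estimate is the sample
#' (cross-product) odds ratio; the confidence interval and two-sided p-value
#' come from Fisher's exact test (conditional maximum-likelihood) when
#' feasible, with a log-normal (Woolf) interval as fallback for tables too
#' large for the exact network algorithm.
#'
#' @param k_a Hits under condition A.
#' @param n_a Total under condition A.
#' @param k_b Hits under condition B.
#' @param n_b Total under condition B.
#' @return List of class `enrichment_result`: `table` (2x2), `odds_ratio`
#'   (sample estimate; `NA` when a margin is all zero), `ci_95`, `p_value`,
#'   `method`.
#' @export
overlap_enrichment <- function(k_a, n_a, k_b, n_b) {
  stopifnot(k_a >= 0, k_b >= 0, k_a <= n_a, k_b <= n_b)
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2L, byrow = TRUE,
                dimnames = list(c("A", "B"), c("hit", "nonhit")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; enrichment undefined", call. = FALSE)
    return(structure(list(table = tab, odds_ratio = NA_real_,
                          ci_95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, method = "undefined"),
                     class = "enrichment_result"))
  }
  or_sample <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  ft <- tryCatch(stats::fisher.test(tab), error = function(e) NULL)
  if (!is.null(ft)) {
    ci <- as.numeric(ft$conf.int)
    p <- ft$p.value
    method <- "fisher_exact"
  } else {
    # Woolf log-normal interval; 0.5 continuity correction on zero cells
    tt <- tab + 0.5 * (any(tab == 0))
    se <- sqrt(sum(1 / tt))
    lor <- log((tt[1L, 1L] * tt[2L, 2L]) / (tt[1L, 2L] * tt[2L, 1L]))
    ci <- exp(lor + c(-1, 1) * stats::qnorm(0.975) * se)
    p <- 2 * stats::pnorm(-abs(lor / se))
    method <- "woolf"
  }
  structure(list(table = tab, odds_ratio = or_sample, ci_95 = ci,
                 p_value = p, method = method),
            class = "enrichment_result")
}

#' Power simulation for a two-group comparison at family-wise significance
#'
#' Over a grid of base mean expression values and case/control fold changes,
#' each cell simulates `n_sim` replicate experiments: control values drawn
#' from Normal(mean, sd) and case values from Normal(mean * fc, sd), compared
#' by the pipeline's two-group ordinary-least-squares test (no covariates;
#' equivalent to an equal-variance t-test, since simulated data carry no
#' principal-component structure). Power is the fraction of replicates whose
#' p-value reaches the Bonferroni family-wise threshold
#' `alpha / n_genes_for_fwer`. Negative draws are kept as-is; truncation
#' would silently change the sampling model.
#'
#' @param n_case Case replicates per experiment (default 9).
#' @param n_ctrl Control replicates per experiment (default 14).
#' @param mean_grid Base mean expression values (default 2, 3, 4, 5).
#' @param fc_grid Case fold changes (default 1.2 to 3.9 in steps of 0.3,
#'   i.e. spanning [1.2, 4)).
#' @param sd Common standard deviation (default 18.5).
#' @param n_sim Simulated replicates per cell (default 1000).
#' @param n_genes_for_fwer Bonferroni denominator: the number of genes the
#'   family-wise threshold is divided over (default 9978, a post-QC gene
#'   universe size typical for this assay).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Integer seed.
#' @return List of class `power_grid`: `power` (matrix mean x fold change),
#'   plus the simulation parameters.
#' @export
simulate_setd_power <- function(n_case = 9L, n_ctrl = 14L,
                                mean_grid = c(2, 3, 4, 5),
                                fc_grid = seq(1.2, 3.9, by = 0.3),
                                sd = 18.5, n_sim = 1000L,
                                n_genes_for_fwer = 9978L, alpha = 0.05,
                                seed = 1L) {
  if (sd <= 0) stop("sd must be positive")
  stopifnot(n_case >= 2, n_ctrl >= 2, n_sim >= 1, n_genes_for_fwer >= 1)
  set.seed(seed)
  threshold <- alpha / n_genes_for_fwer
  X <- .design_matrix(c(rep(0, n_ctrl), rep(1, n_case)))
  power <- matrix(NA_real_, length(mean_grid), length(fc_grid),
                  dimnames = list(mean = format(mean_grid),
                                  fc = format(fc_grid)))
  for (i in seq_along(mean_grid)) {
    for (j in seq_along(fc_grid)) {
      mu <- mean_grid[i]
      fc <- fc_grid[j]
      # one row per simulated replicate experiment: controls then cases
      Y <- cbind(matrix(stats::rnorm(n_sim * n_ctrl, mu, sd), n_sim),
                 matrix(stats::rnorm(n_sim * n_case, mu * fc, sd), n_sim))
      fit <- .ols_group_test(Y, X)
      power[i, j] <- mean(fit$p_value <= threshold)
    }
  }
  structure(list(power = power, n_sim = as.integer(n_sim),
                 n_case_reps = as.integer(n_case),
                 n_ctrl_reps = as.integer(n_ctrl), sd = sd,
                 fwer_alpha = alpha,
                 n_genes_for_fwer = as.integer(n_genes_for_fwer)),
            class = "power_grid")
}
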
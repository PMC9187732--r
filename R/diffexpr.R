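# Vectorized per-gene ordinary least squares of expression on a design
# matrix; returns the second column's coefficient, its two-sided t-test
# p-value, and flags degenerate (zero residual variance) genes with p = 1.
# Y is genes x samples; X is samples x predictors with the group indicator
# in column 2. Shared by the observed fit and every permutation refit.
.ols_group_test <- function(Y, X) {
  n <- ncol(Y)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    stop("design matrix is rank-deficient (collinear covariate)")
  }
  xtxi <- chol2inv(qr.R(qx))
  beta_all <- xtxi %*% crossprod(X, t(Y))          # p x genes
  res <- t(Y) - X %*% beta_all                     # samples x genes
  df <- n - p
  rss <- colSums(res^2)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtxi[2L, 2L])
  beta <- beta_all[2L, ]
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- sigma2 < .Machine$double.eps * max(1, mean(abs(Y)))^2 * n
  pval[degenerate] <- 1
  list(beta = beta, p_value = pval, df = df, degenerate = degenerate)
}

# Build the regression design for a label vector (1 = case) plus covariates.
.design_matrix <- function(group01, covariates = NULL) {
  X <- cbind(intercept = 1, group = group01)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  X
}

#' Principal components of the sample-by-gene expression matrix
#'
#' Samples are observations and genes are features (centered). Returns
#' per-sample scores and the fraction of total variance carried by each
#' component. The sign of each component is fixed so that its loading sum is
#' non-negative, making score signs reproducible across runs.
#'
#' @param m Gene-by-sample matrix (normalized expression).
#' @param n_components Number of leading components to return (default all).
#' @return List: `scores` (samples x components), `var_frac`, `loadings`
#'   (genes x components).
#' @export
compute_pca <- function(m, n_components = NULL) {
  if (ncol(m) < 2L) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(if (is.null(n_components)) length(var_frac) else n_components,
           ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- colSums(loadings) < 0
  scores[, flip] <- -scores[, flip, drop = FALSE]
  loadings[, flip] <- -loadings[, flip, drop = FALSE]
  list(scores = scores, var_frac = var_frac[seq_len(k)], loadings = loadings)
}

#' Per-gene differential expression by linear regression
#'
#' Ordinary least squares of (inverse-normal) expression on the case/control
#' indicator plus covariates, with a two-sided t-test on the group
#' coefficient. All replicates are treated as independent samples. By default
#' the first principal component of the expression matrix is included as the
#' single covariate, acting as a surrogate for technical sample-level
#' variation.
#'
#' @param m Gene-by-sample matrix of normalized expression.
#' @param sheet Sample sheet; columns of `m` are matched by `sample_id`.
#' @param covariates Per-sample covariate matrix/vector aligned to the sheet,
#'   `"pc1"` (default) to use the leading principal component of `m`, or
#'   `NULL` for none.
#' @param raw Optional FPKM-scale matrix for fold changes (case mean /
#'   control mean); otherwise the `fold_change` column is `NA`.
#' @return Data frame: gene, beta, p_value, q_value (Benjamini-Hochberg),
#'   fold_change, n_case, n_control.
#' @export
fit_differential_expression <- function(m, sheet, covariates = "pc1",
                                        raw = NULL) {
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(sheet$sample_id, colnames(m))
  if (length(missing)) {
    stop("sample(s) in sheet absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  m <- m[, sheet$sample_id, drop = FALSE]
  g <- as.numeric(sheet$group == "case")
  if (length(unique(g)) < 2L) stop("need both cases and controls")
  if (identical(covariates, "pc1")) {
    covariates <- compute_pca(m, 1L)$scores[, 1L, drop = FALSE]
    colnames(covariates) <- "PC1"
  }
  X <- .design_matrix(g, covariates)
  fit <- .ols_group_test(m, X)
  if (any(fit$degenerate)) {
    warning(sum(fit$degenerate),
            " gene(s) with zero residual variance set to p = 1",
            call. = FALSE)
  }
  fc <- rep(NA_real_, nrow(m))
  if (!is.null(raw)) {
    fc <- compute_fold_changes(raw, sheet)[rownames(m)]
  }
  data.frame(gene = rownames(m), beta = fit$beta, p_value = fit$p_value,
             q_value = adjust_bh_fdr(fit$p_value), fold_change = unname(fc),
             n_case = sum(g == 1), n_control = sum(g == 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values, clipped at 1, monotone in p-rank.
#' @export
adjust_bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene fold change of case over control group means
#'
#' Computed on the raw FPKM scale (never on rank-normalized values), so that
#' copy-number dosage reads out directly: a hemizygous deletion is expected
#' near 0.5, a duplication near 1.5.
#'
#' @param raw Gene-by-sample FPKM matrix.
#' @param sheet Sample sheet.
#' @return Named numeric vector, gene -> case mean / control mean; `NA` with
#'   a message where the control mean is zero.
#' @export
compute_fold_changes <- function(raw, sheet) {
  sheet <- validate_sample_sheet(sheet)
  raw <- raw[, sheet$sample_id, drop = FALSE]
  case_mean <- rowMeans(raw[, sheet$group == "case", drop = FALSE])
  ctrl_mean <- rowMeans(raw[, sheet$group == "control", drop = FALSE])
  fc <- case_mean / ctrl_mean
  zero <- ctrl_mean == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with zero control mean: fold change NA")
    fc[zero] <- NA_real_
  }
  fc
}
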
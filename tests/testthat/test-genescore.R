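test_that("connectivity tables hold squared correlations with exclusions", {
  set.seed(10)
  n_s <- 20
  base <- matrix(rnorm(6 * n_s), 6,
                 dimnames = list(c("L1", "L2", "R1", "R2", "R3", "FLAT"),
                                 sprintf("s%02d", 1:n_s)))
  base["L1", ] <- base["R1", ]          # identical profiles
  base["FLAT", ] <- 7                   # zero variance
  expect_message(conn <- compute_connectivity(c("L1", "L2", "GHOST"), base),
                 "GHOST")
  expect_identical(conn$dropped, "GHOST")
  expect_identical(conn$locus_genes, c("L1", "L2"))
  expect_equal(conn$r_squared["L1", "R1"], 1, tolerance = 1e-12)
  expect_true(is.na(conn$r_squared["L1", "L1"]))     # self excluded
  expect_true(is.na(conn$r_squared["L1", "FLAT"]))   # zero variance
  # num_available: 6 reference genes minus self minus FLAT
  expect_equal(unname(conn$num_available["L1"]), 4)

  # exact zero sample correlation
  m0 <- rbind(x = c(1, -1, 1, -1), y = c(1, 1, -1, -1), z = c(2, 1, -1, -2))
  colnames(m0) <- paste0("s", 1:4)
  c0 <- compute_connectivity("x", m0)
  expect_equal(c0$r_squared["x", "y"], 0, tolerance = 1e-12)

  # correlations are scale-invariant
  conn2 <- suppressMessages(compute_connectivity(c("L1", "L2"), base * 3.7))
  expect_equal(conn2$r_squared, conn$r_squared, tolerance = 1e-12)
})

test_that("locus genes missing from the compendium are excluded up front", {
  set.seed(11)
  genes <- c(sprintf("LOC%02d", 1:22), sprintf("REF%02d", 1:30))
  comp <- matrix(rnorm(52 * 15), 52, dimnames = list(genes, paste0("s", 1:15)))
  comp <- comp[!rownames(comp) %in% c("LOC05", "LOC17"), ]
  conn <- suppressMessages(compute_connectivity(sprintf("LOC%02d", 1:22),
                                                comp))
  expect_length(conn$locus_genes, 20L)
  expect_setequal(conn$dropped, c("LOC05", "LOC17"))
})

test_that("genomic-control lambda matches the chi-square quantile identities", {
  expect_equal(genomic_control_lambda(rep(0.5, 7)), 1, tolerance = 1e-12)
  expect_equal(genomic_control_lambda(rep(0.05, 3)),
               qchisq(0.95, 1) / qchisq(0.5, 1), tolerance = 1e-12)
  expect_equal(genomic_control_lambda(rep(0.05, 3)), 8.4439,
               tolerance = 1e-3)
  # uniform-quantile p-values give lambda near 1
  n <- 999
  expect_equal(genomic_control_lambda((1:n) / (n + 1)), 1, tolerance = 0.02)
  expect_error(genomic_control_lambda(numeric()), "empty")
  expect_error(genomic_control_lambda(c(0.5, 0)), "0, 1")
})

test_that("driver score follows the weighted-connectivity formula", {
  conn <- structure(list(
    r_squared = matrix(c(NA, 0.5, 0.5), 1,
                       dimnames = list("x", c("x", "y1", "y2"))),
    locus_genes = "x", reference_genes = c("x", "y1", "y2"),
    num_available = c(x = 2), dropped = character()),
    class = "connectivity_table")
  de <- make_de(c("y1", "y2"), c(0.01, 0.0001))
  out <- compute_genescore("x", conn, de, lambda = 10)
  expect_equal(out$score, 1.5)   # (2*0.5 + 4*0.5)/2, prefactor 1/log10(10)
  expect_equal(out$num_y, 2L)

  # all-zero connectivity annihilates the score
  conn0 <- conn
  conn0$r_squared[1, 2:3] <- 0
  expect_equal(compute_genescore("x", conn0, de, lambda = 10)$score, 0)

  # doubling every -log10 p doubles the unnormalized sum
  de2 <- make_de(c("y1", "y2"), c(0.01, 0.0001)^2)
  expect_equal(compute_genescore("x", conn, de2, lambda = 10)$raw_score,
               2 * out$raw_score)

  # lambda at or below 1: unnormalized score, flagged
  expect_warning(g1 <- compute_genescore("x", conn, de, lambda = 1),
                 "lambda")
  expect_false(g1$normalized)
  expect_equal(g1$score, g1$raw_score)
})

test_that("restricting to the full reference set reproduces the score exactly", {
  set.seed(13)
  comp <- make_matrix(30, 12, seed = 13)
  conn <- compute_connectivity(rownames(comp)[1:3], comp)
  de <- make_de(rownames(comp), runif(30, 0.001, 1))
  full <- compute_genescore("g001", conn, de, lambda = 2)
  sub <- compute_genescore("g001", conn, de, gene_subset = rownames(comp),
                           lambda = 2)
  expect_identical(full$score, sub$score)
  expect_identical(full$num_y, sub$num_y)
})

test_that("the connectivity-lambda-score pipeline matches a brute-force oracle", {
  set.seed(14)
  comp <- matrix(rlnorm(10 * 6, 2, 0.8), 10,
                 dimnames = list(sprintf("G%02d", 1:10), paste0("s", 1:6)))
  locus <- c("G01", "G02", "G03")
  de <- make_de(rownames(comp), runif(10, 1e-4, 1))
  conn <- compute_connectivity(locus, comp)
  lam <- genomic_control_lambda(de$p_value)

  # oracle: plain loops and explicit formulas, no shared code path
  pearson <- function(a, b) {
    am <- mean(a); bm <- mean(b)
    sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
  }
  lam_oracle <- median(qchisq(de$p_value, 1, lower.tail = FALSE)) /
    qchisq(0.5, 1)
  expect_equal(lam, lam_oracle, tolerance = 1e-12)
  for (x in locus) {
    acc <- 0; num <- 0
    for (y in rownames(comp)) {
      if (y == x) next
      r2 <- pearson(comp[x, ], comp[y, ])^2
      acc <- acc + (-log10(de$p_value[de$gene == y])) * r2
      num <- num + 1
    }
    oracle <- (acc / num) / log10(lam_oracle)
    expect_equal(compute_genescore(x, conn, de)$score, oracle,
                 tolerance = 1e-10)
  }
})

test_that("driver permutation p-values are reproducible and find planted drivers", {
  co <- generate_cohort(n_case_donors = 6, n_ctrl_donors = 9,
                        reps_per_donor = 2, n_genes = 300, locus_size = 3,
                        seed = 101)
  locus <- co$truth$locus_genes
  driver <- locus[1]
  set.seed(101)
  targets <- sample(setdiff(co$truth$expressed_genes, locus), 15)
  expr <- co$expression
  case_cols <- co$samples$sample_id[co$samples$group == "case"]
  expr[targets, case_cols] <- expr[targets, case_cols] * 2^0.8
  refgenes <- unique(c(locus, targets,
                       sample(setdiff(rownames(expr), c(locus, targets)),
                              130)))
  comp <- generate_reference_compendium(
    n_samples = 120, gene_names = refgenes,
    block_spec = list(list(genes = c(driver, targets), rho = 0.8)),
    seed = 101)
  conn <- compute_connectivity(locus, comp$expression)
  norm <- suppressMessages(inverse_normal_transform(expr))
  g1 <- suppressWarnings(genescore_permutation_pvalues(
    norm, co$samples, conn, n_perm = 120, seed = 5, enumerate = FALSE))
  g2 <- suppressWarnings(genescore_permutation_pvalues(
    norm, co$samples, conn, n_perm = 120, seed = 5, enumerate = FALSE))
  expect_identical(g1$results, g2$results)

  res <- g1$results
  expect_equal(res$p_empirical[res$gene == driver],
               min(res$p_empirical))
  # cluster scope restricted to its gene lists
  part <- list(cluster_id = "c1", specific_genes = targets,
               nonspecific_genes = character())
  g3 <- suppressWarnings(genescore_permutation_pvalues(
    norm, co$samples, conn, clusters = part, n_perm = 60, seed = 5,
    enumerate = FALSE))
  expect_setequal(unique(g3$results$scope), c("all", "c1"))
})

test_that("percentile FDR thresholds use nearest-rank order statistics", {
  p100 <- sort(runif(100))
  th <- percentile_fdr_thresholds(p100)
  expect_equal(unname(th["fdr_0.05"]), p100[5])
  expect_equal(unname(th["fdr_0.1"]), p100[10])

  p20 <- sort(runif(20))
  expect_equal(unname(percentile_fdr_thresholds(p20)["fdr_0.05"]), p20[1])

  expect_equal(unname(percentile_fdr_thresholds(rep(0.3, 50))),
               c(0.3, 0.3))

  th19 <- percentile_fdr_thresholds(sort(runif(19)))
  expect_true(is.na(th19["fdr_0.05"]))
  expect_false(is.na(th19["fdr_0.1"]))
})
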
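test_that("cluster partition separates unique from shared genes", {
  # disjoint clusters: everything specific
  parts <- partition_cluster_genes(list(A = c("a", "b"), B = c("c", "d")))
  expect_setequal(parts$A$specific_genes, c("a", "b"))
  expect_length(parts$A$nonspecific_genes, 0L)

  # a shared gene is non-specific in every cluster carrying it
  parts <- partition_cluster_genes(list(A = c("a", "g"), B = c("b", "g")))
  expect_identical(parts$A$nonspecific_genes, "g")
  expect_identical(parts$B$nonspecific_genes, "g")

  # bookkeeping: specific + shared memberships reproduce the input counts
  cs <- generate_cluster_sets(n_clusters = 10, specific_per_cluster = 25,
                              shared_per_cluster = 8, shared_pool_size = 20,
                              seed = 5)
  parts <- partition_cluster_genes(cs$sets)
  n_members <- sum(lengths(lapply(cs$sets, unique)))
  expect_equal(sum(vapply(parts, function(p) {
    length(p$specific_genes) + length(p$nonspecific_genes)
  }, 0L)), n_members)
  # and the planted partition is recovered exactly
  for (cl in names(parts)) {
    expect_setequal(parts[[cl]]$specific_genes,
                    cs$expected_partition[[cl]]$specific_genes)
    expect_setequal(parts[[cl]]$nonspecific_genes,
                    cs$expected_partition[[cl]]$nonspecific_genes)
  }
})

test_that("cluster score equals the specific minus non-specific -log10 p means", {
  de <- make_de(c("a", "b", "c"), c(1e-3, 1e-1, 1e-2))
  part <- list(cluster_id = "x", specific_genes = c("a", "b"),
               nonspecific_genes = "c")
  expect_equal(as.numeric(compute_cellscore(de, part)), 0)

  de2 <- make_de(c("a", "b", "c", "d"), c(0.01, 0.01, 1, 1))
  part2 <- list(cluster_id = "x", specific_genes = c("a", "b"),
                nonspecific_genes = c("c", "d"))
  expect_equal(as.numeric(compute_cellscore(de2, part2)), 2)

  # denominators count only genes present in the table
  part3 <- list(cluster_id = "x", specific_genes = c("a", "b", "ghost"),
                nonspecific_genes = "c")
  expect_message(s3 <- compute_cellscore(de, part3), "2/3")
  expect_equal(as.numeric(s3), 0)
  expect_equal(attr(s3, "n_specific"), 2L)

  part4 <- list(cluster_id = "x", specific_genes = "ghost",
                nonspecific_genes = "c")
  expect_warning(s4 <- compute_cellscore(de, part4), "no specific")
  expect_true(is.na(s4))
})

test_that("the score is centered when both gene groups are exchangeable", {
  set.seed(8)
  part <- list(cluster_id = "x", specific_genes = sprintf("s%d", 1:20),
               nonspecific_genes = sprintf("n%d", 1:10))
  scores <- vapply(1:1000, function(i) {
    de <- make_de(c(part$specific_genes, part$nonspecific_genes), runif(30))
    as.numeric(compute_cellscore(de, part))
  }, 0)
  expect_lt(abs(mean(scores)), 3 * sd(scores) / sqrt(1000))
})

test_that("pseudo-cases are drawn from controls only, at the observed counts", {
  sheet <- make_sheet(23, 36)
  set.seed(1)
  labels <- draw_permutation(sheet)
  expect_equal(sum(labels == "case"), 23L)
  real_ctrl <- sheet$sample_id[sheet$group == "control"]
  expect_true(all(names(labels)[labels == "case"] %in% real_ctrl))
  # all real cases end up pseudo-controls
  real_case <- sheet$sample_id[sheet$group == "case"]
  expect_true(all(labels[real_case] == "control"))

  sheet2 <- make_sheet(12, 36)
  expect_equal(sum(draw_permutation(sheet2) == "case"), 12L)

  expect_error(draw_permutation(make_sheet(5, 4)), "inapplicable")
})

test_that("null distributions are reproducible and enumerate small designs", {
  co <- generate_cohort(n_case_donors = 3, n_ctrl_donors = 6,
                        reps_per_donor = 1, n_genes = 80, locus_size = 0,
                        seed = 2)
  cs <- generate_cluster_sets(n_clusters = 2, specific_per_cluster = 10,
                              shared_per_cluster = 4, shared_pool_size = 6,
                              gene_pool = rownames(co$expression), seed = 2)
  parts <- partition_cluster_genes(cs$sets)
  norm <- suppressMessages(inverse_normal_transform(co$expression))
  n1 <- build_null_distribution(norm, co$samples, parts, n_perm = 40,
                                seed = 9, enumerate = FALSE)
  n2 <- build_null_distribution(norm, co$samples, parts, n_perm = 40,
                                seed = 9, enumerate = FALSE)
  expect_identical(n1$null_scores, n2$null_scores)

  # C(4,2) = 6 exhaustive pseudo-case assignments, each exactly once
  co2 <- generate_cohort(n_case_donors = 2, n_ctrl_donors = 4,
                         reps_per_donor = 1, n_genes = 60, locus_size = 0,
                         seed = 3)
  cs2 <- generate_cluster_sets(n_clusters = 2, specific_per_cluster = 8,
                               shared_per_cluster = 3, shared_pool_size = 5,
                               gene_pool = rownames(co2$expression), seed = 3)
  parts2 <- partition_cluster_genes(cs2$sets)
  norm2 <- suppressMessages(inverse_normal_transform(co2$expression))
  nn <- build_null_distribution(norm2, co2$samples, parts2, n_perm = 100,
                                seed = 1)
  expect_true(nn$enumerated)
  expect_equal(nn$n_permutations, 6L)
  expect_equal(length(unique(nn$null_scores[, 1])), 6L)
})

test_that("empirical p-values count null exceedances with a floor", {
  ep <- empirical_pvalue(2.5, c(1, 2, 3, 4))
  expect_equal(ep$p_empirical, 0.5)
  expect_false(ep$at_floor)

  expect_equal(empirical_pvalue(0.5, c(1, 2, 3, 4))$p_empirical, 1)

  ep2 <- empirical_pvalue(5, c(1, 2, 3, 4))
  expect_true(ep2$at_floor)
  expect_equal(ep2$p_empirical, 1 / 4)
})

test_that("Bonferroni thresholds divide the level by the test count", {
  expect_equal(fwer_threshold(10, 0.05), 0.005)
  expect_equal(fwer_threshold(10, 0.1), 0.01)
  expect_equal(fwer_threshold(1, 0.05), 0.05)
  expect_error(fwer_threshold(0, 0.05))
  expect_error(fwer_threshold(10, 1.5))
})

test_that("score-weighted p combination follows the stated weights", {
  expect_equal(combine_dataset_pvalues(1, 0.01, 1, 0.01)$neglog10, 2)
  expect_equal(combine_dataset_pvalues(2, 1e-3, 0, 0.5)$neglog10, 3)
  out <- combine_dataset_pvalues(3, 1e-4, 1, 1e-2)
  expect_equal(out$neglog10, 3.5)
  expect_equal(out$p, 10^-3.5)
  # signs do not matter, only magnitudes
  expect_equal(combine_dataset_pvalues(-3, 1e-4, 1, 1e-2)$neglog10, 3.5)
  expect_warning(out0 <- combine_dataset_pvalues(0, 0.5, 0, 0.5), "zero")
  expect_true(is.na(out0$neglog10))
})

test_that("directional overlaps and cluster merging behave as set operations", {
  sets <- list(A = c("a", "b", "c", "d"), B = c("a", "b"),
               C = c("x", "y"))
  ov <- pairwise_overlap_matrix(sets)
  expect_equal(ov["A", "B"], 50)
  expect_equal(ov["B", "A"], 100)
  expect_equal(ov["A", "C"], 0)
  expect_equal(unname(diag(ov)), rep(100, 3))

  # no pair reaches the threshold: every cluster is its own group
  disj <- list(A = letters[1:4], B = letters[5:8], C = letters[9:12])
  dd <- deduplicate_clusters(pairwise_overlap_matrix(disj), disj,
                             threshold = 50)
  expect_length(dd$groups, 3L)

  # chain A~B, B~C joins into one component
  sets2 <- list(A = letters[1:4], B = letters[3:6], C = letters[5:8])
  ov2 <- pairwise_overlap_matrix(sets2)
  dd2 <- deduplicate_clusters(ov2, sets2, threshold = 50)
  expect_length(dd2$groups, 1L)
  expect_setequal(dd2$union_sets[[1]], letters[1:8])
})

test_that("24 clusters built from 11 templates collapse to 11 groups", {
  set.seed(6)
  templates <- lapply(1:11, function(i) sprintf("t%02d_g%02d", i, 1:20))
  names(templates) <- sprintf("T%02d", 1:11)
  copies <- lapply(1:13, function(j) {
    src <- templates[[((j - 1) %% 11) + 1]]
    sample(src, 12)  # subset: 100% of the copy lies in its template
  })
  names(copies) <- sprintf("K%02d", 1:13)
  sets <- c(templates, copies)
  dd <- deduplicate_clusters(pairwise_overlap_matrix(sets), sets,
                             threshold = 50)
  expect_length(dd$groups, 11L)
})

test_that("atlas profiles average the two overlap directions", {
  atlas <- list(N = sprintf("n%d", 1:10), G = sprintf("g%d", 1:8))
  cluster <- sprintf("n%d", 1:5)  # fully inside atlas set N
  prof <- atlas_overlap_profile(cluster, atlas)
  expect_equal(unname(prof["N"]), mean(c(100, 50)))
  expect_equal(unname(prof["G"]), 0)

  expect_true(all(atlas_overlap_profile(c("q1", "q2"), atlas) == 0))

  atlas6 <- setNames(lapply(1:6, function(i) sprintf("a%d_%d", i, 1:5)),
                     paste0("ct", 1:6))
  expect_length(atlas_overlap_profile(cluster, atlas6), 6L)
})

test_that("profile correlations pass through Pearson with guards", {
  a <- c(1, 5, 2, 8)
  expect_equal(profile_correlation(a, a)$r, 1)
  expect_equal(profile_correlation(a, -a + 10)$r, -1)
  expect_equal(profile_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_warning(out <- profile_correlation(c(1, 1, 1), a[1:3]), "zero")
  expect_true(is.na(out$r))
})

test_that("a strongly perturbed cluster is flagged by the full analysis", {
  co <- generate_cohort(n_case_donors = 6, n_ctrl_donors = 9,
                        reps_per_donor = 2, n_genes = 400, locus_size = 0,
                        seed = 1)
  cs <- generate_cluster_sets(n_clusters = 10, specific_per_cluster = 15,
                              shared_per_cluster = 5, shared_pool_size = 30,
                              gene_pool = rownames(co$expression), seed = 1)
  tgt <- cs$expected_partition$c1$specific_genes
  co <- generate_cohort(n_case_donors = 6, n_ctrl_donors = 9,
                        reps_per_donor = 2, n_genes = 400, locus_size = 0,
                        perturbed_genes = tgt, perturbed_effect = 0.8,
                        seed = 1)
  norm <- suppressMessages(inverse_normal_transform(co$expression))
  r <- suppressWarnings(suppressMessages(
    run_cellscore(norm, co$samples, cs$sets, n_perm = 500, seed = 1,
                  enumerate = FALSE)))
  res <- r$results
  expect_identical(res$cluster[which.min(res$p_empirical)], "c1")
  expect_true(res$fwer_0.05[res$cluster == "c1"])
  expect_true(res$at_floor[res$cluster == "c1"])
})
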
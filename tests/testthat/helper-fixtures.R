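# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal sample sheet with n_case + n_ctrl donors and `reps` replicates each.
make_sheet <- function(n_case, n_ctrl, reps = 1L) {
  donors <- c(sprintf("ca%02d", seq_len(n_case)),
              sprintf("co%02d", seq_len(n_ctrl)))
  grp <- rep(c("case", "control"), c(n_case, n_ctrl))
  data.frame(
    sample_id = paste0(rep(donors, each = reps), "_r", seq_len(reps)),
    donor_id = rep(donors, each = reps),
    replicate_index = rep(seq_len(reps), n_case + n_ctrl),
    group = rep(grp, each = reps),
    stringsAsFactors = FALSE)
}

# Differential-expression table stub from gene names and p-values.
make_de <- function(genes, p) {
  data.frame(gene = genes, p_value = p, stringsAsFactors = FALSE)
}

# Random expression matrix with named dimensions.
make_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(stats::rlnorm(n_genes * n_samples, 1, 0.6), n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# A null cohort with exchangeable samples (no donor effect, no global
# factor), a 2-cluster gene-set collection over its genes, and the empirical
# p-value of the first cluster's score at `n_perm` permutations.
null_cohort_pvalue <- function(seed, n_perm = 1000L) {
  co <- generate_cohort(n_case_donors = 6, n_ctrl_donors = 9,
                        reps_per_donor = 2, n_genes = 150, locus_size = 0,
                        donor_sd = 0, rep_sd = 0.4, global_factor_sd = 0,
                        seed = 1000 + seed)
  cs <- generate_cluster_sets(n_clusters = 2, specific_per_cluster = 12,
                              shared_per_cluster = 6, shared_pool_size = 8,
                              gene_pool = rownames(co$expression),
                              seed = seed)
  norm <- suppressMessages(inverse_normal_transform(co$expression))
  r <- suppressWarnings(suppressMessages(
    run_cellscore(norm, co$samples, cs$sets, n_perm = n_perm, seed = seed,
                  enumerate = FALSE)))
  r$results$p_empirical[1L]
}
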
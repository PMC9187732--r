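#' Collapse a transcript-level matrix to one representative transcript per gene
#'
#' For each gene, the transcript with the highest mean FPKM across all samples
#' (cases and controls alike) is retained and relabelled by its gene symbol.
#' Ties are broken by the lexicographically smallest transcript id, with a
#' message naming the genes affected.
#'
#' @param tx Transcript-by-sample matrix carrying a `gene_of_transcript`
#'   attribute (named character vector, transcript id -> gene symbol), or
#'   supply `gene_of_transcript` directly.
#' @param gene_of_transcript Optional named character vector overriding the
#'   attribute.
#' @return Gene-by-sample matrix; the `representative_transcript` attribute
#'   records which transcript backs each gene row.
#' @export
select_representative_transcripts <- function(tx, gene_of_transcript = NULL) {
  map <- if (is.null(gene_of_transcript)) attr(tx, "gene_of_transcript")
         else gene_of_transcript
  if (is.null(map)) stop("no transcript-to-gene mapping supplied")
  unmapped <- setdiff(rownames(tx), names(map))
  if (length(unmapped)) {
    stop("transcript(s) without a gene mapping: ",
         paste(unmapped, collapse = ", "))
  }
  gene <- map[rownames(tx)]
  mu <- rowMeans(tx)
  # order: gene, descending mean, ascending transcript id -> first per gene wins
  ord <- order(gene, -mu, rownames(tx), method = "radix")
  keep <- ord[!duplicated(gene[ord])]
  # report genuine ties at the top mean
  top_by_gene <- split(mu, gene)
  tie <- names(top_by_gene)[vapply(top_by_gene, function(v) {
    sum(v == max(v)) > 1L
  }, NA)]
  if (length(tie)) {
    message("tie on mean FPKM for gene(s) ", paste(tie, collapse = ", "),
            "; kept the lexicographically smallest transcript id")
  }
  out <- tx[keep, , drop = FALSE]
  reps <- rownames(out)
  rownames(out) <- unname(gene[keep])
  attr(out, "representative_transcript") <- stats::setNames(reps,
                                                            rownames(out))
  attr(out, "gene_of_transcript") <- NULL
  out
}

#' Remove genes not expressed above a mean-FPKM threshold
#'
#' A gene is kept when its mean FPKM across all samples (cases and controls)
#' is at least `threshold`; genes with mean strictly below are removed. The
#' default of 2 FPKM is the conventional floor below which bulk RNA-seq
#' quantification is dominated by background.
#'
#' @param m Gene-by-sample FPKM matrix.
#' @param threshold Positive mean-FPKM cutoff (default 2).
#' @return The filtered matrix; warns (not errors) when nothing survives.
#' @export
filter_expressed <- function(m, threshold = 2) {
  stopifnot(threshold > 0)
  keep <- rowMeans(m) >= threshold
  if (!any(keep)) {
    warning("no gene reaches mean FPKM >= ", threshold, call. = FALSE)
  }
  m[keep, , drop = FALSE]
}

#' Flag genes with outlying intra- or inter-individual variability
#'
#' Variability is measured on control samples only, so that genuine
#' case/control differences are not discarded as noise. Per gene, the
#' intra-individual statistic is the maximum across control donors of the SD
#' over that donor's replicates; the inter-individual statistic is the SD
#' across control-donor mean expressions. Each statistic is z-scored across
#' genes and flagged when the z-score exceeds the cutoff (defaults 2 intra,
#' 1.5 inter). Donors with a single replicate contribute no intra-donor SD.
#'
#' @param m Gene-by-sample FPKM matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @param intra_z z cutoff on the max intra-donor SD (default 2).
#' @param inter_z z cutoff on the inter-donor SD (default 1.5).
#' @return A list with `per_gene` (data.frame: gene, max_intra_sd, inter_sd,
#'   the z-scores, intra_flag, inter_flag), `intra_sd_per_donor` (gene x donor
#'   matrix), and `flagged` (union of flagged gene names).
#' @export
flag_variable_genes <- function(m, sheet, intra_z = 2, inter_z = 1.5) {
  sheet <- validate_sample_sheet(sheet)
  ctrl <- sheet[sheet$group == "control", , drop = FALSE]
  if (length(unique(ctrl$donor_id)) < 2L) {
    stop("need at least 2 control donors to assess variability")
  }
  missing <- setdiff(ctrl$sample_id, colnames(m))
  if (length(missing)) {
    stop("control sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  donors <- unique(ctrl$donor_id)
  donor_cols <- lapply(donors, function(d) ctrl$sample_id[ctrl$donor_id == d])
  names(donor_cols) <- donors
  multi <- vapply(donor_cols, function(cc) length(cc) >= 2L, NA)
  if (any(!multi)) {
    message("control donor(s) with a single replicate contribute no ",
            "intra-donor SD: ", paste(donors[!multi], collapse = ", "))
  }
  intra_sd <- sapply(donor_cols[multi], function(cc) {
    apply(m[, cc, drop = FALSE], 1L, stats::sd)
  })
  if (is.null(dim(intra_sd)) || ncol(as.matrix(intra_sd)) == 0L) {
    intra_sd <- matrix(NA_real_, nrow(m), 0L,
                       dimnames = list(rownames(m), NULL))
  }
  if (ncol(intra_sd) == 0L) {
    warning("all control donors have a single replicate; ",
            "intra-individual flags are all FALSE", call. = FALSE)
    max_intra <- rep(NA_real_, nrow(m))
    z_intra <- rep(NA_real_, nrow(m))
    intra_flag <- rep(FALSE, nrow(m))
  } else {
    max_intra <- apply(intra_sd, 1L, max)
    z_intra <- as.numeric(scale(max_intra))
    intra_flag <- !is.na(z_intra) & z_intra > intra_z
  }
  donor_means <- sapply(donor_cols, function(cc) {
    rowMeans(m[, cc, drop = FALSE])
  })
  inter_sd <- apply(donor_means, 1L, stats::sd)
  z_inter <- as.numeric(scale(inter_sd))
  inter_flag <- !is.na(z_inter) & z_inter > inter_z
  per_gene <- data.frame(gene = rownames(m), max_intra_sd = max_intra,
                         inter_sd = inter_sd, z_intra = z_intra,
                         z_inter = z_inter, intra_flag = intra_flag,
                         inter_flag = inter_flag, row.names = NULL,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene, intra_sd_per_donor = intra_sd,
       flagged = per_gene$gene[intra_flag | inter_flag])
}

#' Rank-based inverse normal transform of each gene's expression profile
#'
#' Per gene across samples, values are replaced by standard-normal quantiles
#' of their Blom-offset fractional ranks, `qnorm((rank - 3/8) / (n + 1/4))`,
#' with ties receiving averaged ranks. This tames outlier expression values
#' before linear-model analyses. A constant row maps to all zeros (noted via
#' a message), not an error.
#'
#' @param m Gene-by-sample matrix.
#' @return Matrix of the same shape on the normal-quantile scale.
#' @export
inverse_normal_transform <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("inverse normal transform needs at least 2 samples")
  const <- apply(m, 1L, function(x) all(x == x[1L]))
  if (any(const)) {
    message(sum(const), " constant row(s) map to all zeros")
  }
  out <- t(apply(m, 1L, function(x) {
    r <- rank(x, ties.method = "average")
    stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  }))
  dimnames(out) <- dimnames(m)
  out
}

#' Replicate-concordance diagnostics
#'
#' All pairwise squared Pearson correlations between sample columns,
#' partitioned into intra-individual pairs (same donor) and inter-individual
#' pairs (different donors), with group means and a two-sided Wilcoxon
#' rank-sum comparison. In a well-behaved cohort the intra-individual
#' correlations should not be lower than the inter-individual ones.
#'
#' @param m Gene-by-sample matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @return A list: `pairs` (data.frame sample_a, sample_b, r_squared, type),
#'   `mean_intra`, `mean_inter`, `p_value` (Wilcoxon; NA when either side is
#'   empty).
#' @export
replicate_correlations <- function(m, sheet) {
  sheet <- validate_sample_sheet(sheet)
  ids <- intersect(colnames(m), sheet$sample_id)
  if (length(ids) < 2L) stop("need at least two samples in common")
  donor <- stats::setNames(sheet$donor_id, sheet$sample_id)
  cm <- stats::cor(m[, ids, drop = FALSE])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(sample_a = ids[idx[, 1L]], sample_b = ids[idx[, 2L]],
                      r_squared = cm[idx]^2, stringsAsFactors = FALSE)
  pairs$type <- ifelse(donor[pairs$sample_a] == donor[pairs$sample_b],
                       "intra", "inter")
  intra <- pairs$r_squared[pairs$type == "intra"]
  inter <- pairs$r_squared[pairs$type == "inter"]
  if (!length(intra)) {
    message("no intra-individual pairs; comparison skipped")
  }
  p <- if (length(intra) && length(inter)) {
    stats::wilcox.test(intra, inter, exact = FALSE)$p.value
  } else NA_real_
  list(pairs = pairs,
       mean_intra = if (length(intra)) mean(intra) else NA_real_,
       mean_inter = if (length(inter)) mean(inter) else NA_real_,
       p_value = p)
}

#' Check that a panel of marker genes is absent from the cohort
#'
#' Used e.g. to confirm clearance of reprogramming-vector (Sendai virus)
#' transcripts: passes when no panel gene has mean expression at or above the
#' threshold. Panel genes absent from the matrix count as not detected.
#'
#' @param m Gene-by-sample FPKM matrix.
#' @param panel Character vector of gene symbols.
#' @param threshold Mean-FPKM presence threshold (default 2).
#' @return A list: `clear` (logical) and `report` (data.frame gene, detected,
#'   mean_fpkm, above_threshold).
#' @export
check_panel_absence <- function(m, panel, threshold = 2) {
  stopifnot(threshold > 0)
  detected <- panel %in% rownames(m)
  mu <- rep(NA_real_, length(panel))
  mu[detected] <- rowMeans(m[panel[detected], , drop = FALSE])
  above <- detected & !is.na(mu) & mu >= threshold
  list(clear = !any(above),
       report = data.frame(gene = panel, detected = detected, mean_fpkm = mu,
                           above_threshold = above, stringsAsFactors = FALSE))
}

#' Run the full QC funnel
#'
#' Fixed order: representative-transcript selection (when a mapping is
#' present), mean-expression filter, variability flagging and removal on
#' control samples, then inverse normal transformation. Returns both the
#' filtered FPKM matrix (for fold changes, which need the raw scale) and the
#' normalized matrix (for PCA and regression).
#'
#' @param m Expression matrix (transcript- or gene-level).
#' @param sheet Sample sheet.
#' @param config An [analysis_config()].
#' @return List: `fpkm` (filtered FPKM matrix), `normalized`,
#'   `variability` (report from [flag_variable_genes()]), `n_input`,
#'   `n_expressed`, `n_retained`.
#' @export
run_qc <- function(m, sheet, config = analysis_config()) {
  if (!is.null(attr(m, "gene_of_transcript"))) {
    m <- select_representative_transcripts(m)
  }
  n_input <- nrow(m)
  expressed <- filter_expressed(m, config$fpkm_threshold)
  rep_var <- flag_variable_genes(expressed, sheet,
                                 intra_z = config$intra_sd_z,
                                 inter_z = config$inter_sd_z)
  keep <- setdiff(rownames(expressed), rep_var$flagged)
  fpkm <- expressed[keep, , drop = FALSE]
  list(fpkm = fpkm, normalized = inverse_normal_transform(fpkm),
       variability = rep_var, n_input = n_input,
       n_expressed = nrow(expressed), n_retained = nrow(fpkm))
}
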
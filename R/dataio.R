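#' Read a gene/transcript-by-sample expression matrix from TSV
#'
#' Expression values are FPKM-scale non-negative reals. The file must be
#' tab-separated with row identifiers (gene symbols or transcript ids) in the
#' first column and sample identifiers in the header. An optional two-column
#' id map (transcript id, gene symbol; TSV, no header required beyond the two
#' columns) attaches the transcript-to-gene mapping used by
#' [select_representative_transcripts()].
#'
#' @param path Path to the expression TSV.
#' @param id_map_path Optional path to a transcript-to-gene map TSV.
#' @return A numeric matrix (rows = genes/transcripts, columns = samples).
#'   When an id map is supplied it is attached as the `gene_of_transcript`
#'   attribute, a named character vector keyed by transcript id.
#' @export
read_expression_matrix <- function(path, id_map_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression file needs a row-id column plus at least one sample: ",
         path)
  }
  ids <- as.character(df[[1L]])
  samples <- colnames(df)[-1L]
  dup_r <- ids[duplicated(ids)]
  if (length(dup_r)) {
    stop("duplicate row identifier(s) in ", path, ": ",
         paste(unique(dup_r), collapse = ", "))
  }
  dup_c <- samples[duplicated(samples)]
  if (length(dup_c)) {
    stop("duplicate sample identifier(s) in ", path, ": ",
         paste(unique(dup_c), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L,
                                              as.numeric))), arr.ind = TRUE)
    stop("non-numeric expression value at row '", ids[bad[1L, 1L]],
         "', column '", samples[bad[1L, 2L]], "' in ", path)
  }
  rownames(m) <- ids
  m <- validate_expression_matrix(m)
  if (!is.null(id_map_path)) {
    map <- utils::read.delim(id_map_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    attr(m, "gene_of_transcript") <-
      stats::setNames(as.character(map[[2L]]), as.character(map[[1L]]))
  }
  m
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique row and column identifiers and
#' finite non-negative values.
#'
#' @param m Numeric matrix with row and column names.
#' @return `m`, invisibly unchanged, for piping.
#' @export
validate_expression_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry row and column identifiers")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate row identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-finite expression value at row '",
         rownames(m)[bad[1L, 1L]], "', column '",
         colnames(m)[bad[1L, 2L]], "'")
  }
  m
}

#' Read and validate a sample sheet
#'
#' The sheet drives the case/control design and the pseudo-case permutation
#' scheme. Required columns: `sample_id`, `donor_id`, `replicate_index`,
#' `group`. Group labels are normalized to lower case and must be `case` or
#' `control`; a donor may belong to only one group.
#'
#' @param path Path to the sample-sheet TSV.
#' @return A `data.frame` with the validated columns (extra columns are kept
#'   as covariates).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data frame
#'
#' @param df Data frame with columns `sample_id`, `donor_id`,
#'   `replicate_index`, `group`.
#' @return The validated data frame with `group` normalized to
#'   `case`/`control`.
#' @export
validate_sample_sheet <- function(df) {
  required <- c("sample_id", "donor_id", "replicate_index", "group")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$donor_id <- as.character(df$donor_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  ri <- df$replicate_index
  if (!is.numeric(ri) || any(!is.finite(ri)) || any(ri < 1) ||
      any(ri != round(ri))) {
    stop("replicate_index must be a positive integer")
  }
  grp <- tolower(trimws(as.character(df$group)))
  unknown <- setdiff(unique(grp), c("case", "control"))
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " (expected 'case' or 'control')")
  }
  df$group <- grp
  split_groups <- tapply(df$group, df$donor_id,
                         function(g) length(unique(g)))
  inconsistent <- names(split_groups)[split_groups > 1L]
  if (length(inconsistent)) {
    stop("donor(s) listed in both groups: ",
         paste(inconsistent, collapse = ", "))
  }
  df
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one gene symbol per field, all
#' tab-separated. Gene symbols are kept verbatim and matched case-sensitively
#' throughout the package; no alias resolution is attempted. Duplicate genes
#' within one set are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors in file order, with set
#'   descriptions in the `description` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- stats::setNames(list(), character())
    attr(out, "description") <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields in ", path)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-c(1L, 2L)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("gene set '", nm[i], "' contains repeated gene(s): ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "),
              "; stored once each", call. = FALSE)
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors, optionally carrying a
#'   `description` attribute.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Header for the row-identifier column.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table to TSV
#'
#' Real values are rendered with at least six significant digits. When the
#' table carries empirical p-values at the permutation floor (columns
#' `p_empirical` and `at_floor`), floored entries are rendered as an explicit
#' bound, e.g. `<1e-06` for one million permutations, mirroring how
#' permutation p-values below the resolution of the null should be reported.
#'
#' @param rows A data frame of homogeneous records.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(signif(v, 6L))
      }, "")
    }
  }
  if (all(c("p_empirical", "at_floor") %in% colnames(out)) &&
      nrow(out) > 0L) {
    fl <- which(rows$at_floor %in% TRUE)
    out$p_empirical[fl] <- paste0("<", format(rows$p_empirical[fl]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Default analysis configuration
#'
#' Central place for the tunable thresholds of the pipeline: the mean-FPKM
#' expression filter (2), the intra-/inter-individual variability z cutoffs
#' (2 and 1.5), the permutation count, the family-wise error levels (0.05,
#' 0.1) and the percentage overlap threshold used to merge redundant clusters
#' (50).
#'
#' @param fpkm_threshold Mean-FPKM expression filter.
#' @param intra_sd_z z-score cutoff for intra-individual variability.
#' @param inter_sd_z z-score cutoff for inter-individual variability.
#' @param n_permutations Number of label permutations for empirical p-values.
#' @param seed Integer seed for all randomized steps.
#' @param fwer_levels Family-wise error levels flagged in score tables.
#' @param overlap_merge_threshold Percentage overlap above which two clusters
#'   are merged as redundant.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fpkm_threshold = 2, intra_sd_z = 2,
                            inter_sd_z = 1.5, n_permutations = 100000L,
                            seed = 1L, fwer_levels = c(0.05, 0.1),
                            overlap_merge_threshold = 50) {
  stopifnot(fpkm_threshold > 0, intra_sd_z > 0, inter_sd_z > 0,
            n_permutations >= 1, overlap_merge_threshold > 0,
            overlap_merge_threshold <= 100, all(fwer_levels > 0),
            all(fwer_levels < 1))
  structure(list(fpkm_threshold = fpkm_threshold, intra_sd_z = intra_sd_z,
                 inter_sd_z = inter_sd_z,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), fwer_levels = fwer_levels,
                 overlap_merge_threshold = overlap_merge_threshold),
            class = "analysis_config")
}
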
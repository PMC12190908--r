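#' Construct an expression matrix object
#'
#' Container for a log2 protein-expression matrix (proteins x samples) with a
#' protein-group to gene-symbol mapping. Missing quantifications are `NA`.
#'
#' @param values numeric matrix of log2 intensities, proteins in rows and
#'   samples in columns; `NA` marks a missing quantification.
#' @param protein_ids character vector of unique protein-group identifiers,
#'   one per row.
#' @param gene_symbols character vector of gene symbols, one per protein
#'   group (the first listed symbol of each group).
#' @param sample_ids character vector of sample identifiers, one per column.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `protein_ids`, `gene_symbols` and `sample_ids`. Row and column
#'   names of `values` are set to `protein_ids` and `sample_ids`.
#' @export
expression_matrix <- function(values, protein_ids, gene_symbols, sample_ids) {
  values <- as.matrix(values)
  protein_ids <- as.character(protein_ids)
  gene_symbols <- as.character(gene_symbols)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(protein_ids) ||
      length(protein_ids) != length(gene_symbols)) {
    .stopf("row count (%d) must equal |protein_ids| and |gene_symbols|",
           nrow(values))
  }
  if (ncol(values) != length(sample_ids)) {
    .stopf("column count (%d) must equal |sample_ids| (%d)",
           ncol(values), length(sample_ids))
  }
  if (anyDuplicated(protein_ids)) {
    .stopf("duplicate protein ids: %s",
           paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) .stopf("duplicate sample ids")
  if (!is.numeric(values)) .stopf("expression values must be numeric")
  if (any(is.infinite(values))) .stopf("expression values must be finite or NA")
  dimnames(values) <- list(protein_ids, sample_ids)
  structure(list(values = values, protein_ids = protein_ids,
                 gene_symbols = gene_symbols, sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read a log2 expression matrix from TSV
#'
#' Expected layout: first column `protein_id`, second column `gene_symbol`,
#' remaining columns one per sample. Blank cells and NA tokens mark missing
#' values; any other non-numeric cell is an error.
#'
#' @param path path to the TSV file.
#' @param na_tokens character vector of cell contents treated as missing.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, na_tokens = c("", "NA")) {
  df <- .read_tsv(path, colClasses = "character")
  if (ncol(df) < 3) .stopf("expression TSV needs protein_id, gene_symbol and >=1 sample column")
  protein_ids <- df[[1]]
  gene_symbols <- df[[2]]
  sample_ids <- names(df)[-(1:2)]
  vals <- sapply(seq_along(sample_ids), function(j) {
    v <- df[[j + 2]]
    v[v %in% na_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      .stopf("non-numeric cell '%s' in column '%s' (data row %d)",
             v[bad[1]], sample_ids[j], bad[1])
    }
    num
  })
  vals <- matrix(vals, nrow = length(protein_ids),
                 dimnames = list(protein_ids, sample_ids))
  expression_matrix(vals, protein_ids, gene_symbols, sample_ids)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; missing values are written as
#' empty cells.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(protein_id = x$protein_ids, gene_symbol = x$gene_symbols,
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}

#' Read a sample-annotation (design) table
#'
#' Required columns: `sample_id`, `condition` (drug label or the control
#' label, conventionally "DMSO"), `batch`, `replicate`.
#'
#' @param path path to the design TSV.
#' @return data.frame with the four design columns.
#' @export
read_sample_annotation <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  .require_columns(df, c("sample_id", "condition", "batch", "replicate"),
                   "sample annotation")
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1)) {
    .stopf("replicate must be an integer >= 1")
  }
  if (anyDuplicated(df$sample_id)) .stopf("duplicate sample_id in design")
  df
}

#' @noRd
.check_design <- function(x, design, control = "DMSO") {
  .require_columns(design, c("sample_id", "condition", "batch", "replicate"),
                   "sample annotation")
  missing <- setdiff(x$sample_ids, design$sample_id)
  if (length(missing) > 0) {
    .stopf("samples missing from design: %s", paste(missing, collapse = ", "))
  }
  design[match(x$sample_ids, design$sample_id), , drop = FALSE]
}

#' Average replicates into per-condition expression values
#'
#' Per protein and condition, the mean over present (non-missing) replicate
#' values; a protein with no present value in a condition stays missing.
#'
#' @param x an [expression_matrix()].
#' @param design design data.frame covering all samples of `x`.
#' @return numeric matrix, proteins x conditions.
#' @export
pool_replicates <- function(x, design) {
  stopifnot(inherits(x, "expression_matrix"))
  design <- .check_design(x, design)
  conditions <- unique(design$condition)
  out <- sapply(conditions, function(cc) {
    cols <- design$sample_id[design$condition == cc]
    rowMeans(x$values[, cols, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(x$protein_ids, conditions))
  out
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson MDS (via [stats::cmdscale()]) on the Euclidean distance between
#' samples, using only proteins quantified in every sample, for quality
#' control of replicate closeness. Deterministic up to axis sign.
#'
#' @param x an [expression_matrix()] with at least 3 samples.
#' @param k number of output dimensions.
#' @return numeric matrix, samples x `k`, rownames = sample ids.
#' @export
mds_projection <- function(x, k = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  if (ncol(x$values) < 3) .stopf("MDS requires >= 3 samples")
  complete <- stats::complete.cases(x$values)
  if (sum(complete) < 1) .stopf("no protein is quantified in all samples")
  d <- dist(t(x$values[complete, , drop = FALSE]))
  coords <- cmdscale(d, k = k)
  rownames(coords) <- x$sample_ids
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}
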
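#' Construct an expression dataset
#'
#' Bundles a samples-by-genes numeric matrix with per-sample class labels.
#' This is the container every other stage of the package consumes: rows are
#' samples (arrays, patients), columns are genes (probes), and `labels` holds
#' the diagnostic class of each sample.
#'
#' @param values numeric matrix, samples in rows, genes in columns. May
#'   contain `NA` for missing intensities (remove them with
#'   [impute_missing()] before modelling).
#' @param labels vector of class labels, one per row of `values`; coerced to
#'   factor.
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values` or generated `gene_k` / `sample_k` names.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `labels`, `gene_ids`, `sample_ids`.
#' @examples
#' x <- matrix(rnorm(12), nrow = 4)
#' ds <- expression_dataset(x, labels = c("a", "a", "b", "b"))
#' dim(ds$values)
#' @export
expression_dataset <- function(values, labels, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2) rb_stop("need at least 2 samples", "rb_invalid_dataset")
  if (ncol(values) < 1) rb_stop("need at least 1 gene", "rb_invalid_dataset")
  if (length(labels) != nrow(values)) {
    rb_stop(sprintf("label count (%d) does not match sample count (%d)",
                    length(labels), nrow(values)), "rb_dim_mismatch")
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, labels = factor(labels),
                 gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "ExpressionDataset")
}

#' @exportS3Method base::print
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d genes, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels),
              paste(levels(x$labels), collapse = ", ")))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  %d missing cells\n", nmiss))
  invisible(x)
}

#' @exportS3Method base::dim
dim.ExpressionDataset <- function(x) dim(x$values)

#' Load an expression matrix and labels from delimited text
#'
#' Reads a tab- or comma-delimited expression matrix (header row of gene ids,
#' first column of sample ids) together with a two-column labels file
#' (`sample_id`, `label`). Cells equal to one of `missing_tokens` become
#' `NA`; any other non-numeric cell is an error.
#'
#' @param matrix_path path to the delimited expression matrix.
#' @param labels_path path to the two-column labels file (header optional).
#' @param genes_as_rows set `TRUE` for the common microarray dialect with
#'   genes in rows and samples in columns; the matrix is transposed on load.
#' @param missing_tokens character vector of strings treated as missing.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @return An [expression_dataset()] whose `values` may contain `NA`.
#' @seealso [write_dataset()], [impute_missing()]
#' @export
load_dataset <- function(matrix_path, labels_path, genes_as_rows = FALSE,
                         missing_tokens = c("NA", ""), sep = NULL) {
  if (!file.exists(matrix_path)) rb_stop(paste("matrix file not found:", matrix_path), "rb_io_error")
  if (!file.exists(labels_path)) rb_stop(paste("labels file not found:", labels_path), "rb_io_error")
  if (is.null(sep)) sep <- "auto"
  dt <- data.table::fread(matrix_path, sep = sep, header = TRUE,
                          na.strings = missing_tokens, colClasses = list(character = 1),
                          data.table = FALSE, showProgress = FALSE)
  row_ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0) {
        rb_stop(sprintf("non-numeric cell '%s' in column %s", col[bad[1]], names(body)[j]),
                "rb_parse_error")
      }
      body[[j]] <- num
    }
  }
  values <- as.matrix(body)
  rownames(values) <- row_ids
  if (genes_as_rows) values <- t(values)

  lab <- data.table::fread(labels_path, sep = sep, header = FALSE,
                           data.table = FALSE, showProgress = FALSE)
  if (ncol(lab) < 2) rb_stop("labels file must have two columns (sample_id, label)", "rb_parse_error")
  # tolerate a header row
  if (nrow(lab) == nrow(values) + 1 && !(lab[1, 1] %in% rownames(values))) {
    lab <- lab[-1, , drop = FALSE]
  }
  if (nrow(lab) != nrow(values)) {
    rb_stop(sprintf("labels file has %d rows but matrix has %d samples",
                    nrow(lab), nrow(values)), "rb_dim_mismatch")
  }
  idx <- match(rownames(values), as.character(lab[[1]]))
  if (anyNA(idx)) rb_stop("sample ids in labels file do not match the matrix", "rb_dim_mismatch")
  expression_dataset(values, labels = as.character(lab[[2]][idx]))
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [load_dataset()]: writes the matrix with a header row of gene
#' ids and a first column of sample ids, plus a two-column labels file.
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,labels_path output paths.
#' @param sep field separator (default tab).
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, matrix_path, labels_path, sep = "\t") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  out <- data.table::data.table(sample_id = ds$sample_ids)
  # format at 17 significant digits so doubles round-trip bit-for-bit
  txt <- data.table::as.data.table(lapply(seq_len(ncol(ds$values)), function(j) {
    col <- ds$values[, j]
    ifelse(is.na(col), NA_character_, sprintf("%.17g", col))
  }))
  data.table::setnames(txt, ds$gene_ids)
  out <- cbind(out, txt)
  data.table::fwrite(out, matrix_path, sep = sep, na = "NA", quote = FALSE)
  data.table::fwrite(data.table::data.table(sample_id = ds$sample_ids,
                                            label = as.character(ds$labels)),
                     labels_path, sep = sep, col.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Impute missing expression values by the gene mean
#'
#' Replaces every missing cell with the mean of the observed values of the
#' same gene; observed cells are untouched.
#'
#' @param ds an [expression_dataset()], possibly with `NA` cells.
#' @return The dataset with no missing cells.
#' @export
impute_missing <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  v <- ds$values
  miss <- is.na(v)
  if (!any(miss)) return(ds)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    rb_stop(sprintf("gene(s) with no observed values: %s",
                    paste(head(ds$gene_ids[all_missing], 5), collapse = ", ")),
            "rb_all_missing_gene")
  }
  gmeans <- colMeans(v, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  v[idx] <- gmeans[idx[, 2]]
  ds$values <- v
  ds
}

#' Gene-wise standardization statistics
#'
#' Computes the per-gene center (mean) and scale (population standard
#' deviation, i.e. dividing by the sample count) used by
#' [normalize_genes()]. Computing the statistics separately lets you fit them
#' on training samples only and apply them to held-out samples.
#'
#' @param ds an [expression_dataset()] without missing cells.
#' @return A list with numeric vectors `center` and `scale` (one entry per
#'   gene; `scale` is 0 for constant genes).
#' @export
normalization_stats <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  v <- ds$values
  if (anyNA(v)) rb_stop("impute missing values before normalization", "rb_missing_values")
  n <- nrow(v)
  center <- colMeans(v)
  # population variance so that standardization is exactly idempotent
  scale <- sqrt(colMeans(v^2) - center^2)
  scale[!is.finite(scale)] <- 0
  list(center = center, scale = scale)
}

#' Standardize each gene to mean 0, variance 1
#'
#' Centers and scales every gene column using population moments (variance
#' computed with denominator N), so a second application is an exact
#' identity. Constant genes are mapped to all-zero columns: they carry no
#' class information and would otherwise produce non-finite values.
#'
#' @param ds an [expression_dataset()] without missing cells.
#' @param stats optional statistics from [normalization_stats()] (e.g. fitted
#'   on training samples only); defaults to statistics of `ds` itself.
#' @return The standardized dataset.
#' @export
normalize_genes <- function(ds, stats = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(stats)) stats <- normalization_stats(ds)
  v <- sweep(ds$values, 2, stats$center, "-")
  sc <- stats$scale
  keep <- sc > 0
  if (any(keep)) v[, keep] <- sweep(v[, keep, drop = FALSE], 2, sc[keep], "/")
  if (any(!keep)) v[, !keep] <- 0
  ds$values <- v
  ds
}

#' Save normalization statistics as JSON
#'
#' @param stats result of [normalization_stats()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_normalization_stats <- function(stats, path) {
  jsonlite::write_json(lapply(stats, unname), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
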
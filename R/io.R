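# TSV/CSV input and output for expression matrices and result tables.
# Layout convention: genes as rows, first column the gene id, samples as
# columns; a sample sheet with columns sample_id, condition, pair_id.

#' Read a genes x samples expression matrix from TSV/CSV
#'
#' @param path Delimited text file, first column gene ids, remaining columns
#'   one per sample (delimiter auto-detected by [data.table::fread()]).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  genes <- as.character(dt[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in first column",
                                 call. = FALSE)
  m <- as.matrix(dt[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a genes x samples matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path Output file; first column `gene_id`.
#' @export
write_expression_matrix <- function(mat, path) {
  dt <- data.table::data.table(gene_id = rownames(mat), mat)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path Delimited file with columns `sample_id`, `condition`
#'   (normal/tumor), `pair_id`.
#' @return `data.frame` with those three character columns.
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = 1:3))
  needed <- c("sample_id", "condition", "pair_id")
  if (!all(needed %in% names(dt)))
    stop("sample sheet needs columns sample_id, condition, pair_id",
         call. = FALSE)
  as.data.frame(dt[, needed, with = FALSE])
}

#' Assemble a raw_counts object from files
#'
#' @param counts_path Count matrix file (see [read_expression_matrix()]).
#' @param sheet_path Sample sheet file (see [read_sample_sheet()]).
#' @return A [raw_counts()] with samples ordered as in the count matrix.
#' @export
read_raw_counts <- function(counts_path, sheet_path) {
  counts <- read_expression_matrix(counts_path)
  sheet <- read_sample_sheet(sheet_path)
  miss <- setdiff(colnames(counts), sheet$sample_id)
  if (length(miss))
    stop(sprintf("samples missing from sheet: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  sheet <- sheet[match(colnames(counts), sheet$sample_id), ]
  raw_counts(counts, sheet$condition, sheet$pair_id)
}
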
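#' Raw count matrix with sample metadata
#'
#' Container for a genes x samples matrix of nonnegative integer read (or UMI)
#' counts together with the per-sample condition and matched-pair labels of a
#' paired tumor/normal design.
#'
#' @param counts Nonnegative numeric matrix, genes in rows (unique rownames),
#'   samples in columns.
#' @param condition Character/factor of length `ncol(counts)` with values
#'   `"normal"` or `"tumor"`.
#' @param pair_id Identifier of the matched pair each sample belongs to; every
#'   pair id must occur exactly once per condition.
#' @return An object of class `raw_counts`: a list with elements `counts`,
#'   `condition` (factor) and `pair_id` (character).
#' @examples
#' cnt <- matrix(rpois(24, 5), 4, 6,
#'               dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' rc <- raw_counts(cnt, rep(c("normal", "tumor"), each = 3),
#'                  rep(paste0("p", 1:3), 2))
#' @export
raw_counts <- function(counts, condition, pair_id) {
  check_matrix(counts, "counts")
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (gene ids)", call. = FALSE)
  condition <- as.character(condition)
  pair_id <- as.character(pair_id)
  if (length(condition) != ncol(counts) || length(pair_id) != ncol(counts))
    stop("condition and pair_id must have one entry per sample", call. = FALSE)
  if (!all(condition %in% c("normal", "tumor")))
    stop('condition values must be "normal" or "tumor"', call. = FALSE)
  for (cond in unique(condition)) {
    ids <- pair_id[condition == cond]
    if (anyDuplicated(ids))
      stop(sprintf("pair ids duplicated within condition %s", cond),
           call. = FALSE)
  }
  structure(list(counts = counts,
                 condition = factor(condition, levels = c("normal", "tumor")),
                 pair_id = pair_id),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("raw_counts: %d genes x %d samples (%d normal, %d tumor)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "normal"), sum(x$condition == "tumor")))
  invisible(x)
}

#' Paired two-condition expression matrices
#'
#' The central data container: two real genes x pairs matrices over a shared
#' gene universe, with column k of `normal` and column k of `tumor` coming
#' from the same matched sample pair.
#'
#' @param normal,tumor Numeric matrices with identical rownames (genes) and
#'   the same number of columns (matched pairs). No missing values.
#' @param pair_ids Optional identifiers for the matched pairs; defaults to the
#'   column names of `normal` or `pair_1 ... pair_n`.
#' @return An object of class `paired_expression`: list with `genes`,
#'   `normal`, `tumor`, `pair_ids`.
#' @seealso [as_paired_expression()] to build one from a single matrix plus a
#'   sample sheet, [preprocess_counts()] for the full preprocessing chain.
#' @export
paired_expression <- function(normal, tumor, pair_ids = NULL) {
  check_matrix(normal, "normal")
  check_matrix(tumor, "tumor")
  if (is.null(rownames(normal)) || is.null(rownames(tumor)))
    stop("normal and tumor must have gene rownames", call. = FALSE)
  if (!identical(rownames(normal), rownames(tumor)))
    stop("normal and tumor must share identical gene order", call. = FALSE)
  if (ncol(normal) == ncol(tumor)) {
    if (is.null(pair_ids)) {
      pair_ids <- colnames(normal)
      if (is.null(pair_ids))
        pair_ids <- paste0("pair_", seq_len(ncol(normal)))
    }
    pair_ids <- as.character(pair_ids)
    if (length(pair_ids) != ncol(normal))
      stop("pair_ids must have one entry per column", call. = FALSE)
    colnames(normal) <- colnames(tumor) <- pair_ids
  } else {
    # unequal condition sizes: a valid two-condition design without matched
    # pairs (rank-based scoring does not require pairing)
    if (!is.null(pair_ids))
      stop("pair_ids require equal column counts", call. = FALSE)
    if (is.null(colnames(normal)))
      colnames(normal) <- paste0("n", seq_len(ncol(normal)))
    if (is.null(colnames(tumor)))
      colnames(tumor) <- paste0("t", seq_len(ncol(tumor)))
  }
  structure(list(genes = rownames(normal), normal = normal, tumor = tumor,
                 pair_ids = pair_ids),
            class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  if (is.null(x$pair_ids)) {
    cat(sprintf(
      "paired_expression: %d genes, %d normal / %d tumor samples (unpaired)\n",
      length(x$genes), ncol(x$normal), ncol(x$tumor)))
  } else {
    cat(sprintf("paired_expression: %d genes x %d matched pairs\n",
                length(x$genes), length(x$pair_ids)))
  }
  invisible(x)
}

#' Split a sample-annotated matrix into paired condition matrices
#'
#' @param expr Numeric genes x samples matrix with sample colnames.
#' @param condition,pair_id Per-sample condition (`"normal"`/`"tumor"`) and
#'   matched-pair identifier, as in [raw_counts()].
#' @return A [paired_expression()] whose columns are ordered by pair id; pairs
#'   present in only one condition are dropped with a warning.
#' @export
as_paired_expression <- function(expr, condition, pair_id) {
  check_matrix(expr, "expr")
  condition <- as.character(condition)
  pair_id <- as.character(pair_id)
  idx_n <- which(condition == "normal")
  idx_t <- which(condition == "tumor")
  common <- intersect(pair_id[idx_n], pair_id[idx_t])
  if (length(common) == 0L)
    stop("no pair id present in both conditions", call. = FALSE)
  dropped <- setdiff(unique(pair_id), common)
  if (length(dropped))
    warning(sprintf("dropping %d unmatched pair id(s)", length(dropped)))
  common <- sort(common)
  paired_expression(
    normal = expr[, idx_n[match(common, pair_id[idx_n])], drop = FALSE],
    tumor = expr[, idx_t[match(common, pair_id[idx_t])], drop = FALSE],
    pair_ids = common
  )
}
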
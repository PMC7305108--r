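#' Filter genes with too few informative samples
#'
#' Keeps the genes whose raw count exceeds `min_count` in at least `min_cells`
#' samples (default: count > 2 in at least 4 samples). Sample set and gene
#' order are unchanged.
#'
#' @param raw A [raw_counts()] object.
#' @param min_count Count a sample must strictly exceed to be informative.
#' @param min_cells Minimum number of informative samples a gene needs.
#' @return A [raw_counts()] restricted to the passing genes. If nothing
#'   passes, an empty object is returned with a warning.
#' @export
filter_low_expression <- function(raw, min_count = 2, min_cells = 4) {
  stopifnot(inherits(raw, "raw_counts"))
  if (min_count < 0) stop("min_count must be >= 0", call. = FALSE)
  if (min_cells < 1) stop("min_cells must be >= 1", call. = FALSE)
  keep <- rowSums(raw$counts > min_count) >= min_cells
  if (!any(keep)) warning("no genes pass the expression filter")
  raw$counts <- raw$counts[keep, , drop = FALSE]
  raw
}

#' Median-of-totals count normalization
#'
#' Scales each sample's counts by its total and multiplies by the median of
#' the per-sample totals, so every normalized sample sums to the median total.
#'
#' @param raw A [raw_counts()] object (or a plain nonnegative matrix).
#' @return Numeric matrix with the layout of the input counts.
#' @export
normalize_counts <- function(raw) {
  counts <- if (inherits(raw, "raw_counts")) raw$counts else raw
  check_matrix(counts, "counts")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop(sprintf("sample(s) with zero total counts: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * median(totals)
}

#' Select highly variable genes by binned dispersion
#'
#' Dispersion (variance/mean) measures excess variability but scales with
#' expression, so genes are compared only with genes of similar average
#' expression: genes are split into `n_bins` equal-occupancy bins by mean
#' expression and the dispersion is standardized within each bin (subtract the
#' bin median, divide by the bin median absolute deviation). The `n_top` genes
#' with the highest standardized dispersion are returned.
#'
#' @param norm Normalized genes x samples matrix with gene rownames.
#' @param n_top Number of genes to return (descending order); capped at the
#'   number of genes, with a warning.
#' @param n_bins Number of mean-expression bins.
#' @return Character vector of gene ids, highest standardized dispersion
#'   first.
#' @export
select_variable_genes <- function(norm, n_top = 2000, n_bins = 20) {
  check_matrix(norm, "norm")
  if (is.null(rownames(norm))) stop("norm must have gene rownames",
                                    call. = FALSE)
  if (n_top < 1) stop("n_top must be >= 1", call. = FALSE)
  p <- nrow(norm)
  if (n_top > p) {
    warning(sprintf("n_top (%d) exceeds gene count (%d); returning all genes",
                    n_top, p))
    n_top <- p
  }
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(as.integer(n_bins), p))
  # equal-occupancy bins via rank; ties in mean fall in rank order
  bin <- ceiling(rank(mu, ties.method = "first") * n_bins / p)
  z <- numeric(p)
  for (b in unique(bin)) {
    i <- bin == b
    med <- median(disp[i])
    s <- mad(disp[i])
    if (s == 0) s <- mean(abs(disp[i] - med))  # degenerate bin: fall back
    z[i] <- if (s == 0) 0 else (disp[i] - med) / s
  }
  ord <- order(z, decreasing = TRUE)
  rownames(norm)[ord[seq_len(n_top)]]
}

#' Per-pair log2 fold change
#'
#' `log2((tumor + pseudocount) / (normal + pseudocount))`, one column per
#' matched pair. A transcriptional-response representation of the paired
#' design; the copula score itself consumes the per-condition matrices.
#'
#' @param paired A [paired_expression()].
#' @param pseudocount Positive stabilizer added to both conditions
#'   (default 1); `0` is allowed only when all entries are positive.
#' @return Numeric genes x pairs matrix.
#' @export
log2_fold_change <- function(paired, pseudocount = 1) {
  stopifnot(inherits(paired, "paired_expression"))
  if (ncol(paired$normal) != ncol(paired$tumor))
    stop("log2 fold change requires matched pairs", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 &&
      (any(paired$normal <= 0) || any(paired$tumor <= 0)))
    stop("pseudocount 0 requires strictly positive expression", call. = FALSE)
  log2((paired$tumor + pseudocount) / (paired$normal + pseudocount))
}

#' Full preprocessing chain: counts to paired variable-gene expression
#'
#' Applies [filter_low_expression()], [normalize_counts()],
#' [select_variable_genes()] and pairs the samples by pair id.
#'
#' @inheritParams filter_low_expression
#' @inheritParams select_variable_genes
#' @return A [paired_expression()] restricted to the selected genes (row
#'   order: selection order, most variable first).
#' @export
preprocess_counts <- function(raw, min_count = 2, min_cells = 4,
                              n_top = 2000, n_bins = 20) {
  stopifnot(inherits(raw, "raw_counts"))
  filt <- filter_low_expression(raw, min_count, min_cells)
  norm <- normalize_counts(filt)
  genes <- select_variable_genes(norm, n_top = n_top, n_bins = n_bins)
  as_paired_expression(norm[genes, , drop = FALSE],
                       filt$condition, filt$pair_id)
}
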
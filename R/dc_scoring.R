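#' Copula-based differential coexpression score for one gene pair
#'
#' The score of pair (i, j) is the Kolmogorov-Smirnov distance between the
#' empirical copula of the pair's tumor profiles and that of its normal
#' profiles. It lies in \[0, 1\], is 0 when the two conditions share the same
#' joint ranks, and is exactly invariant to strictly increasing transforms of
#' any profile.
#'
#' @param xi_n,xj_n Profiles of genes i and j across normal samples.
#' @param xi_t,xj_t Profiles of genes i and j across tumor samples (the two
#'   conditions may differ in sample count).
#' @param eval_mode,grid_size Passed to [ks_distance()].
#' @return Scalar score in \[0, 1\].
#' @examples
#' set.seed(1)
#' x <- MASS::mvrnorm(80, c(0, 0), matrix(c(1, .9, .9, 1), 2))
#' y <- MASS::mvrnorm(80, c(0, 0), matrix(c(1, -.9, -.9, 1), 2))
#' dc_copula_score(x[, 1], x[, 2], y[, 1], y[, 2])
#' @export
dc_copula_score <- function(xi_n, xj_n, xi_t, xj_t,
                            eval_mode = "pooled", grid_size = 200) {
  if (length(xi_n) < 3 || length(xi_t) < 3)
    stop("each condition needs at least 3 samples", call. = FALSE)
  ks_distance(empirical_copula(xi_t, xj_t),
              empirical_copula(xi_n, xj_n),
              eval_mode = eval_mode, grid_size = grid_size)
}

#' Differential coexpression score matrix over all gene pairs
#'
#' Applies [dc_copula_score()] to every unordered gene pair of a paired
#' dataset. Pseudo-observations are computed once per gene and condition, so
#' the result is identical to, but much faster than, independent per-pair
#' calls.
#'
#' @param paired A [paired_expression()] with >= 2 genes and >= 3 samples per
#'   condition.
#' @inheritParams dc_copula_score
#' @return Symmetric genes x genes matrix of class `dc_matrix` with zero
#'   diagonal and entries in \[0, 1\].
#' @export
dc_copula_matrix <- function(paired, eval_mode = "pooled", grid_size = 200) {
  stopifnot(inherits(paired, "paired_expression"))
  p <- length(paired$genes)
  if (p < 2) stop("need at least 2 genes", call. = FALSE)
  if (ncol(paired$normal) < 3 || ncol(paired$tumor) < 3)
    stop("need at least 3 samples per condition", call. = FALSE)
  Un <- t(apply(paired$normal, 1, pseudo_observations))
  Ut <- t(apply(paired$tumor, 1, pseudo_observations))
  mn <- ncol(Un); mt <- ncol(Ut)
  D <- matrix(0, p, p, dimnames = list(paired$genes, paired$genes))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      cn <- structure(list(u = Un[i, ], v = Un[j, ], m = mn),
                      class = "empirical_copula")
      ct <- structure(list(u = Ut[i, ], v = Ut[j, ], m = mt),
                      class = "empirical_copula")
      s <- tryCatch(
        ks_distance(ct, cn, eval_mode = eval_mode, grid_size = grid_size),
        error = function(e) stop(sprintf("pair (%s, %s): %s",
                                         paired$genes[i], paired$genes[j],
                                         conditionMessage(e)), call. = FALSE))
      D[i, j] <- D[j, i] <- s
    }
  }
  class(D) <- c("dc_matrix", class(D))
  D
}

#' Correlation-difference baseline score
#'
#' The classical differential coexpression score: the absolute difference of
#' a pair's correlation in the two conditions, `|rho_p1 - rho_p2|`, in
#' \[0, 2\]. Used as the baseline the copula score is compared against, and
#' as the criterion defining truly differentially coexpressed pairs in
#' simulations.
#'
#' @param rho_p1,rho_p2 Correlations in the two conditions, in \[-1, 1\]
#'   (vectorized).
#' @return `|rho_p1 - rho_p2|`.
#' @examples
#' baseline_dc_score(0.2, 0.7)   # 0.5
#' baseline_dc_score(-0.2, 0.2)  # 0.4
#' @export
baseline_dc_score <- function(rho_p1, rho_p2) {
  if (any(abs(rho_p1) > 1) || any(abs(rho_p2) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  abs(rho_p1 - rho_p2)
}

#' Extract differentially coexpressed gene pairs
#'
#' Pairs at or above a score threshold (or the `top_k` by score), annotated
#' with each pair's correlation in normal and tumor samples. Ordering is
#' deterministic: score descending, ties broken by gene names.
#'
#' @param d A `dc_matrix` from [dc_copula_matrix()].
#' @param paired The [paired_expression()] the matrix was computed from.
#' @param threshold Minimum score (default 0.56, the cut used for the
#'   strongly differentially coexpressed pairs on real data).
#' @param top_k If non-`NULL`, return the `top_k` highest-scoring pairs
#'   instead of thresholding.
#' @param cor_method `"pearson"` (default) or `"spearman"` for the
#'   per-condition correlation annotation.
#' @return `data.frame` with columns `gene_i`, `gene_j` (gene_i before gene_j
#'   in matrix order), `score`, `rho_normal`, `rho_tumor`.
#' @export
extract_dc_pairs <- function(d, paired, threshold = 0.56, top_k = NULL,
                             cor_method = c("pearson", "spearman")) {
  stopifnot(inherits(d, "dc_matrix"), inherits(paired, "paired_expression"))
  stop_if_not_scalar01(threshold, "threshold")
  cor_method <- match.arg(cor_method)
  genes <- rownames(d)
  stopifnot(identical(genes, paired$genes))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  rn <- cor(t(paired$normal), method = cor_method)
  rt <- cor(t(paired$tumor), method = cor_method)
  out <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                    score = d[idx], rho_normal = rn[idx], rho_tumor = rt[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_i, out$gene_j), , drop = FALSE]
  if (!is.null(top_k)) {
    out <- head(out, top_k)
  } else {
    out <- out[out$score >= threshold, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-sample expression-ratio features for selected pairs
#'
#' For each selected pair (i, j) and each sample, the ratio
#' `(expr_i + pseudocount) / (expr_j + pseudocount)`. Normal samples come
#' first, then tumor samples; the condition of each row is attached both as
#' the `condition` attribute and in the rownames. This is the feature matrix
#' a downstream classifier consumes (one row per sample, one column per
#' pair); classifier training itself is out of scope here.
#'
#' @param pairs `data.frame` from [extract_dc_pairs()] (columns `gene_i`,
#'   `gene_j`).
#' @param paired A [paired_expression()].
#' @param pseudocount Stabilizer added to numerator and denominator
#'   (default 1); `0` requires nonzero denominators.
#' @return Numeric samples x pairs matrix with attribute `condition`
#'   (factor, normal/tumor per row).
#' @export
ratio_feature_matrix <- function(pairs, paired, pseudocount = 1) {
  stopifnot(inherits(paired, "paired_expression"))
  if (nrow(pairs) == 0) stop("pairs is empty", call. = FALSE)
  expr <- cbind(paired$normal, paired$tumor)
  cond <- rep(c("normal", "tumor"),
              c(ncol(paired$normal), ncol(paired$tumor)))
  num <- expr[pairs$gene_i, , drop = FALSE] + pseudocount
  den <- expr[pairs$gene_j, , drop = FALSE] + pseudocount
  if (any(den == 0)) stop("zero denominator; use a positive pseudocount",
                          call. = FALSE)
  out <- t(num / den)
  colnames(out) <- paste(pairs$gene_i, pairs$gene_j, sep = "/")
  rownames(out) <- paste(cond, colnames(expr), sep = ".")
  attr(out, "condition") <- factor(cond, levels = c("normal", "tumor"))
  out
}

#' Binary same-pattern matrix for selected pairs
#'
#' Visual summary of pair agreement: entry (sample, pair) is 1 when both
#' genes of the pair sit on the same side of their own per-gene median in
#' that sample, else 0. (The sign is taken against each gene's median across
#' the samples of `expr`.)
#'
#' @param pairs `data.frame` with columns `gene_i`, `gene_j`.
#' @param expr Numeric genes x samples matrix (one condition at a time).
#' @return Integer samples x pairs matrix of 0/1.
#' @export
pattern_match_matrix <- function(pairs, expr) {
  check_matrix(expr, "expr")
  if (nrow(pairs) == 0) stop("pairs is empty", call. = FALSE)
  med <- apply(expr, 1, median)
  sgn <- sign(expr - med)
  out <- t((sgn[pairs$gene_i, , drop = FALSE] ==
              sgn[pairs$gene_j, , drop = FALSE]) * 1L)
  colnames(out) <- paste(pairs$gene_i, pairs$gene_j, sep = "/")
  rownames(out) <- colnames(expr)
  out
}
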
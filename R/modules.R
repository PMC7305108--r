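#' Copula distance from a differential coexpression matrix
#'
#' `dist(i, j) = 1 - score(i, j)`: strongly differentially coexpressed pairs
#' become close, so clusters of the resulting dissimilarity are modules in
#' which differential coexpression is prevalent between every pair. Diagonal
#' stays 0.
#'
#' @param d A `dc_matrix` from [dc_copula_matrix()].
#' @return Symmetric matrix of dissimilarities in \[0, 1\], zero diagonal.
#' @export
copula_distance_matrix <- function(d) {
  check_matrix(unclass(d), "d")
  out <- 1 - unclass(d)
  diag(out) <- 0
  out
}

#' Detect differentially coexpressed modules
#'
#' Average-linkage (UPGMA) hierarchical clustering of the copula distance,
#' cut either into `k` clusters or at dendrogram height `cut_height` (exactly
#' one of the two must be given). Clusters smaller than `min_size` are then
#' merged, smallest first, into the cluster nearest by average inter-cluster
#' distance. Fully deterministic given the input.
#'
#' @param dist Symmetric dissimilarity matrix (e.g. from
#'   [copula_distance_matrix()]) with gene dimnames.
#' @param k Desired number of clusters (before small-cluster merging).
#' @param cut_height Dendrogram cut height alternative to `k`.
#' @param min_size Minimum module size enforced by merging (default 5; use 1
#'   to disable).
#' @return Object of class `module_set`: list with `genes`, `labels` (named
#'   integer vector, module ids 1..K in order of first appearance), `K`, and
#'   the `hclust` tree as `tree`.
#' @export
detect_modules <- function(dist, k = NULL, cut_height = NULL, min_size = 5) {
  check_matrix(dist, "dist")
  if (is.null(rownames(dist)))
    stop("dist must have gene dimnames", call. = FALSE)
  if (is.null(k) == is.null(cut_height))
    stop("give exactly one of k or cut_height", call. = FALSE)
  p <- nrow(dist)
  if (!is.null(k) && (k < 1 || k > p))
    stop("k must be between 1 and the number of genes", call. = FALSE)
  if (min_size < 1) stop("min_size must be >= 1", call. = FALSE)
  tree <- hclust(as.dist(dist), method = "average")
  labels <- if (!is.null(k)) cutree(tree, k = k)
            else cutree(tree, h = cut_height)

  # merge undersized clusters into their nearest neighbor (average linkage)
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0 || length(sizes) == 1) break
    s <- small[which.min(sizes[small])]
    members <- names(labels)[labels == s]
    others <- setdiff(names(sizes), s)
    avg <- vapply(others, function(o) {
      mean(dist[members, names(labels)[labels == o], drop = FALSE])
    }, numeric(1))
    labels[labels == s] <- as.integer(others[which.min(avg)])
  }
  # relabel 1..K in order of first appearance for determinism
  labels <- setNames(match(labels, unique(labels)), names(labels))
  structure(list(genes = names(labels), labels = labels,
                 K = length(unique(labels)), tree = tree),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d genes in %d modules (sizes: %s)\n",
              length(x$genes), x$K,
              paste(as.integer(table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Module eigengene
#'
#' Summary profile of a module: the first principal component, in sample
#' space, of the members' standardized (per-gene zero-mean, unit-variance)
#' expression. The vector has unit Euclidean norm and its sign is fixed so
#' it correlates nonnegatively with the members' mean standardized profile.
#'
#' @param expr Numeric genes x samples matrix with gene rownames.
#' @param member_genes Gene ids of the module (subset of `rownames(expr)`).
#' @return Object of class `eigengene`: list with `vector` (length =
#'   samples, unit norm), `variance_explained` (leading eigenvalue fraction),
#'   `n_genes` (members used).
#' @export
module_eigengene <- function(expr, member_genes) {
  check_matrix(expr, "expr")
  if (length(member_genes) < 1) stop("empty module", call. = FALSE)
  if (ncol(expr) < 2) stop("need at least 2 samples", call. = FALSE)
  missing <- setdiff(member_genes, rownames(expr))
  if (length(missing))
    stop(sprintf("genes not in expr: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  X <- expr[member_genes, , drop = FALSE]
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene(s) from the eigengene PCA",
                    sum(sds == 0)))
    X <- X[sds > 0, , drop = FALSE]
    if (nrow(X) == 0) stop("all module genes are constant", call. = FALSE)
    sds <- sds[sds > 0]
  }
  Xs <- (X - rowMeans(X)) / sds
  dec <- svd(Xs)
  v <- dec$v[, 1]
  if (sum(v * colMeans(Xs)) < 0) v <- -v
  structure(list(vector = v,
                 variance_explained = dec$d[1]^2 / sum(dec$d^2),
                 n_genes = nrow(Xs)),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("eigengene of %d genes, variance explained %.3f\n",
              x$n_genes, x$variance_explained))
  invisible(x)
}

#' Module eigengene correlation networks in the two conditions
#'
#' Computes every module's eigengene separately within the normal and the
#' tumor samples, then the Pearson correlation matrix among eigengenes in
#' each condition. The composite display matrix carries the normal
#' correlations strictly above the diagonal, the tumor correlations strictly
#' below, and 1 on the diagonal -- modules that flip correlation sign across
#' the diagonal are differentially coexpressed at module level.
#'
#' @param modules A `module_set` from [detect_modules()].
#' @param paired A [paired_expression()] covering the module genes.
#' @return List with K x K matrices `normal`, `tumor`, `composite`, and the
#'   per-condition eigengene matrices `eigengenes_normal`,
#'   `eigengenes_tumor` (samples x modules).
#' @export
eigengene_network <- function(modules, paired) {
  stopifnot(inherits(modules, "module_set"),
            inherits(paired, "paired_expression"))
  ids <- sort(unique(modules$labels))
  eg <- function(expr) {
    vapply(ids, function(k) {
      module_eigengene(expr,
                       modules$genes[modules$labels == k])$vector
    }, numeric(ncol(expr)))
  }
  En <- eg(paired$normal)
  Et <- eg(paired$tumor)
  colnames(En) <- colnames(Et) <- paste0("M", ids)
  cn <- cor(En); ct <- cor(Et)
  composite <- cn
  composite[lower.tri(composite)] <- ct[lower.tri(ct)]
  diag(composite) <- 1
  list(normal = cn, tumor = ct, composite = composite,
       eigengenes_normal = En, eigengenes_tumor = Et)
}
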
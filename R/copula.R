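#' Rank-based pseudo-observations
#'
#' Maps a sample to its scaled ranks `rank(x) / m` (average ranks for ties),
#' the empirical-CDF values of the sample at its own points. These are the
#' uniform-like coordinates the empirical copula is built from; they are
#' invariant under any strictly increasing transform of `x`.
#'
#' @param x Numeric vector, length >= 2, all finite.
#' @return Numeric vector in (0, 1] of the same length.
#' @examples
#' pseudo_observations(c(10, 20, 30, 40))  # 0.25 0.50 0.75 1.00
#' @export
pseudo_observations <- function(x) {
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  m <- length(x)
  if (m < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("x contains non-finite values", call. = FALSE)
  rank(x, ties.method = "average") / m
}

#' Empirical copula of a bivariate sample
#'
#' Stores the paired pseudo-observations \eqn{(u_j, v_j)} of `(x, y)` -- the
#' rank-transformed sample on the unit square. The associated distribution
#' function is the lower-quadrant counting measure evaluated by
#' [evaluate_copula()]. Construction depends on the data only through ranks.
#'
#' @param x,y Numeric vectors of equal length m >= 2.
#' @return Object of class `empirical_copula`: list with `u`, `v`, `m`.
#' @export
empirical_copula <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  structure(list(u = pseudo_observations(x),
                 v = pseudo_observations(y),
                 m = length(x)),
            class = "empirical_copula")
}

#' @export
print.empirical_copula <- function(x, ...) {
  cat(sprintf("empirical_copula on %d pseudo-observations\n", x$m))
  invisible(x)
}

#' Evaluate an empirical copula
#'
#' \eqn{\hat C(u, v) = m^{-1} \sum_j 1\{u_j \le u, v_j \le v\}}: the fraction
#' of pseudo-observations in the lower-left quadrant of `(u, v)`. Vectorized
#' over `u`, `v` (recycled to common length).
#'
#' @param cop An [empirical_copula()].
#' @param u,v Evaluation coordinates in \[0, 1\].
#' @return Numeric vector of copula values in \[0, 1\].
#' @export
evaluate_copula <- function(cop, u, v) {
  stopifnot(inherits(cop, "empirical_copula"))
  if (any(!is.finite(u)) || any(!is.finite(v)) ||
      any(u < 0 | u > 1) || any(v < 0 | v > 1))
    stop("u and v must lie in [0, 1]", call. = FALSE)
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  colMeans(outer(cop$u, u, "<=") & outer(cop$v, v, "<="))
}

# Copula CDF on the product grid ue x ve via a 2-D cumulative histogram:
# O(m + |ue| * |ve|). Each point (u_j, v_j) contributes to all grid cells
# (a, b) with ue[a] >= u_j and ve[b] >= v_j.
cum_hist_cdf <- function(cop, ue, ve) {
  iu <- findInterval(cop$u, ue, left.open = TRUE) + 1L  # first ue >= u_j
  iv <- findInterval(cop$v, ve, left.open = TRUE) + 1L
  keep <- iu <= length(ue) & iv <= length(ve)
  h <- matrix(0, length(ue), length(ve))
  if (any(keep)) {
    tab <- table(factor(iu[keep], levels = seq_along(ue)),
                 factor(iv[keep], levels = seq_along(ve)))
    h <- matrix(as.numeric(tab), length(ue), length(ve))
  }
  h <- apply(h, 2, cumsum)
  h <- t(apply(h, 1, cumsum))
  h / cop$m
}

#' Kolmogorov-Smirnov distance between two empirical copulas
#'
#' The differential-coexpression primitive: the supremum absolute difference
#' between two empirical joint (copula) distribution functions,
#' \eqn{D = \sup_{u,v} |\hat C_1(u,v) - \hat C_2(u,v)|}, a number in
#' \[0, 1\].
#'
#' Both copula CDFs are lower-quadrant step functions, so the supremum is
#' attained on the product grid of the pooled marginal coordinates; the
#' default mode `"pooled"` evaluates exactly there. Mode `"grid"` uses a
#' regular `grid_size` x `grid_size` lattice of the open unit square (a
#' cross-check; agrees with `"pooled"` up to grid resolution). Mode
#' `"values_1d"` instead applies the classical one-dimensional two-sample
#' K-S statistic to the two vectors of copula values at their own points --
#' an alternative reading of a "K-S test between joint distributions", kept
#' behind this explicit flag.
#'
#' @param c1,c2 [empirical_copula()] objects.
#' @param eval_mode `"pooled"` (default), `"grid"`, or `"values_1d"`.
#' @param grid_size Lattice side for `"grid"` mode (>= 2).
#' @return The distance, a scalar in \[0, 1\]; symmetric in its arguments.
#' @examples
#' x <- rnorm(100); y <- x + rnorm(100)
#' ks_distance(empirical_copula(x, y), empirical_copula(x, -y))
#' @export
ks_distance <- function(c1, c2, eval_mode = c("pooled", "grid", "values_1d"),
                        grid_size = 200) {
  stopifnot(inherits(c1, "empirical_copula"),
            inherits(c2, "empirical_copula"))
  eval_mode <- match.arg(eval_mode)
  if (eval_mode == "values_1d") {
    w1 <- evaluate_copula(c1, c1$u, c1$v)
    w2 <- evaluate_copula(c2, c2$u, c2$v)
    return(unname(suppressWarnings(ks.test(w1, w2)$statistic)))
  }
  if (eval_mode == "grid") {
    if (grid_size < 2) stop("grid_size must be >= 2", call. = FALSE)
    s <- seq_len(grid_size) / (grid_size + 1)
    ue <- s; ve <- s
  } else {
    ue <- sort(unique(c(c1$u, c2$u)))
    ve <- sort(unique(c(c1$v, c2$v)))
  }
  max(abs(cum_hist_cdf(c1, ue, ve) - cum_hist_cdf(c2, ue, ve)))
}
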
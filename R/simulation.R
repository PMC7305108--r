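#' Bivariate normal sample with (exactly) controlled correlation
#'
#' Draws `n` observations of a bivariate normal with correlation `rho`. With
#' `exact = TRUE` (the default) the draw is rescaled so the *sample* Pearson
#' correlation equals `rho` to machine precision
#' ([MASS::mvrnorm()] with `empirical = TRUE`); this is what lets simulation
#' grids pin the correlation difference between conditions precisely.
#'
#' @param n Sample size (>= 3).
#' @param rho Target correlation in \[-1, 1\].
#' @param exact Make the sample correlation exactly `rho` (default TRUE).
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return An `n` x 2 numeric matrix.
#' @export
correlated_pair <- function(n, rho, exact = TRUE, seed = NULL) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  sigma <- matrix(c(1, rho, rho, 1), 2, 2)
  with_seed(seed, MASS::mvrnorm(n, c(0, 0), sigma, empirical = exact))
}

#' Simulation configuration
#'
#' Describes a synthetic paired tumor/normal dataset: independent per-gene
#' Gaussian profiles in each condition, except for the genes named in
#' `pair_specs`, which are drawn jointly with controlled per-condition
#' correlations. Per-gene means and variances are free parameters; because
#' the copula score is rank-based it is exactly invariant to them, and the
#' defaults are standard normal profiles.
#'
#' @param p Number of genes.
#' @param m_normal,m_tumor Samples per condition (default 51 each, a typical
#'   matched-pair cohort size).
#' @param mean_normal,mean_tumor,var_normal,var_tumor Per-gene means and
#'   variances, recycled to length `p`.
#' @param pair_specs `data.frame` with columns `gene_i`, `gene_j` (1-based
#'   gene indices), `rho_normal`, `rho_tumor`, and optionally `exact`
#'   (default TRUE). A gene may appear in at most one spec.
#' @param noise_level Standard deviation of Gaussian noise added to the
#'   *tumor* matrix after ground truth is established (default 0 = none).
#' @param seed Integer seed fixing all randomness of the draw.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(p, m_normal = 51, m_tumor = 51,
                       mean_normal = 0, mean_tumor = 0,
                       var_normal = 1, var_tumor = 1,
                       pair_specs = NULL, noise_level = 0, seed = 1) {
  stopifnot(p >= 2, m_normal >= 3, m_tumor >= 3, noise_level >= 0)
  cfg <- list(p = as.integer(p),
              m_normal = as.integer(m_normal),
              m_tumor = as.integer(m_tumor),
              mean_normal = rep_len(mean_normal, p),
              mean_tumor = rep_len(mean_tumor, p),
              var_normal = rep_len(var_normal, p),
              var_tumor = rep_len(var_tumor, p),
              pair_specs = pair_specs,
              noise_level = noise_level,
              seed = seed)
  if (any(cfg$var_normal <= 0) || any(cfg$var_tumor <= 0))
    stop("variances must be positive", call. = FALSE)
  if (!is.null(pair_specs)) {
    needed <- c("gene_i", "gene_j", "rho_normal", "rho_tumor")
    if (!all(needed %in% names(pair_specs)))
      stop("pair_specs needs columns gene_i, gene_j, rho_normal, rho_tumor",
           call. = FALSE)
    if (is.null(pair_specs$exact)) cfg$pair_specs$exact <- TRUE
    used <- c(pair_specs$gene_i, pair_specs$gene_j)
    if (anyDuplicated(used))
      stop("a gene may appear in at most one pair spec", call. = FALSE)
    if (any(used < 1 | used > p))
      stop("pair spec gene indices out of range", call. = FALSE)
    if (any(abs(pair_specs$rho_normal) > 1) ||
        any(abs(pair_specs$rho_tumor) > 1))
      stop("pair spec correlations must lie in [-1, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired tumor/normal expression dataset
#'
#' Unpaired genes are drawn i.i.d. normal per condition with their
#' configured mean and variance. Genes named in `pair_specs` are drawn via
#' [correlated_pair()] at the requested per-condition correlation and then
#' shifted/scaled to their mean and variance (an increasing affine map, so
#' the realized correlation is untouched). Ground truth -- the set of truly
#' differentially coexpressed pairs -- is computed on the clean draw with
#' [ground_truth_dc()]; any configured `noise_level` is added to the tumor
#' matrix afterwards.
#'
#' @param config A [sim_config()].
#' @return List with `paired` (a [paired_expression()]) and `truth` (the
#'   [ground_truth_dc()] data.frame of the clean draw).
#' @export
simulate_paired_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    p <- config$p
    genes <- sprintf("g%03d", seq_len(p))
    normal <- matrix(rnorm(p * config$m_normal, config$mean_normal,
                           sqrt(config$var_normal)),
                     p, config$m_normal,
                     dimnames = list(genes, NULL))
    tumor <- matrix(rnorm(p * config$m_tumor, config$mean_tumor,
                          sqrt(config$var_tumor)),
                    p, config$m_tumor,
                    dimnames = list(genes, NULL))
    ps <- config$pair_specs
    if (!is.null(ps)) {
      for (r in seq_len(nrow(ps))) {
        i <- ps$gene_i[r]; j <- ps$gene_j[r]; ex <- isTRUE(ps$exact[r])
        zn <- correlated_pair(config$m_normal, ps$rho_normal[r], exact = ex)
        zt <- correlated_pair(config$m_tumor, ps$rho_tumor[r], exact = ex)
        normal[i, ] <- config$mean_normal[i] +
          sqrt(config$var_normal[i]) * zn[, 1]
        normal[j, ] <- config$mean_normal[j] +
          sqrt(config$var_normal[j]) * zn[, 2]
        tumor[i, ] <- config$mean_tumor[i] +
          sqrt(config$var_tumor[i]) * zt[, 1]
        tumor[j, ] <- config$mean_tumor[j] +
          sqrt(config$var_tumor[j]) * zt[, 2]
      }
    }
    paired <- paired_expression(normal, tumor)
    truth <- ground_truth_dc(paired)
    if (config$noise_level > 0)
      paired$tumor <- paired$tumor +
        config$noise_level * matrix(rnorm(length(paired$tumor)),
                                    nrow(paired$tumor))
    list(paired = paired, truth = truth)
  })
}

#' Truly differentially coexpressed pairs of a dataset
#'
#' A pair counts as truly differentially coexpressed when its
#' correlation-difference baseline exceeds `score_threshold` *and* its
#' correlation flips sign between conditions:
#' `|rho_normal - rho_tumor| > score_threshold` and
#' `rho_normal * rho_tumor < 0`.
#'
#' @param paired A [paired_expression()].
#' @param score_threshold Baseline-score cut (default 0.5).
#' @return `data.frame` with columns `gene_i`, `gene_j`, `rho_normal`,
#'   `rho_tumor` (possibly 0 rows).
#' @export
ground_truth_dc <- function(paired, score_threshold = 0.5) {
  stopifnot(inherits(paired, "paired_expression"))
  rn <- cor(t(paired$normal))
  rt <- cor(t(paired$tumor))
  idx <- which(upper.tri(rn), arr.ind = TRUE)
  keep <- baseline_dc_score(rn[idx], rt[idx]) > score_threshold &
    rn[idx] * rt[idx] < 0
  data.frame(gene_i = paired$genes[idx[keep, 1]],
             gene_j = paired$genes[idx[keep, 2]],
             rho_normal = rn[idx][keep], rho_tumor = rt[idx][keep],
             stringsAsFactors = FALSE)
}

#' Add Gaussian noise to a matrix
#'
#' `output = input + level * epsilon` with `epsilon` i.i.d. standard normal.
#' With `relative = TRUE`, `level` is interpreted as a fraction of the
#' pooled standard deviation of the clean matrix (so `level = 0.8` means
#' "80% noise" relative to the data's spread).
#'
#' @param mat Numeric matrix.
#' @param level Noise multiplier >= 0; 0 returns the input unchanged.
#' @param seed Optional integer seed.
#' @param relative Interpret `level` relative to `sd(mat)` (default FALSE).
#' @return Matrix of the same shape.
#' @export
inject_noise <- function(mat, level, seed = NULL, relative = FALSE) {
  check_matrix(mat, "mat")
  if (level < 0) stop("level must be >= 0", call. = FALSE)
  if (level == 0) return(mat)
  if (relative) level <- level * sd(as.vector(mat))
  with_seed(seed, mat + level * matrix(rnorm(length(mat)), nrow(mat)))
}

#' Fraction of true differentially coexpressed pairs recovered
#'
#' `|detected ∩ truth| / |truth|`, comparing unordered gene pairs.
#'
#' @param detected `data.frame` with columns `gene_i`, `gene_j` (e.g. from
#'   [extract_dc_pairs()]).
#' @param truth `data.frame` with columns `gene_i`, `gene_j` (e.g. from
#'   [ground_truth_dc()]); must be nonempty.
#' @return Scalar in \[0, 1\].
#' @export
matching_proportion <- function(detected, truth) {
  if (nrow(truth) == 0) stop("truth is empty", call. = FALSE)
  tk <- pair_keys(truth$gene_i, truth$gene_j)
  dk <- if (nrow(detected)) pair_keys(detected$gene_i, detected$gene_j)
        else character(0)
  length(intersect(dk, tk)) / length(unique(tk))
}
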
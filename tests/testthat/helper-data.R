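# Shared fixture builders and independent oracles, all generated in code.

# Small raw count matrix: 4 genes x 6 samples (3 matched pairs).
toy_raw_counts <- function() {
  cnt <- rbind(
    gA = c(3, 3, 3, 3, 0, 0),   # > 2 in 4 samples: passes default filter
    gB = c(3, 3, 3, 2, 2, 2),   # > 2 in only 3 samples: filtered
    gC = c(10, 20, 30, 40, 50, 60),
    gD = c(5, 5, 5, 5, 5, 5)
  )
  colnames(cnt) <- paste0("s", 1:6)
  raw_counts(cnt, rep(c("normal", "tumor"), each = 3),
             rep(paste0("p", 1:3), times = 2))
}

# Paired expression with planted per-pair correlations (exact by default).
planted_paired <- function(p, m, specs, seed) {
  cfg <- sim_config(p = p, m_normal = m, m_tumor = m,
                    pair_specs = specs, seed = seed)
  simulate_paired_expression(cfg)
}

# Brute-force O(m) counting oracle for the empirical copula CDF.
brute_copula_cdf <- function(cop, u, v) {
  n <- 0
  for (j in seq_len(cop$m))
    if (cop$u[j] <= u && cop$v[j] <= v) n <- n + 1
  n / cop$m
}

# Exact upper-tail hypergeometric P(X >= ov) as a sum of binomial ratios.
brute_hyper_upper <- function(ov, set_size, universe, draws) {
  ks <- ov:min(set_size, draws)
  sum(choose(set_size, ks) * choose(universe - set_size, draws - ks)) /
    choose(universe, draws)
}

# A dc_matrix with hand-set scores (symmetric, zero diagonal).
handmade_dc_matrix <- function(scores, genes) {
  p <- length(genes)
  d <- matrix(0, p, p, dimnames = list(genes, genes))
  d[upper.tri(d)] <- scores
  d <- d + t(d)
  class(d) <- c("dc_matrix", class(d))
  d
}

# Two-block planted DC structure: high scores within blocks, low between.
two_block_dc <- function(p = 40, within = 0.8, between = 0.1, jitter = 0.02,
                         seed = 404) {
  genes <- sprintf("g%02d", seq_len(p))
  block <- rep(1:2, each = p / 2)
  base <- ifelse(outer(block, block, "=="), within, between)
  noise <- codc:::with_seed(seed, matrix(runif(p * p, -jitter, jitter), p))
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  d <- pmin(pmax(base + noise, 0), 1)
  diag(d) <- 0
  dimnames(d) <- list(genes, genes)
  class(d) <- c("dc_matrix", class(d))
  list(d = d, labels = block, genes = genes)
}
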
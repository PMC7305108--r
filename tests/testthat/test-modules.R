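test_that("copula distance is the involution 1 - score off-diagonal", {
  d <- handmade_dc_matrix(c(0, 1, 0.3), c("a", "b", "c"))
  dist <- copula_distance_matrix(d)
  expect_equal(dist["a", "b"], 1)   # score 0 -> distance 1
  expect_equal(dist["a", "c"], 0)   # score 1 -> distance 0
  expect_true(all(diag(dist) == 0))
  expect_true(isSymmetric(dist))
  # applying 1 - . twice returns the original off-diagonal scores
  again <- copula_distance_matrix(
    structure(dist, class = c("dc_matrix", class(dist))))
  expect_equal(again[upper.tri(again)], unclass(d)[upper.tri(d)])
})

test_that("average-linkage clustering recovers a planted two-block structure", {
  tb <- two_block_dc(p = 40, within = 0.8, between = 0.1)
  ms <- detect_modules(copula_distance_matrix(tb$d), k = 2, min_size = 1)
  expect_equal(ms$K, 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(ms$labels, tb$labels), 1)
})

test_that("dendrogram cuts and small-module merging behave as documented", {
  tb <- two_block_dc(p = 20)
  dist <- copula_distance_matrix(tb$d)
  all_in_one <- detect_modules(dist, k = 1, min_size = 1)
  expect_equal(all_in_one$K, 1)
  singletons <- detect_modules(dist, k = 20, min_size = 1)
  expect_equal(singletons$K, 20)
  # min_size forces the singletons back together
  merged <- detect_modules(dist, k = 20, min_size = 10)
  expect_true(all(table(merged$labels) >= 10))
  expect_error(detect_modules(dist, k = 21), "between 1")
  expect_error(detect_modules(dist, k = 2, cut_height = 0.5), "exactly one")
  expect_error(detect_modules(dist), "exactly one")
  # cut-height route is available and deterministic
  by_h <- detect_modules(dist, cut_height = 0.5, min_size = 1)
  expect_equal(by_h$K, 2)
})

test_that("module labels are invariant to gene input order", {
  tb <- two_block_dc(p = 16, jitter = 0.05, seed = 12)
  dist <- copula_distance_matrix(tb$d)
  ms1 <- detect_modules(dist, k = 4, min_size = 1)
  perm <- sample(16)
  ms2 <- detect_modules(dist[perm, perm], k = 4, min_size = 1)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(ms1$labels[tb$genes[perm]],
                                         ms2$labels), 1)
})

test_that("module eigengene is the leading PC with fixed sign and norm", {
  set.seed(66)
  expr <- matrix(rnorm(10 * 30), 10, 30,
                 dimnames = list(paste0("g", 1:10), NULL))
  eg <- module_eigengene(expr, rownames(expr))
  expect_equal(sum(eg$vector^2), 1)
  expect_true(eg$variance_explained >= 0 && eg$variance_explained <= 1)
  # Rayleigh quotient: no random unit vector explains more variance
  Xs <- t(scale(t(expr)))
  total <- sum(Xs^2)
  rayleigh <- function(v) sum((Xs %*% v)^2) / total
  best_random <- max(vapply(1:1000, function(i) {
    v <- rnorm(30); rayleigh(v / sqrt(sum(v^2)))
  }, numeric(1)))
  expect_gte(eg$variance_explained + 1e-12, best_random)
  # sign convention: aligned with the mean member profile
  expect_gte(sum(eg$vector * colMeans(Xs)), 0)
})

test_that("degenerate modules are handled explicitly", {
  set.seed(67)
  base <- rnorm(20)
  expr <- rbind(g1 = base, g2 = base, g3 = base, flat = rep(1, 20),
                g4 = rnorm(20))
  # duplicated identical genes: variance fully explained, profile recovered
  eg <- module_eigengene(expr, c("g1", "g2", "g3"))
  expect_equal(eg$variance_explained, 1)
  z <- (base - mean(base)) / sd(base)
  expect_equal(abs(cor(eg$vector, z)), 1)
  # single-gene module: the standardized renormalized profile itself
  eg1 <- module_eigengene(expr, "g4")
  z4 <- scale(expr["g4", ])[, 1]
  expect_equal(eg1$vector, z4 / sqrt(sum(z4^2)))
  expect_equal(eg1$variance_explained, 1)
  expect_warning(egc <- module_eigengene(expr, c("g1", "flat")), "constant")
  expect_equal(egc$n_genes, 1)
  expect_error(suppressWarnings(module_eigengene(expr, "flat")),
               "all module genes")
})

test_that("eigengene network composes per-condition correlations", {
  # plant two modules whose eigengenes correlate +0.9 in normal, -0.9 in tumor
  m <- 40
  zn <- correlated_pair(m, 0.9, seed = 301)
  zt <- correlated_pair(m, -0.9, seed = 302)
  dup <- function(v, k, eps, seed) {
    codc:::with_seed(seed,
      t(vapply(1:k, function(i) v + eps * rnorm(length(v)), numeric(length(v)))))
  }
  normal <- rbind(dup(zn[, 1], 4, 0.05, 1), dup(zn[, 2], 4, 0.05, 2))
  tumor <- rbind(dup(zt[, 1], 4, 0.05, 3), dup(zt[, 2], 4, 0.05, 4))
  rownames(normal) <- rownames(tumor) <- paste0("g", 1:8)
  pe <- paired_expression(normal, tumor)
  ms <- structure(list(genes = pe$genes,
                       labels = setNames(rep(1:2, each = 4), pe$genes),
                       K = 2), class = "module_set")
  net <- eigengene_network(ms, pe)
  expect_equal(dim(net$composite), c(2, 2))
  expect_true(all(diag(net$composite) == 1))
  # opposite signs across the diagonal
  expect_lt(net$composite[1, 2] * net$composite[2, 1], 0)
  expect_gt(net$normal[1, 2], 0.8)
  expect_lt(net$tumor[1, 2], -0.8)
  expect_equal(net$composite[1, 2], net$normal[1, 2])
  expect_equal(net$composite[2, 1], net$tumor[1, 2])
  # per-condition correlation matrices are symmetric PSD
  for (mat in list(net$normal, net$tumor)) {
    expect_true(isSymmetric(mat))
    expect_true(all(eigen(mat, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-8))
  }
  # K = 1 degenerates to the 1 x 1 identity
  ms1 <- structure(list(genes = pe$genes,
                        labels = setNames(rep(1, 8), pe$genes),
                        K = 1), class = "module_set")
  expect_equal(unname(eigengene_network(ms1, pe)$composite),
               matrix(1, 1, 1))
})
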
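test_that("exact-correlation pairs hit their target to machine precision", {
  for (rho in c(-0.95, -0.3, 0, 0.5, 0.9)) {
    z <- correlated_pair(50, rho, exact = TRUE, seed = 5)
    expect_lt(abs(cor(z[, 1], z[, 2]) - rho), 1e-10)
  }
  # rho = 1: second margin an affine function of the first
  z1 <- correlated_pair(30, 1, exact = TRUE, seed = 6)
  fit <- lm(z1[, 2] ~ z1[, 1])
  expect_lt(max(abs(residuals(fit))), 1e-8)
  # different seeds: different draws, same exact correlation
  a <- correlated_pair(50, -0.3, exact = TRUE, seed = 1)
  b <- correlated_pair(50, -0.3, exact = TRUE, seed = 2)
  expect_false(isTRUE(all.equal(a, b)))
  expect_equal(cor(a[, 1], a[, 2]), cor(b[, 1], b[, 2]), tolerance = 1e-10)
  expect_error(correlated_pair(2, 0.5), "n must be")
  expect_error(correlated_pair(10, 1.5), "rho")
})

test_that("simulated paired data honor dimensions, specs and the seed", {
  specs <- data.frame(gene_i = c(1, 3), gene_j = c(2, 4),
                      rho_normal = c(0.8, 0.2), rho_tumor = c(-0.8, 0.3))
  cfg <- sim_config(p = 12, m_normal = 25, m_tumor = 30, pair_specs = specs,
                    seed = 91)
  sim <- simulate_paired_expression(cfg)
  expect_equal(dim(sim$paired$normal), c(12, 25))
  expect_equal(dim(sim$paired$tumor), c(12, 30))
  # planted sign-flip pair is ground truth; same-sign mild pair is not
  keys <- paste(sim$truth$gene_i, sim$truth$gene_j)
  expect_true("g001 g002" %in% keys)
  expect_false("g003 g004" %in% keys)
  # realized correlations are exact
  expect_lt(abs(cor(sim$paired$normal[1, ], sim$paired$normal[2, ]) - 0.8),
            1e-10)
  expect_lt(abs(cor(sim$paired$tumor[1, ], sim$paired$tumor[2, ]) + 0.8),
            1e-10)
  # bit-reproducible under the same config
  sim2 <- simulate_paired_expression(cfg)
  expect_identical(sim$paired, sim2$paired)
  # independent genes: true DC pairs are rare (a large correlation shift
  # plus a sign flip almost never arises by chance among 45 pairs)
  plain <- simulate_paired_expression(sim_config(p = 10, seed = 13))
  expect_lte(nrow(plain$truth), 2)
  expect_error(
    sim_config(p = 5, pair_specs = data.frame(
      gene_i = c(1, 1), gene_j = c(2, 3),
      rho_normal = 0.5, rho_tumor = 0.5)),
    "at most one")
})

test_that("per-gene means and variances are applied on the affine scale", {
  cfg <- sim_config(p = 4, m_normal = 400, m_tumor = 400,
                    mean_normal = c(10, 20, 30, 40), var_normal = 4,
                    mean_tumor = 5, var_tumor = 9, seed = 17)
  sim <- simulate_paired_expression(cfg)
  expect_equal(unname(rowMeans(sim$paired$normal)), c(10, 20, 30, 40),
               tolerance = 0.5)
  expect_equal(mean(apply(sim$paired$tumor, 1, sd)), 3, tolerance = 0.3)
})

test_that("ground-truth rule needs both a large shift and a sign flip", {
  # build genes whose pairwise sample correlations are exact by construction
  build <- function(rho_n, rho_t, seed) {
    zn <- correlated_pair(40, rho_n, seed = seed)
    zt <- correlated_pair(40, rho_t, seed = seed + 1)
    paired_expression(
      rbind(a = zn[, 1], b = zn[, 2]),
      rbind(a = zt[, 1], b = zt[, 2]))
  }
  # 0.4 vs -0.4: shift 0.8 > 0.5 with opposite signs -> included
  expect_equal(nrow(ground_truth_dc(build(0.4, -0.4, 11))), 1)
  # 0.2 vs 0.9: same sign -> excluded
  expect_equal(nrow(ground_truth_dc(build(0.2, 0.9, 21))), 0)
  # -0.1 vs 0.3: shift 0.4 <= 0.5 -> excluded
  expect_equal(nrow(ground_truth_dc(build(-0.1, 0.3, 31))), 0)
})

test_that("noise injection is additive, seeded and calibrated", {
  m <- matrix(rnorm(500 * 500), 500)
  expect_identical(inject_noise(m, 0), m)
  n1 <- inject_noise(m, 1, seed = 3)
  expect_identical(n1, inject_noise(m, 1, seed = 3))
  # mean absolute perturbation of unit noise: folded normal sqrt(2/pi)
  expect_equal(mean(abs(n1 - m)), sqrt(2 / pi), tolerance = 0.02)
  # relative mode scales by the pooled sd of the clean matrix
  n2 <- inject_noise(m, 0.5, seed = 3, relative = TRUE)
  expect_equal(sd(n2 - m), 0.5 * sd(as.vector(m)), tolerance = 0.02)
  expect_error(inject_noise(m, -1), "level")
})

test_that("matching proportion counts unordered pair overlap", {
  truth <- data.frame(gene_i = c("a", "b", "c", "x"),
                      gene_j = c("b", "c", "d", "y"))
  expect_equal(matching_proportion(truth, truth), 1)
  # order within a pair does not matter; 3 of 4 matched
  det <- data.frame(gene_i = c("b", "c", "d"), gene_j = c("a", "b", "c"))
  expect_equal(matching_proportion(det, truth), 0.75)
  none <- data.frame(gene_i = "q", gene_j = "r")
  expect_equal(matching_proportion(none, truth), 0)
  expect_error(matching_proportion(det, truth[0, ]), "empty")
})
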
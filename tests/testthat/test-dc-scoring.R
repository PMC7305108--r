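test_that("pair score is zero for identical conditions and ranks strength", {
  set.seed(31)
  x <- rnorm(40); y <- x + rnorm(40)
  expect_identical(dc_copula_score(x, y, x, y), 0)
  # a sign flip scores higher than a mild attenuation (fixed seed, m = 200)
  flip_n <- correlated_pair(200, 0.9, seed = 101)
  flip_t <- correlated_pair(200, -0.9, seed = 102)
  mild_t <- correlated_pair(200, 0.8, seed = 103)
  s_flip <- dc_copula_score(flip_n[, 1], flip_n[, 2],
                            flip_t[, 1], flip_t[, 2])
  s_mild <- dc_copula_score(flip_n[, 1], flip_n[, 2],
                            mild_t[, 1], mild_t[, 2])
  expect_gt(s_flip, s_mild)
  expect_error(dc_copula_score(1:2, 1:2, 1:5, 1:5), "3 samples")
})

test_that("pair score is bitwise invariant to increasing transforms", {
  set.seed(32)
  for (rep in 1:15) {
    xn <- rnorm(50); yn <- xn * runif(1, -1, 1) + rnorm(50)
    xt <- rnorm(50); yt <- xt * runif(1, -1, 1) + rnorm(50)
    s <- dc_copula_score(xn, yn, xt, yt)
    expect_identical(dc_copula_score(xn, yn^3 + 5, exp(xt), yt), s)
  }
})

test_that("DC matrix equals independent per-pair recomputation", {
  sim <- planted_paired(10, 30, NULL, seed = 77)
  pe <- sim$paired
  D <- dc_copula_matrix(pe)
  expect_true(isSymmetric(unclass(D)))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_identical(D[i, j],
                     dc_copula_score(pe$normal[i, ], pe$normal[j, ],
                                     pe$tumor[i, ], pe$tumor[j, ]))
  }
  # permuting gene order permutes rows/columns identically
  perm <- c(4, 1, 10, 3, 2, 9, 5, 8, 6, 7)
  pe_perm <- paired_expression(pe$normal[perm, ], pe$tumor[perm, ])
  expect_equal(dc_copula_matrix(pe_perm), D[perm, perm],
               ignore_attr = TRUE)
  # two genes: a single distinct off-diagonal value
  pe2 <- paired_expression(pe$normal[1:2, ], pe$tumor[1:2, ])
  D2 <- dc_copula_matrix(pe2)
  expect_equal(dim(D2), c(2, 2))
  expect_identical(D2[1, 2], D2[2, 1])
})

test_that("identical joint ranks across conditions give all-zero scores", {
  set.seed(55)
  normal <- matrix(rnorm(5 * 20), 5, dimnames = list(paste0("g", 1:5), NULL))
  pe <- paired_expression(normal, exp(normal))  # same ranks, new scale
  expect_true(all(dc_copula_matrix(pe) == 0))
})

test_that("baseline correlation-difference score matches worked values", {
  expect_equal(baseline_dc_score(0.2, 0.7), 0.5)
  expect_equal(baseline_dc_score(-0.2, 0.2), 0.4)
  expect_equal(baseline_dc_score(0.9, 0.9), 0)
  expect_equal(baseline_dc_score(-1, 1), 2)  # range endpoint
  expect_error(baseline_dc_score(1.2, 0), "\\[-1, 1\\]")
})

test_that("pair extraction thresholds, ranks and annotates deterministically", {
  genes <- c("a", "b", "c", "d")
  d <- handmade_dc_matrix(c(0.9, 0.5, 0.2, 0.5, 0.7, 0.1), genes)
  set.seed(9)
  pe <- paired_expression(
    matrix(rnorm(4 * 12), 4, dimnames = list(genes, NULL)),
    matrix(rnorm(4 * 12), 4, dimnames = list(genes, NULL)))
  got <- extract_dc_pairs(d, pe, threshold = 0.5)
  expect_equal(nrow(got), 4)
  expect_true(all(got$score >= 0.5))
  # descending score, ties broken by gene names
  expect_equal(got$score, sort(got$score, decreasing = TRUE))
  tied <- got[got$score == 0.5, ]
  expect_equal(paste(tied$gene_i, tied$gene_j),
               sort(paste(tied$gene_i, tied$gene_j)))
  # correlation annotations match direct computation
  expect_equal(got$rho_normal[1], cor(pe$normal["a", ], pe$normal["b", ]))
  expect_equal(extract_dc_pairs(d, pe, threshold = 0.95) |> nrow(), 0)
  expect_equal(nrow(extract_dc_pairs(d, pe, threshold = 0)), 6)  # 4*3/2
  expect_equal(nrow(extract_dc_pairs(d, pe, threshold = 0, top_k = 2)), 2)
})

test_that("expression-ratio features have paper layout and arithmetic", {
  genes <- c("a", "b")
  nm <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(genes, NULL))
  tm <- matrix(c(5, 7, 6, 8), 2, 2, dimnames = list(genes, NULL))
  pe <- paired_expression(nm, tm)
  pairs <- data.frame(gene_i = "a", gene_j = "b")
  rf <- ratio_feature_matrix(pairs, pe, pseudocount = 0)
  expect_equal(dim(rf), c(4, 1))  # n samples x n pairs
  expect_equal(unname(rf[, 1]), c(1 / 3, 2 / 4, 5 / 7, 6 / 8))
  expect_equal(as.character(attr(rf, "condition")),
               rep(c("normal", "tumor"), each = 2))
  # self-pair gives an all-ones column
  self <- ratio_feature_matrix(data.frame(gene_i = "a", gene_j = "a"), pe)
  expect_true(all(self == 1))
  z <- pe; z$normal["b", 1] <- 0
  expect_error(ratio_feature_matrix(pairs, z, pseudocount = 0), "zero")
})

test_that("binary pattern matrix encodes same-side-of-median agreement", {
  expr <- rbind(g1 = c(1, 5, 9), g2 = c(9, 5, 1), g3 = c(2, 6, 10))
  colnames(expr) <- paste0("s", 1:3)
  pm <- pattern_match_matrix(
    data.frame(gene_i = c("g1", "g1", "g1"),
               gene_j = c("g1", "g2", "g3")), expr)
  expect_true(all(pm[, "g1/g1"] == 1))
  # g2 is g1 reversed: disagree off the median, agree at it
  expect_equal(unname(pm[, "g1/g2"]), c(0, 1, 0))
  expect_true(all(pm[, "g1/g3"] == 1))
})
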
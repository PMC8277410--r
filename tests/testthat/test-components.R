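test_that("pca_fit reproduces the correlation-matrix eigendecomposition", {
  for (i in 1:20) {
    x <- make_factor_matrix(20, matrix(rnorm(10), 5), noise_sd = 0.8,
                            seed = 300 + i)
    m <- pca_fit(x)
    o <- pca_oracle(x)
    expect_equal(m$eigenvalues, o$eigenvalues, tolerance = 1e-8)
    expect_equal(m$loadings, align_signs(m$loadings, o$loadings),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(m$scores, align_signs(m$scores, o$scores),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("variance shares are ordered, conserved, and complete in rank-1", {
  x <- make_factor_matrix(30, matrix(rnorm(8), 4), seed = 9)
  m <- pca_fit(x)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(sum(m$eigenvalues) / ncol(x), 1, tolerance = 1e-12)
  # three exactly collinear columns: one component carries everything
  z <- rnorm(25)
  col3 <- cbind(a = z, b = 2 * z, c = -3 * z)
  m1 <- pca_fit(col3, retention_rule = "cumulative_variance",
                min_cumulative_variance = 0.85)
  expect_identical(ncol(m1$loadings), 1L)
  expect_equal(m1$variance_share[1], 1, tolerance = 1e-12)
})

test_that("sign convention makes the largest loading positive", {
  x <- make_factor_matrix(40, matrix(rnorm(12), 6), seed = 31)
  m <- pca_fit(x)
  for (j in seq_len(ncol(m$loadings))) {
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  }
  # scores carry zero column means
  expect_equal(colMeans(m$scores), rep(0, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pca_fit rejects degenerate problems", {
  x <- matrix(rnorm(40), 10)
  expect_error(pca_fit(cbind(x[, 1], rep(1, 10))), "constant")
  expect_error(pca_fit(x, k = 5), "unsatisfiable")
  expect_error(pca_fit(x[1:2, ]), ">= 3 units")
})

test_that("score_new_units projects without refitting", {
  x <- make_factor_matrix(50, matrix(rnorm(10), 5), seed = 41)
  m <- pca_fit(x)
  expect_equal(score_new_units(m, x), m$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  mu <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
  expect_equal(drop(score_new_units(m, mu)), rep(0, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # raising an indicator with positive loadings raises the unit's score
  j <- which(m$loadings[, 1] > 0)[1]
  unit <- x[3, , drop = FALSE]
  bumped <- unit
  bumped[, j] <- bumped[, j] + 2
  expect_gt(score_new_units(m, bumped)[1], score_new_units(m, unit)[1])
  expect_error(score_new_units(m, x[, 1:3]), "mismatch")
})

test_that("optimal scaling equals plain PCA when categories are already linear", {
  fx <- linear_ordinal_fixture()
  cat_m <- catpca_fit(fx$x, fx$specs, seed = 1)
  num_m <- pca_fit(fx$x)
  expect_equal(cat_m$cumulative_variance, num_m$cumulative_variance,
               tolerance = 1e-6)
})

test_that("ALS quantifications are monotone and VAF never decreases", {
  set.seed(55)
  for (rep in 1:3) {
    n <- 120
    f <- matrix(rnorm(n * 2), n)
    x <- sapply(1:5, function(j) {
      y <- f[, 1 + (j > 3)] * 0.9 + 0.5 * rnorm(n)
      findInterval(y, quantile(y, seq_len(4) / 5))
    })
    colnames(x) <- paste0("o", 1:5)
    specs <- lapply(colnames(x), function(nm)
      indicator_spec(nm, "academic_reputation", "ordinal", levels = 0:4))
    names(specs) <- colnames(x)
    m <- catpca_fit(x, specs, seed = rep)
    expect_true(all(diff(m$convergence$vaf_trace) >= -1e-10))
    for (q in m$quantifications) {
      expect_true(all(diff(q$quantification) >= -1e-12))
    }
    # optimal scaling can only improve on the integer coding
    expect_gte(m$cumulative_variance, pca_fit(x)$cumulative_variance - 1e-9)
    # deterministic under the recorded seed
    m2 <- catpca_fit(x, specs, seed = rep)
    expect_identical(m$scores, m2$scores)
  }
})

test_that("catpca refuses single-level categorical columns", {
  x <- cbind(a = rep(1, 20), b = rbinom(20, 3, 0.5))
  specs <- list(a = indicator_spec("a", "academic_reputation", "ordinal",
                                   levels = 0:3),
                b = indicator_spec("b", "academic_reputation", "ordinal",
                                   levels = 0:3))
  expect_error(catpca_fit(x, specs), "fewer than 2 observed levels")
})

test_that("planted two-factor loadings are recovered", {
  L <- cbind(c(rep(0.8, 3), rep(0, 3)), c(rep(0, 3), rep(0.6, 3)))
  x <- make_factor_matrix(300, L, noise_sd = 0.5, seed = 77)
  m <- pca_fit(x)
  for (f in 1:2) {
    best <- max(apply(m$loadings, 2, function(l) abs(cor(l, L[, f]))))
    expect_gt(best, 0.9)
  }
})

test_that("subset search drops a planted noise indicator and keeps coherent sets", {
  # 5 structural indicators on 2 factors plus 1 pure-noise column
  L <- rbind(matrix(c(0.9, 0.15, 0.85, 0.2, 0.9, 0.1, 0.2, 0.85, 0.15, 0.9),
                    5, 2, byrow = TRUE), c(0, 0))
  x <- make_factor_matrix(250, L, noise_sd = 0.35, seed = 91)
  specs <- lapply(colnames(x), function(nm)
    indicator_spec(nm, "research_and_development"))
  names(specs) <- colnames(x)
  res <- subset_search(x, specs, scoring_config())
  expect_true(res$acceptable)
  expect_identical(sort(res$chosen), paste0("v", 1:5))

  # three mutually correlated indicators: the full set wins
  base <- rnorm(100)
  y <- sapply(1:3, function(i) 0.9 * base + 0.45 * rnorm(100))
  colnames(y) <- paste0("v", 1:3)
  specs3 <- lapply(colnames(y), function(nm)
    indicator_spec(nm, "quality_and_safety"))
  names(specs3) <- colnames(y)
  res3 <- subset_search(y, specs3, scoring_config())
  expect_true(res3$acceptable)
  expect_identical(sort(res3$chosen), paste0("v", 1:3))

  # enumeration bound
  big <- matrix(rnorm(20 * 17), 20)
  colnames(big) <- paste0("v", 1:17)
  specsb <- lapply(colnames(big), function(nm)
    indicator_spec(nm, "research_and_development"))
  expect_error(subset_search(big, specsb, scoring_config()), "16")
})
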
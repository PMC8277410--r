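test_that("logit transform maps component scores into (0,1) correctly", {
  x <- make_factor_matrix(40, matrix(rnorm(8), 4), seed = 3)
  m <- pca_fit(x)
  S <- logit_transform(m)
  expect_true(all(S > 0 & S < 1))
  # zero score maps to the logistic midpoint under both variants
  m0 <- m
  m0$scores[1, ] <- 0
  expect_equal(logit_transform(m0)[1, ], c(0.5, 0.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(logit_transform(m0, "plain_logistic")[1, ], c(0.5, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # strictly increasing in the component score
  ord <- order(m$scores[, 1])
  expect_true(all(diff(S[ord, 1]) > 0))
  # with a single retained component the two variants coincide
  m1 <- pca_fit(x, k = 1)
  expect_equal(logit_transform(m1, "scaled_logistic"),
               logit_transform(m1, "plain_logistic"), tolerance = 1e-12)
})

test_that("entropy weights match the hand-computed oracle", {
  m <- matrix(c(0.5, 0.5, 0.25, 0.75), 2)
  w <- entropy_weights(m)
  e2 <- -(0.25 * log(0.25) + 0.75 * log(0.75)) / log(2)
  expect_equal(w$entropy, c(1, e2), tolerance = 1e-12)
  expect_equal(w$entropy[2], 0.8113, tolerance = 1e-4)
  expect_equal(w$weight, c(0, 1), tolerance = 1e-12)
  # identical columns share the weight equally
  w2 <- entropy_weights(cbind(c(.2, .4, .6), c(.2, .4, .6)))
  expect_equal(w2$weight, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("entropy weights are a simplex point on every valid input", {
  set.seed(33)
  for (i in 1:1000) {
    x <- matrix(runif(5 * 3, min = 1e-3), 5)
    w <- entropy_weights(x)
    expect_equal(sum(w$weight), 1, tolerance = 1e-12)
    expect_true(all(w$weight >= 0))
  }
  expect_error(entropy_weights(matrix(c(0.5, -0.1, 0.2, 0.3), 2)),
               "positive")
  expect_error(entropy_weights(matrix(1, 1, 2)), ">= 2 units")
})

test_that("domain combination is the expected convex combination", {
  S <- matrix(c(.2, .8, .4, .6, .9, .1), 3)
  expect_equal(combine_domain(S, c(1, 0)), S[, 1], tolerance = 1e-12)
  expect_equal(combine_domain(matrix(0.5, 4, 2), c(.3, .7)), rep(0.5, 4),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    S <- matrix(runif(12), 4)
    w <- runif(3)
    w <- w / sum(w)
    sc <- combine_domain(S, w)
    expect_true(all(sc >= apply(S, 1, min) - 1e-12))
    expect_true(all(sc <= apply(S, 1, max) + 1e-12))
  }
  expect_error(combine_domain(S, c(1, 0)), "mismatch")
})

test_that("min-max aggregation hits the endpoints and ranks correctly", {
  ds <- list()
  raw <- c(2, 5, 10) / 3          # equal weights triple the domain scores
  for (d in chdi_domains()) {
    ds[[d]] <- setNames(raw, c("u1", "u2", "u3"))
  }
  res <- aggregate_chdi(ds)
  tab <- res$table[order(res$table$unit), ]
  expect_equal(tab$chdi, c(0, 0.375, 1), tolerance = 1e-12)
  expect_equal(tab$rank, c(3, 2, 1))
  res100 <- aggregate_chdi(ds, output_scale = 100)
  expect_equal(max(res100$table$chdi), 100, tolerance = 1e-12)
  expect_equal(min(res100$table$chdi), 0, tolerance = 1e-12)
  # ties share the average rank
  ds2 <- lapply(ds, function(v) setNames(c(1, 1, 2), names(v)))
  r2 <- aggregate_chdi(ds2)
  expect_equal(sort(r2$table$rank), c(1, 2.5, 2.5))
  # degenerate range collapses to zero with a warning
  ds3 <- lapply(ds, function(v) setNames(rep(0.4, 3), names(v)))
  expect_warning(r3 <- aggregate_chdi(ds3), "degenerate")
  expect_equal(r3$table$chdi, rep(0, 3))
  # unit mismatch is an error
  ds4 <- ds
  names(ds4[[2]]) <- c("u1", "u2", "zz")
  expect_error(aggregate_chdi(ds4), "mismatch")
})

test_that("pipeline output is exchangeable, permutation- and scale-invariant", {
  tbl <- small_table(n = 60, seed = 19)
  cfg <- fast_config(seed = 19)
  run <- run_pipeline(tbl, cfg)
  base <- run$ranking$table
  chdi_of <- function(r) setNames(r$ranking$table$chdi, r$ranking$table$unit)

  # duplicated hospitals tie exactly
  dup <- indicator_table(rbind(tbl$values, tbl$values[7, , drop = FALSE]),
                         tbl$specs, units = c(tbl$units, "CLONE"))
  rdup <- run_pipeline(dup, cfg)
  cd <- chdi_of(rdup)
  expect_equal(cd[["CLONE"]], cd[["H07"]], tolerance = 1e-12)
  tt <- rdup$ranking$table
  expect_equal(tt$rank[tt$unit == "CLONE"], tt$rank[tt$unit == "H07"])

  # permuting rows changes nothing per hospital
  set.seed(1)
  perm <- sample(length(tbl$units))
  ptbl <- indicator_table(tbl$values[perm, ], tbl$specs,
                          units = tbl$units[perm])
  expect_equal(chdi_of(run_pipeline(ptbl, cfg))[tbl$units],
               chdi_of(run)[tbl$units], tolerance = 1e-9)

  # rescaling a numeric benefit column by a positive constant changes nothing
  stbl <- tbl
  stbl$values[, "r2"] <- 1000 * stbl$values[, "r2"]
  expect_equal(chdi_of(run_pipeline(stbl, cfg))[tbl$units],
               chdi_of(run)[tbl$units], tolerance = 1e-9)

  # same seed, same input: byte-identical ranking artifacts
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_run_outputs(run_pipeline(tbl, cfg), tbl, d1)
  write_run_outputs(run_pipeline(tbl, cfg), tbl, d2)
  expect_identical(readLines(file.path(d1, "ranking.csv")),
                   readLines(file.path(d2, "ranking.csv")))
})
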
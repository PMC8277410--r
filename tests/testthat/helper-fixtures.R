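# shared fixtures and oracles, built in code at test time

# correlated numeric matrix with a planted 2-factor structure
make_factor_matrix <- function(n, loadings, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  p <- nrow(loadings)
  f <- matrix(rnorm(n * ncol(loadings)), n)
  x <- f %*% t(loadings) + noise_sd * matrix(rnorm(n * p), n)
  colnames(x) <- paste0("v", seq_len(p))
  x
}

# small three-domain table that runs the whole pipeline in well under a second
small_table <- function(n = 80, seed = 5) {
  set.seed(seed)
  f <- matrix(rnorm(n * 3), n) %*% chol(matrix(c(1, .7, .7, .7, 1, .7,
                                                 .7, .7, 1), 3))
  specs <- list(); cols <- list()
  mk <- function(nm, dom, fi, scale = "numeric", direction = "benefit",
                 levels = NULL) {
    v <- 0.9 * f[, fi] + 0.35 * rnorm(n)
    if (direction == "cost") v <- -v
    if (scale == "ordinal") {
      v <- findInterval(v, quantile(v, seq_len(4) / 5))
      levels <- 0:4
    }
    cols[[nm]] <<- v
    specs[[nm]] <<- indicator_spec(nm, dom, scale, direction, levels)
  }
  mk("r1", "research_and_development", 1)
  mk("r2", "research_and_development", 1)
  mk("r3", "research_and_development", 1)
  mk("a1", "academic_reputation", 2, scale = "ordinal")
  mk("a2", "academic_reputation", 2, scale = "ordinal")
  mk("a3", "academic_reputation", 2, scale = "ordinal")
  mk("q1", "quality_and_safety", 3, direction = "cost")
  mk("q2", "quality_and_safety", 3, direction = "cost")
  mk("q3", "quality_and_safety", 3)
  indicator_table(do.call(cbind, cols), specs,
                  units = sprintf("H%02d", seq_len(n)))
}

fast_config <- function(...) {
  scoring_config(subset_search = FALSE, ...)
}

# ordinal data that is exactly rank-2 with equally spaced categories, so
# optimal scaling has nothing to improve over the numeric coding
linear_ordinal_fixture <- function() {
  g <- expand.grid(f1 = -1:1, f2 = -1:1)
  g <- g[rep(seq_len(nrow(g)), times = 4), ]          # n = 36
  x <- cbind(c1 = g$f1, c2 = g$f1, c3 = g$f2, c4 = g$f2, c5 = g$f1 + g$f2)
  specs <- lapply(colnames(x), function(nm)
    indicator_spec(nm, "academic_reputation", "ordinal",
                   levels = sort(unique(x[, nm]))))
  names(specs) <- colnames(x)
  list(x = x, specs = specs)
}

# brute-force KMO oracle: partial correlations from residual regressions
kmo_oracle <- function(x) {
  p <- ncol(x)
  r <- cor(x)
  u <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      others <- setdiff(seq_len(p), c(i, j))
      ri <- if (length(others)) resid(lm(x[, i] ~ x[, others])) else x[, i]
      rj <- if (length(others)) resid(lm(x[, j] ~ x[, others])) else x[, j]
      u[i, j] <- u[j, i] <- cor(ri, rj)
    }
  }
  diag(r) <- 0
  sum(r^2) / (sum(r^2) + sum(u^2))
}

# brute-force PCA oracle: eigendecomposition of the correlation matrix
pca_oracle <- function(x, k = 2) {
  z <- scale(x)
  e <- eigen(cor(x), symmetric = TRUE)
  list(eigenvalues = e$values,
       loadings = e$vectors[, seq_len(k), drop = FALSE],
       scores = z %*% e$vectors[, seq_len(k), drop = FALSE])
}

# align oracle component signs to a fitted model before comparing
align_signs <- function(ref, other) {
  for (j in seq_len(ncol(ref))) {
    if (sum(ref[, j] * other[, j]) < 0) other[, j] <- -other[, j]
  }
  other
}

# memoised default fixture + full pipeline run shared across test files
.chdi_cache <- new.env(parent = emptyenv())
cached_fixture <- function(seed = 17) {
  key <- paste0("fx", seed)
  if (is.null(.chdi_cache[[key]])) {
    .chdi_cache[[key]] <- default_fixture(seed = seed)
  }
  .chdi_cache[[key]]
}
cached_run <- function(seed = 17) {
  key <- paste0("run", seed)
  if (is.null(.chdi_cache[[key]])) {
    fx <- cached_fixture(seed)
    .chdi_cache[[key]] <- run_pipeline(fx$table, scoring_config(seed = seed))
  }
  .chdi_cache[[key]]
}
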
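# ---- internal helpers -------------------------------------------------------

# KMO from a correlation matrix (shared by kmo() and the subset search)
kmo_from_cor <- function(r) {
  q <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(q) || !all(is.finite(q))) return(NA_real_)
  d <- 1 / sqrt(diag(q))
  u <- -q * tcrossprod(d)
  diag(r) <- 0
  diag(u) <- 0
  sum(r^2) / (sum(r^2) + sum(u^2))
}

# Weighted pool-adjacent-violators: nondecreasing fit to y with weights w.
pava <- function(y, w) {
  stopifnot(length(y) == length(w), all(w > 0))
  n <- length(y)
  if (n == 1L) return(y)
  # blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; sz[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tw
      wt[m - 1L] <- tw
      sz[m - 1L] <- sz[m - 1L] + sz[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = sz[seq_len(m)])
}

# number of components to retain given eigenvalues of a correlation matrix
retained_components <- function(eig, retention_rule, k, min_cumulative_variance,
                                n_units) {
  p <- length(eig)
  m <- if (retention_rule == "fixed_k") {
    if (k > p) stop("retention rule unsatisfiable: k = ", k, " > ", p,
                    " components", call. = FALSE)
    k
  } else {
    g <- cumsum(eig) / sum(eig)
    which(g >= min_cumulative_variance)[1L]
  }
  if (is.na(m)) stop("retention rule unsatisfiable", call. = FALSE)
  if (n_units <= m) {
    stop("need more units (", n_units, ") than retained components (", m, ")",
         call. = FALSE)
  }
  m
}

# deterministic sign convention: the largest-|loading| entry of each retained
# component is positive
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

new_component_model <- function(method, indicators, loadings, eigenvalues,
                                scores, transforms, quantifications = NULL,
                                convergence = NULL) {
  p <- length(eigenvalues)
  m <- ncol(loadings)
  C <- eigenvalues / p
  structure(list(method = method,
                 indicators = indicators,
                 loadings = loadings,
                 eigenvalues = eigenvalues,
                 variance_share = C[seq_len(m)],
                 cumulative_variance = sum(C[seq_len(m)]),
                 scores = scores,
                 transforms = transforms,
                 quantifications = quantifications,
                 convergence = convergence),
            class = "component_model")
}

# ---- PCA --------------------------------------------------------------------

#' Principal component model of one domain
#'
#' Standardizes each column to zero mean and unit variance and
#' eigendecomposes the correlation matrix (via [stats::prcomp()]).
#' Components are ordered by eigenvalue, the number retained is governed by
#' the retention rule, and a deterministic sign convention (largest-magnitude
#' loading positive) fixes the reflection ambiguity.
#'
#' @param x Numeric matrix, units x indicators (validated and
#'   direction-adjusted).
#' @param retention_rule,k,min_cumulative_variance See [scoring_config()].
#' @return A `component_model` with unit-norm eigenvector `loadings`
#'   (indicators x retained components), all `eigenvalues`, per-component
#'   `variance_share` \eqn{C_i}, `cumulative_variance` \eqn{G(m)}, and
#'   per-unit `scores` \eqn{F_{hi}} (standardized data projected on the
#'   eigenvectors).
#' @export
pca_fit <- function(x, retention_rule = c("fixed_k", "cumulative_variance"),
                    k = 2L, min_cumulative_variance = 0.85) {
  retention_rule <- match.arg(retention_rule)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("pca_fit requires >= 2 columns", call. = FALSE)
  if (nrow(x) < 3L) stop("pca_fit requires >= 3 units", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  m <- retained_components(eig, retention_rule, k, min_cumulative_variance,
                           nrow(x))
  sgn <- fix_signs(pc$rotation[, seq_len(m), drop = FALSE],
                   pc$x[, seq_len(m), drop = FALSE])
  transforms <- list(type = rep("numeric", ncol(x)),
                     center = pc$center, scale = pc$scale)
  new_component_model("pca", colnames(x), sgn$loadings, eig, sgn$scores,
                      transforms)
}

# ---- CATPCA -----------------------------------------------------------------

#' Categorical principal components by optimal scaling
#'
#' Alternating least squares: given current category quantifications the
#' standardized data are decomposed as in [pca_fit()]; given component scores
#' and loadings, each categorical column's quantifications are updated to the
#' least-squares optimum — category centroids for nominal columns, a weighted
#' monotone (pool-adjacent-violators) regression of those centroids for
#' ordinal columns — then restandardized. Iterations continue until the
#' variance accounted for (VAF) by the retained components changes by less
#' than `tol`. VAF is nondecreasing across iterations by construction.
#'
#' Ordinal columns are initialized from their category-index coding, nominal
#' columns from seeded random quantifications.
#'
#' @param x Numeric matrix of raw (direction-adjusted) values.
#' @param specs List of `indicator_spec`, one per column of `x`; at least one
#'   must be ordinal or nominal.
#' @param retention_rule,k,min_cumulative_variance See [scoring_config()].
#' @param seed Integer seed for nominal initialization (recorded).
#' @param tol Convergence tolerance on the VAF change; default `1e-6`.
#' @param max_iter Iteration cap; non-convergence returns the best iterate
#'   with a warning and `converged = FALSE`.
#' @return A `component_model` (method `"catpca"`) whose `quantifications`
#'   element maps, for each categorical column, observed category value to
#'   its optimal standardized quantification; `convergence` records the VAF
#'   trace.
#' @export
catpca_fit <- function(x, specs,
                       retention_rule = c("fixed_k", "cumulative_variance"),
                       k = 2L, min_cumulative_variance = 0.85,
                       seed = 1L, tol = 1e-6, max_iter = 200L) {
  retention_rule <- match.arg(retention_rule)
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  stopifnot(length(specs) == p)
  scales <- vapply(specs, function(s) s$scale, character(1))
  if (!any(scales != "numeric")) {
    stop("catpca_fit requires >= 1 ordinal/nominal column; use pca_fit",
         call. = FALSE)
  }
  for (j in which(scales != "numeric")) {
    if (length(unique(x[, j])) < 2L) {
      stop("categorical column '", colnames(x)[j],
           "' has fewer than 2 observed levels", call. = FALSE)
    }
  }

  # initial coding: standardized category index for ordinal, seeded random
  # quantifications for nominal, standardized raw values for numeric
  set.seed(seed)
  Z <- matrix(0, n, p, dimnames = dimnames(x))
  lev <- vector("list", p)            # observed levels, category order
  for (j in seq_len(p)) {
    if (scales[j] == "numeric") {
      Z[, j] <- x[, j]
    } else {
      lv <- specs[[j]]$levels
      lv <- lv[lv %in% x[, j]]        # observed levels in declared order
      lev[[j]] <- lv
      code <- if (scales[j] == "ordinal") {
        match(x[, j], lv)
      } else {
        stats::runif(length(lv))[match(x[, j], lv)]
      }
      Z[, j] <- code
    }
  }
  Z <- scale(Z)

  # fix the retained dimensionality on the initial solution
  pc <- stats::prcomp(Z, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  m <- retained_components(eig, retention_rule, k, min_cumulative_variance, n)

  vaf_trace <- sum(eig[seq_len(m)]) / p
  converged <- FALSE
  iter <- 0L
  cat_cols <- which(scales != "numeric")
  while (iter < max_iter) {
    iter <- iter + 1L
    X <- pc$x[, seq_len(m), drop = FALSE]
    A <- pc$rotation[, seq_len(m), drop = FALSE]
    for (j in cat_cols) {
      target <- drop(X %*% A[j, ])
      g <- match(x[, j], lev[[j]])
      cnt <- tabulate(g, nbins = length(lev[[j]]))
      obs <- which(cnt > 0)
      mu <- vapply(obs, function(l) mean(target[g == l]), numeric(1))
      if (scales[j] == "ordinal") mu <- pava(mu, cnt[obs])
      z <- mu[match(g, obs)]
      s <- stats::sd(z)
      if (s > 0) Z[, j] <- (z - mean(z)) / s   # constant fit: keep previous
    }
    pc <- stats::prcomp(Z, center = TRUE, scale. = TRUE)
    eig <- pc$sdev^2
    vaf <- sum(eig[seq_len(m)]) / p
    vaf_trace <- c(vaf_trace, vaf)
    if (abs(vaf - vaf_trace[iter]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("catpca_fit: not converged after ", max_iter,
            " iterations; returning best iterate", call. = FALSE)
  }

  sgn <- fix_signs(pc$rotation[, seq_len(m), drop = FALSE],
                   pc$x[, seq_len(m), drop = FALSE])
  # per-column transform maps for scoring new units: categorical columns map
  # observed value -> final standardized quantification; numeric columns are
  # standardized with the training mean/sd
  quants <- vector("list", p)
  names(quants) <- colnames(x)
  Zs <- scale(Z)                       # == final prcomp input, standardized
  for (j in cat_cols) {
    g <- match(x[, j], lev[[j]])
    qv <- vapply(seq_along(lev[[j]]), function(l) {
      idx <- which(g == l)
      if (length(idx)) Zs[idx[1L], j] else NA_real_
    }, numeric(1))
    keep <- !is.na(qv)
    quants[[j]] <- data.frame(value = lev[[j]][keep],
                              quantification = qv[keep])
  }
  transforms <- list(type = ifelse(scales == "numeric", "numeric", "map"),
                     center = vapply(seq_len(p), function(j)
                       if (scales[j] == "numeric") mean(x[, j]) else 0,
                       numeric(1)),
                     scale = vapply(seq_len(p), function(j)
                       if (scales[j] == "numeric") stats::sd(x[, j]) else 1,
                       numeric(1)))
  names(transforms$center) <- names(transforms$scale) <- colnames(x)
  new_component_model("catpca", colnames(x), sgn$loadings, eig, sgn$scores,
                      transforms, quantifications = quants,
                      convergence = list(converged = converged,
                                         iterations = iter,
                                         vaf = vaf_trace[length(vaf_trace)],
                                         vaf_trace = vaf_trace,
                                         seed = seed))
}

# ---- projection of new units ------------------------------------------------

#' Score new units under a fitted component model
#'
#' Applies the stored standardization (and, for categorical models, the
#' stored category quantifications) and projects onto the retained loadings
#' without refitting.
#'
#' @param model A `component_model`.
#' @param x Numeric matrix whose columns match `model$indicators` (any
#'   order).
#' @return Units x retained-components score matrix.
#' @export
score_new_units <- function(model, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$indicators)) {
      stop("column mismatch: expected ", length(model$indicators),
           " columns", call. = FALSE)
    }
    colnames(x) <- model$indicators
  }
  if (!setequal(colnames(x), model$indicators)) {
    stop("column mismatch: expected ",
         paste(model$indicators, collapse = ", "), call. = FALSE)
  }
  x <- x[, model$indicators, drop = FALSE]
  Z <- x
  for (j in seq_along(model$indicators)) {
    nm <- model$indicators[j]
    if (model$transforms$type[j] == "numeric") {
      Z[, j] <- (x[, j] - model$transforms$center[[nm]]) /
        model$transforms$scale[[nm]]
    } else {
      q <- model$quantifications[[nm]]
      idx <- match(x[, j], q$value)
      if (anyNA(idx)) {
        stop("unseen category value(s) in '", nm, "'", call. = FALSE)
      }
      Z[, j] <- q$quantification[idx]
    }
  }
  Z %*% model$loadings
}

# ---- exhaustive indicator-subset search -------------------------------------

#' Exhaustive indicator-subset search within a domain
#'
#' Enumerates every nonempty subset of the domain's indicators and evaluates
#' each candidate model. A subset is acceptable when its suitability
#' diagnostic (KMO for numeric domains, Cronbach alpha for categorical
#' domains) strictly exceeds `config$kmo_threshold` and the retained
#' components' cumulative variance reaches
#' `config$min_cumulative_variance`. Among acceptable subsets the largest
#' wins (models with more indicators produce more informative component
#' scores); ties on size are broken by higher cumulative variance, then by
#' lexicographic indicator order. If no subset is acceptable the full set is
#' returned, flagged.
#'
#' @param values Numeric matrix, units x domain indicators (direction
#'   adjusted).
#' @param specs List of `indicator_spec` for the columns of `values`.
#' @param config A `scoring_config`.
#' @return An object of class `subset_search_result`: `records` (one row per
#'   candidate subset), `chosen` (indicator names), `acceptable`,
#'   `rationale`.
#' @export
subset_search <- function(values, specs, config = scoring_config()) {
  values <- as.matrix(values)
  p <- ncol(values)
  if (p > 16L) {
    stop("subset search is exhaustive and limited to 16 indicators (got ",
         p, ")", call. = FALSE)
  }
  method <- domain_method(specs)
  nm <- colnames(values)
  thr <- config$kmo_threshold
  minG <- config$min_cumulative_variance

  R <- stats::cor(values)              # subset statistics only need this
  V <- stats::cov(values)              # for alpha on subsets

  n_sub <- 2L^p - 1L
  size <- integer(n_sub); diag_val <- numeric(n_sub)
  cumvar <- numeric(n_sub); ok <- logical(n_sub)
  members <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    idx <- which(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    members[[s]] <- idx
    size[s] <- length(idx)
    if (size[s] < 2L) {                # diagnostic & 2 components undefined
      diag_val[s] <- NA_real_; cumvar[s] <- NA_real_; ok[s] <- FALSE
      next
    }
    if (method == "pca") {
      d <- kmo_from_cor(R[idx, idx])
      eig <- eigen(R[idx, idx], symmetric = TRUE, only.values = TRUE)$values
      kk <- min(config$k, size[s])
      g <- sum(eig[seq_len(kk)]) / size[s]
    } else {
      kk <- ncol(V[idx, idx])
      d <- (kk / (kk - 1)) * (1 - sum(diag(V[idx, idx])) / sum(V[idx, idx]))
      # candidate screening only needs VAF to ~1e-3: coarser ALS tolerance
      fit <- tryCatch(
        suppressWarnings(
          catpca_fit(values[, idx, drop = FALSE], specs[idx],
                     retention_rule = config$retention_rule,
                     k = min(config$k, size[s]),
                     min_cumulative_variance = minG, seed = config$seed,
                     tol = 1e-5, max_iter = 100L)),
        error = function(e) NULL)
      g <- if (is.null(fit)) NA_real_ else fit$cumulative_variance
    }
    diag_val[s] <- d
    cumvar[s] <- g
    ok[s] <- isTRUE(d > thr) && isTRUE(g >= minG)
  }

  key <- vapply(members, function(i) paste(i, collapse = "."), character(1))
  records <- data.frame(subset = vapply(members, function(i)
    paste(nm[i], collapse = "+"), character(1)),
    size = size, diagnostic = diag_val, cumulative_variance = cumvar,
    acceptable = ok)

  if (any(ok)) {
    cand <- which(ok)
    cand <- cand[order(-size[cand], -cumvar[cand], key[cand])]
    best <- cand[1L]
    chosen <- nm[members[[best]]]
    rationale <- sprintf(
      "largest acceptable subset (%d of %d indicators; %s = %.3f, cumulative variance = %.3f)",
      size[best], p, if (method == "pca") "KMO" else "alpha",
      diag_val[best], cumvar[best])
    acceptable <- TRUE
  } else {
    chosen <- nm
    rationale <- "no acceptable subset; full indicator set returned, flagged"
    acceptable <- FALSE
  }
  structure(list(records = records, chosen = chosen,
                 acceptable = acceptable, method = method,
                 n_indicators = p, rationale = rationale),
            class = "subset_search_result")
}

#' @export
print.component_model <- function(x, ...) {
  cat("component_model (", x$method, "): ", length(x$indicators),
      " indicators, ", ncol(x$loadings), " retained components\n", sep = "")
  cat("  variance shares:",
      paste(sprintf("%.3f", x$variance_share), collapse = ", "), "\n")
  cat("  cumulative variance:", sprintf("%.3f", x$cumulative_variance), "\n")
  if (!is.null(x$convergence)) {
    cat("  ALS: ", x$convergence$iterations, " iterations, converged = ",
        x$convergence$converged, "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.subset_search_result <- function(x, ...) {
  cat("subset_search_result:", x$rationale, "\n")
  cat("  chosen:", paste(x$chosen, collapse = ", "), "\n")
  invisible(x)
}
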
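#' Logit transformation of component scores
#'
#' Maps each retained component score onto the open unit interval — the
#' strictly positive values the entropy weight method requires. Under the
#' default `"scaled_logistic"` variant a component's score is first scaled by
#' its share of the retained variance:
#' \deqn{S_{hi} = \frac{1}{1 + \exp(-(C_i / G(m)) \, F_{hi})},}
#' where \eqn{C_i} is component \eqn{i}'s variance share, \eqn{G(m)} the
#' cumulative variance of the retained set, and \eqn{F_{hi}} unit \eqn{h}'s
#' component score. `"plain_logistic"` omits the \eqn{C_i/G(m)} factor. Both
#' are strictly increasing in \eqn{F_{hi}} and coincide when a single
#' component is retained.
#'
#' @param model A fitted `component_model`.
#' @param variant `"scaled_logistic"` (default) or `"plain_logistic"`.
#' @param scores Optional score matrix to transform instead of
#'   `model$scores` (e.g. from [score_new_units()]).
#' @return Units x components matrix with entries strictly in (0, 1).
#' @export
logit_transform <- function(model,
                            variant = c("scaled_logistic", "plain_logistic"),
                            scores = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "component_model"))
  F <- if (is.null(scores)) model$scores else as.matrix(scores)
  slope <- switch(variant,
                  scaled_logistic = model$variance_share /
                    model$cumulative_variance,
                  plain_logistic = rep(1, ncol(F)))
  S <- stats::plogis(sweep(F, 2L, slope, `*`))
  # logistic is total: clamp only exact 0/1 from floating underflow
  pmin(pmax(S, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Entropy weights for retained components
#'
#' Objective weighting by diversification: a component whose transformed
#' scores differ more across units carries more information and receives
#' more weight. With column-normalized shares
#' \eqn{p_{hi} = x_{hi} / \sum_h x_{hi}}, the information entropy is
#' \eqn{e_i = -(1/\ln n) \sum_h p_{hi} \ln p_{hi}} (with
#' \eqn{0 \ln 0 := 0}), the diversification degree \eqn{d_i = 1 - e_i}, and
#' the weight \eqn{w_i = d_i / \sum_i d_i}. If every column is constant
#' (all \eqn{d_i = 0}) equal weights are returned with a warning.
#'
#' @param x Units x components matrix of strictly positive values (as
#'   produced by [logit_transform()]).
#' @return An object of class `entropy_weights`: data frame with columns
#'   `component`, `entropy`, `diversification`, `weight`.
#' @export
entropy_weights <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("entropy weights require >= 2 units", call. = FALSE)
  if (any(x <= 0)) stop("entropy weights require strictly positive values",
                        call. = FALSE)
  p <- sweep(x, 2L, colSums(x), `/`)
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  e <- -colSums(plogp) / log(n)
  d <- 1 - e
  d[d < 0] <- 0                       # guard tiny negative rounding
  if (sum(d) == 0) {
    warning("all components constant; falling back to equal weights",
            call. = FALSE)
    w <- rep(1 / ncol(x), ncol(x))
  } else {
    w <- d / sum(d)
  }
  structure(data.frame(component = seq_len(ncol(x)), entropy = e,
                       diversification = d, weight = w),
            class = c("entropy_weights", "data.frame"))
}

#' Combine transformed component scores into a domain score
#'
#' The per-unit domain score is the entropy-weighted convex combination
#' \eqn{\mathrm{score}_h = \sum_i w_i S_{hi}}, hence lies strictly in (0, 1).
#'
#' @param S Units x components matrix in (0, 1).
#' @param w An `entropy_weights` object (or bare weight vector).
#' @return Named per-unit score vector.
#' @export
combine_domain <- function(S, w) {
  S <- as.matrix(S)
  wv <- if (inherits(w, "entropy_weights") || is.data.frame(w)) w$weight else w
  if (length(wv) != ncol(S)) {
    stop("dimension mismatch: ", length(wv), " weights for ", ncol(S),
         " components", call. = FALSE)
  }
  # elementwise accumulation (not %*%) so identical units get bit-identical
  # scores regardless of row position
  out <- numeric(nrow(S))
  for (i in seq_along(wv)) out <- out + wv[i] * S[, i]
  names(out) <- rownames(S)
  out
}

#' Aggregate domain scores into the ranked composite index
#'
#' Computes the raw score as the weighted sum of the three domain scores,
#' min-max rescales it so the top unit attains `output_scale` and the bottom
#' unit 0 — \eqn{\mathrm{CHDI}_h = (\mathrm{raw}_h - \min) / \mathrm{range}}
#' — and ranks units in descending order (average ranks on ties). Pearson
#' correlations among the three domain scores and the raw total are attached
#' as a validation report.
#'
#' @param domain_scores Named list (one element per domain label) of
#'   per-unit score vectors over the same units.
#' @param domain_weights Named nonnegative domain weights (normalized
#'   internally); default equal.
#' @param output_scale 1 or 100.
#' @return An object of class `ranking_result`: `table` (data frame with
#'   unit, the three domain scores, `raw`, `chdi`, `rank`, sorted by rank),
#'   `domain_weights`, `validation` (correlation matrix), and
#'   `validation_p` (two-sided p-values).
#' @export
aggregate_chdi <- function(domain_scores, domain_weights = NULL,
                           output_scale = 1) {
  stopifnot(is.list(domain_scores),
            setequal(names(domain_scores), chdi_domains()))
  domain_scores <- domain_scores[chdi_domains()]
  n <- length(domain_scores[[1L]])
  units <- names(domain_scores[[1L]])
  for (d in chdi_domains()) {
    if (length(domain_scores[[d]]) != n ||
        !identical(names(domain_scores[[d]]), units)) {
      stop("unit-set mismatch across domains", call. = FALSE)
    }
  }
  if (is.null(domain_weights)) {
    domain_weights <- stats::setNames(rep(1 / 3, 3), chdi_domains())
  }
  domain_weights <- unlist(domain_weights)[chdi_domains()]
  domain_weights <- domain_weights / sum(domain_weights)

  M <- do.call(cbind, domain_scores)
  raw <- numeric(n)
  for (i in seq_len(3)) raw <- raw + domain_weights[i] * M[, i]
  rng <- max(raw) - min(raw)
  if (rng == 0) {
    warning("degenerate raw-score range; all index values set to 0",
            call. = FALSE)
    chdi_val <- rep(0, n)
  } else {
    chdi_val <- (raw - min(raw)) / rng * output_scale
  }
  rk <- rank(-chdi_val, ties.method = "average")

  vm <- cbind(M, total = raw)
  validation <- suppressWarnings(stats::cor(vm))  # NA for constant columns
  pmat <- matrix(NA_real_, ncol(vm), ncol(vm),
                 dimnames = dimnames(validation))
  for (i in seq_len(ncol(vm) - 1L)) {
    for (j in seq((i + 1L), ncol(vm))) {
      pv <- tryCatch(suppressWarnings(stats::cor.test(vm[, i], vm[, j])$p.value),
                     error = function(e) NA_real_)
      pmat[i, j] <- pmat[j, i] <- pv
    }
  }

  tab <- data.frame(unit = if (is.null(units)) paste0("H", seq_len(n)) else units,
                    M, raw = raw, chdi = chdi_val, rank = rk,
                    check.names = FALSE, row.names = NULL)
  tab <- tab[order(tab$rank, tab$unit), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, domain_weights = domain_weights,
                 output_scale = output_scale,
                 validation = validation, validation_p = pmat),
            class = "ranking_result")
}

#' Run the full scoring pipeline
#'
#' Executes the whole chain on a validated table: direction adjustment,
#' per-domain suitability diagnostics, exhaustive indicator-subset search
#' (optional), component-model fitting (PCA for all-numeric domains, CATPCA
#' otherwise), logit transformation, entropy weighting, domain combination,
#' and composite aggregation with ranking. Fully deterministic given
#' `config$seed`.
#'
#' @param tbl A validated `indicator_table`.
#' @param config A `scoring_config`.
#' @param outdir Optional directory: when given, every intermediate artifact
#'   (diagnostics, per-domain models, entropy weights, ranking, validation
#'   correlations, manifest) is written there as CSV/YAML.
#' @return An object of class `chdi_run`: the `ranking_result` plus
#'   `diagnostics`, per-domain `models`, `subset_searches`, `weights`
#'   (entropy), `domain_scores`, and `config`.
#' @export
run_pipeline <- function(tbl, config = scoring_config(), outdir = NULL) {
  stopifnot(inherits(tbl, "indicator_table"), inherits(config, "scoring_config"))
  tbl <- apply_direction(tbl)
  diagnostics <- diagnose_domains(tbl, config)
  if (any(!diagnostics$pass)) {
    failed <- diagnostics$domain[!diagnostics$pass]
    msg <- paste("domain(s) below diagnostic threshold:",
                 paste(failed, collapse = ", "))
    if (config$on_diagnostic_failure == "abort") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }

  models <- list(); searches <- list(); weights <- list()
  domain_scores <- list()
  for (d in chdi_domains()) {
    sl <- domain_slice(tbl, d)
    method <- domain_method(sl$specs)
    sel <- colnames(sl$values)
    if (config$subset_search && ncol(sl$values) >= 2L) {
      sr <- subset_search(sl$values, sl$specs, config)
      searches[[d]] <- sr
      sel <- sr$chosen
    }
    xv <- sl$values[, sel, drop = FALSE]
    sp <- sl$specs[sel]
    model <- if (method == "pca") {
      pca_fit(xv, retention_rule = config$retention_rule, k = config$k,
              min_cumulative_variance = config$min_cumulative_variance)
    } else {
      catpca_fit(xv, sp, retention_rule = config$retention_rule,
                 k = config$k,
                 min_cumulative_variance = config$min_cumulative_variance,
                 seed = config$seed)
    }
    models[[d]] <- model
    S <- logit_transform(model, config$logit_variant)
    w <- entropy_weights(S)
    weights[[d]] <- w
    sc <- combine_domain(S, w)
    names(sc) <- tbl$units
    domain_scores[[d]] <- sc
  }

  ranking <- aggregate_chdi(domain_scores, config$domain_weights,
                            config$output_scale)
  run <- structure(list(ranking = ranking, diagnostics = diagnostics,
                        models = models, subset_searches = searches,
                        weights = weights, domain_scores = domain_scores,
                        config = config),
                   class = "chdi_run")
  if (!is.null(outdir)) write_run_outputs(run, tbl, outdir)
  run
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("ranking_result:", nrow(x$table), "units; top of the table:\n")
  print(utils::head(x$table, 5), digits = 4)
  invisible(x)
}

#' @export
print.chdi_run <- function(x, ...) {
  cat("chdi_run over", nrow(x$ranking$table), "units\n")
  for (d in chdi_domains()) {
    m <- x$models[[d]]
    cat(sprintf("  %s: %s, %d indicators, G(m) = %.3f\n", d, m$method,
                length(m$indicators), m$cumulative_variance))
  }
  print(x$ranking)
  invisible(x)
}
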
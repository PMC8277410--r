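#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares squared Pearson correlations against squared anti-image partial
#' correlations obtained from the inverse correlation matrix:
#' \deqn{KMO = \frac{\sum_{i \ne j} r_{ij}^2}{\sum_{i \ne j} r_{ij}^2 +
#'   \sum_{i \ne j} u_{ij}^2},}
#' where \eqn{u_{ij} = -q_{ij} / \sqrt{q_{ii} q_{jj}}} and \eqn{Q = R^{-1}}.
#' Values above 0.7 are taken here as evidence that the variables share
#' enough correlation for principal component analysis to be sensible.
#'
#' @param x Numeric matrix (units x indicators), at least two columns.
#' @param msa Also return per-variable measures of sampling adequacy as the
#'   `"msa"` attribute?
#' @return The overall KMO value in `[0, 1]`.
#' @export
kmo <- function(x, msa = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("KMO requires >= 2 columns", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  q <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(q) || !all(is.finite(q))) {
    stop("singular correlation matrix; consider an indicator subset search",
         call. = FALSE)
  }
  d <- 1 / sqrt(diag(q))
  u <- -q * tcrossprod(d)          # anti-image partial correlations
  diag(r) <- 0
  diag(u) <- 0
  r2 <- sum(r^2)
  u2 <- sum(u^2)
  out <- r2 / (r2 + u2)
  if (msa) {
    r2i <- colSums(r^2)
    u2i <- colSums(u^2)
    attr(out, "msa") <- r2i / (r2i + u2i)
  }
  out
}

#' Cronbach alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right),}
#' with \eqn{k} items, item variances \eqn{s_j^2} and total-score variance
#' \eqn{s_T^2}. Used as the pre-fit reliability check for domains scored by
#' categorical principal components.
#'
#' @param x Numeric matrix (units x items), at least two rows and columns.
#' @return The alpha coefficient (at most 1; can be negative).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 2L) {
    stop("cronbach_alpha requires >= 2 rows and >= 2 columns", call. = FALSE)
  }
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop("zero total-score variance", call. = FALSE)
  item_var <- sum(apply(x, 2, stats::var))
  (k / (k - 1)) * (1 - item_var / total_var)
}

#' Per-domain suitability diagnostics
#'
#' Computes, for each domain, the statistic matching its dimension-reduction
#' method: KMO when all indicators are numeric (standard principal
#' components), Cronbach alpha when any indicator is ordinal or nominal
#' (categorical principal components). A domain passes when its statistic
#' strictly exceeds the configured threshold.
#'
#' @param tbl A validated, direction-adjusted `indicator_table` (direction
#'   adjustment is applied if missing).
#' @param config A `scoring_config`.
#' @return Data frame with columns `domain`, `statistic`, `value`, `pass`.
#' @export
diagnose_domains <- function(tbl, config = scoring_config()) {
  stopifnot(inherits(tbl, "indicator_table"))
  tbl <- apply_direction(tbl)
  out <- lapply(chdi_domains(), function(d) {
    sl <- domain_slice(tbl, d)
    stat <- domain_method(sl$specs)
    val <- if (stat == "pca") kmo(sl$values) else cronbach_alpha(sl$values)
    data.frame(domain = d,
               statistic = if (stat == "pca") "KMO" else "alpha",
               value = as.numeric(val),
               pass = as.numeric(val) > config$kmo_threshold)
  })
  do.call(rbind, out)
}

# pca when every indicator in the domain is numeric, catpca otherwise
domain_method <- function(specs) {
  if (all(vapply(specs, function(s) s$scale == "numeric", logical(1)))) {
    "pca"
  } else {
    "catpca"
  }
}
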
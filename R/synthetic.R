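#' Indicator template for the simulator
#'
#' Describes how one synthetic indicator is produced from its domain's two
#' latent strength factors: a loading vector, additive Gaussian noise, and a
#' value family mapping the latent linear combination to a realistic
#' marginal.
#'
#' @param name Indicator name.
#' @param family `"count"` (lognormal-then-rounded, heavy-tailed like
#'   publication or citation counts), `"proportion"` (logistic squash, for
#'   ratio indicators), `"ordinal"` (quantile-cut into `n_levels` ordered
#'   small-integer codes), or `"gaussian"` (plain linear).
#' @param loadings Length-2 numeric: loadings on the domain's primary and
#'   secondary latent factors.
#' @param noise_sd Standard deviation of the indicator-specific Gaussian
#'   noise.
#' @param direction `"benefit"` or `"cost"`; cost indicators are generated
#'   with reversed polarity (a stronger hospital gets a lower value).
#' @param n_levels Number of ordered levels for the `"ordinal"` family.
#' @param location,spread Family location/spread: log-mean and log-sd for
#'   `"count"`, intercept and slope (on the logit scale) for
#'   `"proportion"`, mean and sd for `"gaussian"`. Ignored for `"ordinal"`.
#' @return A list of class `indicator_template`.
#' @export
indicator_template <- function(name,
                               family = c("count", "proportion", "ordinal",
                                          "gaussian"),
                               loadings = c(0.9, 0.15), noise_sd = 0.3,
                               direction = "benefit", n_levels = 5L,
                               location = 4, spread = 0.6) {
  family <- match.arg(family)
  stopifnot(length(loadings) == 2L, all(is.finite(loadings)), noise_sd >= 0)
  structure(list(name = name, family = family, loadings = as.numeric(loadings),
                 noise_sd = noise_sd,
                 direction = match.arg(direction, .directions),
                 n_levels = as.integer(n_levels),
                 location = location, spread = spread),
            class = "indicator_template")
}

#' Simulation design for synthetic hospital tables
#'
#' A design couples a cohort size, one list of [indicator_template()]s per
#' domain, and the 3x3 correlation matrix of the domains' primary latent
#' strength factors. Each domain additionally has an independent secondary
#' factor, so indicators within a domain load on one or two factors.
#'
#' @param n_units Number of hospitals (>= 10).
#' @param templates Named list (domain label -> list of
#'   `indicator_template`).
#' @param latent_correlation Symmetric positive-semidefinite 3x3 matrix with
#'   unit diagonal, rows/columns ordered as [chdi_domains()].
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_units, templates, latent_correlation) {
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 10L, setequal(names(templates), chdi_domains()))
  R <- as.matrix(latent_correlation)
  if (!isTRUE(all.equal(R, t(R))) || !all(diag(R) == 1) ||
      any(eigen(R, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("latent_correlation must be symmetric PSD with unit diagonal",
         call. = FALSE)
  }
  structure(list(n_units = n_units, templates = templates[chdi_domains()],
                 latent_correlation = R),
            class = "simulation_design")
}

# push a standardized latent score through a value family
apply_family <- function(tmpl, y) {
  switch(tmpl$family,
         count = round(exp(tmpl$location + tmpl$spread * y)),
         proportion = stats::plogis(tmpl$location + tmpl$spread * y),
         gaussian = tmpl$location + tmpl$spread * y,
         ordinal = {
           k <- tmpl$n_levels
           br <- stats::quantile(y, probs = seq_len(k - 1L) / k)
           findInterval(y, br)          # codes 0 .. k-1, monotone in y
         })
}

#' Generate a synthetic hospitals-by-indicators table
#'
#' Draws correlated primary strength factors across the three domains, an
#' independent secondary factor per domain, builds each indicator as
#' loading-weighted factors plus Gaussian noise, standardizes, and pushes
#' the result through the indicator's value family. Cost indicators are
#' generated with reversed polarity. Deterministic given `seed`.
#'
#' @param design A `simulation_design`.
#' @param seed Integer seed.
#' @return List with `table` (a validated `indicator_table`), and `truth`
#'   (a `simulation_truth`: per-unit latent factor scores, the names of the
#'   pure-noise indicators, the design and the seed).
#' @export
generate_hospitals <- function(design, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  n <- design$n_units
  L <- chol(design$latent_correlation)
  primary <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  colnames(primary) <- chdi_domains()
  secondary <- matrix(stats::rnorm(n * 3), n, 3)
  colnames(secondary) <- chdi_domains()

  specs <- list(); cols <- list(); noise_ind <- character(0)
  for (d in chdi_domains()) {
    for (tmpl in design$templates[[d]]) {
      lat <- tmpl$loadings[1] * primary[, d] +
        tmpl$loadings[2] * secondary[, d] +
        tmpl$noise_sd * stats::rnorm(n)
      sd_theor <- sqrt(sum(tmpl$loadings^2) + tmpl$noise_sd^2)
      y <- if (sd_theor > 0) lat / sd_theor else lat
      if (tmpl$direction == "cost") y <- -y
      v <- apply_family(tmpl, y)
      cols[[tmpl$name]] <- v
      if (all(tmpl$loadings == 0)) noise_ind <- c(noise_ind, tmpl$name)
      specs[[tmpl$name]] <- indicator_spec(
        name = tmpl$name, domain = d,
        scale = if (tmpl$family == "ordinal") "ordinal" else "numeric",
        direction = tmpl$direction,
        levels = if (tmpl$family == "ordinal") seq_len(tmpl$n_levels) - 1L
                 else NULL)
    }
  }
  values <- do.call(cbind, cols)
  units <- sprintf("H%03d", seq_len(n))
  rownames(values) <- units
  tbl <- indicator_table(values, specs, units = units)
  truth <- structure(list(
    primary = as.data.frame(primary, row.names = units),
    secondary = as.data.frame(secondary, row.names = units),
    noise_indicators = noise_ind, design = design, seed = seed),
    class = "simulation_truth")
  list(table = tbl, truth = truth)
}

#' The packaged default simulation design
#'
#' Emulates the structure of the study cohort the scoring chain is meant
#' for: 310 tertiary hospitals and three domains with 13, 9 and 3 candidate
#' indicators. The research-and-development domain has 11 structural
#' count-type indicators (publications, citations, high-impact papers,
#' clinical trials) on two factors plus 2 pure-noise indicators; academic
#' reputation has 6 structural small-integer ordinal indicators
#' (academicians, editorships, association posts, awards) plus 3 noise
#' ordinal indicators; quality and safety has two cost-direction malpractice
#' ratio indicators and one specialty-care count. Primary-factor
#' correlations are 0.78 (research-reputation), 0.62 (research-quality) and
#' 0.60 (reputation-quality), so all domains correlate positively and the
#' quality domain is the weakest link, and communalities are high enough
#' that two components capture most of each domain's variance.
#'
#' @param n_units Cohort size; default 310.
#' @return A `simulation_design`.
#' @export
default_design <- function(n_units = 310L) {
  rd_main <- function(name, location) {
    indicator_template(name, family = "count", loadings = c(0.93, 0.17),
                       noise_sd = 0.36, location = location, spread = 0.6)
  }
  rd_high <- function(name, location) {
    indicator_template(name, family = "count", loadings = c(0.45, 0.84),
                       noise_sd = 0.36, location = location, spread = 0.6)
  }
  rd_noise <- function(name, location) {
    indicator_template(name, family = "count", loadings = c(0, 0),
                       noise_sd = 1, location = location, spread = 0.6)
  }
  rd <- list(
    rd_main("sci_papers_all", 5.5), rd_main("sci_papers_first", 5.0),
    rd_main("sci_papers_corr", 4.8), rd_main("citations_all", 8.0),
    rd_main("citations_first", 7.2), rd_main("citations_corr", 7.0),
    rd_main("clinical_trials", 4.0),
    rd_high("high_if_papers_all", 3.2), rd_high("high_if_papers_first", 2.8),
    rd_high("high_if_papers_corr", 2.6), rd_high("top_journal_papers_all", 2.4),
    rd_noise("top_journal_papers_first", 2.0),
    rd_noise("top_journal_papers_corr", 1.8))

  ar_main <- function(name, k) {
    indicator_template(name, family = "ordinal", loadings = c(0.93, 0.15),
                       noise_sd = 0.31, n_levels = k)
  }
  ar_second <- function(name, k) {
    indicator_template(name, family = "ordinal", loadings = c(0.45, 0.85),
                       noise_sd = 0.31, n_levels = k)
  }
  ar_noise <- function(name, k) {
    indicator_template(name, family = "ordinal", loadings = c(0, 0),
                       noise_sd = 1, n_levels = k)
  }
  ar <- list(
    ar_main("academicians_cas_cae", 9L), ar_main("chief_editors_cscd", 8L),
    ar_main("assoc_chairpersons", 8L), ar_main("state_science_awards", 7L),
    ar_second("assoc_members", 10L), ar_second("medical_science_awards", 8L),
    ar_noise("doctor_awards", 6L), ar_noise("tech_progress_awards", 7L),
    ar_noise("preeminent_awards", 5L))

  qs <- list(
    indicator_template("compensation_case_ratio", family = "proportion",
                       loadings = c(0.82, 0.30), noise_sd = 0.30,
                       direction = "cost", location = -2, spread = 0.8),
    indicator_template("liability_ratio", family = "proportion",
                       loadings = c(0.80, -0.30), noise_sd = 0.30,
                       direction = "cost", location = -1.5, spread = 0.7),
    indicator_template("key_specialties", family = "count",
                       loadings = c(0.90, 0.10), noise_sd = 0.25,
                       location = 2.2, spread = 0.7))

  R <- matrix(c(1, 0.78, 0.62,
                0.78, 1, 0.60,
                0.62, 0.60, 1), 3, 3,
              dimnames = list(chdi_domains(), chdi_domains()))
  simulation_design(n_units, list(research_and_development = rd,
                                  academic_reputation = ar,
                                  quality_and_safety = qs), R)
}

#' Generate the packaged default fixture
#'
#' Convenience wrapper: [generate_hospitals()] on [default_design()].
#'
#' @param seed Integer seed; default 17.
#' @param n_units Cohort size; default 310.
#' @return List with `table` and `truth` (see [generate_hospitals()]).
#' @export
default_fixture <- function(seed = 17L, n_units = 310L) {
  generate_hospitals(default_design(n_units), seed = seed)
}

#' Write simulation truth to CSV
#'
#' @param truth A `simulation_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  df <- data.frame(unit = rownames(truth$primary),
                   stats::setNames(truth$primary,
                                   paste0(chdi_domains(), "_primary")),
                   stats::setNames(truth$secondary,
                                   paste0(chdi_domains(), "_secondary")),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
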
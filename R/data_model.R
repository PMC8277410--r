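#' Canonical domain labels
#'
#' The three performance domains every indicator must belong to:
#' research and development, academic reputation, and quality and safety.
#'
#' @return Character vector of the three domain labels.
#' @export
chdi_domains <- function() {
  c("research_and_development", "academic_reputation", "quality_and_safety")
}

.scales <- c("numeric", "ordinal", "nominal")
.directions <- c("benefit", "cost")

#' Declare a single indicator
#'
#' An indicator is a named column of the hospitals-by-indicators table with
#' three pieces of metadata: the domain it measures, its measurement scale,
#' and its direction (whether larger values are better or worse).
#'
#' @param name Indicator name (unique within a table).
#' @param domain One of [chdi_domains()].
#' @param scale `"numeric"`, `"ordinal"` or `"nominal"`.
#' @param direction `"benefit"` (larger is better) or `"cost"` (larger is
#'   worse, e.g. a malpractice compensation ratio).
#' @param levels For ordinal/nominal indicators, the finite set of admissible
#'   category codes, in category order for ordinal scales.
#' @return An object of class `indicator_spec`.
#' @export
indicator_spec <- function(name, domain, scale = "numeric",
                           direction = "benefit", levels = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  domain <- match.arg(domain, chdi_domains())
  scale <- match.arg(scale, .scales)
  direction <- match.arg(direction, .directions)
  if (scale != "numeric") {
    if (is.null(levels) || length(levels) < 2L) {
      stop("indicator '", name, "': ", scale,
           " scale requires a declared set of >= 2 levels", call. = FALSE)
    }
    levels <- as.numeric(levels)
    if (anyDuplicated(levels)) {
      stop("indicator '", name, "': duplicated levels", call. = FALSE)
    }
  } else {
    levels <- NULL
  }
  structure(list(name = name, domain = domain, scale = scale,
                 direction = direction, levels = levels),
            class = "indicator_spec")
}

#' Assemble a hospitals-by-indicators table
#'
#' The central data container: a numeric matrix of hospitals (rows) by
#' indicators (columns) together with one [indicator_spec()] per column.
#'
#' @param values Numeric matrix or data frame, one row per hospital.
#' @param specs List of [indicator_spec()], one per column, in column order.
#' @param units Character vector of unique hospital identifiers; defaults to
#'   the row names of `values`.
#' @param validate Run [validate_indicator_table()] before returning?
#' @return An object of class `indicator_table` with elements `units`,
#'   `specs`, `values` (matrix with dimnames), and attribute
#'   `direction_adjusted`.
#' @export
indicator_table <- function(values, specs, units = rownames(values),
                            validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(units)) units <- paste0("H", seq_len(nrow(values)))
  units <- as.character(units)
  if (length(units) != nrow(values)) {
    stop("length(units) must equal nrow(values)", call. = FALSE)
  }
  if (anyDuplicated(units)) {
    stop("duplicate unit identifiers: ",
         paste(unique(units[duplicated(units)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(specs) || length(specs) != ncol(values)) {
    stop("specs must be a list with one indicator_spec per column",
         call. = FALSE)
  }
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate indicator names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  dimnames(values) <- list(units, nm)
  names(specs) <- nm
  tbl <- structure(list(units = units, specs = specs, values = values),
                   direction_adjusted = FALSE, class = "indicator_table")
  if (validate) validate_indicator_table(tbl) else tbl
}

#' Validate an indicator table
#'
#' Checks that every domain is represented, that no cell is missing, and that
#' categorical cells take only their declared levels. Incomplete hospitals can
#' be dropped instead of rejected.
#'
#' @param tbl An `indicator_table`.
#' @param drop_incomplete_units Drop (with a message) hospitals that have any
#'   missing cell instead of raising an error.
#' @return The validated table (possibly with rows removed).
#' @export
validate_indicator_table <- function(tbl, drop_incomplete_units = FALSE) {
  stopifnot(inherits(tbl, "indicator_table"))
  doms <- vapply(tbl$specs, function(s) s$domain, character(1))
  missing_dom <- setdiff(chdi_domains(), doms)
  if (length(missing_dom)) {
    stop("no indicators declared for domain(s): ",
         paste(missing_dom, collapse = ", "), call. = FALSE)
  }
  bad <- !stats::complete.cases(tbl$values)
  if (any(bad)) {
    if (drop_incomplete_units) {
      message("dropping ", sum(bad), " unit(s) with missing cells: ",
              paste(tbl$units[bad], collapse = ", "))
      tbl$values <- tbl$values[!bad, , drop = FALSE]
      tbl$units <- tbl$units[!bad]
    } else {
      stop("missing values in units: ",
           paste(tbl$units[bad], collapse = ", "),
           " (use drop_incomplete_units = TRUE to remove them)",
           call. = FALSE)
    }
  }
  for (s in tbl$specs) {
    if (s$scale != "numeric") {
      v <- tbl$values[, s$name]
      undeclared <- setdiff(unique(v), s$levels)
      if (length(undeclared)) {
        stop("indicator '", s$name, "': undeclared category level(s) ",
             paste(undeclared, collapse = ", "), call. = FALSE)
      }
    }
  }
  tbl
}

#' Negate cost-direction indicators
#'
#' Rewrites every cost indicator so that larger values are better for all
#' columns, by negation (which preserves the linear correlation structure the
#' component models rely on). Idempotent: a flag on the table prevents double
#' application.
#'
#' @param tbl A validated `indicator_table`.
#' @return The table with cost columns negated and attribute
#'   `direction_adjusted = TRUE`.
#' @export
apply_direction <- function(tbl) {
  stopifnot(inherits(tbl, "indicator_table"))
  if (isTRUE(attr(tbl, "direction_adjusted"))) return(tbl)
  for (s in tbl$specs) {
    if (s$direction == "cost") {
      tbl$values[, s$name] <- -tbl$values[, s$name]
      if (s$scale != "numeric") {
        tbl$specs[[s$name]]$levels <- sort(-s$levels)
      }
    }
  }
  attr(tbl, "direction_adjusted") <- TRUE
  tbl
}

#' Scoring configuration
#'
#' All tunable parameters of the scoring chain, with the package defaults.
#'
#' @param retention_rule `"fixed_k"` (retain exactly `k` components, the
#'   default) or `"cumulative_variance"` (retain the smallest number of
#'   components whose cumulative variance share reaches
#'   `min_cumulative_variance`).
#' @param k Number of components under `"fixed_k"`; default 2.
#' @param min_cumulative_variance Cumulative-variance fraction used both by
#'   the `"cumulative_variance"` retention rule and as the subset-search
#'   acceptability floor; default 0.85.
#' @param domain_weights Named nonnegative weights for the three domains;
#'   normalized to sum to 1. Default: equal weights.
#' @param logit_variant `"scaled_logistic"` (default) scales each component
#'   score by its variance share before the logistic squash;
#'   `"plain_logistic"` does not.
#' @param subset_search Run the exhaustive indicator-subset search per domain?
#' @param kmo_threshold Diagnostic pass threshold (strictly greater than);
#'   applied to KMO for numeric domains and Cronbach alpha for categorical
#'   domains. Default 0.7.
#' @param output_scale 1 or 100: the value assigned to the top-ranked unit.
#' @param seed Integer seed recorded in models and manifests.
#' @param on_diagnostic_failure `"flag"` (proceed, mark the domain) or
#'   `"abort"`.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(retention_rule = c("fixed_k", "cumulative_variance"),
                           k = 2L,
                           min_cumulative_variance = 0.85,
                           domain_weights = NULL,
                           logit_variant = c("scaled_logistic", "plain_logistic"),
                           subset_search = TRUE,
                           kmo_threshold = 0.7,
                           output_scale = 1,
                           seed = 1L,
                           on_diagnostic_failure = c("flag", "abort")) {
  retention_rule <- match.arg(retention_rule)
  logit_variant <- match.arg(logit_variant)
  on_diagnostic_failure <- match.arg(on_diagnostic_failure)
  k <- as.integer(k)
  stopifnot(k >= 1L,
            min_cumulative_variance > 0, min_cumulative_variance < 1,
            kmo_threshold > 0, kmo_threshold < 1,
            output_scale %in% c(1, 100))
  if (is.null(domain_weights)) {
    domain_weights <- stats::setNames(rep(1 / 3, 3), chdi_domains())
  }
  if (is.null(names(domain_weights)) ||
      !setequal(names(domain_weights), chdi_domains())) {
    stop("domain_weights must be named with the three domain labels",
         call. = FALSE)
  }
  domain_weights <- unlist(domain_weights)[chdi_domains()]
  if (any(domain_weights < 0) || sum(domain_weights) <= 0) {
    stop("domain_weights must be nonnegative with positive sum", call. = FALSE)
  }
  domain_weights <- domain_weights / sum(domain_weights)
  structure(list(retention_rule = retention_rule, k = k,
                 min_cumulative_variance = min_cumulative_variance,
                 domain_weights = domain_weights,
                 logit_variant = logit_variant,
                 subset_search = isTRUE(subset_search),
                 kmo_threshold = kmo_threshold,
                 output_scale = output_scale,
                 seed = as.integer(seed),
                 on_diagnostic_failure = on_diagnostic_failure),
            class = "scoring_config")
}

#' Read a configuration file
#'
#' The configuration is a YAML document with an `indicators` sequence (each
#' entry: `name`, `domain`, `scale`, `direction`, optional `levels`) and an
#' optional `scoring` mapping overriding [scoring_config()] defaults.
#'
#' @param path Path to the YAML configuration.
#' @return List with elements `specs` (list of `indicator_spec`) and
#'   `scoring` (a `scoring_config`).
#' @export
read_chdi_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$indicators)) {
    stop("configuration has no 'indicators' section: ", path, call. = FALSE)
  }
  specs <- lapply(cfg$indicators, function(x) {
    indicator_spec(name = x$name, domain = x$domain,
                   scale = if (is.null(x$scale)) "numeric" else x$scale,
                   direction = if (is.null(x$direction)) "benefit" else x$direction,
                   levels = x$levels)
  })
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  scoring <- do.call(scoring_config, if (is.null(cfg$scoring)) list() else cfg$scoring)
  list(specs = specs, scoring = scoring)
}

#' Write a configuration file
#'
#' Inverse of [read_chdi_config()]: serializes indicator specs and scoring
#' parameters to YAML.
#'
#' @param specs List of `indicator_spec`.
#' @param scoring A `scoring_config` (or `NULL` for defaults).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chdi_config <- function(specs, scoring = NULL, path) {
  ind <- lapply(specs, function(s) {
    out <- list(name = s$name, domain = s$domain, scale = s$scale,
                direction = s$direction)
    if (!is.null(s$levels)) out$levels <- s$levels
    out
  })
  doc <- list(indicators = unname(ind))
  if (!is.null(scoring)) {
    doc$scoring <- unclass(scoring)
    doc$scoring$domain_weights <- as.list(scoring$domain_weights)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a hospitals-by-indicators CSV
#'
#' Expects UTF-8 comma-delimited text with a header row of indicator names
#' and a leading unit-identifier column. Every column in the header must be
#' declared in the configuration and vice versa.
#'
#' @param path Path to the CSV file.
#' @param config Either a path to a YAML configuration or the list returned
#'   by [read_chdi_config()].
#' @param drop_incomplete_units Passed to [validate_indicator_table()].
#' @return A validated `indicator_table`.
#' @export
read_indicator_table <- function(path, config, drop_incomplete_units = FALSE) {
  if (is.character(config)) config <- read_chdi_config(config)
  specs <- config$specs
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table must have a unit column plus >= 1 indicator",
                          call. = FALSE)
  units <- as.character(df[[1L]])
  cols <- names(df)[-1L]
  unknown <- setdiff(cols, names(specs))
  if (length(unknown)) {
    stop("column(s) not declared in configuration: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(names(specs), cols)
  if (length(absent)) {
    stop("declared indicator(s) absent from table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  vals <- df[, names(specs), drop = FALSE]
  for (nm in names(specs)) {
    v <- suppressWarnings(as.numeric(vals[[nm]]))
    bad <- which(is.na(v) & !is.na(vals[[nm]]) & vals[[nm]] != "")
    if (length(bad)) {
      stop("non-numeric cell(s) in indicator '", nm, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    vals[[nm]] <- v
  }
  tbl <- indicator_table(as.matrix(vals), specs[names(specs)], units = units,
                         validate = FALSE)
  validate_indicator_table(tbl, drop_incomplete_units = drop_incomplete_units)
}

#' Write a hospitals-by-indicators CSV
#'
#' @param tbl An `indicator_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "indicator_table"))
  # %.17g keeps doubles lossless so read-after-write is the identity
  chr <- apply(tbl$values, 2, function(v) sprintf("%.17g", v))
  df <- data.frame(unit = tbl$units, chr, check.names = FALSE,
                   row.names = NULL)
  names(df) <- c("unit", colnames(tbl$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset an indicator table to one domain
#'
#' @param tbl An `indicator_table`.
#' @param domain One of [chdi_domains()].
#' @return List with `values` (matrix), `specs` (list), `units`.
#' @export
domain_slice <- function(tbl, domain) {
  domain <- match.arg(domain, chdi_domains())
  keep <- vapply(tbl$specs, function(s) s$domain == domain, logical(1))
  if (!any(keep)) stop("no indicators in domain ", domain, call. = FALSE)
  list(values = tbl$values[, keep, drop = FALSE],
       specs = tbl$specs[keep], units = tbl$units)
}

#' @export
print.indicator_table <- function(x, ...) {
  doms <- vapply(x$specs, function(s) s$domain, character(1))
  cat("indicator_table:", length(x$units), "units x", length(x$specs),
      "indicators\n")
  for (d in chdi_domains()) {
    cat("  ", d, ": ", sum(doms == d), " indicator(s)\n", sep = "")
  }
  cat("  direction adjusted:", isTRUE(attr(x, "direction_adjusted")), "\n")
  invisible(x)
}
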
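format_p <- function(p) ifelse(p < 0.001, "<.001", sprintf("%.3f", p))

#' Render a human-readable results report
#'
#' One text document with four sections: per-domain component-model summary
#' (original vs selected indicator counts, retained components, cumulative
#' variance), entropy weights as percentages, the top-k ranking with the
#' index printed to four decimals, and the domain-score correlation matrix
#' with two-sided p-values.
#'
#' @param run A `chdi_run` from [run_pipeline()].
#' @param top_k Number of ranking rows to print; default 10.
#' @return Character vector of report lines, invisibly printed with
#'   `cat()` when `print = TRUE`.
#' @param print Emit the report to the console?
#' @export
render_report <- function(run, top_k = 10L, print = FALSE) {
  stopifnot(inherits(run, "chdi_run"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, unlist(list(...)))

  add("== Component models ==")
  add(sprintf("%-28s %9s %9s %11s %21s", "domain", "original", "selected",
              "components", "cumulative variance"))
  for (d in chdi_domains()) {
    m <- run$models[[d]]
    orig <- if (!is.null(run$subset_searches[[d]])) {
      run$subset_searches[[d]]$n_indicators
    } else {
      length(m$indicators)
    }
    add(sprintf("%-28s %9d %9d %11d %21.3f", d, orig, length(m$indicators),
                ncol(m$loadings), m$cumulative_variance))
  }

  add("", "== Entropy weights (%) ==")
  for (d in chdi_domains()) {
    w <- run$weights[[d]]
    add(sprintf("%-28s %s", d,
                paste(sprintf("PC%d: %5.1f", w$component, 100 * w$weight),
                      collapse = "  ")))
  }

  add("", sprintf("== Ranking (top %d of %d) ==", top_k,
                  nrow(run$ranking$table)))
  add(sprintf("%5s %-10s %9s", "rank", "unit", "index"))
  top <- utils::head(run$ranking$table, top_k)
  for (i in seq_len(nrow(top))) {
    add(sprintf("%5g %-10s %9.4f", top$rank[i], top$unit[i], top$chdi[i]))
  }

  add("", "== Domain-score correlations ==")
  v <- run$ranking$validation
  p <- run$ranking$validation_p
  add(sprintf("%-28s %s", "", paste(sprintf("%24s", colnames(v)),
                                    collapse = " ")))
  for (i in seq_len(nrow(v))) {
    cells <- vapply(seq_len(ncol(v)), function(j) {
      if (i == j) sprintf("%24s", "1") else
        sprintf("%16.3f (p%s)", v[i, j],
                sub("^<", "<", format_p(p[i, j])))
    }, character(1))
    add(sprintf("%-28s %s", rownames(v)[i], paste(cells, collapse = " ")))
  }

  if (print) cat(ln, sep = "\n")
  invisible(ln)
}

#' Run manifest for reproducibility
#'
#' Records content hashes of the input table and configuration, the seed,
#' the package version, timestamps and stage outcomes, so that two runs with
#' equal hashes and seed are certified to declare identical outputs.
#'
#' @param run A `chdi_run`.
#' @param input_path Path to the input table file (hashed if it exists).
#' @param config_path Path to the configuration file (hashed if it exists).
#' @return Named list (the manifest).
#' @export
run_manifest <- function(run, input_path = NULL, config_path = NULL) {
  hash_file <- function(p) {
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }
  hash_obj <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2)
    unname(tools::md5sum(f))
  }
  list(toolkit_version = as.character(utils::packageVersion("chdi")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = run$config$seed,
       input_hash = hash_file(input_path),
       config_hash = hash_file(config_path),
       config_digest = hash_obj(unclass(run$config)),
       ranking_digest = hash_obj(run$ranking$table),
       stages = list(
         diagnostics = all(run$diagnostics$pass),
         subset_search = length(run$subset_searches) > 0,
         models = vapply(run$models, function(m) m$method, character(1)),
         converged = vapply(run$models, function(m)
           is.null(m$convergence) || isTRUE(m$convergence$converged),
           logical(1))))
}

#' Write every run artifact to a directory
#'
#' Emits `ranking.csv`, `entropy_weights.csv`, `diagnostics.csv`,
#' `validation_correlations.csv`, one `model_<domain>.txt` per domain
#' (loadings, variance shares, quantifications, seed — enough to reproduce
#' scoring bit-for-bit), `report.txt` and `manifest.yaml`.
#'
#' @param run A `chdi_run`.
#' @param tbl The input `indicator_table` (used only for bookkeeping).
#' @param outdir Output directory, created if missing.
#' @param input_path,config_path Optional source paths for the manifest.
#' @return `outdir`, invisibly.
#' @export
write_run_outputs <- function(run, tbl = NULL, outdir,
                              input_path = NULL, config_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$ranking$table, file.path(outdir, "ranking.csv"),
                   row.names = FALSE, quote = FALSE)
  ew <- do.call(rbind, lapply(chdi_domains(), function(d) {
    w <- run$weights[[d]]
    data.frame(domain = d, component = w$component, entropy = w$entropy,
               diversification = w$diversification, weight = w$weight)
  }))
  utils::write.csv(ew, file.path(outdir, "entropy_weights.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$diagnostics, file.path(outdir, "diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  v <- as.data.frame(run$ranking$validation)
  v <- cbind(score = rownames(v), v)
  utils::write.csv(v, file.path(outdir, "validation_correlations.csv"),
                   row.names = FALSE, quote = FALSE)
  for (d in chdi_domains()) {
    write_component_model(run$models[[d]],
                          file.path(outdir, paste0("model_", d, ".txt")))
  }
  writeLines(render_report(run), file.path(outdir, "report.txt"))
  yaml::write_yaml(run_manifest(run, input_path, config_path),
                   file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' Serialize a component model to structured text
#'
#' @param model A `component_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_component_model <- function(model, path) {
  doc <- list(method = model$method,
              indicators = model$indicators,
              eigenvalues = as.numeric(model$eigenvalues),
              variance_share = as.numeric(model$variance_share),
              cumulative_variance = model$cumulative_variance,
              loadings = lapply(seq_len(ncol(model$loadings)), function(j)
                as.numeric(model$loadings[, j])),
              transforms = list(type = model$transforms$type,
                                center = as.numeric(model$transforms$center),
                                scale = as.numeric(model$transforms$scale)))
  if (!is.null(model$quantifications)) {
    doc$quantifications <- lapply(model$quantifications, function(q) {
      if (is.null(q)) NULL else
        list(value = as.numeric(q$value),
             quantification = as.numeric(q$quantification))
    })
  }
  if (!is.null(model$convergence)) {
    doc$convergence <- model$convergence[c("converged", "iterations",
                                           "vaf", "seed")]
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}
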
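#' Configuration for a full sequence analysis
#'
#' @param tables Named list mapping context labels to [call_table()] objects
#'   or CSV paths readable by [read_call_table()]. Paths are checked before
#'   any computation starts.
#' @param trials Optional trial table (data frame or CSV path) for the
#'   cued-number accuracy model.
#' @param n_iter Monte-Carlo iterations for both null models.
#' @param seed Base integer seed; per-stage seeds are derived from it and
#'   echoed in the report.
#' @param include_singles_variants Fit both with and without singleton
#'   sequences (default `TRUE`).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(tables, trials = NULL, n_iter = 1000L, seed = 1L,
                            include_singles_variants = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            !is.null(names(tables)), all(nzchar(names(tables))))
  for (nm in names(tables)) {
    t <- tables[[nm]]
    if (is.character(t) && !file.exists(t)) {
      stop_menzerath("io_error",
        sprintf("input for context '%s' not found: %s", nm, t))
    }
    if (!is.character(t) && !inherits(t, "call_table")) {
      stop_menzerath("format_error",
        sprintf("input for context '%s' is neither a path nor a call_table", nm))
    }
  }
  if (is.character(trials) && !file.exists(trials)) {
    stop_menzerath("io_error", sprintf("trial table not found: %s", trials))
  }
  structure(list(tables = tables, trials = trials,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 include_singles_variants = include_singles_variants),
            class = "analysis_config")
}

#' Run the full Menzerath analysis
#'
#' For every context: the mixed-model fit (with and, optionally, without
#' singleton sequences), both Monte-Carlo null distributions, the first/last
#' correlations, and the final-lengthening test; then all pairwise group
#' interaction fits; and, if a trial table is supplied, the cued-number
#' accuracy model. Stage failures are recorded in the report (with the error
#' message) and independent stages continue. The run is deterministic given
#' the configured seed.
#'
#' @param config An [analysis_config()].
#' @return An object of class `analysis_report`; serialize it with
#'   [write_report()].
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  tables <- lapply(config$tables, function(t) {
    if (is.character(t)) read_call_table(t) else t
  })
  stage <- function(expr) {
    tryCatch(list(ok = TRUE, value = suppressWarnings(expr)),
             error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  }
  contexts <- list()
  for (i in seq_along(tables)) {
    ctx <- names(tables)[i]
    tab <- tables[[i]]
    ctx_seed <- config$seed + 1000L * i
    res <- list(
      summary = stage(summary(tab)),
      fit_all = stage(fit_menzerath(tab, include_singles = TRUE)),
      null_shuffle = stage(shuffle_null(tab, n_iter = config$n_iter,
                                        seed = ctx_seed)),
      null_production = stage(production_constraint_null(
        tab, n_iter = config$n_iter, seed = ctx_seed + 1L)),
      boundary = stage(first_last_correlation(tab)),
      final_lengthening = stage(final_lengthening_test(tab))
    )
    if (config$include_singles_variants) {
      res$fit_no_singles <- stage(fit_menzerath(tab, include_singles = FALSE))
    }
    res$seed <- ctx_seed
    contexts[[ctx]] <- res
  }
  interactions <- list()
  if (length(tables) >= 2L) {
    pairs <- utils::combn(names(tables), 2L, simplify = FALSE)
    for (p in pairs) {
      interactions[[paste(p, collapse = "_vs_")]] <- stage(
        fit_group_interaction(tables[[p[1]]], tables[[p[2]]],
                              group_name = "group", labels = p))
    }
  }
  accuracy <- NULL
  if (!is.null(config$trials)) {
    trials <- if (is.character(config$trials)) {
      read_trial_table(config$trials)
    } else config$trials
    accuracy <- stage(fit_accuracy_model(trials))
  }
  out <- list(
    contexts = contexts,
    interactions = interactions,
    accuracy = accuracy,
    provenance = list(
      package = "menzerath",
      version = as.character(utils::packageVersion("menzerath")),
      seed = config$seed,
      n_iter = config$n_iter
    )
  )
  class(out) <- "analysis_report"
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Menzerath analysis report (seed", x$provenance$seed, ")\n")
  for (ctx in names(x$contexts)) {
    cat("==", ctx, "==\n")
    f <- x$contexts[[ctx]]$fit_all
    if (f$ok) print(f$value) else cat("  fit FAILED:", f$error, "\n")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Model objects are reduced to their coefficient tables, variance
#' components, and diagnostics; no timestamps are written, so identical
#' configurations and seeds produce byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  payload <- report_payload(report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

report_payload <- function(report) {
  strip <- function(x) {
    if (is.list(x) && !is.null(x$ok)) {
      if (!x$ok) return(list(ok = FALSE, error = x$error))
      return(list(ok = TRUE, value = strip(x$value)))
    }
    if (inherits(x, "menzerath_fit")) {
      return(list(coefficients = x$coefficients, varcomp = x$varcomp,
                  n_obs = x$n_obs, n_sequences = x$n_sequences,
                  n_individuals = x$n_individuals, reml = x$reml,
                  df_method = x$df_method, converged = x$converged,
                  singular = x$singular,
                  interactions = x$interactions))
    }
    if (inherits(x, "null_distribution")) {
      return(list(model = x$model, n_iter = x$n_iter, seed = x$seed,
                  observed_size = x$observed_size,
                  observed_position = x$observed_position,
                  empirical_p_size = x$empirical_p_size,
                  empirical_p_position = x$empirical_p_position,
                  slopes_size = x$slopes_size,
                  slopes_position = x$slopes_position,
                  pseudo_check = x$pseudo_check))
    }
    if (inherits(x, "summary.call_table")) {
      return(list(n_calls = x$n_calls, n_sequences = x$n_sequences,
                  n_individuals = x$n_individuals,
                  per_individual = x$per_individual))
    }
    if (inherits(x, c("boundary_correlation", "final_lengthening"))) {
      return(unclass(x))
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}
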
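# Tiny polynomial rolling hash of a deparsed object, used to stamp report
# artifacts with the configuration they were produced under. Arithmetic
# stays below 2^53 so plain doubles are exact.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full affiliation analysis
#'
#' Orchestrates the end-to-end pipeline: validation, orphan-status
#' assignment, sampling summary, dyad-table assembly for each of the four
#' stratum/activity combinations, interaction-rate and rank-test
#' descriptives, the collinearity screen, and the four hierarchical NB model
#' fits with convergence assessment. Descriptives are always computed before
#' fitting, and a fit refuses to start when its covariates fail the
#' collinearity screen. If any model fails to converge (some Rhat >= 1.1) a
#' warning is raised and the partial results are still returned.
#'
#' @param registry,follows,interactions Validated input tables (see
#'   [read_registry()], [read_follows()], [read_interactions()]).
#' @param window A [study_window()].
#' @param config An [mcmc_config()] applied to every model.
#' @param outdir Optional directory; when given, the report tables are also
#'   written there as CSV files stamped with the config hash and seed.
#' @return A list of class `study_report`: `status`, `sampling`, `dyads`
#'   (named list of the four dyad tables), `rates`, `kw_tests`, `screens`,
#'   `fits`, `coefficients` (Table-1-style tidy summary over all models),
#'   `convergence`, `config`, `config_hash`.
#' @export
run_study <- function(registry, follows, interactions, window,
                      config = mcmc_config(), outdir = NULL) {
  registry <- validate_registry(registry)
  follows <- validate_follows(follows)
  interactions <- validate_interactions(interactions, follows)
  status <- orphan_status(registry, unique(follows$focal_id), window$end,
                          follows = follows)
  sampling <- sampling_summary(follows, status)
  kw <- kw_partner_tests(follows, interactions, registry, window, status)

  dyads <- list()
  for (stratum in STRATA) {
    for (act in ACTIVITIES) {
      dyads[[paste(stratum, act, sep = "_")]] <-
        build_dyad_table(follows, interactions, registry, act, stratum,
                         window, status = status)
    }
  }
  rates <- interaction_rates(dplyr::bind_rows(dyads))

  screens <- lapply(dyads, function(dy) {
    if (nrow(dy) == 0L) return(NULL)
    collinearity_screen(dyad_model_matrix(dy))
  })

  fits <- list()
  coefs <- list()
  for (m in names(dyads)) {
    if (nrow(dyads[[m]]) == 0L) next
    cfg <- config
    cfg$seed <- config$seed + match(m, names(dyads))
    fits[[m]] <- fit_affiliation_model(dyads[[m]], cfg)
    td <- tidy(fits[[m]])
    td$model <- m
    coefs[[m]] <- td
  }
  coefficients <- dplyr::relocate(dplyr::bind_rows(coefs), "model")
  convergence <- dplyr::bind_rows(lapply(fits, glance))
  if (nrow(convergence) > 0 && !all(convergence$converged)) {
    warn(paste0("model(s) failed Rhat < 1.1: ",
                paste(convergence$stratum[!convergence$converged],
                      convergence$activity[!convergence$converged],
                      sep = "/", collapse = ", ")))
  }

  report <- structure(
    list(status = status, sampling = sampling, dyads = dyads, rates = rates,
         kw_tests = kw, screens = screens, fits = fits,
         coefficients = coefficients, convergence = convergence,
         config = config, config_hash = config_hash(config)),
    class = "study_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Affiliation study report (config ", x$config_hash,
      ", seed ", x$config$seed, ")\n", sep = "")
  cat("\nSampling effort:\n")
  print(as.data.frame(x$sampling), digits = 4, row.names = FALSE)
  cat("\nKruskal-Wallis comparisons (orphan vs non-orphan):\n")
  print(as.data.frame(x$kw_tests), digits = 4, row.names = FALSE)
  cat("\nPosterior coefficient estimates:\n")
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  cat("\nConvergence:\n")
  print(as.data.frame(x$convergence), digits = 4, row.names = FALSE)
  invisible(x)
}

# Write the report tables as CSVs stamped with config hash and seed.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("# config ", report$config_hash, " seed ",
                  report$config$seed)
  emit <- function(df, name) {
    path <- file.path(outdir, paste0(name, ".csv"))
    writeLines(stamp, path)
    suppressWarnings(
      utils::write.table(df, path, append = TRUE, sep = ",",
                         row.names = FALSE, qmethod = "double")
    )
  }
  emit(report$coefficients, "coefficients")
  emit(report$rates, "interaction_rates")
  emit(report$kw_tests, "kw_tests")
  emit(report$sampling, "sampling_summary")
  emit(report$convergence, "convergence")
  invisible(outdir)
}
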
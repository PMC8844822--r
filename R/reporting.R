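#' Validated run configurations and machine-readable reports
#'
#' The reporting layer wires the simulation, accounting and fitting stages
#' into reproducible runs. A run configuration is a plain named list,
#' validated against the keys its command understands (unknown keys are
#' rejected); every run returns a `run_report` that embeds the package
#' version, the full config (seed included), per-stage results, warnings and
#' elapsed time, so the report alone suffices to reproduce the run.
#'
#' @param config a named list; see Details for the keys of each command.
#' @param command one of `"simulate"`, `"account"`, `"fit"`, `"recover"`.
#'
#' @details Keys by command — common: `seed` (int), `out_dir` (optional).
#' `simulate`: `kind` ("rates", "inhibition" or "time_course"), `truth`
#' (parameter record, see [params_to_record()]), `S`, `I`, `cv`,
#' `replicates`, and for time courses `S0`, `fractions`, `free_base_uM`,
#' `protein_conc_ug_ml`, `duration_min`. `account`: `input` (time-course
#' CSV), `max_consumed_fraction`, `r2_min`, `balance_tolerance`. `fit`:
#' `input` (rate CSV), `analysis` ("model" | "select" | "ic50" |
#' "inhibition" | "compete"), `model`, `censor_threshold`. `recover`:
#' `truth`, `n_sims`, `cv`, `S`, `I`, `fit_model`.
#' @return `validate_config()` the config, invisibly, or an error.
#' @export
validate_config <- function(config, command) {
  allowed <- list(
    simulate = c("kind", "truth", "S", "I", "cv", "replicates", "S0",
                 "fractions", "free_base_uM", "protein_conc_ug_ml",
                 "duration_min", "n_points", "seed", "out_dir"),
    account = c("input", "max_consumed_fraction", "r2_min",
                "balance_tolerance", "seed", "out_dir"),
    fit = c("input", "analysis", "model", "censor_threshold", "seed",
            "out_dir"),
    recover = c("truth", "n_sims", "cv", "S", "I", "fit_model", "seed",
                "out_dir")
  )[[command]]
  if (is.null(allowed)) stop("unknown command: ", command, call. = FALSE)
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config keys for `", command, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

new_report <- function(command, config, results, warnings, t0) {
  structure(list(
    tool = "nadkin",
    version = as.character(utils::packageVersion("nadkin")),
    command = command,
    config = config,
    results = results,
    warnings = warnings,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_report")
}

collect_warnings <- function(expr) {
  warns <- character()
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

#' @rdname validate_config
#' @return the run functions return a `run_report`.
#' @export
run_simulate <- function(config) {
  t0 <- Sys.time()
  validate_config(config, "simulate")
  seed <- config$seed %||% 1L
  res <- collect_warnings({
    if (identical(config$kind, "time_course")) {
      tc <- simulate_time_course(
        params_from_record(config$truth), S0 = config$S0,
        fractions = unlist(config$fractions),
        free_base_uM = if (!is.null(config$free_base_uM)) unlist(config$free_base_uM),
        protein_conc_ug_ml = config$protein_conc_ug_ml %||% 3,
        duration_min = config$duration_min %||% 30,
        n_points = config$n_points %||% 16)
      if (!is.null(config$out_dir)) {
        write_time_course(tc, file.path(config$out_dir, "time_course.csv"))
      }
      list(time_course = tc, truth = config$truth)
    } else {
      cfg <- sim_config(params_from_record(config$truth),
                        S = config$S, I = config$I,
                        cv = config$cv %||% 0.05,
                        replicates = config$replicates %||% 1L, seed = seed)
      d <- if (identical(config$kind, "inhibition")) {
        generate_inhibition_series(cfg)
      } else generate_initial_rates(cfg)
      if (!is.null(config$out_dir)) {
        utils::write.csv(as.data.frame(d),
                         file.path(config$out_dir, "rates.csv"),
                         row.names = FALSE)
      }
      list(data = d, truth = config$truth)
    }
  })
  new_report("simulate", config, res$value, res$warnings, t0)
}

#' @rdname validate_config
#' @export
run_account <- function(config) {
  t0 <- Sys.time()
  validate_config(config, "account")
  res <- collect_warnings({
    tc <- read_time_course(config$input)
    account_time_course(tc,
                        max_consumed_fraction = config$max_consumed_fraction %||% 0.20,
                        r2_min = config$r2_min %||% 0.98,
                        balance_tolerance = config$balance_tolerance %||% 0.05)
  })
  new_report("account", config, res$value, res$warnings, t0)
}

#' @rdname validate_config
#' @export
run_fit <- function(config) {
  t0 <- Sys.time()
  validate_config(config, "fit")
  analysis <- config$analysis %||% "model"
  res <- collect_warnings({
    if (analysis == "ic50") {
      # dose-response series: columns I_uM, activity
      d <- tibble::as_tibble(utils::read.csv(config$input, check.names = FALSE))
      fit_ic50(d)
    } else {
      d <- read_rate_data(config$input)
      switch(analysis,
        model = fit_rate_model(d, config$model %||% "eq1",
                               censor_threshold = config$censor_threshold %||% 8000),
        select = select_substrate_model(d),
        inhibition = fit_mixed_inhibition(d),
        compete = nmn_titration_analysis(d),
        stop("unknown analysis: ", analysis, call. = FALSE))
    }
  })
  new_report("fit", config, res$value, res$warnings, t0)
}

#' @rdname validate_config
#' @export
run_recover <- function(config) {
  t0 <- Sys.time()
  validate_config(config, "recover")
  res <- collect_warnings({
    parameter_recovery(params_from_record(config$truth),
                       n_sims = config$n_sims %||% 100,
                       cv = config$cv %||% 0.05,
                       S = config$S, I = config$I,
                       seed = config$seed %||% 1L,
                       fit_model = config$fit_model %||% config$truth$model)
  })
  new_report("recover", config, res$value, res$warnings, t0)
}

#' Write a run report as JSON
#'
#' Serializes a `run_report` (config, seed, results, warnings, timing) to a
#' JSON file; tibbles become arrays of records, parameter objects become
#' their flat key-value records.
#'
#' @param report a `run_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

report_to_list <- function(x) {
  simplify <- function(v) {
    if (inherits(v, "rate_params")) return(params_to_record(v))
    if (inherits(v, "kin_fit")) {
      return(list(model = v$model, estimates = v$estimates,
                  params = params_to_record(v$params),
                  rss = v$rss, aicc = v$aicc, n_obs = v$n_obs))
    }
    if (inherits(v, "inhibition_fit")) {
      return(list(classification = v$classification, fit = simplify(v$fit),
                  replots = v$replots,
                  replot_nonlinear = as.list(v$replot_nonlinear)))
    }
    if (inherits(v, "competition_analysis")) {
      return(list(verdict = v$verdict, maxima = v$maxima,
                  kia_trend = v$kia_trend, vopt_trend = v$vopt_trend))
    }
    if (inherits(v, "recovery_study")) {
      return(list(summary = v$summary, n_sims = v$n_sims,
                  n_failed = v$n_failed, cv = v$cv, seed = v$seed))
    }
    if (is.list(v) && !is.data.frame(v)) return(lapply(v, simplify))
    v
  }
  out <- unclass(x)
  out$results <- simplify(out$results)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$command, "— nadkin", x$version,
      sprintf("(%.2fs)\n", x$elapsed_sec))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
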
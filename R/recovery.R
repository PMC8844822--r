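#' Parameter-recovery simulation
#'
#' End-to-end check of estimator calibration: generate many noisy datasets
#' from a known truth, refit the generating model to each, and summarize
#' how well each parameter is recovered (median, IQR, median relative bias).
#' Censored estimates are excluded from the summary of the censored
#' parameter (they carry no point value) but counted.
#'
#' @param truth the generating parameter object ([kinetic-params]).
#' @param n_sims number of simulated datasets (default 100).
#' @param cv multiplicative noise level (default 0.05).
#' @param S substrate grid; default 12 log-spaced points, 15-4000 uM.
#' @param I inhibitor grid for eq4/eq5 truths.
#' @param seed master seed; dataset i uses seed + i.
#' @param fit_model model to fit; defaults to the generating model.
#' @return a list of class `recovery_study`: `$estimates` (tibble: `sim`,
#'   `term`, `estimate`, `censored`), `$summary` (tibble per term: `truth`,
#'   `median`, `q25`, `q75`, `median_rel_bias`, `n_censored`, `n_failed`),
#'   `$truth`, `$seed`.
#' @export
parameter_recovery <- function(truth, n_sims = 100, cv = 0.05,
                               S = NULL, I = NULL, seed = 1L,
                               fit_model = model_id_of(truth)) {
  truth_rec <- params_to_record(truth)
  rows <- vector("list", n_sims)
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    s <- (seed + i) %% .Machine$integer.max
    est <- tryCatch({
      if (fit_model == "eq4") {
        cfg <- sim_config(truth, S = 1, I = I, cv = cv, seed = s)
        f <- fit_ic50(generate_inhibition_series(cfg))
      } else {
        cfg <- sim_config(truth, S = S, I = I, cv = cv, seed = s)
        f <- fit_rate_model(generate_initial_rates(cfg), fit_model)
      }
      dplyr::mutate(f$estimates[c("term", "estimate", "censored")], sim = i)
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else rows[[i]] <- est
  }
  estimates <- dplyr::bind_rows(rows)
  if (!nrow(estimates)) stop("all recovery fits failed", call. = FALSE)
  qs <- function(x, p) if (length(x)) stats::quantile(x, p, names = FALSE) else NA_real_
  summary <- dplyr::group_by(estimates, .data$term)
  summary <- dplyr::summarise(
    summary,
    truth = truth_rec[[.data$term[1]]] %||% Inf,
    median = qs(.data$estimate[!.data$censored], 0.5),
    q25 = qs(.data$estimate[!.data$censored], 0.25),
    q75 = qs(.data$estimate[!.data$censored], 0.75),
    n_censored = sum(.data$censored),
    .groups = "drop"
  )
  summary$median_rel_bias <- ifelse(
    is.finite(summary$truth),
    (summary$median - summary$truth) / summary$truth, NA_real_)
  structure(list(estimates = estimates, summary = summary,
                 truth = truth_rec, seed = seed, n_sims = n_sims,
                 n_failed = n_failed, cv = cv),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("<recovery_study>", x$n_sims, "simulations at CV", x$cv,
      "(", x$n_failed, "failed )\n")
  print(x$summary)
  invisible(x)
}
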
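#' Linear trend of a kinetic constant against effector concentration
#'
#' Ordinary least-squares regression of a per-level constant (e.g. the
#' allosteric-site inhibition constant Kia, or a curve maximum) on effector
#' concentration, with the two-sided t-test on the slope. A significantly
#' positive slope in Kia is the signature of competition between the
#' effector and the substrate for the allosteric site.
#'
#' @param effector_uM effector concentrations (uM).
#' @param values the per-level constant.
#' @param alpha significance level for the slope test (default 0.05).
#' @return a one-row tibble: `slope`, `intercept`, `r2`, `p_value`,
#'   `significant_positive`.
#' @export
competition_trend <- function(effector_uM, values, alpha = 0.05) {
  stopifnot(length(effector_uM) == length(values), length(values) >= 3)
  fit <- stats::lm(values ~ effector_uM)
  sm <- summary(fit)
  slope <- stats::coef(fit)[[2]]
  p <- sm$coefficients[2, "Pr(>|t|)"]
  tibble::tibble(slope = slope, intercept = stats::coef(fit)[[1]],
                 r2 = sm$r.squared, p_value = p,
                 significant_positive = slope > 0 && p < alpha)
}

#' Allosteric competition analysis from an effector titration
#'
#' Reproduces the titration analysis used to establish NMN-NAD competition
#' at the allosteric site: each dataset (one per fixed effector level) is
#' fitted on its own to the dual-site substrate-inhibition law; the fitted
#' allosteric constant Kia and the curve maximum (S_opt, V_opt) are
#' extracted per level; Kia and V_opt are then regressed on effector
#' concentration. The verdict is "competitive-allosteric" when the Kia slope
#' is significantly positive (two-sided OLS t-test, p < `alpha`) and the
#' curve maxima increase monotonically with effector; otherwise
#' "non-allosteric".
#'
#' @param datasets a named list of initial-rate data frames (names or the
#'   `effector_uM` argument give the levels), or one data frame with an
#'   `effector_uM` column.
#' @param effector_uM effector level per dataset (uM); taken from list names
#'   when omitted.
#' @param alpha significance level for the slope test.
#' @return an object of class `competition_analysis`: `$levels`, `$fits`
#'   (per-level `kin_fit`s), `$maxima` (tibble: `effector_uM`, `Kia`,
#'   `S_opt`, `V_opt`), `$kia_trend`, `$vopt_trend`, `$verdict`.
#' @export
nmn_titration_analysis <- function(datasets, effector_uM = NULL, alpha = 0.05) {
  if (is.data.frame(datasets)) {
    stopifnot("effector_uM" %in% names(datasets))
    datasets <- split(tibble::as_tibble(datasets), datasets$effector_uM)
    effector_uM <- as.numeric(names(datasets))
  } else if (is.null(effector_uM)) {
    effector_uM <- as.numeric(names(datasets))
  }
  if (length(datasets) < 3) stop("need >= 3 effector levels", call. = FALSE)
  if (anyNA(effector_uM)) stop("effector levels must be numeric", call. = FALSE)

  ord <- order(effector_uM)
  datasets <- datasets[ord]; effector_uM <- effector_uM[ord]

  fits <- lapply(datasets, fit_rate_model, model = "eq3")
  maxima <- purrr::map2_dfr(fits, effector_uM, function(f, e) {
    mx <- tryCatch(curve_maximum(f$params),
                   error = function(err) tibble::tibble(S_opt = NA_real_,
                                                        V_opt = NA_real_))
    tibble::tibble(effector_uM = e, Kia = f$params$Kia,
                   S_opt = mx$S_opt, V_opt = mx$V_opt)
  })
  # levels whose Kia was censored carry no point value for the replot
  ok <- is.finite(maxima$Kia)
  if (sum(ok) < 3) {
    warning("fewer than 3 effector levels with a bounded Kia; ",
            "competition replot not informative", call. = FALSE)
    kia_trend <- tibble::tibble(slope = NA_real_, intercept = NA_real_,
                                r2 = NA_real_, p_value = NA_real_,
                                significant_positive = FALSE)
  } else {
    kia_trend <- competition_trend(maxima$effector_uM[ok], maxima$Kia[ok], alpha)
  }
  vok <- is.finite(maxima$V_opt)
  vopt_trend <- competition_trend(maxima$effector_uM[vok], maxima$V_opt[vok], alpha)
  monotone_maxima <- all(diff(maxima$V_opt[vok]) > 0)
  verdict <- if (kia_trend$significant_positive && monotone_maxima) {
    "competitive-allosteric"
  } else "non-allosteric"
  structure(list(levels = effector_uM, fits = fits, maxima = maxima,
                 kia_trend = kia_trend, vopt_trend = vopt_trend,
                 verdict = verdict),
            class = "competition_analysis")
}

#' @export
print.competition_analysis <- function(x, ...) {
  cat("<competition_analysis>", x$verdict, "\n")
  print(x$maxima)
  cat(sprintf("  Kia ~ effector: slope %.3g (p = %.3g), intercept %.3g\n",
              x$kia_trend$slope, x$kia_trend$p_value, x$kia_trend$intercept))
  invisible(x)
}
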
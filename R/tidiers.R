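#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns the coefficient table, `glance()`
#' a one-row model summary.
#'
#' @param x a `kin_fit`, `inhibition_fit`, `competition_analysis` or
#'   `recovery_study` object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy kin_fit
#' @export
tidy.kin_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, model = x$model, .before = 1)
}

#' @rdname tidiers
#' @method glance kin_fit
#' @export
glance.kin_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, aicc = x$aicc,
                 n_obs = x$n_obs, converged = x$converged)
}

#' @rdname tidiers
#' @method tidy inhibition_fit
#' @export
tidy.inhibition_fit <- function(x, ...) tidy.kin_fit(x$fit, ...)

#' @rdname tidiers
#' @method glance inhibition_fit
#' @export
glance.inhibition_fit <- function(x, ...) {
  dplyr::mutate(glance.kin_fit(x$fit),
                classification = x$classification,
                replot_slope_nonlinear = x$replot_nonlinear[["slope"]],
                replot_intercept_nonlinear = x$replot_nonlinear[["intercept"]])
}

#' @rdname tidiers
#' @method tidy competition_analysis
#' @export
tidy.competition_analysis <- function(x, ...) x$maxima

#' @rdname tidiers
#' @method glance competition_analysis
#' @export
glance.competition_analysis <- function(x, ...) {
  tibble::tibble(verdict = x$verdict,
                 kia_slope = x$kia_trend$slope,
                 kia_intercept = x$kia_trend$intercept,
                 kia_p_value = x$kia_trend$p_value,
                 vopt_slope = x$vopt_trend$slope,
                 n_levels = length(x$levels))
}

#' @rdname tidiers
#' @method tidy recovery_study
#' @export
tidy.recovery_study <- function(x, ...) x$summary

#' @rdname tidiers
#' @method glance recovery_study
#' @export
glance.recovery_study <- function(x, ...) {
  tibble::tibble(n_sims = x$n_sims, n_failed = x$n_failed, cv = x$cv,
                 seed = x$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
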
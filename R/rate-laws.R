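#' Rate laws for multifunctional NAD(P)ases
#'
#' Closed-form initial-rate laws used for CD38, Aplysia cyclase and SARM1:
#'
#' * `rate_mm()` — hyperbolic Michaelis-Menten kinetics,
#'   v = Vmax S / (Km + S).
#' * `rate_catalytic_inhibition()` — substrate inhibition at the catalytic
#'   (TIR) site, v = Vmax S / (Km + S (1 + S/Kis)).
#' * `rate_dual_inhibition()` — substrate inhibition at both the catalytic
#'   site and the allosteric (ARM) site,
#'   v = Vmax S / ((Km + S (1 + S/Kis)) (1 + S/Kia)).
#' * `fractional_activity()` — one-site inhibitor dose response,
#'   activity fraction = 1 / (1 + I/IC50).
#' * `rate_mixed_inhibition()` — multi-site mixed-type inhibition,
#'   v = Vmax S / (Km (1 + (I/Ki)^n) + S (1 + (I/(a Ki))^n)), valid where
#'   substrate inhibition is negligible; reduces exactly to `rate_mm()` at
#'   I = 0, and at a = 1, n = 1 to the pure-noncompetitive form
#'   Vmax S / ((Km + S)(1 + I/Ki)).
#'
#' All are vectorized over concentrations; `Inf` inhibition constants make
#' the corresponding term exactly 1 (see [kinetic-params]).
#'
#' @param S substrate concentration (uM), >= 0; vectorized.
#' @param I inhibitor concentration (uM), >= 0; vectorized.
#' @param p the matching parameter object ([michaelis_params()],
#'   [catalytic_inhibition_params()], [dual_inhibition_params()],
#'   [ic50_value()], [mixed_inhibition_params()]).
#' @return rate in mU/mg (or, for `fractional_activity()`, a dimensionless
#'   fraction in (0, 1]).
#' @examples
#' rate_mm(10.4, michaelis_params(Km = 10.4, Vmax = 6649))  # half-Vmax
#' rate_dual_inhibition(300, dual_inhibition_params(30.3, 22.4, Kia = 324))
#' @name rate-laws
NULL

check_nonneg_vec <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  }
  invisible(x)
}

#' @rdname rate-laws
#' @export
rate_mm <- function(S, p) {
  stopifnot(inherits(p, "rate_params"))
  check_nonneg_vec(S, "S")
  p$Vmax * S / (p$Km + S)
}

#' @rdname rate-laws
#' @export
rate_catalytic_inhibition <- function(S, p) {
  stopifnot(inherits(p, "catalytic_inhibition_params") ||
              inherits(p, "dual_inhibition_params"))
  check_nonneg_vec(S, "S")
  p$Vmax * S / (p$Km + S * (1 + S / p$Kis))
}

#' @rdname rate-laws
#' @export
rate_dual_inhibition <- function(S, p) {
  stopifnot(inherits(p, "dual_inhibition_params"))
  check_nonneg_vec(S, "S")
  p$Vmax * S / ((p$Km + S * (1 + S / p$Kis)) * (1 + S / p$Kia))
}

#' @rdname rate-laws
#' @export
fractional_activity <- function(I, p) {
  stopifnot(inherits(p, "ic50_value"))
  check_nonneg_vec(I, "I")
  1 / (1 + I / p$ic50)
}

#' @rdname rate-laws
#' @export
rate_mixed_inhibition <- function(S, I, p) {
  stopifnot(inherits(p, "mixed_inhibition_params"))
  check_nonneg_vec(S, "S"); check_nonneg_vec(I, "I")
  # (I/(a*Ki))^n with a = Inf is exactly 0 for the competitive limit, but
  # 0^n at I = 0 must also be 0 when a = Inf (0/Inf = 0, fine in IEEE).
  p$Vmax * S / (p$Km * (1 + (I / p$Ki)^p$n) + S * (1 + (I / (p$a * p$Ki))^p$n))
}

#' Evaluate a rate law by model id
#'
#' Dispatch helper used by the fitting and simulation layers: evaluates the
#' rate law a parameter object belongs to at given substrate (and, for eq5,
#' inhibitor) concentrations.
#'
#' @inheritParams rate-laws
#' @return rates in mU/mg.
#' @export
eval_rate_law <- function(S, p, I = 0) {
  switch(model_id_of(p),
    eq1 = rate_mm(S, p),
    eq2 = rate_catalytic_inhibition(S, p),
    eq3 = rate_dual_inhibition(S, p),
    eq4 = fractional_activity(I, p),
    eq5 = rate_mixed_inhibition(S, I, p)
  )
}

#' Locate the substrate optimum of a substrate-inhibited rate curve
#'
#' Substrate-inhibited rate laws rise, peak and fall; the peak location and
#' height are the quantities re-plotted against effector concentration in
#' allosteric-competition analysis. For catalytic-site-only inhibition the
#' optimum is closed form, S_opt = sqrt(Km Kis) with
#' V_opt = Vmax / (1 + 2 sqrt(Km/Kis)); with only the allosteric site finite
#' the same form holds with Kia. When both sites are finite the unique
#' interior maximum is located numerically: a 512-point log-spaced grid over
#' 1e-2 to 1e6 uM brackets the peak, then golden-section search on log(S)
#' refines it.
#'
#' @param p a [catalytic_inhibition_params()] or [dual_inhibition_params()]
#'   object with at least one finite inhibition constant.
#' @return a tibble with columns `S_opt` (uM) and `V_opt` (mU/mg).
#' @export
curve_maximum <- function(p) {
  if (inherits(p, "dual_inhibition_params")) {
    finite_is <- is.finite(p$Kis); finite_ia <- is.finite(p$Kia)
    if (!finite_is && !finite_ia) {
      stop("no maximum: hyperbolic curve (both inhibition constants unbounded)",
           call. = FALSE)
    }
    if (finite_is && !finite_ia) {
      S_opt <- sqrt(p$Km * p$Kis)
    } else if (!finite_is && finite_ia) {
      S_opt <- sqrt(p$Km * p$Kia)
    } else {
      S_opt <- numeric_curve_max(function(S) rate_dual_inhibition(S, p))
    }
    return(tibble::tibble(S_opt = S_opt, V_opt = rate_dual_inhibition(S_opt, p)))
  }
  if (inherits(p, "catalytic_inhibition_params")) {
    if (!is.finite(p$Kis)) {
      stop("no maximum: hyperbolic curve (Kis unbounded)", call. = FALSE)
    }
    S_opt <- sqrt(p$Km * p$Kis)
    return(tibble::tibble(S_opt = S_opt,
                          V_opt = p$Vmax / (1 + 2 * sqrt(p$Km / p$Kis))))
  }
  stop("no maximum: hyperbolic curve has no interior optimum", call. = FALSE)
}

# Bracket on a 512-point log grid over [1e-2, 1e6] uM, then golden-section
# (stats::optimize) on log(S) inside the bracketing interval.
numeric_curve_max <- function(f, lower = 1e-2, upper = 1e6, grid_n = 512) {
  lg <- seq(log(lower), log(upper), length.out = grid_n)
  v <- f(exp(lg))
  i <- which.max(v)
  lo <- lg[max(1L, i - 1L)]; hi <- lg[min(grid_n, i + 1L)]
  opt <- stats::optimize(function(x) f(exp(x)), c(lo, hi),
                         maximum = TRUE, tol = 1e-12)
  exp(opt$maximum)
}

#' Turnover number from crude specific activity
#'
#' Converts a mass-specific limiting rate measured on a crude preparation
#' into a per-molecule turnover number:
#' kcat (s^-1) = Vmax (mU/mg = nmol min^-1 mg^-1) x molar mass (kg/mol,
#' i.e. ug/nmol) / (purity x 60000) — equivalently
#' Vmax x molar_mass x 1e-3 / (60 x purity).
#'
#' @param Vmax limiting specific rate of the crude preparation (mU/mg).
#' @param molar_mass enzyme molar mass (kg/mol = kDa / 1000... i.e. kg/mol;
#'   80.4 for full-length human SARM1 with a C-terminal FLAG tag).
#' @param purity_fraction mass fraction of the preparation that is the
#'   enzyme, in (0, 1].
#' @return turnover number kcat in s^-1.
#' @export
kcat_from_specific_activity <- function(Vmax, molar_mass, purity_fraction = 1) {
  check_pos(Vmax, "Vmax"); check_pos(molar_mass, "molar_mass")
  check_pos(purity_fraction, "purity_fraction")
  if (purity_fraction > 1) stop("`purity_fraction` must be <= 1", call. = FALSE)
  Vmax * molar_mass * 1e-3 / (60 * purity_fraction)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat turnover number (s^-1).
#' @param Km Michaelis constant (uM).
#' @return efficiency in M^-1 s^-1, i.e. kcat / (Km x 1e-6).
#' @export
catalytic_efficiency <- function(kcat, Km) {
  check_pos(kcat, "kcat"); check_pos(Km, "Km")
  kcat / (Km * 1e-6)
}

#' Catalytic constants with verified efficiency
#'
#' Bundles kcat, Km-derived efficiency, molar mass and purity into one
#' record, verifying efficiency = kcat / (Km in molar) on construction.
#'
#' @inheritParams kcat_from_specific_activity
#' @param Km Michaelis constant (uM).
#' @return a tibble row: `kcat`, `Km`, `efficiency`, `molar_mass`,
#'   `purity_fraction`.
#' @export
catalytic_constants <- function(Vmax, Km, molar_mass, purity_fraction = 1) {
  kcat <- kcat_from_specific_activity(Vmax, molar_mass, purity_fraction)
  tibble::tibble(kcat = kcat, Km = Km,
                 efficiency = catalytic_efficiency(kcat, Km),
                 molar_mass = molar_mass, purity_fraction = purity_fraction)
}
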
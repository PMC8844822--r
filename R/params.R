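#' Kinetic parameter objects
#'
#' Constructors for the parameter sets of the five rate laws used throughout
#' the package. Units are fixed package-wide: substrate and inhibitor
#' concentrations in uM, rates in mU per mg protein (1 U = 1 umol/min, so
#' mU/mg = nmol/min/mg), turnover numbers in s^-1 and catalytic efficiencies
#' in M^-1 s^-1.
#'
#' Inhibition constants that the data cannot bound (reported as "> 8000 uM"
#' in censored fits) are represented as `Inf`: IEEE arithmetic then makes the
#' corresponding denominator term exactly 1, so the substrate-inhibited laws
#' reduce exactly to their simpler limits.
#'
#' @param Km Michaelis constant (uM), > 0.
#' @param Vmax limiting mass-specific rate (mU/mg), > 0.
#' @param Kis substrate-inhibition constant at the catalytic site (uM);
#'   `Inf` means no catalytic-site inhibition.
#' @param Kia substrate-inhibition constant at the allosteric site (uM);
#'   `Inf` means no allosteric-site inhibition.
#' @param Ki inhibitor dissociation constant (uM), > 0.
#' @param a dimensionless multiplier on `Ki` distinguishing inhibition type
#'   (competitive in the `a = Inf` limit, purely noncompetitive at `a = 1`,
#'   mixed otherwise).
#' @param n dimensionless inhibitor-binding stoichiometry, >= 1.
#' @param ic50 half-inhibitory inhibitor concentration (uM), > 0.
#'
#' @return A classed list carrying the parameters; all constructors validate
#'   their invariants and error on violation.
#' @name kinetic-params
NULL

check_pos <- function(x, name, allow_inf = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (!allow_inf && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

#' @rdname kinetic-params
#' @export
michaelis_params <- function(Km, Vmax) {
  check_pos(Km, "Km"); check_pos(Vmax, "Vmax")
  structure(list(Km = Km, Vmax = Vmax),
            class = c("michaelis_params", "rate_params"))
}

#' @rdname kinetic-params
#' @export
catalytic_inhibition_params <- function(Km, Vmax, Kis = Inf) {
  check_pos(Km, "Km"); check_pos(Vmax, "Vmax")
  check_pos(Kis, "Kis", allow_inf = TRUE)
  structure(list(Km = Km, Vmax = Vmax, Kis = Kis),
            class = c("catalytic_inhibition_params", "rate_params"))
}

#' @rdname kinetic-params
#' @export
dual_inhibition_params <- function(Km, Vmax, Kis = Inf, Kia = Inf) {
  check_pos(Km, "Km"); check_pos(Vmax, "Vmax")
  check_pos(Kis, "Kis", allow_inf = TRUE)
  check_pos(Kia, "Kia", allow_inf = TRUE)
  structure(list(Km = Km, Vmax = Vmax, Kis = Kis, Kia = Kia),
            class = c("dual_inhibition_params", "rate_params"))
}

#' @rdname kinetic-params
#' @export
ic50_value <- function(ic50) {
  check_pos(ic50, "ic50")
  structure(list(ic50 = ic50), class = c("ic50_value", "rate_params"))
}

#' @rdname kinetic-params
#' @export
mixed_inhibition_params <- function(Km, Vmax, Ki, a = 1, n = 1) {
  check_pos(Km, "Km"); check_pos(Vmax, "Vmax"); check_pos(Ki, "Ki")
  check_pos(a, "a", allow_inf = TRUE)
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a single number >= 1", call. = FALSE)
  }
  structure(list(Km = Km, Vmax = Vmax, Ki = Ki, a = a, n = n),
            class = c("mixed_inhibition_params", "rate_params"))
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<", class(x)[1], "> ", sep = "")
  vals <- vapply(x, function(v) format(v, digits = 4), character(1))
  cat(paste(names(x), vals, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# model id ("eq1".."eq5") <-> parameter class mapping used by the fitters
# and the JSON serialization.
model_id_of <- function(p) {
  switch(class(p)[1],
    michaelis_params            = "eq1",
    catalytic_inhibition_params = "eq2",
    dual_inhibition_params      = "eq3",
    ic50_value                  = "eq4",
    mixed_inhibition_params     = "eq5",
    stop("unknown parameter class", call. = FALSE)
  )
}

#' Serialize and restore kinetic parameter sets
#'
#' Parameter sets round-trip through a flat key-value record (JSON): keys
#' `model` ("eq1".."eq5") plus whichever of `Km, Vmax, Kis, Kia, Ki, a, n,
#' ic50` apply. Absent inhibition constants mean unbounded (`Inf`); absent
#' keys irrelevant to the model are dropped.
#'
#' @param p a parameter object from one of the [kinetic-params] constructors.
#' @param x a named list (or the parsed JSON record) with a `model` key.
#' @param path file path for the JSON record.
#' @return `params_to_record()` a named list; `params_from_record()` a
#'   parameter object; `write_params()`/`read_params()` the same via a file.
#' @export
params_to_record <- function(p) {
  rec <- c(list(model = model_id_of(p)), unclass(p))
  rec[vapply(rec, function(v) is.numeric(v) && is.infinite(v), logical(1))] <- NULL
  rec
}

#' @rdname params_to_record
#' @export
params_from_record <- function(x) {
  stopifnot(is.list(x), !is.null(x$model))
  g <- function(key, default = Inf) if (is.null(x[[key]])) default else x[[key]]
  switch(as.character(x$model),
    eq1 = michaelis_params(x$Km, x$Vmax),
    eq2 = catalytic_inhibition_params(x$Km, x$Vmax, g("Kis")),
    eq3 = dual_inhibition_params(x$Km, x$Vmax, g("Kis"), g("Kia")),
    eq4 = ic50_value(x$ic50),
    eq5 = mixed_inhibition_params(x$Km, x$Vmax, x$Ki, g("a", 1), g("n", 1)),
    stop("unknown model id: ", x$model, call. = FALSE)
  )
}

#' @rdname params_to_record
#' @export
write_params <- function(p, path) {
  jsonlite::write_json(params_to_record(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_record
#' @export
read_params <- function(path) {
  params_from_record(jsonlite::read_json(path, simplifyVector = TRUE))
}
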
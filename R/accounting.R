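#' Select the initial-rate window of a progress curve
#'
#' Initial rates are taken over the longest prefix of time points in which
#' (i) cumulative substrate consumption stays at or below a fixed fraction of
#' the starting concentration (default 20%) and (ii) total product
#' accumulation is still nearly linear in time, judged by the R-squared of an
#' ordinary least-squares line through total products vs time. The window
#' always starts at t = 0 and must contain at least 3 points.
#'
#' @param tc a [time_course()].
#' @param max_consumed_fraction maximum fraction of starting substrate that
#'   may be consumed inside the window (default 0.20).
#' @param r2_min minimum R-squared of the total-product-vs-time line
#'   (default 0.98; linear screens accept exact lines and reject curvature).
#' @return an integer vector of row indices (the window), with the fitted
#'   R-squared as attribute `r2`.
#' @export
select_initial_window <- function(tc, max_consumed_fraction = 0.20,
                                  r2_min = 0.98) {
  stopifnot(inherits(tc, "time_course"))
  n <- nrow(tc)
  if (n < 3L) stop("insufficient linear range: need >= 3 time points", call. = FALSE)
  S0 <- attr(tc, "S0")
  consumed <- S0 - tc$substrate_uM
  total_prod <- rowSums(as.data.frame(tc)[product_columns(tc)])
  ok_consumption <- consumed <= max_consumed_fraction * S0 + 1e-12
  best <- NULL; best_r2 <- NA_real_
  for (k in 3:n) {
    if (!all(ok_consumption[1:k])) break
    r2 <- ols_r2(tc$time_min[1:k], total_prod[1:k])
    if (r2 >= r2_min) { best <- seq_len(k); best_r2 <- r2 }
  }
  if (is.null(best)) {
    stop("insufficient linear range: no 3-point prefix satisfies the ",
         "consumption and linearity limits", call. = FALSE)
  }
  structure(best, r2 = best_r2)
}

# R^2 of y ~ x; a perfectly flat response counts as linear (R^2 = 1).
ols_r2 <- function(x, y) {
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) return(1)
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / ssy
}

#' Estimate initial rates from a time-course window
#'
#' Each product's initial rate is the ordinary least-squares slope of its
#' concentration vs time over the window (intercept free); the substrate
#' consumption rate is minus the slope of the substrate series.
#'
#' @param tc a [time_course()].
#' @param window row indices from [select_initial_window()]; default selects
#'   the window with the default screening settings.
#' @return a tibble with one row per series: `series`, `role` (substrate /
#'   hydrolysis / cyclization / base_exchange / released_base) and
#'   `rate_uM_min` (consumption reported as a positive rate).
#' @export
estimate_rates <- function(tc, window = select_initial_window(tc)) {
  stopifnot(inherits(tc, "time_course"))
  t <- tc$time_min[window]
  if (length(unique(t)) < 2L) stop("degenerate window: times are all equal", call. = FALSE)
  slope <- function(y) {
    stats::cov(t, y) / stats::var(t)
  }
  xcols <- exchange_columns(tc)
  series <- c("substrate_uM", "adpr_uM", "cyclic_uM", xcols, "base_uM")
  role <- c("substrate", "hydrolysis", "cyclization",
            rep("base_exchange", length(xcols)), "released_base")
  rate <- vapply(series, function(cl) slope(tc[[cl]][window]), numeric(1))
  rate[1] <- -rate[1]  # consumption rate, positive
  tibble::tibble(series = series, role = role, rate_uM_min = unname(rate))
}

#' Partition total activity into hydrolysis, cyclization and base exchange
#'
#' The multifunctional NAD(P)ases resolve one consumed dinucleotide into one
#' of three products: the free ADP-ribosyl product (hydrolysis), the cyclic
#' product (cyclization), or an exchange dinucleotide per supplied free base
#' (base exchange / transglycosidation). Total activity is the sum of all
#' product formation rates; one unit (U) forms 1 umol/min of overall
#' products, so specific activity in mU/mg is
#' total rate (uM/min = nmol mL^-1 min^-1) / protein (ug/mL) x 1000.
#'
#' @param rates a tibble from [estimate_rates()] (or any tibble with
#'   `series`, `role`, `rate_uM_min`).
#' @param protein_conc_ug_ml protein concentration (ug/mL); taken from the
#'   rates' originating assay.
#' @return a one-row tibble: per-route rates (uM/min), fractions of total,
#'   `total_rate_uM_min`, `specific_activity_mU_mg`, plus a list-column
#'   `per_base` of named base-exchange rates.
#' @export
partition_activities <- function(rates, protein_conc_ug_ml = NA_real_) {
  stopifnot(all(c("series", "role", "rate_uM_min") %in% names(rates)))
  if (any(rates$rate_uM_min[rates$role != "substrate"] < -1e-9)) {
    stop("product rates must be nonnegative", call. = FALSE)
  }
  r <- function(role) sum(pmax(rates$rate_uM_min[rates$role == role], 0))
  hyd <- r("hydrolysis"); cyc <- r("cyclization"); bex <- r("base_exchange")
  total <- hyd + cyc + bex
  if (total <= 0) stop("no activity: total product formation rate is zero", call. = FALSE)
  per_base <- rates$rate_uM_min[rates$role == "base_exchange"]
  names(per_base) <- sub("^x_(.+)_uM$", "\\1", rates$series[rates$role == "base_exchange"])
  tibble::tibble(
    rate_hydrolysis = hyd,
    rate_cyclization = cyc,
    rate_base_exchange_total = bex,
    frac_hydrolysis = hyd / total,
    frac_cyclization = cyc / total,
    frac_base_exchange = bex / total,
    total_rate_uM_min = total,
    specific_activity_mU_mg = total / protein_conc_ug_ml * 1000,
    per_base = list(per_base)
  )
}

#' Check mass balance of a time course
#'
#' At every time point the substrate consumed (S0 - S) should match both the
#' sum of all products formed and the pyridine base released, per the
#' ordered Uni-Bi scheme (one base out, then one ADP-ribosyl product out,
#' per dinucleotide in). The report gives the worst relative discrepancy of
#' each pairing and a pass flag at the configured tolerance.
#'
#' @param tc a [time_course()].
#' @param tolerance maximum tolerated relative discrepancy (default 0.05).
#' @return a one-row tibble: `substrate_consumed_uM`, `products_sum_uM`,
#'   `base_released_uM` (all at the final time), `disc_products` and
#'   `disc_base` (worst relative discrepancies over time points), `pass`.
#' @export
check_mass_balance <- function(tc, tolerance = 0.05) {
  stopifnot(inherits(tc, "time_course"))
  S0 <- attr(tc, "S0")
  consumed <- S0 - tc$substrate_uM
  prod_sum <- rowSums(as.data.frame(tc)[product_columns(tc)])
  base <- tc$base_uM
  rel <- function(a, b) {
    ref <- pmax(abs(a), abs(b))
    d <- abs(a - b) / ifelse(ref > 0, ref, 1)
    max(d)
  }
  disc_p <- rel(consumed, prod_sum)
  disc_b <- rel(consumed, base)
  n <- nrow(tc)
  tibble::tibble(
    substrate_consumed_uM = consumed[n],
    products_sum_uM = prod_sum[n],
    base_released_uM = base[n],
    disc_products = disc_p,
    disc_base = disc_b,
    pass = disc_p <= tolerance && disc_b <= tolerance
  )
}

#' Normalize a profile to its maximum
#'
#' pH and temperature activity profiles are compared across enzymes after
#' dividing each curve by its own maximum, so every curve peaks at 1.
#'
#' @param values numeric vector of rates across conditions; at least one
#'   must be positive.
#' @return `values / max(values)`.
#' @export
normalize_profile <- function(values) {
  check_nonneg_vec(values, "values")
  m <- max(values)
  if (m <= 0) stop("cannot normalize an all-zero profile", call. = FALSE)
  values / m
}

#' Protein amount by inverse prediction from an immunoblot standard curve
#'
#' Fits an ordinary least-squares line (free intercept) of band intensity on
#' loaded mass through the standards, then inverse-predicts the sample mass
#' from its intensity. Samples whose intensity falls outside the standards'
#' intensity range are extrapolations and are flagged.
#'
#' @param sample_intensity band intensity of the sample (arbitrary units);
#'   vectorized.
#' @param standards a data frame with columns `intensity` and `mass_ng`
#'   (>= 3 rows).
#' @return a tibble: `intensity`, `mass_ng` (inverse prediction),
#'   `extrapolated` flag.
#' @export
protein_from_standard_curve <- function(sample_intensity, standards) {
  stopifnot(all(c("intensity", "mass_ng") %in% names(standards)))
  if (nrow(standards) < 3L) stop("need >= 3 standards", call. = FALSE)
  fit <- stats::lm(intensity ~ mass_ng, data = standards)
  b <- stats::coef(fit)
  if (b[2] == 0) stop("degenerate standard curve: zero slope", call. = FALSE)
  mass <- (sample_intensity - b[1]) / b[2]
  out_of_range <- sample_intensity < min(standards$intensity) |
    sample_intensity > max(standards$intensity)
  if (any(out_of_range)) {
    warning("sample intensity outside the standard range; value extrapolated",
            call. = FALSE)
  }
  tibble::tibble(intensity = sample_intensity, mass_ng = unname(mass),
                 extrapolated = out_of_range)
}

#' Internal-standard-corrected metabolite level per mg protein
#'
#' Extracted metabolite amounts are corrected for extraction losses using
#' the measured recovery of a spiked internal standard (cAMP), then
#' normalized to the protein mass extracted in parallel:
#' result = (measured / recovery) / protein_mass with
#' recovery = recovered / spiked.
#'
#' @param measured_nmol measured metabolite amount (nmol).
#' @param spiked_nmol internal standard spiked (nmol).
#' @param recovered_nmol internal standard recovered (nmol); must not exceed
#'   `spiked_nmol`.
#' @param protein_mg protein mass extracted in parallel (mg).
#' @param recovery_floor minimum acceptable recovery (default 0.5); lower
#'   recoveries indicate a failed extraction and raise an error.
#' @return metabolite level in nmol per mg protein, with the recovery as
#'   attribute `recovery`.
#' @export
normalize_metabolite <- function(measured_nmol, spiked_nmol, recovered_nmol,
                                 protein_mg, recovery_floor = 0.5) {
  check_pos(measured_nmol, "measured_nmol")
  check_pos(spiked_nmol, "spiked_nmol")
  check_pos(recovered_nmol, "recovered_nmol")
  check_pos(protein_mg, "protein_mg")
  if (recovered_nmol > spiked_nmol) {
    stop("recovered internal standard exceeds the spiked amount", call. = FALSE)
  }
  recovery <- recovered_nmol / spiked_nmol
  if (recovery < recovery_floor) {
    stop(sprintf("extraction failure: recovery %.2f below floor %.2f",
                 recovery, recovery_floor), call. = FALSE)
  }
  structure(measured_nmol / recovery / protein_mg, recovery = recovery)
}

#' Full accounting of a time course
#'
#' Convenience pipeline: initial window, per-series rates, activity
#' partition and mass balance in one call.
#'
#' @inheritParams select_initial_window
#' @param balance_tolerance tolerance for [check_mass_balance()].
#' @return a list with elements `window`, `rates`, `partition`, `balance`.
#' @export
account_time_course <- function(tc, max_consumed_fraction = 0.20,
                                r2_min = 0.98, balance_tolerance = 0.05) {
  w <- select_initial_window(tc, max_consumed_fraction, r2_min)
  rates <- estimate_rates(tc, w)
  list(window = w,
       rates = rates,
       partition = partition_activities(rates, attr(tc, "protein_conc_ug_ml")),
       balance = check_mass_balance(tc, balance_tolerance))
}
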
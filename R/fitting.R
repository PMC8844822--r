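#' Fit a rate law to an initial-rate dataset
#'
#' Nonlinear least squares on untransformed rates (Levenberg-Marquardt via
#' minpack.lm, box-constrained to positive parameters) with a deterministic
#' multistart: starting values follow the curve shape (Vmax from the maximum
#' observed rate, doubled for substrate-inhibited models; Km from the
#' substrate giving half the maximum rate; inhibition constants from the
#' largest tested substrate; Ki from the median inhibitor level; a and n
#' from 1) and the fit is repeated over a 0.3x / 1x / 3x grid on Km and the
#' inhibition constants, the lowest residual sum of squares winning (ties to
#' the first start in order).
#'
#' Inhibition constants the data cannot bound are censored: an estimate
#' above 8000 uM is reported as "> 8000" (flagged, standard error dropped)
#' and treated as unbounded in the returned parameter object. The
#' stoichiometry n is constrained to [1, 6]; estimates pinned at a bound are
#' flagged.
#'
#' @param data a data frame with columns `S_uM`, `rate_mU_mg` and, for eq5,
#'   `I_uM`; replicate rows are fitted as independent points.
#' @param model one of `"eq1"` (hyperbolic), `"eq2"` (catalytic-site
#'   substrate inhibition), `"eq3"` (dual-site substrate inhibition),
#'   `"eq5"` (multi-site mixed inhibition).
#' @param censor_threshold inhibition-constant censoring bound (uM).
#' @param multistart multipliers applied to the Km / inhibition-constant
#'   starting values.
#' @return an object of class `kin_fit`: model id, the fitted parameter
#'   object, a coefficient tibble (`term`, `estimate`, `std.error`,
#'   `censored`, `pinned`), `rss`, `aicc`, `n_obs`, `converged`. Supports
#'   [generics::tidy()], [generics::glance()], `predict()` and
#'   [ggplot2::autoplot()].
#' @export
fit_rate_model <- function(data, model = c("eq1", "eq2", "eq3", "eq5"),
                           censor_threshold = 8000,
                           multistart = c(0.3, 1, 3)) {
  model <- match.arg(model)
  data <- tibble::as_tibble(data)
  stopifnot(all(c("S_uM", "rate_mU_mg") %in% names(data)))
  if (any(data$S_uM <= 0)) stop("all substrate concentrations must be > 0", call. = FALSE)
  if (model == "eq5" && !"I_uM" %in% names(data)) {
    stop("eq5 requires an `I_uM` column", call. = FALSE)
  }
  free <- model_free_params(model)
  if (nrow(data) < length(free) + 2L) {
    stop("need at least 2 more observations than free parameters", call. = FALSE)
  }

  S <- data$S_uM; y <- data$rate_mU_mg
  I <- if ("I_uM" %in% names(data)) data$I_uM else rep(0, nrow(data))

  st <- base_starts(S, y, I, model)
  lower <- c(Km = 1e-3, Vmax = 1e-9, Kis = 1e-3, Kia = 1e-3,
             Ki = 1e-3, a = 1e-4, n = 1)[free]
  upper <- c(Km = 1e7, Vmax = 1e12, Kis = 1e8, Kia = 1e8,
             Ki = 1e7, a = 1e6, n = 6)[free]

  pred <- model_predictor(model)
  run_variant <- function(free_v, fixed_v) {
    st_v <- st[free_v]
    scaled <- intersect(c("Km", "Kis", "Kia", "Ki"), free_v)
    starts <- multistart_grid(st_v, scaled, multistart, lower, upper)
    best_v <- NULL
    for (s in starts) {
      fit <- try_nls(y, S, I,
                     function(p, S, I) pred(c(p, fixed_v), S, I),
                     s, lower, upper)
      if (!is.null(fit) && (is.null(best_v) || fit$rss < best_v$rss - 1e-12)) {
        best_v <- fit
      }
    }
    if (!is.null(best_v) && length(fixed_v)) {
      best_v$estimates <- dplyr::bind_rows(
        best_v$estimates,
        tibble::tibble(term = names(fixed_v), estimate = unname(fixed_v),
                       std.error = NA_real_))
      best_v$estimates <- best_v$estimates[order(match(best_v$estimates$term,
                                                       free)), ]
    }
    best_v
  }

  if (model == "eq3") {
    # The two substrate-inhibition sites are structurally confounded when
    # only one is active (a pure allosteric-site curve coincides exactly
    # with a catalytic-site curve of Kis' = Kia + Km whenever Kis' >= 4 Km),
    # so the general fit is tried alongside both single-site attributions
    # and, on an RSS tie, the reduced attribution wins (allosteric first).
    variants <- list(
      allosteric = run_variant(c("Km", "Vmax", "Kia"), c(Kis = Inf)),
      catalytic  = run_variant(c("Km", "Vmax", "Kis"), c(Kia = Inf)),
      general    = run_variant(free, NULL)
    )
    variants <- variants[!vapply(variants, is.null, logical(1))]
    if (!length(variants)) {
      stop("non-convergence: no multistart fit of eq3 converged", call. = FALSE)
    }
    rss <- vapply(variants, `[[`, numeric(1), "rss")
    # ridge tie tolerance: relative, with an absolute floor so exact fits
    # (RSS ~ 0) still tie
    tie <- min(rss) * (1 + 1e-3) + 1e-12 * sum(y^2)
    best <- variants[[which(rss <= tie)[1]]]
  } else {
    best <- run_variant(free, NULL)
    if (is.null(best)) {
      stop("non-convergence: no multistart fit of ", model, " converged",
           call. = FALSE)
    }
  }

  est <- best$estimates
  est$censored <- est$term %in% c("Kis", "Kia") & est$estimate > censor_threshold
  est$pinned <- mapply(function(tm, e) {
    isTRUE(abs(e - lower[[tm]]) < 1e-9) || isTRUE(abs(e - upper[[tm]]) < 1e-9)
  }, est$term, est$estimate)
  # competitive limit of eq5: a pinned at its upper bound
  if ("a" %in% est$term) {
    est$censored <- est$censored |
      (est$term == "a" & est$estimate >= 0.99 * upper[["a"]])
  }
  est$std.error[est$censored] <- NA_real_

  coefs <- stats::setNames(est$estimate, est$term)
  coefs[est$term %in% c("Kis", "Kia", "a") & est$censored] <- Inf
  params <- params_from_coefs(model, coefs)

  n <- length(y); k <- length(free) + 1L
  aicc <- n * log(best$rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
  structure(list(model = model, params = params, estimates = est,
                 rss = best$rss, aicc = aicc, n_obs = n,
                 converged = TRUE, data = data,
                 censor_threshold = censor_threshold),
            class = "kin_fit")
}

model_free_params <- function(model) {
  switch(model,
    eq1 = c("Km", "Vmax"),
    eq2 = c("Km", "Vmax", "Kis"),
    eq3 = c("Km", "Vmax", "Kis", "Kia"),
    eq5 = c("Km", "Vmax", "Ki", "a", "n"),
    stop("unknown model: ", model, call. = FALSE)
  )
}

model_predictor <- function(model) {
  switch(model,
    eq1 = function(p, S, I) p[["Vmax"]] * S / (p[["Km"]] + S),
    eq2 = function(p, S, I) p[["Vmax"]] * S / (p[["Km"]] + S * (1 + S / p[["Kis"]])),
    eq3 = function(p, S, I) p[["Vmax"]] * S /
      ((p[["Km"]] + S * (1 + S / p[["Kis"]])) * (1 + S / p[["Kia"]])),
    eq5 = function(p, S, I) p[["Vmax"]] * S /
      (p[["Km"]] * (1 + (I / p[["Ki"]])^p[["n"]]) +
         S * (1 + (I / (p[["a"]] * p[["Ki"]]))^p[["n"]]))
  )
}

params_from_coefs <- function(model, cf) {
  switch(model,
    eq1 = michaelis_params(cf[["Km"]], cf[["Vmax"]]),
    eq2 = catalytic_inhibition_params(cf[["Km"]], cf[["Vmax"]], cf[["Kis"]]),
    eq3 = dual_inhibition_params(cf[["Km"]], cf[["Vmax"]], cf[["Kis"]], cf[["Kia"]]),
    eq5 = mixed_inhibition_params(cf[["Km"]], cf[["Vmax"]], cf[["Ki"]],
                                  cf[["a"]], cf[["n"]])
  )
}

base_starts <- function(S, y, I, model) {
  base_rows <- I == 0
  yy <- if (any(base_rows)) y[base_rows] else y
  SS <- if (any(base_rows)) S[base_rows] else S
  vmax0 <- max(yy) * if (model %in% c("eq2", "eq3")) 2 else 1
  km0 <- SS[which.min(abs(yy - max(yy) / 2))]
  st <- c(Km = max(km0, 1e-2), Vmax = max(vmax0, 1e-6))
  if (model %in% c("eq2", "eq3")) st[["Kis"]] <- max(S)
  if (model == "eq3") st[["Kia"]] <- max(S)
  if (model == "eq5") {
    Ipos <- I[I > 0]
    st[["Ki"]] <- if (length(Ipos)) stats::median(Ipos) else 1
    st[["a"]] <- 1; st[["n"]] <- 1
  }
  st
}

multistart_grid <- function(st, scaled, mult, lower, upper) {
  if (!length(scaled)) return(list(st))
  grids <- rep(list(mult), length(scaled))
  names(grids) <- scaled
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    s <- st
    for (nm in scaled) {
      s[[nm]] <- min(max(s[[nm]] * combos[i, nm], lower[[nm]] * 1.01),
                     upper[[nm]] * 0.99)
    }
    s
  })
}

try_nls <- function(y, S, I, pred, start, lower, upper) {
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) y - pred(p, S, I),
      lower = lower[names(start)], upper = upper[names(start)],
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(res) || res$info %in% c(0, 5, 9)) return(NULL)
  se <- tryCatch(summary(res)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(start)))
  list(
    estimates = tibble::tibble(term = names(start),
                               estimate = unname(res$par),
                               std.error = unname(se)),
    rss = res$deviance
  )
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("<kin_fit> model", x$model, "on", x$n_obs, "points; RSS =",
      format(x$rss, digits = 5), "AICc =", format(x$aicc, digits = 5), "\n")
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-5s %s%s\n", est$term[i],
                if (est$censored[i]) paste0("> ", format(x$censor_threshold))
                else format(est$estimate[i], digits = 5),
                if (!est$censored[i] && is.finite(est$std.error[i]))
                  paste0(" ± ", format(est$std.error[i], digits = 3)) else ""))
  }
  invisible(x)
}

#' @export
predict.kin_fit <- function(object, newdata = object$data, ...) {
  I <- if ("I_uM" %in% names(newdata)) newdata$I_uM else 0
  eval_rate_law(newdata$S_uM, object$params, I = I)
}

#' Choose among the substrate-kinetics models by AICc
#'
#' Fits the hyperbolic, catalytic-site-inhibited and dual-site-inhibited
#' rate laws to the same dataset and selects by corrected Akaike information
#' criterion, preferring the simpler model whenever its AICc comes within 2
#' of the minimum.
#'
#' @inheritParams fit_rate_model
#' @param models candidate models in increasing complexity order.
#' @return the winning `kin_fit`, with the per-model AICc table in
#'   `$selection` and the chosen id in `$model`.
#' @export
select_substrate_model <- function(data, models = c("eq1", "eq2", "eq3"),
                                   censor_threshold = 8000) {
  if (max(data$S_uM) / min(data$S_uM) < 30) {
    stop("substrate range must span at least 30-fold for model selection",
         call. = FALSE)
  }
  fits <- lapply(models, function(m) fit_rate_model(data, m, censor_threshold))
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  chosen <- which(aicc <= min(aicc) + 2)[1]  # simplest within 2 of the best
  out <- fits[[chosen]]
  out$selection <- tibble::tibble(model = models, aicc = aicc,
                                  delta_aicc = aicc - min(aicc),
                                  chosen = seq_along(models) == chosen)
  out
}

#' Double-reciprocal (Lineweaver-Burk) diagnostics
#'
#' Transforms an initial-rate dataset to (1/S, 1/rate), grouped by inhibitor
#' level, and fits an ordinary least-squares line per group. Used as a
#' diagnostic only — never for estimation. Substrate inhibition shows as
#' upward curvature at high S (small 1/S); a group is flagged nonlinear when
#' adding a quadratic term in 1/S improves the fit (partial F-test,
#' p < 0.05).
#'
#' @param data data frame with `S_uM`, `rate_mU_mg`, optional `I_uM`; all
#'   rates must be positive.
#' @return a list with `points` (tibble: `I_uM`, `inv_S`, `inv_rate`) and
#'   `lines` (tibble per inhibitor level: `slope`, `intercept`, `r2`,
#'   `nonlinear`).
#' @export
double_reciprocal <- function(data) {
  data <- tibble::as_tibble(data)
  if (any(data$rate_mU_mg <= 0)) stop("zero rates cannot be reciprocal-transformed", call. = FALSE)
  if (!"I_uM" %in% names(data)) data$I_uM <- 0
  pts <- dplyr::transmute(data, I_uM = .data$I_uM,
                          inv_S = 1 / .data$S_uM,
                          inv_rate = 1 / .data$rate_mU_mg)
  lines <- dplyr::group_modify(dplyr::group_by(pts, .data$I_uM), function(g, key) {
    lin <- stats::lm(inv_rate ~ inv_S, data = g)
    nonlin <- FALSE
    if (nrow(g) >= 4) {
      # substrate inhibition adds an S/(Vmax Kis) term to 1/v, i.e. a
      # 1/(1/S) term on the reciprocal plot: test whether it improves on
      # the straight line
      aug <- stats::lm(inv_rate ~ inv_S + I(1 / inv_S), data = g)
      pv <- stats::anova(lin, aug)[["Pr(>F)"]][2]
      nonlin <- is.finite(pv) && pv < 0.05
    }
    tibble::tibble(slope = stats::coef(lin)[[2]],
                   intercept = stats::coef(lin)[[1]],
                   r2 = ols_r2(g$inv_S, g$inv_rate),
                   nonlinear = nonlin)
  })
  list(points = pts, lines = dplyr::ungroup(lines))
}

#' Fit a one-site IC50 dose-response curve
#'
#' Fits fractional activity = 1 / (1 + I/IC50) by nonlinear least squares.
#' The series must include the uninhibited control (I = 0); activities are
#' normalized to the mean control value before fitting (a no-op when already
#' normalized). A series that does not decrease overall triggers a warning;
#' an IC50 escaping to the search bound is reported as a failure.
#'
#' @param data data frame with columns `I_uM` and `activity` (fractional,
#'   control = 1); at least 4 inhibitor levels including 0.
#' @return a `kin_fit`-like object of class `ic50_fit` with the fitted
#'   [ic50_value()] in `$params`.
#' @export
fit_ic50 <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("I_uM", "activity") %in% names(data)))
  if (!any(data$I_uM == 0)) stop("an I = 0 control is required", call. = FALSE)
  if (length(unique(data$I_uM)) < 4) stop("need >= 4 inhibitor levels", call. = FALSE)
  ctrl <- mean(data$activity[data$I_uM == 0])
  if (ctrl <= 0) stop("control activity must be positive", call. = FALSE)
  y <- data$activity / ctrl
  I <- data$I_uM
  ct <- suppressWarnings(stats::cor(I, y))
  if (is.na(ct) || ct > 0) {
    warning("activities do not decrease with inhibitor; IC50 ill-defined",
            call. = FALSE)
  }
  Ipos <- I[I > 0]
  start <- c(ic50 = max(stats::median(Ipos), 1e-3))
  upper <- c(ic50 = 1e6)
  fit <- try_nls(y, S = I, I = I,
                 pred = function(p, S, I) 1 / (1 + I / p[["ic50"]]),
                 start = start, lower = c(ic50 = 1e-6), upper = upper)
  if (is.null(fit)) stop("IC50 fit failed to converge", call. = FALSE)
  est <- fit$estimates
  if (est$estimate >= 0.99 * upper[["ic50"]]) {
    stop("IC50 diverged: no inhibition detectable in the series", call. = FALSE)
  }
  est$censored <- FALSE; est$pinned <- FALSE
  n <- length(y); k <- 2L
  structure(list(model = "eq4", params = ic50_value(est$estimate),
                 estimates = est, rss = fit$rss,
                 aicc = n * log(fit$rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9),
                 n_obs = n, converged = TRUE,
                 data = tibble::tibble(I_uM = I, activity = y)),
            class = c("ic50_fit", "kin_fit"))
}

#' Fit and classify multi-site mixed-type inhibition
#'
#' Fits the mixed-inhibition rate law (Km, Vmax, Ki, multiplier a,
#' stoichiometry n all free) to an initial-rate grid over substrate and
#' inhibitor, classifies the inhibition type from the fitted a —
#' competitive when a is censored at its upper bound, noncompetitive when
#' a is in [0.8, 1.25] with n in [0.9, 1.1], mixed otherwise — and computes
#' the Lineweaver-Burk secondary replots (per-inhibitor-level slope and
#' intercept against inhibitor concentration), flagging each replot
#' nonlinear when a quadratic term improves on the line (partial F-test,
#' p < 0.05); nonlinear replots indicate more than one inhibitor molecule
#' binding (n > 1).
#'
#' @param data data frame with `S_uM`, `I_uM`, `rate_mU_mg`; at least 3
#'   inhibitor levels plus the I = 0 series, substrate restricted to the
#'   range where substrate inhibition is negligible.
#' @return an object of class `inhibition_fit`: the underlying `kin_fit`
#'   (`$fit`), `$classification`, `$replots` (tibble: `I_uM`, `lb_slope`,
#'   `lb_intercept`) and `$replot_nonlinear` (named flags for the slope and
#'   intercept replots).
#' @export
fit_mixed_inhibition <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("S_uM", "I_uM", "rate_mU_mg") %in% names(data)))
  levels_I <- sort(unique(data$I_uM))
  if (!0 %in% levels_I || length(levels_I) < 4) {
    stop("need an I = 0 series plus >= 3 inhibitor levels", call. = FALSE)
  }
  fit <- fit_rate_model(data, "eq5")
  est <- fit$estimates
  a_hat <- est$estimate[est$term == "a"]
  n_hat <- est$estimate[est$term == "n"]
  a_censored <- est$censored[est$term == "a"]
  classification <- if (a_censored) "competitive"
    else if (a_hat >= 0.8 && a_hat <= 1.25 && n_hat >= 0.9 && n_hat <= 1.1) "noncompetitive"
    else "mixed"

  dr <- double_reciprocal(data)
  replots <- dplyr::rename(dr$lines, lb_slope = "slope", lb_intercept = "intercept")
  nonlin <- c(slope = replot_nonlinear(replots$I_uM, replots$lb_slope),
              intercept = replot_nonlinear(replots$I_uM, replots$lb_intercept))

  structure(list(fit = fit, params = fit$params,
                 classification = classification,
                 replots = replots[c("I_uM", "lb_slope", "lb_intercept")],
                 replot_nonlinear = nonlin),
            class = "inhibition_fit")
}

# Quadratic-vs-linear improvement test on a secondary replot.
replot_nonlinear <- function(I, y) {
  if (length(I) < 4) return(NA)
  lin <- stats::lm(y ~ I)
  quad <- stats::lm(y ~ I + I(I^2))
  pv <- stats::anova(lin, quad)[["Pr(>F)"]][2]
  is.finite(pv) && pv < 0.05
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("<inhibition_fit>", x$classification, "inhibition\n")
  print(x$fit)
  cat("  secondary replots nonlinear: slope =", x$replot_nonlinear[["slope"]],
      ", intercept =", x$replot_nonlinear[["intercept"]], "\n")
  invisible(x)
}
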
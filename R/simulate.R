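#' Simulation configuration
#'
#' Bundles everything a synthetic initial-rate dataset needs: the generating
#' model and its true parameters, the substrate (and optional inhibitor)
#' grids, the multiplicative noise level, replicate count and seed. Defaults
#' mirror the assay design this package targets: 12 log-spaced substrate
#' points from 15 to 4000 uM and, for inhibition series, 8 inhibitor points
#' from 10 to 300 uM.
#'
#' @param params true parameter object ([kinetic-params]).
#' @param S substrate grid (uM) or NULL to build one from `S_n`, `S_min`,
#'   `S_max`, `log_spacing`.
#' @param I inhibitor grid (uM), optional.
#' @param S_n,S_min,S_max,log_spacing substrate grid construction (defaults
#'   12 points, 15-4000 uM, log spaced).
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param replicates technical replicates per grid point.
#' @param seed integer RNG seed recorded in all outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(params, S = NULL, I = NULL,
                       S_n = 12, S_min = 15, S_max = 4000, log_spacing = TRUE,
                       cv = 0.05, replicates = 1, seed = 1L) {
  stopifnot(inherits(params, "rate_params"))
  if (is.null(S)) {
    S <- if (log_spacing) exp(seq(log(S_min), log(S_max), length.out = S_n))
         else seq(S_min, S_max, length.out = S_n)
  }
  if (any(S <= 0)) stop("substrate grid must be positive", call. = FALSE)
  if (!is.null(I)) check_nonneg_vec(I, "I")
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(params = params, S = S, I = I, cv = cv,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "sim_config")
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a noisy initial-rate dataset
#'
#' Evaluates the configured rate law on the substrate (x inhibitor) grid and
#' applies mean-one multiplicative Gaussian noise, rate x (1 + eps) with
#' eps ~ N(0, cv), truncated at zero so rates stay nonnegative. Deterministic
#' given the config seed; the generating truth is embedded as attributes.
#'
#' @param cfg a [sim_config()].
#' @return a tibble (`S_uM`, optional `I_uM`, `replicate`, `rate_mU_mg`)
#'   with attributes `truth` (the parameter record) and `seed`.
#' @export
generate_initial_rates <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- if (is.null(cfg$I)) {
    tidyr::expand_grid(S_uM = cfg$S, replicate = seq_len(cfg$replicates))
  } else {
    tidyr::expand_grid(S_uM = cfg$S, I_uM = cfg$I,
                       replicate = seq_len(cfg$replicates))
  }
  mu <- eval_rate_law(grid$S_uM, cfg$params,
                      I = if (is.null(cfg$I)) 0 else grid$I_uM)
  eps <- with_seed(cfg$seed, stats::rnorm(nrow(grid), 0, cfg$cv))
  out <- dplyr::mutate(grid, rate_mU_mg = pmax(mu * (1 + eps), 0))
  attr(out, "truth") <- params_to_record(cfg$params)
  attr(out, "seed") <- cfg$seed
  out
}

#' Generate inhibition series
#'
#' For a dose-response truth ([ic50_value()]) draws noisy fractional
#' activities on the inhibitor grid (always including the I = 0 control) and
#' normalizes each replicate by its I = 0 value. For a mixed-inhibition
#' truth ([mixed_inhibition_params()]) draws a noisy rate grid over
#' (S, I) as [generate_initial_rates()] does.
#'
#' @param cfg a [sim_config()] whose `params` are eq4 or eq5 truth. For eq4
#'   the substrate grid is ignored (rates at fixed saturating substrate).
#' @return a tibble; eq4: `I_uM`, `replicate`, `activity` (normalized
#'   fractional activity); eq5: as [generate_initial_rates()].
#' @export
generate_inhibition_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  model <- model_id_of(cfg$params)
  if (model == "eq5") return(generate_initial_rates(cfg))
  if (model != "eq4") stop("inhibition series need eq4 or eq5 truth", call. = FALSE)
  I <- cfg$I %||% exp(seq(log(10), log(300), length.out = 8))
  if (!any(I == 0)) I <- c(0, I)
  grid <- tidyr::expand_grid(I_uM = I, replicate = seq_len(cfg$replicates))
  mu <- fractional_activity(grid$I_uM, cfg$params)
  eps <- with_seed(cfg$seed, stats::rnorm(nrow(grid), 0, cfg$cv))
  raw <- pmax(mu * (1 + eps), 0)
  out <- dplyr::mutate(grid, activity = raw)
  out <- dplyr::group_by(out, .data$replicate)
  out <- dplyr::mutate(out, activity = .data$activity /
                         .data$activity[.data$I_uM == 0][1])
  out <- dplyr::ungroup(out)
  attr(out, "truth") <- params_to_record(cfg$params)
  attr(out, "seed") <- cfg$seed
  out
}

#' Simulate a branching Uni-Bi progress curve
#'
#' Integrates substrate depletion dS/dt = -v(S) under a chosen rate law
#' (deSolve's adaptive lsoda) and allocates the cumulative consumption to
#' hydrolysis, cyclization and per-base exchange products by fixed branch
#' fractions — the experimental observation being that product proportions
#' do not depend on substrate concentration. Released base equals total
#' consumption (one pyridine base out per dinucleotide in), so mass balance
#' is exact by construction. Exchange into a free base is capped at the
#' supplied base amount: when a base pool is exhausted its branch fraction
#' is reallocated pro rata to the remaining branches from that point on
#' (event recorded); if no branch remains, consumption stops there.
#'
#' @param params rate-law parameters governing consumption (any of eq1-eq3).
#' @param S0 starting substrate (uM), > 0.
#' @param fractions named numeric: `hydrolysis`, `cyclization`, plus one
#'   entry per exchange base (named by its dinucleotide product, e.g.
#'   `AcPyrAD`); nonnegative, summing to 1. Exchange fractions require the
#'   matching entry in `free_base_uM`.
#' @param free_base_uM named numeric of free base supplied at t = 0 (uM).
#' @param protein_conc_ug_ml protein in the assay (ug/mL); converts the
#'   mass-specific law (mU/mg = nmol/min/mg) to uM/min.
#' @param duration_min assay duration (min).
#' @param n_points number of output time points (including t = 0).
#' @param tolerance conservation tolerance checked at every output point.
#' @return a [time_course()]; attribute `events` lists base exhaustions,
#'   attribute `fractions` echoes the branch configuration.
#' @export
simulate_time_course <- function(params, S0, fractions,
                                 free_base_uM = NULL,
                                 protein_conc_ug_ml = 3,
                                 duration_min = 30, n_points = 16,
                                 tolerance = 1e-6) {
  stopifnot(inherits(params, "rate_params"))
  check_pos(S0, "S0")
  f <- fractions
  if (is.null(names(f)) || any(!nzchar(names(f)))) {
    stop("`fractions` must be fully named", call. = FALSE)
  }
  for (needed in c("hydrolysis", "cyclization")) {
    if (!needed %in% names(f)) f[[needed]] <- 0
  }
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    stop("branch fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  bases <- setdiff(names(f), c("hydrolysis", "cyclization"))
  for (b in bases) {
    if (f[[b]] > 0 && !b %in% names(free_base_uM)) {
      stop(sprintf("exchange fraction for `%s` requires supplied free base", b),
           call. = FALSE)
    }
  }

  # substrate depletion; rate law is mass-specific, convert to uM/min
  v_uM_min <- function(S) {
    eval_rate_law(pmax(S, 0), params) * protein_conc_ug_ml * 1e-3
  }
  times <- seq(0, duration_min, length.out = n_points)
  sol <- deSolve::ode(
    y = c(S = S0), times = times,
    func = function(t, y, parms) list(-v_uM_min(y[["S"]])),
    rtol = 1e-10, atol = 1e-10
  )
  S <- pmax(as.numeric(sol[, "S"]), 0)

  alloc <- allocate_consumption(S0 - S, f, free_base_uM)
  # if allocation is capped (exchange-only scheme, base exhausted),
  # consumption stops: clamp substrate accordingly
  S <- S0 - alloc$consumed

  cols <- list(time_min = times, substrate_uM = S,
               adpr_uM = alloc$products[["hydrolysis"]],
               cyclic_uM = alloc$products[["cyclization"]])
  for (b in bases) cols[[paste0("x_", b, "_uM")]] <- alloc$products[[b]]
  cols$base_uM <- alloc$consumed
  tc <- time_course(tibble::as_tibble(cols),
                    protein_conc_ug_ml = protein_conc_ug_ml, S0 = S0,
                    free_base_supplied = free_base_uM)
  bal <- check_mass_balance(tc, tolerance)
  if (!bal$pass) stop("simulated course violates mass conservation", call. = FALSE)
  attr(tc, "events") <- alloc$events
  attr(tc, "fractions") <- f
  tc
}

# Piecewise-linear allocation of cumulative consumption C to branches with
# per-base caps. Returns per-product series, the (possibly capped) consumed
# series, and exhaustion events.
allocate_consumption <- function(C, fractions, caps) {
  branches <- names(fractions)
  caps <- as.list(caps)
  capped <- vapply(branches, function(b) b %in% names(caps), logical(1))
  cap_of <- function(b) if (capped[[b]]) caps[[b]] else Inf
  # breakpoints in C-space
  f_cur <- fractions
  alloc0 <- stats::setNames(numeric(length(branches)), branches)
  segs <- list()  # each: C_start, alloc at start, fractions in force
  C_done <- 0
  events <- list()
  repeat {
    segs[[length(segs) + 1L]] <- list(C0 = C_done, a0 = alloc0, f = f_cur)
    active_capped <- branches[capped & f_cur > 0]
    if (!length(active_capped)) { C_stop <- Inf; break }
    exhaust_at <- vapply(active_capped, function(b) {
      C_done + (cap_of(b) - alloc0[[b]]) / f_cur[[b]]
    }, numeric(1))
    b_next <- active_capped[which.min(exhaust_at)]
    C_next <- min(exhaust_at)
    if (C_next > max(C)) { C_stop <- Inf; break }
    # advance to the breakpoint
    alloc0 <- alloc0 + f_cur * (C_next - C_done)
    C_done <- C_next
    events[[length(events) + 1L]] <-
      list(base = b_next, consumption_uM = C_next)
    f_cur[[b_next]] <- 0
    tot <- sum(f_cur)
    if (tot <= 0) { C_stop <- C_done; break }
    f_cur <- f_cur / tot
  }
  C_eff <- if (is.finite(C_stop)) pmin(C, C_stop) else C
  products <- lapply(stats::setNames(branches, branches), function(b) {
    out <- numeric(length(C_eff))
    for (i in seq_along(C_eff)) {
      # find segment containing C_eff[i]
      k <- max(which(vapply(segs, function(s) s$C0 <= C_eff[i] + 1e-15,
                            logical(1))))
      s <- segs[[k]]
      out[i] <- s$a0[[b]] + s$f[[b]] * (C_eff[i] - s$C0)
    }
    out
  })
  list(products = products, consumed = C_eff, events = events)
}

#' Write the canonical synthetic fixture suite
#'
#' Generates the package's reference datasets — noisy initial-rate tables
#' for each enzyme/substrate parameter set (CD38, Aplysia cyclase,
#' full-length SARM1 and its SAM-TIR fragment, with NAD and NADP, including
#' the NMN titration series), riboside inhibition grids, a 90:10
#' hydrolysis:cyclization progress curve and a DRG-style metabolite record —
#' as CSV files plus a JSON manifest mapping each file to its generating
#' model, parameters, grids, noise level and seed. Regenerating with the
#' same seed reproduces the files byte for byte.
#'
#' @param dir output directory (created if missing).
#' @param seed master seed; per-file seeds are derived deterministically.
#' @param cv noise level for the rate datasets.
#' @return invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(dir, seed = 20230101L, cv = 0.05) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("destination not writable", call. = FALSE)
  specs <- fixture_specs()
  manifest <- list(master_seed = seed, cv = cv, files = list())
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]; sp <- specs[[i]]
    fseed <- (seed + i * 1009L) %% .Machine$integer.max
    path <- file.path(dir, paste0(nm, ".csv"))
    if (sp$kind == "rates") {
      cfg <- sim_config(sp$params, S = sp$S, I = sp$I, cv = cv,
                        replicates = sp$replicates %||% 1L, seed = fseed)
      d <- generate_initial_rates(cfg)
      utils::write.csv(as.data.frame(d), path, row.names = FALSE)
    } else if (sp$kind == "ic50") {
      cfg <- sim_config(sp$params, S = 1, I = sp$I, cv = cv,
                        replicates = sp$replicates %||% 1L, seed = fseed)
      d <- generate_inhibition_series(cfg)
      utils::write.csv(as.data.frame(d), path, row.names = FALSE)
    } else if (sp$kind == "time_course") {
      tc <- simulate_time_course(sp$params, S0 = sp$S0,
                                 fractions = sp$fractions,
                                 protein_conc_ug_ml = sp$protein,
                                 duration_min = sp$duration)
      write_time_course(tc, path)
    } else if (sp$kind == "metabolite") {
      utils::write.csv(sp$record, path, row.names = FALSE)
    }
    manifest$files[[paste0(nm, ".csv")]] <-
      c(list(kind = sp$kind, seed = fseed),
        if (!is.null(sp$params)) list(truth = params_to_record(sp$params)))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Reference parameter sets for the fixture suite (fitted kinetic constants
# for each enzyme/substrate pair, in uM and mU/mg).
fixture_specs <- function() {
  Sgrid <- exp(seq(log(15), log(4000), length.out = 12))
  Snarrow <- exp(seq(log(15), log(600), length.out = 8))
  Igrid <- exp(seq(log(10), log(300), length.out = 8))
  nmn <- list(
    `5`  = dual_inhibition_params(44.1, 39.7, Kia = 385.1),
    `10` = dual_inhibition_params(34.2, 54.1, Kia = 414.9),
    `20` = dual_inhibition_params(44.6, 88.2, Kia = 787.0),
    `50` = dual_inhibition_params(56.1, 161,  Kia = 1201.7)
  )
  out <- list(
    cd38_nad       = list(kind = "rates", params = michaelis_params(10.4, 6649), S = Sgrid),
    cyclase_nad    = list(kind = "rates", params = michaelis_params(212, 51353), S = Sgrid),
    fl_nad         = list(kind = "rates", params = dual_inhibition_params(30.3, 22.4, Kia = 324), S = Sgrid, replicates = 4L),
    fl_nadp        = list(kind = "rates", params = dual_inhibition_params(66.9, 14.3, Kis = 132), S = Sgrid, replicates = 3L),
    samtir_nad     = list(kind = "rates", params = catalytic_inhibition_params(69.5, 723), S = Sgrid, replicates = 4L),
    samtir_nadp    = list(kind = "rates", params = catalytic_inhibition_params(83.5, 582, Kis = 151), S = Sgrid, replicates = 2L),
    ic50_fl_nar    = list(kind = "ic50", params = ic50_value(87),  I = Igrid),
    ic50_fl_vr     = list(kind = "ic50", params = ic50_value(154), I = Igrid),
    ic50_samtir_nar = list(kind = "ic50", params = ic50_value(36), I = Igrid),
    ic50_samtir_vr = list(kind = "ic50", params = ic50_value(61),  I = Igrid),
    ki_samtir_nar  = list(kind = "rates", params = mixed_inhibition_params(69.5, 723, Ki = 15, a = 0.5, n = 2),
                          S = Snarrow, I = c(0, 25, 50, 80, 120)),
    ki_samtir_vr   = list(kind = "rates", params = mixed_inhibition_params(69.5, 723, Ki = 25.9, a = 0.5, n = 2),
                          S = Snarrow, I = c(0, 25, 50, 80, 120)),
    partition_90_10 = list(kind = "time_course",
                           params = dual_inhibition_params(30.3, 22.4, Kia = 324),
                           S0 = 250, fractions = c(hydrolysis = 0.9, cyclization = 0.1),
                           protein = 3, duration = 30),
    drg_metabolite = list(kind = "metabolite", params = NULL,
                          record = data.frame(analyte = "AcPyrAD",
                                              measured_nmol = 0.4282,
                                              spiked_nmol = 10,
                                              recovered_nmol = 9.6,
                                              protein_mg = 1.0))
  )
  for (lv in names(nmn)) {
    out[[paste0("fl_nad_nmn", lv)]] <-
      list(kind = "rates", params = nmn[[lv]], S = Sgrid)
  }
  out
}
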
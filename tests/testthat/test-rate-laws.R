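test_that("hyperbolic law matches hand-computed values and boundary behaviour", {
  p <- ref_cd38_nad()
  expect_equal(rate_mm(10.4, p), 6649 / 2)          # half-Vmax at S = Km
  expect_equal(rate_mm(250, p), 6649 * 250 / 260.4) # direct arithmetic
  expect_equal(rate_mm(0, p), 0)
  S <- seq(0, 5000, by = 50)
  expect_true(all(diff(rate_mm(S, p)) >= 0))        # monotone nondecreasing
  expect_error(rate_mm(-1, p), "nonnegative")
})

test_that("catalytic-site substrate inhibition matches arithmetic and limits", {
  p <- ref_samtir_nadp()
  expect_equal(rate_catalytic_inhibition(100, p),
               582 * 100 / (83.5 + 100 * (1 + 100 / 151)))
  # unbounded Kis reduces exactly to the hyperbola
  p0 <- catalytic_inhibition_params(83.5, 582, Kis = Inf)
  expect_equal(rate_catalytic_inhibition(83.5, p0), 291.0)
  # dominant S^2/Kis term drives the rate to zero
  expect_lt(rate_catalytic_inhibition(1e9, p), 1e-3)
  expect_error(rate_catalytic_inhibition(-5, p), "nonnegative")
})

test_that("dual-site substrate inhibition matches arithmetic and shows the high-S drop", {
  p <- ref_fl_nad()
  expect_equal(rate_dual_inhibition(300, p),
               22.4 * 300 / ((30.3 + 300) * (1 + 300 / 324)))
  v150 <- rate_dual_inhibition(150, p)
  expect_equal(v150, 22.4 * 150 / ((30.3 + 150) * (1 + 150 / 324)))
  # halving substrate from 300 uM increases the rate (past the optimum)
  expect_gt(v150, rate_dual_inhibition(300, p))
  # both sites unbounded: exact hyperbola, half-Vmax at S = Km
  pu <- dual_inhibition_params(30.3, 22.4)
  expect_equal(rate_dual_inhibition(30.3, pu), 22.4 / 2)
})

test_that("dose-response law is the one-site hyperbolic decay", {
  p <- ic50_value(87)
  expect_equal(fractional_activity(0, p), 1)
  expect_equal(fractional_activity(87, p), 0.5)
  expect_equal(fractional_activity(261, p), 0.25)  # I = 3 x IC50
  I <- seq(0, 1000, by = 10)
  fa <- fractional_activity(I, p)
  expect_true(all(diff(fa) < 0))
  expect_true(all(fa > 0 & fa <= 1))
  expect_error(fractional_activity(-1, p), "nonnegative")
})

test_that("mixed-inhibition law matches arithmetic and its closed-form limits", {
  p <- mixed_inhibition_params(69.5, 723, Ki = 15, a = 0.5, n = 2)
  expect_equal(rate_mixed_inhibition(69.5, 0, p), 723 / 2)  # I = 0, S = Km
  expect_equal(rate_mixed_inhibition(69.5, 15, p), 723 * 69.5 / 486.5)
  # I = 0 reduces exactly to the hyperbola for all S
  S <- default_S_grid()
  mm <- michaelis_params(69.5, 723)
  expect_equal(rate_mixed_inhibition(S, 0, p), rate_mm(S, mm))
  # a = 1, n = 1 equals the pure-noncompetitive closed form; at I = Ki that
  # is exactly half the uninhibited rate
  pn <- mixed_inhibition_params(69.5, 723, Ki = 15, a = 1, n = 1)
  expect_equal(rate_mixed_inhibition(S, 15, pn),
               723 * S / ((69.5 + S) * 2))
  expect_equal(rate_mixed_inhibition(S, 15, pn), rate_mm(S, mm) / 2)
})

test_that("reduction chain eq3 -> eq2 -> eq1 holds at large constants and exactly at Inf", {
  S <- default_S_grid()
  big <- 1e4 * max(S)
  p3 <- dual_inhibition_params(30.3, 22.4, Kis = big, Kia = big)
  p2 <- catalytic_inhibition_params(30.3, 22.4, Kis = big)
  p1 <- michaelis_params(30.3, 22.4)
  expect_lt(max(abs(rate_dual_inhibition(S, p3) -
                      rate_catalytic_inhibition(S, p2)) /
                  rate_catalytic_inhibition(S, p2)), 1e-3)
  expect_lt(max(abs(rate_catalytic_inhibition(S, p2) - rate_mm(S, p1)) /
                  rate_mm(S, p1)), 1e-3)
  # exact with the unbounded flag
  p3i <- dual_inhibition_params(30.3, 22.4)
  expect_identical(rate_dual_inhibition(S, p3i), rate_mm(S, p1))
})

test_that("all rate laws are nonnegative, zero at S = 0 and continuous in parameters", {
  S <- c(0, default_S_grid())
  laws <- list(
    function(s) rate_mm(s, ref_cd38_nad()),
    function(s) rate_catalytic_inhibition(s, ref_samtir_nadp()),
    function(s) rate_dual_inhibition(s, ref_fl_nad()),
    function(s) rate_mixed_inhibition(s, 40, mixed_inhibition_params(69.5, 723, 15, 0.5, 2))
  )
  for (f in laws) {
    v <- f(S)
    expect_true(all(v >= 0))
    expect_equal(v[1], 0)
  }
  # continuity: small parameter perturbation gives small rate change
  base <- rate_dual_inhibition(S, dual_inhibition_params(30.3, 22.4, Kia = 324))
  pert <- rate_dual_inhibition(S, dual_inhibition_params(30.3 * (1 + 1e-8),
                                                         22.4, Kia = 324))
  expect_lt(max(abs(pert - base)), 1e-5)
})

test_that("curve maxima match closed forms, cross-checked numerically", {
  mx2 <- curve_maximum(ref_samtir_nadp())
  expect_equal(mx2$S_opt, sqrt(83.5 * 151), tolerance = 1e-9)
  expect_equal(mx2$V_opt, 582 / (1 + 2 * sqrt(83.5 / 151)), tolerance = 1e-9)
  # dense grid cross-check
  Sg <- exp(seq(log(1), log(1e5), length.out = 2e5))
  vg <- rate_catalytic_inhibition(Sg, ref_samtir_nadp())
  expect_equal(mx2$S_opt, Sg[which.max(vg)], tolerance = 1e-4)
  expect_equal(mx2$V_opt, max(vg), tolerance = 1e-8)

  mx3 <- curve_maximum(ref_fl_nad())  # Kis unbounded: closed form sqrt(Km Kia)
  expect_equal(mx3$S_opt, sqrt(30.3 * 324), tolerance = 1e-9)
  vg3 <- rate_dual_inhibition(Sg, ref_fl_nad())
  expect_equal(mx3$V_opt, max(vg3), tolerance = 1e-8)

  # both sites finite: numeric interior maximum agrees with grid search
  pb <- dual_inhibition_params(30, 100, Kis = 500, Kia = 1500)
  mxb <- curve_maximum(pb)
  vgb <- rate_dual_inhibition(Sg, pb)
  expect_equal(mxb$V_opt, max(vgb), tolerance = 1e-8)
  # numeric search agrees with the closed form in the single-site limits
  pa <- dual_inhibition_params(30, 100, Kis = 1e12, Kia = 1500)
  expect_equal(nadkin:::numeric_curve_max(function(s) rate_dual_inhibition(s, pa)),
               sqrt(30 * 1500), tolerance = 1e-6)
  expect_error(curve_maximum(dual_inhibition_params(30, 100)), "no maximum")
  expect_error(curve_maximum(ref_cd38_nad()), "no maximum")
})

test_that("kcat and efficiency conversions reproduce the steady-state constants", {
  # crude Vmax 22.4 mU/mg, 80.4 kg/mol full-length construct -> kcat 0.030/s
  expect_equal(kcat_from_specific_activity(22.4, 80.4), 0.030, tolerance = 0.02)
  expect_equal(kcat_from_specific_activity(60, 60), 0.060)  # units cancel
  # halving purity doubles kcat
  expect_equal(kcat_from_specific_activity(22.4, 80.4, 0.5),
               2 * kcat_from_specific_activity(22.4, 80.4))
  expect_equal(catalytic_efficiency(1, 1), 1e6)
  expect_equal(catalytic_efficiency(0.030, 30.3), 990, tolerance = 1e-3)
  expect_equal(catalytic_efficiency(0.448, 69.5), 6446, tolerance = 1e-4)
  expect_error(kcat_from_specific_activity(-1, 80), "> 0")
  expect_error(kcat_from_specific_activity(22.4, 80.4, 1.2), "<= 1")
  cc <- catalytic_constants(22.4, 30.3, 80.4)
  expect_equal(cc$efficiency, cc$kcat / (30.3e-6))
})

test_that("parameter records round-trip through JSON with unbounded constants dropped", {
  ps <- list(ref_cd38_nad(), ref_samtir_nadp(), ref_fl_nad(), ic50_value(87),
             mixed_inhibition_params(69.5, 723, 15, 0.5, 2))
  for (p in ps) {
    path <- tempfile(fileext = ".json")
    write_params(p, path)
    q <- read_params(path)
    expect_equal(q, p)
    unlink(path)
  }
  rec <- params_to_record(ref_fl_nad())
  expect_false("Kis" %in% names(rec))  # unbounded key absent
  expect_equal(rec$Kia, 324)
})

test_that("constructors reject invariant violations", {
  expect_error(michaelis_params(-1, 5), "> 0")
  expect_error(michaelis_params(1, 0), "> 0")
  expect_error(mixed_inhibition_params(1, 1, 1, n = 0.5), ">= 1")
  expect_error(ic50_value(0), "> 0")
})
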
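test_that("initial window honours the 20% consumption rule", {
  # 20% of 250 uM = 50 uM: the 150 uM point (100 consumed) must be excluded
  tc <- time_course(tibble::tibble(
    time_min = c(0, 10, 20, 30, 40),
    substrate_uM = c(250, 230, 210, 195, 150),
    adpr_uM = c(0, 20, 40, 55, 100),
    cyclic_uM = 0,
    base_uM = c(0, 20, 40, 55, 100)), protein_conc_ug_ml = 3)
  w <- select_initial_window(tc)
  expect_equal(w, 1:3, ignore_attr = TRUE)  # 195 uM point: 55 consumed > 50
})

test_that("20% threshold excludes points below 80% of starting substrate", {
  tc <- time_course(tibble::tibble(
    time_min = c(0, 10, 20, 30, 40),
    substrate_uM = c(250, 234, 218, 202, 150),
    adpr_uM = c(0, 16, 32, 48, 100),
    cyclic_uM = 0,
    base_uM = c(0, 16, 32, 48, 100)), protein_conc_ug_ml = 3)
  w <- select_initial_window(tc)
  expect_equal(max(w), 4)  # 202 uM is within 20%; 150 uM is not
  # a perfectly linear course consuming 10% overall is retained in full
  lin <- linear_time_course(times = seq(0, 25, by = 5), S0 = 250, rate = 1)
  expect_equal(length(select_initial_window(lin)), 6)
})

test_that("an off-trend final point is dropped by the linearity screen", {
  times <- c(0, 5, 10, 15, 20)
  consumed <- c(0, 10, 20, 30, 34)  # last point clearly off the line
  tc <- time_course(tibble::tibble(
    time_min = times, substrate_uM = 250 - consumed,
    adpr_uM = consumed, cyclic_uM = 0, base_uM = consumed),
    protein_conc_ug_ml = 3)
  r2_full <- nadkin:::ols_r2(times, consumed)
  expect_lt(r2_full, 0.99)  # hand-check: the full series fails the screen
  w <- select_initial_window(tc, r2_min = 0.99)
  expect_equal(max(w), 4)
  expect_error(select_initial_window(tc[1:2, ]), "3 time points")
})

test_that("rates are exact OLS slopes and zero for flat series", {
  tc <- time_course(tibble::tibble(
    time_min = c(0, 10, 20, 30),
    substrate_uM = c(250, 249, 248, 247),
    adpr_uM = 0,
    cyclic_uM = c(0, 1, 2, 3),
    base_uM = c(0, 1, 2, 3)), protein_conc_ug_ml = 3)
  r <- estimate_rates(tc, window = 1:4)
  expect_equal(r$rate_uM_min[r$series == "cyclic_uM"], 0.1)
  expect_equal(r$rate_uM_min[r$series == "adpr_uM"], 0)
  expect_equal(r$rate_uM_min[r$series == "substrate_uM"], 0.1)
})

test_that("partition fractions, totals and specific activity follow the unit definition", {
  rates <- tibble::tibble(
    series = c("substrate_uM", "adpr_uM", "cyclic_uM", "base_uM"),
    role = c("substrate", "hydrolysis", "cyclization", "released_base"),
    rate_uM_min = c(1, 0.9, 0.1, 1))
  p <- partition_activities(rates, protein_conc_ug_ml = 3)
  expect_equal(p$frac_hydrolysis, 0.9)
  expect_equal(p$frac_cyclization, 0.1)
  expect_equal(p$frac_base_exchange, 0)
  expect_equal(p$frac_hydrolysis + p$frac_cyclization + p$frac_base_exchange, 1)

  rates2 <- tibble::tibble(
    series = c("adpr_uM", "cyclic_uM", "x_AcPyrAD_uM"),
    role = c("hydrolysis", "cyclization", "base_exchange"),
    rate_uM_min = c(0.6, 0.05, 0.35))
  p2 <- partition_activities(rates2, 3)
  expect_equal(p2$frac_base_exchange, 0.35)
  expect_equal(names(p2$per_base[[1]]), "AcPyrAD")

  # 0.06 uM/min at 3 ug/mL -> 20 mU/mg
  rates3 <- tibble::tibble(series = "adpr_uM", role = "hydrolysis",
                           rate_uM_min = 0.06)
  expect_equal(partition_activities(rates3, 3)$specific_activity_mU_mg, 20)

  rates0 <- tibble::tibble(series = "adpr_uM", role = "hydrolysis",
                           rate_uM_min = 0)
  expect_error(partition_activities(rates0, 3), "no activity")
})

test_that("mass balance passes balanced courses and quantifies deficits", {
  balanced <- time_course(tibble::tibble(
    time_min = c(0, 10, 20),
    substrate_uM = c(250, 200, 150),
    adpr_uM = c(0, 30, 60), cyclic_uM = c(0, 2.5, 5),
    x_AcPyrAD_uM = c(0, 17.5, 35),
    base_uM = c(0, 50, 100)), protein_conc_ug_ml = 3)
  b <- check_mass_balance(balanced)
  expect_true(b$pass)
  expect_equal(b$disc_products, 0)
  expect_equal(b$disc_base, 0)

  short <- time_course(tibble::tibble(
    time_min = c(0, 10, 20),
    substrate_uM = c(250, 200, 150),
    adpr_uM = c(0, 40, 80), cyclic_uM = 0,
    base_uM = c(0, 50, 100)), protein_conc_ug_ml = 3)
  b2 <- check_mass_balance(short, tolerance = 0.05)
  expect_false(b2$pass)
  expect_equal(b2$disc_products, 0.2)  # products sum to 80 of 100 consumed
})

test_that("profile normalization maps the maximum to 1 and is scale-invariant", {
  expect_equal(normalize_profile(c(2, 5, 10, 4)), c(0.2, 0.5, 1.0, 0.4))
  expect_equal(normalize_profile(7), 1)
  v <- c(0.3, 1.8, 0.9, 2.4)
  expect_equal(normalize_profile(v), normalize_profile(v * 137.5))
  expect_error(normalize_profile(c(0, 0)), "all-zero")
})

test_that("standard-curve inverse prediction recovers masses and flags extrapolation", {
  std <- tibble::tibble(mass_ng = c(5, 10, 20, 40), intensity = 2 * c(5, 10, 20, 40))
  r <- protein_from_standard_curve(50, std)
  expect_equal(r$mass_ng, 25)
  expect_false(r$extrapolated)
  # intercept-free truth fitted with free intercept: intercept ~ 0
  fit <- stats::lm(intensity ~ mass_ng, data = std)
  expect_lt(abs(coef(fit)[1]), 1e-10)
  expect_warning(r2 <- protein_from_standard_curve(100, std), "extrapolated")
  expect_true(r2$extrapolated)
  expect_error(protein_from_standard_curve(50, std[1:2, ]), ">= 3")
})

test_that("metabolite normalization corrects by recovery and guards failures", {
  # 96% recovery of the spiked internal standard
  out <- normalize_metabolite(0.4282, 10, 9.6, 1.0)
  expect_equal(as.numeric(out), 0.446, tolerance = 1e-3)
  expect_equal(attr(out, "recovery"), 0.96)
  expect_equal(as.numeric(normalize_metabolite(0.3, 10, 10, 2)), 0.15)
  expect_error(normalize_metabolite(0.3, 10, 4, 1), "extraction failure")
  expect_error(normalize_metabolite(0.3, 10, 11, 1), "exceeds")
  # homogeneity: degree 1 in measured amount, -1 in protein mass
  base <- as.numeric(normalize_metabolite(0.4, 10, 9.6, 1))
  expect_equal(as.numeric(normalize_metabolite(0.4 * 3, 10, 9.6, 1)), 3 * base)
  expect_equal(as.numeric(normalize_metabolite(0.4, 10, 9.6, 2)), base / 2)
})

test_that("tightening the consumption limit never lengthens the window", {
  tc <- linear_time_course(times = seq(0, 50, by = 5), S0 = 250, rate = 1)
  fr <- seq(0.05, 0.20, by = 0.025)
  lens <- vapply(fr, function(f)
    length(select_initial_window(tc, max_consumed_fraction = f)), integer(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("time courses round-trip through CSV with metadata", {
  tc <- linear_time_course()
  path <- tempfile(fileext = ".csv")
  write_time_course(tc, path)
  tc2 <- read_time_course(path)
  expect_equal(as.data.frame(tc2), as.data.frame(tc))
  expect_equal(attr(tc2, "protein_conc_ug_ml"), attr(tc, "protein_conc_ug_ml"))
  expect_equal(attr(tc2, "S0"), attr(tc, "S0"))
  unlink(path)
})

test_that("time-course invariants are enforced", {
  bad_t <- tibble::tibble(time_min = c(0, 10, 10), substrate_uM = c(10, 9, 8),
                          adpr_uM = c(0, 1, 2), cyclic_uM = 0, base_uM = c(0, 1, 2))
  expect_error(time_course(bad_t), "strictly increasing")
  bad_p <- tibble::tibble(time_min = c(0, 10), substrate_uM = c(10, 9),
                          adpr_uM = c(1, 2), cyclic_uM = 0, base_uM = c(0, 1))
  expect_error(time_course(bad_p), "start at 0")
  bad_s <- tibble::tibble(time_min = c(0, 10), substrate_uM = c(10, 12),
                          adpr_uM = c(0, 1), cyclic_uM = 0, base_uM = c(0, 1))
  expect_error(time_course(bad_s), "nonincreasing")
})
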
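test_that("distensibility estimator inverts area waveforms", {
  t <- seq(0, 0.88, by = 0.01)
  w <- area_waveform(t, 500 + 60 * sin(pi * t / 0.88)^2)
  expect_equal(distensibility_from_area(w, 36), 60 / (500 * 36))

  # doubling the pulse pressure halves the distensibility
  expect_equal(distensibility_from_area(w, 72),
               distensibility_from_area(w, 36) / 2)

  flat <- area_waveform(t, rep(500, length(t)))
  expect_warning(d0 <- distensibility_from_area(flat, 36), "rigid")
  expect_equal(d0, 0)
  expect_error(distensibility_from_area(w, 0), "positive")
})

test_that("branch distensibility follows the empirical diameter relation", {
  b1 <- branch_distensibility(1)
  expect_equal(b1$pwv, 13.3)

  b8 <- branch_distensibility(8, rho = 1056)
  expect_equal(b8$pwv, 13.3 * 8^-0.3, tolerance = 1e-12)
  expect_equal(b8$pwv, 7.127, tolerance = 1e-3)
  expect_equal(b8$D_pa, 1 / (1056 * b8$pwv^2))
  expect_equal(b8$D_pa, 1.864e-5, tolerance = 1e-3)

  # distensibility increases monotonically with diameter
  d <- seq(2, 30, by = 1)
  D <- vapply(d, function(x) branch_distensibility(x)$D_pa, numeric(1))
  expect_true(all(diff(D) > 0))

  # physiological wave speeds across the branch diameter range
  pwv <- vapply(seq(3, 30, by = 0.5),
                function(x) branch_distensibility(x)$pwv, numeric(1))
  expect_true(all(pwv >= 4.79 & pwv <= 9.57))

  expect_error(branch_distensibility(-1), "positive")
})

test_that("inertance and volume compliance follow their defining relations", {
  expect_equal(inductance(0, 4e-4)$L_si, 0)
  L <- inductance(0.1, 4e-4, rho = 1056)
  expect_equal(L$L_si, (4 / 3) * 1056 * 0.1 / 4e-4)  # 3.52e5
  expect_equal(L$L_si, 3.52e5, tolerance = 1e-6)
  expect_equal(inductance(0.1, 8e-4)$L_si, L$L_si / 2)
  expect_error(inductance(0.1, 0), "positive")

  expect_equal(volume_compliance(0, 40), 0)
  expect_equal(volume_compliance(3.333e-3, 40), 0.13332)
  expect_equal(volume_compliance(2 * 3.333e-3, 40),
               2 * volume_compliance(3.333e-3, 40))
})

test_that("Poiseuille resistance estimate and overrides behave", {
  expect_equal(segment_resistance_estimate(0, 5e-4)$R_si, 0)
  r <- segment_resistance_estimate(0.05, 5e-4, 3.5e-3)
  expect_equal(r$R_si, 8 * pi * 3.5e-3 * 0.05 / (5e-4)^2)
  expect_equal(r$R_clinical, 1.32e-4, tolerance = 1e-2)
  expect_equal(segment_resistance_estimate(1, 1, override = 0.42)$R_clinical,
               0.42)
})

test_that("Carreau-Yasuda viscosity has the correct limits and mid-range", {
  fp <- fluid_props()
  expect_equal(carreau_yasuda_viscosity(0, fp), fp$mu0)
  expect_lt(rel_err(carreau_yasuda_viscosity(1e6, fp), fp$muInf), 0.01)

  # direct formula evaluation at a mid-range shear rate
  g <- 10
  ref <- fp$muInf + (fp$mu0 - fp$muInf) *
    (1 + (fp$lambda * g)^fp$a)^((fp$n - 1) / fp$a)
  expect_equal(carreau_yasuda_viscosity(g, fp), ref)
  # shear-thinning: monotone non-increasing
  mu <- carreau_yasuda_viscosity(10^seq(-2, 5, by = 0.25), fp)
  expect_true(all(diff(mu) <= 0))
  expect_error(fluid_props(mu0 = 1e-3, muInf = 3.5e-3), "mu0 > muInf")
})

test_that("turbulence-onset check computes Re and compares strictly", {
  # fixed-viscosity Reynolds number oracle
  fp <- fluid_props(muInf = 3.5e-3, mu0 = 3.5001e-3, lambda = 0)
  rep_ <- turbulence_onset_check(1.0, 0.025, fp)
  expect_equal(rep_$re_peak, 1056 * 1.0 * 0.025 / rep_$mu_eff)
  expect_lt(rel_err(rep_$re_peak, 7543), 0.01)

  low <- turbulence_onset_check(0.05, 0.01, fp)
  expect_false(low$turbulent)
  # equality is not turbulence: the comparison is strict
  eq <- turbulence_onset_check(1.0, 0.025, fp,
                               crit_coef = rep_$re_peak / rep_$alpha)
  expect_false(eq$turbulent)
  expect_true(turbulence_onset_check(3, 0.025, fp)$re_peak >
                turbulence_onset_check(1, 0.025, fp)$re_peak)
})

test_that("mechanics unit conversions round-trip to machine precision", {
  x <- c(1e-6, 0.37, 42, 9.6e4)
  expect_equal(pa_to_mmhg(mmhg_to_pa(x)), x, tolerance = 1e-12)
  expect_equal(resistance_si_to_clinical(resistance_clinical_to_si(x)), x,
               tolerance = 1e-12)
  expect_equal(inductance_clinical_to_si(inductance_si_to_clinical(x)), x,
               tolerance = 1e-12)
  expect_equal(compliance_si_to_clinical(compliance_clinical_to_si(x)), x,
               tolerance = 1e-12)
  expect_equal(distensibility_mmhg_to_pa(distensibility_pa_to_mmhg(x)), x,
               tolerance = 1e-12)
})

test_that("synthetic cylinder chains distensibility into volume compliance", {
  # a segment whose area waveform has known dA reproduces CV = D*V to 0.1%
  amin <- 480; ppulse <- 36; d_true <- 3.1e-3
  w <- make_area_waveform(amin, d_true, ppulse)
  D <- distensibility_from_area(w, ppulse)
  vol <- 42
  expect_lt(rel_err(volume_compliance(D, vol), d_true * vol), 1e-3)
})

test_that("segment property assembly is unit consistent", {
  s <- segment_props("AA", 0.06, 6.2e-4, 37.2, 3.2e-3)
  expect_equal(s$CV, 3.2e-3 * 37.2)
  expect_gt(s$L, 0)
  expect_gt(s$R, 0)
  s2 <- segment_props("AA", 0.06, 6.2e-4, 37.2, 3.2e-3, R_override = 0.01)
  expect_equal(s2$R, 0.01)
})

test_that("area waveform CSV round-trips by region", {
  waves <- list(AA = make_area_waveform(620, 3.2e-3, 36, dt = 0.038),
                DA = make_area_waveform(400, 2.4e-3, 36, dt = 0.038))
  p <- withr::local_tempfile(fileext = ".csv")
  write_area_csv(waves, p)
  back <- read_area_csv(p)
  expect_named(back, c("AA", "DA"))
  expect_equal(back$AA$amin, waves$AA$amin)
  expect_equal(back$DA$da, waves$DA$da, tolerance = 1e-9)
})
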
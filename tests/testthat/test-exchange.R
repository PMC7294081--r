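test_that("closed form reduces to R2^0 with no exchange and at fast pulsing", {
  p0 <- fast_exchange_params(2970, 0, c("564.686" = 204), 564.686)
  nu <- nu_cpmg_grid()
  expect_equal(luz_meiboom_r2(p0, nu, 564.686), rep(204, length(nu)))

  # tanh expansion: the bracket decays like (kex/4nu)^2/3 at high nu
  p <- fast_exchange_params(2970, 3e5, c("564.686" = 204), 564.686)
  expect_equal(luz_meiboom_r2(p, 10 * 2970, 564.686), 204,
               tolerance = 1e-3)
})

test_that("slow-pulsing limit approaches R2^0 + phi_ex/kex", {
  # analytic nu -> 0 limit of the closed form: 204 + 3e5/2970 = 305.0101...
  p <- fast_exchange_params(2970, 3e5, c("564.686" = 204), 564.686)
  expect_equal(luz_meiboom_r2(p, 1e-4, 564.686), 204 + 3e5 / 2970,
               tolerance = 1e-6)
})

test_that("closed-form dispersion is non-increasing in nu_cpmg", {
  set.seed(42)
  nu <- nu_cpmg_grid(n = 40, range = c(1, 1e5))
  for (i in 1:25) {
    p <- fast_exchange_params(10^runif(1, 2, 5), 10^runif(1, 3, 6),
                              c("564.686" = runif(1, 10, 300)), 564.686)
    r2 <- luz_meiboom_r2(p, nu, 564.686)
    expect_true(all(diff(r2) <= 1e-12))
    expect_true(all(r2 >= p$r20_by_field[[1]] - 1e-9))
  }
})

test_that("closed form rejects invalid frequencies and unknown fields", {
  p <- fast_exchange_params(2970, 3e5, c("564.686" = 204), 564.686)
  expect_error(luz_meiboom_r2(p, -5, 564.686), "positive")
  expect_error(luz_meiboom_r2(p, 100, 658.780), "no R2\\^0")
  # Phi scaling rule with a supplied plateau works for an undeclared field
  expect_equal(luz_meiboom_r2(p, 1e-4, 658.780, r20 = 260),
               260 + (3e5 * (658.780 / 564.686)^2) / 2970, tolerance = 1e-6)
})

test_that("Bloch-McConnell oracle collapses to single-state limits", {
  nu <- nu_cpmg_grid(n = 8)
  sched <- cpmg_schedule(nu)
  # pB = 0: only state A relaxes
  sysA <- exchange_system(1, 5000, 0.3, 150, 80, 564.686)
  dc <- bloch_mcconnell_r2eff(sysA, sched)
  expect_equal(dc$r2eff, rep(150, length(nu)), tolerance = 1e-10)
  # degenerate states: population-averaged R2 with no shift difference
  sysD <- exchange_system(0.7, 5000, 0, 120, 120, 564.686)
  dcD <- bloch_mcconnell_r2eff(sysD, sched)
  expect_equal(dcD$r2eff, rep(120, length(nu)), tolerance = 1e-10)
})

test_that("oracle matches the closed form across random fast-exchange systems", {
  set.seed(7)
  sched <- cpmg_schedule(nu_cpmg_grid())
  worst <- 0
  for (i in 1:100) {
    field <- sample(c(564.686, 658.780), 1)
    kex <- 10^runif(1, 3.2, 4.6)
    # keep kex / delta_omega >= 10 (fast exchange)
    dw <- kex / runif(1, 10, 40)
    dppm <- dw / (2 * pi * field)
    pA <- runif(1, 0.55, 0.97)
    r20 <- runif(1, 50, 250)
    sys <- exchange_system(pA, kex, dppm, r20, r20, field)
    phi <- pA * (1 - pA) * dw^2
    p <- fast_exchange_params(kex, phi,
                              stats::setNames(r20, sprintf("%.3f", field)),
                              field)
    bm <- bloch_mcconnell_r2eff(sys, sched)$r2eff
    cf <- luz_meiboom_r2(p, sched$nu_cpmg, field)
    worst <- max(worst, max(abs(bm - cf) / cf))
  }
  expect_lt(worst, 0.02)
})

test_that("field scaling of phi_ex mirrors linear field scaling of delta_omega", {
  # closed form at the high field via the squared-field-ratio rule vs the
  # oracle with delta_omega (in ppm) held fixed, i.e. rad/s scaling linearly
  f1 <- 564.686; f2 <- 658.780
  kex <- 30000; dppm <- 0.25; pA <- 0.9; r20 <- 120
  dw1 <- 2 * pi * f1 * dppm
  p <- fast_exchange_params(kex, pA * (1 - pA) * dw1^2,
                            c("564.686" = r20, "658.780" = r20), f1)
  sched <- cpmg_schedule(nu_cpmg_grid())
  sys2 <- exchange_system(pA, kex, dppm, r20, r20, f2)
  bm2 <- bloch_mcconnell_r2eff(sys2, sched)$r2eff
  cf2 <- luz_meiboom_r2(p, sched$nu_cpmg, f2)
  expect_lt(max(abs(bm2 - cf2) / cf2), 0.02)
})

test_that("intensity-to-rate conversion is exact and validated", {
  expect_equal(r2eff_from_intensities(3.7, 3.7, 0.04), 0)
  expect_equal(r2eff_from_intensities(exp(-1), 1, 0.05), 20)
  expect_error(r2eff_from_intensities(-1, 1, 0.05), "positive")
  expect_error(r2eff_from_intensities(1, 1, 0), "positive")

  # round trip through the oracle's surviving intensities
  sys <- exchange_system(0.9, 8000, 0.2, 100, 140, 564.686)
  sched <- cpmg_schedule(c(100, 1000))
  dc <- bloch_mcconnell_r2eff(sys, sched)
  for (i in 1:2) {
    I <- fluordyn:::bloch_mcconnell_intensity(sys, sched$tau_cp[i],
                                              sched$n_pulses[i])
    expect_equal(r2eff_from_intensities(I, 1, sched$t_relax), dc$r2eff[i])
  }
})

test_that("CPMG schedule enforces its conventions", {
  expect_error(cpmg_schedule(c(-1, 5)), "positive")
  expect_error(cpmg_schedule(c(100, 50)), "increasing")
  expect_error(cpmg_schedule(100, t_relax = 0), "positive")
  s <- cpmg_schedule(c(50, 500), t_relax = 0.04)
  expect_true(all(s$n_pulses %% 2 == 0))
  expect_equal(s$n_pulses, c(4L, 40L))
  # tau_cp consistent with n * 2 * tau = t_relax
  expect_equal(s$n_pulses * 2 * s$tau_cp, rep(0.04, 2))
})
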
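test_that("noiseless two-field round trips recover all generating parameters", {
  fx <- exchange_fixtures()
  for (nm in names(fx)) {
    truth <- fx[[nm]]
    curves <- generate_dispersion_dataset(nm, noise_frac = 0)
    fit <- fit_dispersion_global(curves)
    expect_true(fit$converged)
    expect_equal(fit$params$kex, truth$kex, tolerance = 5e-5)
    expect_equal(unname(fit$params$r20_by_field),
                 unname(truth$r20_by_field), tolerance = 5e-5)
    expect_equal(fit$params$phi_ex_ref, truth$phi_ex_ref, tolerance = 5e-4)
  }
})

test_that("reference-field choice is a pure reparameterization", {
  curves <- generate_dispersion_dataset("thrombin_W215", noise_frac = 0.01,
                                        seed = 2)
  lo <- fit_dispersion_global(curves, ref_field_mhz = 564.686)
  hi <- fit_dispersion_global(curves, ref_field_mhz = 658.780)
  expect_equal(hi$params$kex, lo$params$kex, tolerance = 1e-8)
  expect_equal(unname(hi$params$r20_by_field),
               unname(lo$params$r20_by_field), tolerance = 1e-8)
  expect_equal(hi$chi2, lo$chi2, tolerance = 1e-8)
  expect_equal(hi$params$phi_ex_ref,
               lo$params$phi_ex_ref * (658.780 / 564.686)^2,
               tolerance = 1e-6)
})

test_that("exchange-free data are flagged and fit to flat plateaus", {
  p0 <- fast_exchange_params(2970, 1e-9,
                             c("564.686" = 204, "658.780" = 260), 564.686)
  curves <- generate_dispersion_dataset(p0, noise_frac = 0.01, seed = 5)
  fit <- fit_dispersion_global(curves)
  expect_true("no dispersion" %in% fit$flags)
  d <- fit$data
  for (i in seq_along(fit$fields)) {
    expect_equal(unname(fit$params$r20_by_field[i]),
                 mean(d$r2eff[d$fidx == i]), tolerance = 0.01)
  }
})

test_that("underdetermined inputs are rejected", {
  nu <- nu_cpmg_grid(n = 3)
  dc <- dispersion_curve(564.686, nu, c(200, 199, 198))
  expect_error(fit_dispersion_global(dc), "4 points|parameters")
})

test_that("fitting oracle-simulated data recovers kex despite the approximation", {
  # generator is the Bloch-McConnell oracle (kex/delta_omega = 20), fit is
  # the closed form; 1% noise, 20 seeds
  f1 <- 564.686; f2 <- 658.780
  kex <- 20000; pA <- 0.7; r20 <- 100
  dppm <- (kex / 20) / (2 * pi * f1)
  sched <- cpmg_schedule(nu_cpmg_grid())
  clean <- lapply(c(f1, f2), function(f) {
    sys <- exchange_system(pA, kex, dppm, r20, r20, f)
    bloch_mcconnell_r2eff(sys, sched)
  })
  kex_hat <- vapply(1:20, function(s) {
    noisy <- list()
    for (i in seq_along(clean)) for (r in 1:2) {  # duplicate acquisitions
      dc <- clean[[i]]
      sig <- 0.01 * dc$r2eff
      r2n <- dc$r2eff + fluordyn:::with_seed(
        s * 1000 + i * 10 + r, stats::rnorm(length(sig), sd = sig))
      noisy[[length(noisy) + 1L]] <-
        dispersion_curve(dc$field_mhz[1], dc$nu_cpmg, r2n, sigma = sig)
    }
    fit_dispersion_global(noisy)$params$kex
  }, numeric(1))
  expect_lt(abs(stats::median(kex_hat) - kex) / kex, 0.05)
})

test_that("parameter recovery at 1% noise is covered by +/- 3 stderr", {
  for (nm in names(exchange_fixtures())) {
    truth <- exchange_fixtures()[[nm]]$kex
    hits <- vapply(1:20, function(s) {
      fit <- fit_dispersion_global(
        generate_dispersion_dataset(nm, noise_frac = 0.01, seed = s))
      abs(fit$params$kex - truth) <= 3 * fit$stderr[["kex"]]
    }, logical(1))
    expect_gte(sum(hits), 18L)
  }
})

test_that("removing points never shrinks the kex uncertainty", {
  curves <- generate_dispersion_dataset("prethrombin2_W51",
                                        noise_frac = 0.01, seed = 8)
  full <- fit_dispersion_global(curves)
  for (drop_frac in c(0.25, 0.5)) {
    sub <- lapply(curves, function(dc) {
      keep <- seq_len(nrow(dc))
      keep <- keep[seq_along(keep) %% round(1 / drop_frac) != 0]
      dispersion_curve(dc$field_mhz[1], dc$nu_cpmg[keep], dc$r2eff[keep],
                       sigma = dc$sigma[keep])
    })
    fs <- fit_dispersion_global(sub)
    expect_gte(fs$stderr[["kex"]], full$stderr[["kex"]])
  }
})

test_that("profile intervals agree with covariance errors in a quadratic basin", {
  curves <- generate_dispersion_dataset("prethrombin2_W51",
                                        noise_frac = 0.01, seed = 1)
  fit <- fit_dispersion_global(curves)
  prof <- profile_uncertainty(fit, curves, "kex", span = 1.5)
  expect_false(prof$unbounded)
  expect_lt(prof$ci[["lower"]], fit$params$kex)
  expect_gt(prof$ci[["upper"]], fit$params$kex)
  half_width <- (prof$ci[["upper"]] - prof$ci[["lower"]]) / 2
  expect_equal(half_width, fit$stderr[["kex"]], tolerance = 0.10)
})

test_that("profiling refuses unusable inputs and flags flat data", {
  p0 <- fast_exchange_params(2970, 1e-9, c("564.686" = 204), 564.686)
  flat <- generate_dispersion_dataset(p0, noise_frac = 0.01, seed = 3,
                                      fields = 564.686)
  fit <- fit_dispersion_global(flat)
  prof <- profile_uncertainty(fit, flat, "kex", span = 10, n_grid = 15)
  expect_true(prof$unbounded)

  bad <- fit
  bad$converged <- FALSE
  expect_error(profile_uncertainty(bad, flat, "kex"), "non-converged")
})

test_that("dispersion CSV and fit report round trips preserve content", {
  curves <- generate_dispersion_dataset("thrombin_W215", noise_frac = 0.01,
                                        seed = 7, n_replicates = 1)
  f <- tempfile(fileext = ".csv")
  write_dispersion(curves, f)
  back <- read_dispersion(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$r2eff, curves[[1]]$r2eff, tolerance = 1e-9)

  fit <- fit_dispersion_global(curves)
  jf <- tempfile(fileext = ".json")
  dispersion_fit_report(fit, jf)
  rep <- jsonlite::fromJSON(readLines(jf))
  expect_equal(rep$kex, fit$params$kex, tolerance = 1e-9)
  expect_equal(rep$converged, TRUE)
})
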
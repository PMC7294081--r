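table2_spectrum <- function(protein, noise_sigma = 0, seed = NULL,
                            field = 658.780, lb = 20) {
  sh <- assignment_shifts(build_table2_fixture(), protein)
  pk <- peak_list(unlist(sh), fwhm_hz = 0.08 * field - lb,
                  label = rep(names(sh), lengths(sh)))
  simulate_spectrum(pk, field_mhz = field, noise_sigma = noise_sigma,
                    lb_hz = lb, seed = seed)
}

test_that("spectrum simulation honors its degenerate cases and lineshape", {
  s0 <- simulate_spectrum(NULL, noise_sigma = 0)
  expect_true(all(s0$intensity == 0))
  expect_error(simulate_spectrum(peak_list(-60, 50), noise_sigma = 0),
               "cover")

  # single peak of 52.7 Hz at 658.780 MHz reads back as 0.08 ppm FWHM
  s1 <- simulate_spectrum(peak_list(-47, fwhm_hz = 52.7), lb_hz = 0,
                          noise_sigma = 0)
  pk <- pick_peaks(s1)
  step <- abs(diff(s1$ppm[1:2]))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$fwhm_hz / s1$field_mhz, 0.08, tolerance = step / 0.08)

  # deterministic for a fixed seed, without touching the global RNG stream
  set.seed(123); before <- rnorm(1)
  a <- simulate_spectrum(peak_list(-47, 50), noise_sigma = 0.05, seed = 9)
  b <- simulate_spectrum(peak_list(-47, 50), noise_sigma = 0.05, seed = 9)
  expect_identical(a$intensity, b$intensity)
})

test_that("reference-table spectra show the expected peak structure", {
  th <- table2_spectrum("thrombin")
  pk <- pick_peaks(th, threshold_frac = 0.01)
  expect_equal(nrow(pk), 7L)
  # most downfield resonance is unique to the protease
  expect_equal(pk$center_ppm[1], -43.5, tolerance = 1e-2)
  expect_equal(which.max(pk$center_ppm), 1L)  # sorted downfield first

  p2 <- table2_spectrum("prethrombin-2")
  pk2 <- pick_peaks(p2, threshold_frac = 0.01)
  expect_equal(nrow(pk2), 4L)
  expect_equal(sort(pk2$center_ppm), c(-49.8, -48.6, -47.9, -46.7),
               tolerance = 1e-2)
})

test_that("peak picking handles flat spectra and merges close maxima", {
  flat <- spectrum1d(seq(-40, -54, length.out = 100), rep(0, 100), 658.78)
  expect_equal(nrow(pick_peaks(flat)), 0L)

  # two maxima 0.02 ppm apart merge into the taller one
  s <- simulate_spectrum(peak_list(c(-47.00, -47.02), fwhm_hz = 30,
                                   amplitude = c(1, 0.6)),
                         lb_hz = 0, noise_sigma = 0)
  pk <- pick_peaks(s, min_separation_ppm = 0.05)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$center_ppm, -47.00, tolerance = 2e-3)
})

test_that("picking recovers simulated centers when peaks are resolved", {
  # round trip property: separations >= 2 FWHM, no noise
  set.seed(11)
  for (rep in 1:5) {
    centers <- sort(-54 + cumsum(runif(6, 0.5, 2)))
    centers <- centers[centers < -40.5]
    s <- simulate_spectrum(peak_list(centers, fwhm_hz = 52.7), lb_hz = 0,
                           noise_sigma = 0)
    pk <- pick_peaks(s, threshold_frac = 0.005)
    step <- abs(diff(s$ppm[1:2]))
    expect_equal(nrow(pk), length(centers))
    expect_true(all(abs(sort(pk$center_ppm) - centers) <= step))
  }
})

test_that("Lorentzian deconvolution recovers known components", {
  # exact self-consistency on a noiseless single line
  s <- simulate_spectrum(peak_list(-46.123, fwhm_hz = 47), lb_hz = 0,
                         noise_sigma = 0)
  fit <- fit_lorentzians(s, peak_list(-46.0, fwhm_hz = 60, amplitude = 0.8))
  expect_true(fit$converged)
  expect_equal(fit$peaks$center_ppm, -46.123, tolerance = 1e-4)
  expect_equal(fit$peaks$fwhm_hz, 47, tolerance = 47 * 5e-4)
  expect_equal(fit$peaks$amplitude, 1, tolerance = 5e-4)

  # two lines 0.2 ppm apart at 1% noise: centers within 0.01 ppm
  s2 <- simulate_spectrum(peak_list(c(-47.5, -47.7), fwhm_hz = 32.7),
                          noise_sigma = 0.01, seed = 4)
  fit2 <- fit_lorentzians(s2, peak_list(c(-47.45, -47.75), fwhm_hz = 50))
  expect_true(fit2$converged)
  expect_equal(sort(fit2$peaks$center_ppm), c(-47.7, -47.5),
               tolerance = 0.01 / 47.7)
})

test_that("an overlapped cluster fitted as one component is broader than an isolated line", {
  # the prethrombin-2 -47.9 ppm cluster: six coincident resonances plus the
  # nearby -48.6 line; fit the cluster as a single broad component
  p2 <- table2_spectrum("prethrombin-2")
  fit <- fit_lorentzians(p2, peak_list(c(-46.7, -47.9, -48.6, -49.8),
                                       fwhm_hz = 60, amplitude = c(1, 6, 1, 1)))
  iso <- fit$peaks[abs(fit$peaks$center_ppm + 46.7) < 0.1, ]
  clus <- fit$peaks[abs(fit$peaks$center_ppm + 47.9) < 0.2, ]
  expect_gte(clus$fwhm_hz, iso$fwhm_hz)
})

test_that("apodization never sharpens fitted lines", {
  widths <- vapply(c(0, 10, 20, 40), function(lb) {
    s <- simulate_spectrum(peak_list(-47, fwhm_hz = 40), lb_hz = lb,
                           noise_sigma = 0)
    fit_lorentzians(s, peak_list(-47, fwhm_hz = 40))$peaks$fwhm_hz
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("difference assignment finds exactly the removed resonances", {
  wt <- table2_spectrum("prethrombin-2")
  expect_equal(nrow(assign_by_difference(wt, wt)), 0L)

  # W215F removes the two slow-exchange Trp215 resonances
  sh <- assignment_shifts(build_table2_fixture(), "prethrombin-2")
  sh_mut <- unlist(sh[setdiff(names(sh), "Trp215")])
  mut <- simulate_spectrum(peak_list(sh_mut, fwhm_hz = 0.08 * 658.78 - 20),
                           noise_sigma = 0)
  reg <- assign_by_difference(wt, mut)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$ppm_extremum, c(-47.9, -49.8), tolerance = 1e-2)

  # magnitude symmetry: same regions whichever direction the difference runs
  reg_rev <- assign_by_difference(mut, wt)
  expect_equal(reg$ppm_extremum, reg_rev$ppm_extremum)
  expect_equal(reg$ppm_from, reg_rev$ppm_from)

  expect_error(assign_by_difference(wt, simulate_spectrum(
    NULL, ppm_range = c(-40, -50), noise_sigma = 0)), "axis")
})

test_that("W141F in thrombin perturbs only the most downfield resonance", {
  wt <- table2_spectrum("thrombin")
  sh <- assignment_shifts(build_table2_fixture(), "thrombin")
  sh_mut <- unlist(sh[setdiff(names(sh), "Trp141")])
  mut <- simulate_spectrum(peak_list(sh_mut, fwhm_hz = 0.08 * 658.78 - 20),
                           noise_sigma = 0)
  reg <- assign_by_difference(wt, mut)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$ppm_extremum, -43.5, tolerance = 1e-2)
})

test_that("spectrum text round trip preserves data and metadata", {
  s <- simulate_spectrum(peak_list(-47, 50), n_points = 256,
                         noise_sigma = 0.02, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f)
  expect_equal(s2$ppm, s$ppm)
  expect_equal(s2$intensity, s$intensity)
  expect_equal(s2$field_mhz, s$field_mhz)
  expect_equal(s2$lb_hz, s$lb_hz)
})
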
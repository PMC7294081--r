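#' Reference 19F chemical-shift table
#'
#' The assigned 5-fluoro-Trp chemical shifts (ppm relative to TFA) of the
#' nine Trp residues of thrombin and prethrombin-2, as determined by
#' Trp-to-Phe difference assignment. Residues in slow exchange between two
#' conformations carry two shifts (Trp60d in thrombin; Trp215 in
#' prethrombin-2); unassignable residues are marked not determined.
#'
#' @return A data frame of class `"assignment_table"` in long form with
#'   columns `protein` (`"thrombin"` / `"prethrombin-2"`), `residue` (e.g.
#'   `"Trp60d"`) and `shift_ppm` (`NA` = not determined).
#' @examples
#' tab <- build_table2_fixture()
#' assignment_shifts(tab, "thrombin")
#' @export
build_table2_fixture <- function() {
  long <- rbind(
    data.frame(protein = "thrombin",
               residue = c("Trp29", "Trp51", "Trp60d", "Trp60d", "Trp96",
                           "Trp141", "Trp148", "Trp207", "Trp215", "Trp237"),
               shift_ppm = c(NA, -46.7, -48.5, -48.7, -47.9,
                             -43.5, -48.5, NA, -47.5, -49.4)),
    data.frame(protein = "prethrombin-2",
               residue = c("Trp29", "Trp51", "Trp60d", "Trp96", "Trp141",
                           "Trp148", "Trp207", "Trp215", "Trp215", "Trp237"),
               shift_ppm = c(NA, -46.7, -47.9, -47.9, -47.9,
                             -47.9, -47.9, -47.9, -49.8, -48.6))
  )
  class(long) <- c("assignment_table", "data.frame")
  long
}

#' Shifts of one protein from an assignment table
#'
#' @param tab An `"assignment_table"` (see [build_table2_fixture()]).
#' @param protein `"thrombin"` or `"prethrombin-2"`.
#' @param drop_na Drop not-determined entries (default `TRUE`).
#' @return Named list mapping residue to its shift vector (ppm).
#' @export
assignment_shifts <- function(tab, protein, drop_na = TRUE) {
  stopifnot(inherits(tab, "assignment_table"))
  d <- tab[tab$protein == protein, , drop = FALSE]
  if (nrow(d) == 0L) stop("unknown protein: ", protein)
  if (drop_na) d <- d[!is.na(d$shift_ppm), , drop = FALSE]
  split(d$shift_ppm, factor(d$residue, levels = unique(d$residue)))
}

#' Write an assignment table as a wide CSV
#'
#' One row per residue, one column per protein; dual shifts joined by
#' `"; "`, not-determined entries written as the literal `ND`.
#'
#' @param tab An `"assignment_table"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_assignment_table <- function(tab, path) {
  stopifnot(inherits(tab, "assignment_table"))
  res <- unique(tab$residue)
  prot <- unique(tab$protein)
  wide <- data.frame(residue = res)
  for (p in prot) {
    wide[[p]] <- vapply(res, function(r) {
      v <- tab$shift_ppm[tab$protein == p & tab$residue == r]
      if (length(v) == 0L || all(is.na(v))) "ND"
      else paste(format(v[!is.na(v)], trim = TRUE), collapse = "; ")
    }, character(1))
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-state exchange parameter fixtures
#'
#' The three fast-exchange parameter sets resolved by two-field dispersion
#' fitting (one per residue/protein combination with an assignable,
#' exchange-broadened resonance), used as ground truth by the synthetic
#' dispersion generator. The exchange amplitude is not separately
#' identifiable in fast exchange and is fixed at
#' `phi_ex(564.686 MHz) = 3e5 1/s^2`, which gives dispersion amplitudes of
#' order 1e2 1/s, comparable to the measured plateaus; recovery of `kex`
#' and `R2^0` does not depend on this choice.
#'
#' @return Named list of [fast_exchange_params()]:
#'   `prethrombin2_W51` (kex 2970), `thrombin_W215` (kex 7980),
#'   `thrombin_W51` (kex 19000).
#' @export
exchange_fixtures <- function() {
  phi <- 3e5
  ref <- 564.686
  list(
    prethrombin2_W51 = fast_exchange_params(
      2970, phi, c("564.686" = 204, "658.780" = 260), ref),
    thrombin_W215 = fast_exchange_params(
      7980, phi, c("564.686" = 160, "658.780" = 258), ref),
    thrombin_W51 = fast_exchange_params(
      19000, phi, c("564.686" = 100, "658.780" = 140), ref)
  )
}

#' Default CPMG frequency grid
#'
#' Twelve log-spaced CPMG frequencies from 25 to 5000 Hz. The upper decade
#' covers the pulse spacings used experimentally (half-echo delays of
#' 50-500 microseconds correspond to 500-5000 Hz, with the convention
#' `nu_cpmg = 1/(4 tau_cp)`); the low-frequency points anchor the
#' slow-pulsing plateau. The high end matters: the fastest exchange process
#' studied here (kex ~ 1.9e4 1/s) only begins to be refocused above ~2 kHz,
#' so a grid truncated there cannot constrain its rate.
#'
#' @param n Number of points (default 12).
#' @param range Frequency range in Hz (default `c(25, 5000)`).
#' @return Numeric vector of frequencies in Hz.
#' @export
nu_cpmg_grid <- function(n = 12, range = c(25, 5000)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Acquisition-condition defaults
#'
#' The measurement conditions emulated by the synthetic generators: the two
#' 19F fields, the T1 inversion-recovery delay list, the T2 spin-echo
#' evolution times, the CPMG frequency grid, the processing line broadening
#' and the default noise levels.
#'
#' @return A named list of class `"study_acquisition"`.
#' @export
study_acquisition <- function() {
  structure(list(
    fields_mhz = c(564.686, 658.780),
    t1_delays_s = c(0.0625, 0.125, 0.25, 0.5, 1.0, 2.0, 4.0, 8.0),
    t2_times_s = c(0.0005, 0.001, 0.002, 0.004, 0.008, 0.032, 0.064, 0.128),
    nu_cpmg_hz = nu_cpmg_grid(),
    lb_hz = 20,
    spectrum_noise_sigma = 0.01,
    dispersion_noise_frac = 0.01,
    n_replicates = 2L
  ), class = "study_acquisition")
}

# effective on-spectrum linewidth target in ppm (includes the 20-Hz lb)
.panel_fwhm_ppm <- 0.08

# peak list of a protein, optionally with one Trp knocked out (Trp -> Phe)
.protein_peaks <- function(protein, drop_residue = NULL, field_mhz = 658.780,
                           lb_hz = 20, jitter_ppm = 0, seed = NULL) {
  shifts <- assignment_shifts(build_table2_fixture(), protein)
  if (!is.null(drop_residue)) {
    if (!drop_residue %in% names(shifts))
      stop("unknown or unassigned residue tag: ", drop_residue)
    shifts <- shifts[setdiff(names(shifts), drop_residue)]
  }
  centers <- unlist(shifts, use.names = FALSE)
  labels <- rep(names(shifts), lengths(shifts))
  if (jitter_ppm > 0 && !is.null(drop_residue)) {
    # optional non-selective perturbation: nudge the two nearest neighbors
    dropped <- assignment_shifts(build_table2_fixture(), protein)[[drop_residue]]
    dist <- vapply(centers, function(cc) min(abs(cc - dropped)), numeric(1))
    nb <- order(dist)[seq_len(min(2L, length(centers)))]
    centers[nb] <- centers[nb] +
      with_seed(seed, stats::runif(length(nb), -jitter_ppm, jitter_ppm))
  }
  fwhm <- max(.panel_fwhm_ppm * field_mhz - lb_hz, 1)
  peak_list(centers, fwhm_hz = fwhm, amplitude = 1, label = labels)
}

#' Generate a WT + mutant spectrum panel
#'
#' Builds the synthetic wild-type 19F spectrum of a protein from the
#' reference shift table (unit amplitude per resonance — the per-residue
#' signal is equimolar by construction) plus one spectrum per requested
#' Trp-to-Phe mutant, identical to the wild type except that the mutated
#' residue's peak(s) are removed. Per-spectrum child seeds are derived
#' deterministically from the root seed, so a panel is reproducible
#' bit-for-bit.
#'
#' @param protein `"thrombin"` or `"prethrombin-2"`.
#' @param mutants Character vector of residue tags to knock out (subset of
#'   the assignable Trp residues, e.g. `"Trp215"`); empty for WT only.
#' @param seed Root integer seed.
#' @param noise_sigma Additive Gaussian noise level (default 0.01 of the
#'   unit peak amplitude).
#' @param field_mhz,lb_hz Acquisition field and processing line broadening.
#' @param jitter_ppm Optional non-selective perturbation: in mutant spectra,
#'   shift the two resonances nearest the removed peak(s) by up to this many
#'   ppm (default 0 = fully selective knockouts).
#' @return Named list of [spectrum1d()] objects: `WT` plus one entry per
#'   mutant (named by residue tag).
#' @examples
#' panel <- generate_panel("prethrombin-2", mutants = "Trp215", seed = 1)
#' names(panel)
#' @export
generate_panel <- function(protein, mutants = character(0), seed = 1L,
                           noise_sigma = 0.01, field_mhz = 658.780,
                           lb_hz = 20, jitter_ppm = 0) {
  out <- list(WT = simulate_spectrum(
    .protein_peaks(protein, NULL, field_mhz, lb_hz),
    field_mhz = field_mhz, noise_sigma = noise_sigma, lb_hz = lb_hz,
    seed = seed))
  for (i in seq_along(mutants)) {
    out[[mutants[i]]] <- simulate_spectrum(
      .protein_peaks(protein, mutants[i], field_mhz, lb_hz,
                     jitter_ppm = jitter_ppm, seed = seed + 1000L + i),
      field_mhz = field_mhz, noise_sigma = noise_sigma, lb_hz = lb_hz,
      seed = seed + i)
  }
  out
}

#' Assign a mutant panel by difference spectroscopy
#'
#' Runs [assign_by_difference()] of each mutant spectrum against the
#' wild type and reports, per mutated residue, the extremal positions of the
#' perturbed regions — the synthetic counterpart of reading a mutant
#' difference panel.
#'
#' @param panel A named list of spectra as returned by [generate_panel()]
#'   (must contain `WT`).
#' @param ... Passed to [assign_by_difference()].
#' @return A data frame with columns `residue`, `ppm_extremum`, `ppm_from`,
#'   `ppm_to`, `max_abs_diff` (one row per perturbed region).
#' @export
assign_panel <- function(panel, ...) {
  stopifnot("WT" %in% names(panel))
  muts <- setdiff(names(panel), "WT")
  out <- do.call(rbind, lapply(muts, function(m) {
    reg <- assign_by_difference(panel$WT, panel[[m]], ...)
    if (nrow(reg) == 0L) return(NULL)
    cbind(residue = m, reg[, c("ppm_extremum", "ppm_from", "ppm_to",
                               "max_abs_diff")])
  }))
  if (is.null(out))
    out <- data.frame(residue = character(0), ppm_extremum = numeric(0),
                      ppm_from = numeric(0), ppm_to = numeric(0),
                      max_abs_diff = numeric(0))
  rownames(out) <- NULL
  out
}

#' Generate a two-field synthetic dispersion dataset
#'
#' Evaluates the fast-exchange closed form at both fields on the default
#' CPMG grid for one of the shipped exchange fixtures (or a user-supplied
#' parameter set) and adds proportional Gaussian noise. Point uncertainties
#' are set to `noise_frac * r2eff` (1% by default); with `noise_frac = 0`
#' the curves are exact and carry no sigma column.
#'
#' @param residue Fixture name (see [exchange_fixtures()]) or a
#'   [fast_exchange_params()] object.
#' @param noise_frac Proportional noise level (default 0.01).
#' @param seed Integer seed.
#' @param fields Fields in MHz (default both study fields).
#' @param nu CPMG grid in Hz (default [nu_cpmg_grid()]).
#' @param n_replicates Replicate acquisitions per field (default 2, the
#'   experimental practice); replicates share the grid and enter the fit as
#'   independent points. Noiseless datasets are generated once per field.
#' @return List of [dispersion_curve()] objects, one per field and
#'   replicate.
#' @examples
#' dc <- generate_dispersion_dataset("prethrombin2_W51", noise_frac = 0)
#' fit_dispersion_global(dc)$params$kex
#' @export
generate_dispersion_dataset <- function(residue, noise_frac = 0.01,
                                        seed = 1L,
                                        fields = c(564.686, 658.780),
                                        nu = nu_cpmg_grid(),
                                        n_replicates = 2L) {
  params <- if (inherits(residue, "fast_exchange_params")) residue else {
    fx <- exchange_fixtures()
    if (!residue %in% names(fx))
      stop("unknown residue fixture: ", residue)
    fx[[residue]]
  }
  label <- if (is.character(residue)) residue else "custom"
  if (noise_frac == 0) n_replicates <- 1L
  out <- list()
  for (i in seq_along(fields)) {
    f <- fields[i]
    r2 <- luz_meiboom_r2(params, nu, f)
    for (r in seq_len(n_replicates)) {
      if (noise_frac > 0) {
        sig <- noise_frac * r2
        r2n <- r2 + with_seed(seed + 10L * i + r,
                              stats::rnorm(length(r2), sd = sig))
        out[[length(out) + 1L]] <- dispersion_curve(f, nu, r2n, sigma = sig,
                                                    label = label)
      } else {
        out[[length(out) + 1L]] <- dispersion_curve(f, nu, r2, label = label)
      }
    }
  }
  out
}

#' Generate a synthetic relaxation series
#'
#' Inversion-recovery (`I(t) = I_inf (1 - 2 f exp(-t/T1))` on the standard
#' eight-delay list) or CPMG-decay (`I(t) = I0 exp(-t/T2)` on the standard
#' 0.5-128 ms evolution times) series with proportional Gaussian noise,
#' collected in duplicate by default.
#'
#' @param kind `"inversion_recovery"` or `"cpmg_decay"`.
#' @param rate True rate (1/T1 or 1/T2) in 1/s.
#' @param amplitude `I_inf` (T1) or `I0` (T2); default 1.
#' @param f Inversion efficiency for T1 (default 1).
#' @param noise_frac Gaussian noise as a fraction of `amplitude`.
#' @param n_replicates Number of replicates sharing the time grid.
#' @param seed Integer seed.
#' @param times Override the default time grid.
#' @return A [relaxation_series()].
#' @export
generate_relaxation_series <- function(kind = c("inversion_recovery",
                                                "cpmg_decay"),
                                       rate, amplitude = 1, f = 1,
                                       noise_frac = 0.02, n_replicates = 2L,
                                       seed = 1L, times = NULL) {
  kind <- match.arg(kind)
  acq <- study_acquisition()
  if (is.null(times))
    times <- if (kind == "inversion_recovery") acq$t1_delays_s else
      acq$t2_times_s
  model <- if (kind == "inversion_recovery")
    amplitude * (1 - 2 * f * exp(-times * rate))
  else amplitude * exp(-times * rate)
  tt <- rep(times, n_replicates)
  rep_id <- rep(seq_len(n_replicates), each = length(times))
  yy <- rep(model, n_replicates)
  if (noise_frac > 0) {
    yy <- yy + with_seed(seed, stats::rnorm(length(yy),
                                            sd = noise_frac * amplitude))
    sig <- rep(noise_frac * amplitude, length(yy))
  } else sig <- NULL
  if (kind == "cpmg_decay") yy <- pmax(yy, 1e-9)
  relaxation_series(kind, tt, yy, sigma = sig, replicate_id = rep_id)
}
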
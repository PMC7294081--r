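#' 1D 19F spectrum
#'
#' A one-dimensional spectrum on a ppm axis referenced to trifluoroacetic
#' acid (TFA = 0 ppm). By convention the axis runs downfield to upfield
#' (decreasing ppm), so printing left to right matches a spectrometer
#' display; 5-fluoro-Trp resonances of proteins fall near -43 to -50 ppm on
#' this scale. The Hz/ppm conversion factor equals `field_mhz`.
#'
#' @param ppm Strictly monotone ppm axis.
#' @param intensity Intensities (arbitrary units), same length as `ppm`.
#' @param field_mhz 19F frequency in MHz.
#' @param lb_hz Exponential line broadening already applied, in Hz.
#' @return An object of class `"spectrum1d"`.
#' @export
spectrum1d <- function(ppm, intensity, field_mhz, lb_hz = 0) {
  stopifnot(is.numeric(ppm), is.numeric(intensity),
            length(ppm) == length(intensity), length(ppm) >= 2L,
            is.numeric(field_mhz), field_mhz > 0, lb_hz >= 0)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone")
  structure(list(ppm = ppm, intensity = intensity,
                 field_mhz = field_mhz, lb_hz = lb_hz),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("1D 19F spectrum: %d points, %.3f to %.3f ppm (TFA = 0), %.3f MHz, lb = %g Hz\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              x$field_mhz, x$lb_hz))
  invisible(x)
}

#' Peak list constructor
#'
#' @param center_ppm Peak positions in ppm.
#' @param fwhm_hz Full widths at half maximum in Hz (> 0), recycled.
#' @param amplitude Peak amplitudes in arbitrary units (> 0), recycled.
#' @param label Optional residue tags (chymotrypsin numbering, e.g.
#'   `"Trp215"`), recycled.
#' @return A data frame of class `"peak_list"` with one row per peak, sorted
#'   downfield (largest ppm) first.
#' @export
peak_list <- function(center_ppm, fwhm_hz, amplitude = 1, label = NA_character_) {
  stopifnot(is.numeric(center_ppm), length(center_ppm) >= 1L,
            all(fwhm_hz > 0), all(amplitude > 0))
  out <- data.frame(center_ppm = center_ppm,
                    fwhm_hz = rep_len(fwhm_hz, length(center_ppm)),
                    amplitude = rep_len(amplitude, length(center_ppm)),
                    label = rep_len(label, length(center_ppm)))
  out <- out[order(-out$center_ppm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

# evaluate a sum of Lorentzians on a ppm axis; width w (Hz) = fwhm + lb
.lorentz_sum <- function(ppm, centers, widths_hz, amps, field_mhz) {
  y <- numeric(length(ppm))
  for (k in seq_along(centers)) {
    y <- y + amps[k] / (1 + (2 * (ppm - centers[k]) * field_mhz / widths_hz[k])^2)
  }
  y
}

# run code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a 1D 19F spectrum from a peak list
#'
#' Builds a frequency-domain spectrum as a sum of Lorentzian lines
#' `L(d) = A / (1 + (2 (d - d0) field / w)^2)` with effective width
#' `w = fwhm_hz + lb_hz` (an ideal exponential apodization adds `lb_hz` to
#' the Lorentzian FWHM), plus optional additive Gaussian noise. Deterministic
#' for a fixed `seed`.
#'
#' @param peaks A [peak_list()] (may be empty via `peaks = NULL`).
#' @param ppm_range Length-2 axis range; default `c(-40, -54)` (stored
#'   downfield to upfield).
#' @param n_points Number of axis points (default 2^14).
#' @param field_mhz 19F frequency in MHz (default 658.780).
#' @param noise_sigma Gaussian noise standard deviation, arbitrary units.
#' @param lb_hz Exponential line broadening in Hz (default 20, the standard
#'   processing value for these samples).
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @return A [spectrum1d()].
#' @examples
#' pk <- peak_list(c(-43.5, -46.7), fwhm_hz = 32.7)
#' sp <- simulate_spectrum(pk, noise_sigma = 0)
#' @export
simulate_spectrum <- function(peaks, ppm_range = c(-40, -54),
                              n_points = 2^14, field_mhz = 658.780,
                              noise_sigma = 0.01, lb_hz = 20, seed = NULL) {
  stopifnot(length(ppm_range) == 2L, n_points >= 2L, noise_sigma >= 0,
            lb_hz >= 0)
  hi <- max(ppm_range); lo <- min(ppm_range)
  ppm <- seq(hi, lo, length.out = n_points)   # downfield -> upfield
  if (is.null(peaks) || nrow(peaks) == 0L) {
    y <- numeric(n_points)
  } else {
    if (any(peaks$center_ppm > hi | peaks$center_ppm < lo))
      stop("axis does not cover all peak centers")
    y <- .lorentz_sum(ppm, peaks$center_ppm, peaks$fwhm_hz + lb_hz,
                      peaks$amplitude, field_mhz)
  }
  if (noise_sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(n_points, sd = noise_sigma))
  spectrum1d(ppm, y, field_mhz, lb_hz)
}

#' Pick peaks in a 1D spectrum
#'
#' Identifies strict local maxima above an intensity threshold, merges maxima
#' closer than `min_separation_ppm` (keeping the taller), and estimates each
#' peak's FWHM by linear interpolation of the half-height crossings.
#'
#' @param s A [spectrum1d()].
#' @param threshold_frac Intensity threshold as a fraction of the spectrum
#'   maximum (default 0.01).
#' @param min_separation_ppm Minimum separation between reported peaks
#'   (default 0.05 ppm).
#' @return A [peak_list()] sorted downfield to upfield; empty (0 rows) for a
#'   flat spectrum.
#' @export
pick_peaks <- function(s, threshold_frac = 0.01, min_separation_ppm = 0.05) {
  stopifnot(inherits(s, "spectrum1d"))
  y <- s$intensity
  ppm <- s$ppm
  n <- length(y)
  ymax <- max(y)
  empty <- data.frame(center_ppm = numeric(0), fwhm_hz = numeric(0),
                      amplitude = numeric(0), label = character(0))
  class(empty) <- c("peak_list", "data.frame")
  if (ymax <= 0 || all(y == y[1])) return(empty)
  thr <- threshold_frac * ymax
  i <- 2:(n - 1)
  # ">=" on the right so a maximum falling exactly between two grid points
  # (two-point plateau) is still detected, once
  is_max <- y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] >= thr
  idx <- i[is_max]
  if (length(idx) == 0L) return(empty)
  # merge close maxima, keeping the taller
  idx <- idx[order(-y[idx])]
  keep <- integer(0)
  for (j in idx) {
    if (all(abs(ppm[j] - ppm[keep]) >= min_separation_ppm)) keep <- c(keep, j)
  }
  keep <- sort(keep)

  fwhm_ppm <- vapply(keep, function(j) .half_height_width(ppm, y, j), numeric(1))
  out <- data.frame(center_ppm = ppm[keep],
                    fwhm_hz = fwhm_ppm * s$field_mhz,
                    amplitude = y[keep],
                    label = NA_character_)
  out <- out[order(-out$center_ppm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

# FWHM (ppm) of the local maximum at index j by half-height interpolation
.half_height_width <- function(ppm, y, j) {
  half <- y[j] / 2
  n <- length(y)
  left <- NA_real_; right <- NA_real_
  k <- j
  while (k > 1L && y[k - 1] > half) k <- k - 1L
  if (k > 1L) {
    t <- (y[k] - half) / (y[k] - y[k - 1])
    left <- ppm[k] + t * (ppm[k - 1] - ppm[k])
  }
  k <- j
  while (k < n && y[k + 1] > half) k <- k + 1L
  if (k < n) {
    t <- (y[k] - half) / (y[k] - y[k + 1])
    right <- ppm[k] + t * (ppm[k + 1] - ppm[k])
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  abs(left - right)
}

.lorentz_residuals <- function(par, ppm, y, field_mhz, n_peaks) {
  centers <- par[seq_len(n_peaks)]
  widths <- par[n_peaks + seq_len(n_peaks)]
  amps <- par[2 * n_peaks + seq_len(n_peaks)]
  y - .lorentz_sum(ppm, centers, widths, amps, field_mhz)
}

#' Least-squares Lorentzian deconvolution
#'
#' Refines the centers, widths and amplitudes of a set of Lorentzian
#' components against a spectrum by Levenberg-Marquardt least squares.
#' Non-convergence after jittered restarts is flagged in the result rather
#' than raised.
#'
#' @param s A [spectrum1d()].
#' @param initial A [peak_list()] of starting components; centers must lie
#'   inside the axis. Note the fitted `fwhm_hz` is the *effective* width on
#'   the spectrum (including any applied line broadening).
#' @param n_restarts Number of jittered restarts tried on non-convergence.
#' @return A list of class `"lorentz_fit"`: `peaks` (refined [peak_list()]),
#'   `residual_rms`, `converged`, `n_restarts_used`.
#' @export
fit_lorentzians <- function(s, initial, n_restarts = 3) {
  stopifnot(inherits(s, "spectrum1d"), nrow(initial) >= 1L)
  rng <- range(s$ppm)
  if (any(initial$center_ppm < rng[1] | initial$center_ppm > rng[2]))
    stop("initial peak centers must lie inside the spectrum axis")
  np <- nrow(initial)
  par0 <- c(initial$center_ppm, initial$fwhm_hz + s$lb_hz, initial$amplitude)
  lower <- c(rep(rng[1], np), rep(1e-6, np), rep(1e-12, np))
  upper <- c(rep(rng[2], np), rep(Inf, 2 * np))

  run <- function(par) {
    minpack.lm::nls.lm(par = par, fn = .lorentz_residuals,
                       ppm = s$ppm, y = s$intensity,
                       field_mhz = s$field_mhz, n_peaks = np,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  }
  fit <- run(par0)
  tries <- 0L
  while (!(fit$info %in% 1:4) && tries < n_restarts) {
    tries <- tries + 1L
    jit <- par0 * (1 + stats::runif(length(par0), -0.05, 0.05))
    jit <- pmin(pmax(jit, lower), upper)
    cand <- run(jit)
    if (sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  pars <- fit$par
  peaks <- data.frame(center_ppm = pars[seq_len(np)],
                      fwhm_hz = pars[np + seq_len(np)],
                      amplitude = pars[2 * np + seq_len(np)],
                      label = initial$label)
  peaks <- peaks[order(-peaks$center_ppm), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_list", "data.frame")
  list(peaks = peaks,
       residual_rms = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:4,
       n_restarts_used = tries)
}

#' Mutant-difference resonance assignment
#'
#' Locates the spectral regions perturbed by a point substitution (the basis
#' of Trp-to-Phe difference assignment): contiguous ppm intervals where the
#' absolute wild-type minus mutant difference exceeds a noise-derived
#' threshold, each annotated with the position of the extremal difference.
#'
#' The noise level is estimated as the standard deviation of the difference
#' over the 10% most upfield (signal-free) end of the axis; the threshold is
#' `max(sigma_mult * sigma_hat, min_frac * max|difference|)`. The `min_frac`
#' floor keeps the operation well-posed on noiseless synthetic spectra,
#' where Lorentzian tails are nonzero over the whole axis.
#'
#' @param wt,mutant Two [spectrum1d()] objects on identical axes and fields.
#' @param sigma_mult Noise threshold multiplier (default 3).
#' @param min_frac Threshold floor as a fraction of the maximum absolute
#'   difference (default 0.01).
#' @param min_width_ppm Minimum width of a reported region (default 0.02
#'   ppm). A genuine perturbation spans an appreciable fraction of a
#'   linewidth; isolated supra-threshold noise points do not and are
#'   discarded.
#' @return A data frame with one row per perturbed region, columns
#'   `ppm_from` (downfield edge), `ppm_to` (upfield edge), `ppm_extremum`
#'   (position of maximal absolute difference) and `max_abs_diff`, sorted
#'   downfield to upfield; zero rows when the spectra are identical.
#' @export
assign_by_difference <- function(wt, mutant, sigma_mult = 3, min_frac = 0.01,
                                 min_width_ppm = 0.02) {
  stopifnot(inherits(wt, "spectrum1d"), inherits(mutant, "spectrum1d"))
  if (length(wt$ppm) != length(mutant$ppm) ||
      max(abs(wt$ppm - mutant$ppm)) > 1e-9 ||
      abs(wt$field_mhz - mutant$field_mhz) > 1e-6)
    stop("spectra must share the same axis and field")
  d <- wt$intensity - mutant$intensity
  empty <- data.frame(ppm_from = numeric(0), ppm_to = numeric(0),
                      ppm_extremum = numeric(0), max_abs_diff = numeric(0))
  dmax <- max(abs(d))
  if (dmax == 0) return(empty)
  # noise from the most upfield (lowest ppm) tenth of the axis
  ord <- order(wt$ppm)
  n_tail <- max(2L, floor(length(d) * 0.1))
  sig <- stats::sd(d[ord[seq_len(n_tail)]])
  thr <- max(sigma_mult * sig, min_frac * dmax)
  above <- abs(d) > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  step <- stats::median(abs(diff(wt$ppm)))
  # merge runs separated by sub-linewidth gaps (noise dips inside a region)
  if (nrow(regions) > 1L) {
    merged <- regions[1, , drop = FALSE]
    for (k in 2:nrow(regions)) {
      gap <- (regions[k, 1] - merged[nrow(merged), 2]) * step
      if (gap < min_width_ppm) merged[nrow(merged), 2] <- regions[k, 2]
      else merged <- rbind(merged, regions[k, ])
    }
    regions <- merged
  }
  width_ok <- (regions[, 2] - regions[, 1] + 1L) * step >= min_width_ppm
  regions <- regions[width_ok, , drop = FALSE]
  if (nrow(regions) == 0L) return(empty)
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(k) {
    i1 <- regions[k, 1]; i2 <- regions[k, 2]
    seg <- i1:i2
    j <- seg[which.max(abs(d[seg]))]
    data.frame(ppm_from = max(wt$ppm[i1], wt$ppm[i2]),
               ppm_to = min(wt$ppm[i1], wt$ppm[i2]),
               ppm_extremum = wt$ppm[j],
               max_abs_diff = abs(d[j]))
  }))
  out <- out[order(-out$ppm_extremum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write a spectrum as headered text
#'
#' Plain-text spectrum format: `# key=value` header lines (`field_mhz`,
#' `lb_hz`, `reference=TFA`) followed by two CSV columns `ppm,intensity`.
#'
#' @param s A [spectrum1d()].
#' @param path File path.
#' @return `read_spectrum()`: a [spectrum1d()]; `write_spectrum()`: `path`,
#'   invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# field_mhz=%.6f", s$field_mhz),
               sprintf("# lb_hz=%g", s$lb_hz),
               "# reference=TFA",
               "ppm,intensity"), con)
  utils::write.table(data.frame(s$ppm, s$intensity), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  get_key <- function(key, default = NA) {
    m <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(m) == 0L) return(default)
    sub(paste0("^", key, "="), "", m[1])
  }
  field <- as.numeric(get_key("field_mhz"))
  lb <- as.numeric(get_key("lb_hz", "0"))
  if (is.na(field)) stop("spectrum file lacks a field_mhz header")
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "" & !grepl("^ppm", body)]
  d <- utils::read.csv(text = body, header = FALSE,
                       col.names = c("ppm", "intensity"))
  spectrum1d(d$ppm, d$intensity, field, lb)
}
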
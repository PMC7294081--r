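#' Two-site chemical exchange system
#'
#' Bundles the microscopic parameters of a two-state (A <-> B) conformational
#' exchange process as seen by a single 19F reporter: state populations,
#' exchange rate, chemical-shift separation and the intrinsic (exchange-free)
#' transverse relaxation rate of each state.
#'
#' The angular shift difference used internally is
#' `delta_omega = 2 * pi * field_mhz * delta_omega_ppm` (rad/s), i.e. linear
#' in the static field.
#'
#' @param pA Population fraction of state A (0 to 1); `pB = 1 - pA`.
#' @param kex Exchange rate `kAB + kBA` in 1/s (non-negative).
#' @param delta_omega_ppm Chemical-shift difference between the two states in
#'   ppm.
#' @param r2a0,r2b0 Intrinsic transverse relaxation rates of states A and B in
#'   1/s (positive).
#' @param field_mhz 19F Larmor frequency in MHz (positive).
#' @return An object of class `"exchange_system"`.
#' @seealso [bloch_mcconnell_r2eff()], [luz_meiboom_r2()]
#' @export
exchange_system <- function(pA, kex, delta_omega_ppm, r2a0, r2b0, field_mhz) {
  stopifnot(is.numeric(pA), length(pA) == 1L, pA >= 0, pA <= 1,
            is.numeric(kex), length(kex) == 1L, kex >= 0,
            is.numeric(delta_omega_ppm), length(delta_omega_ppm) == 1L,
            is.numeric(r2a0), r2a0 > 0, is.numeric(r2b0), r2b0 > 0,
            is.numeric(field_mhz), field_mhz > 0)
  structure(list(pA = pA, kex = kex, delta_omega_ppm = delta_omega_ppm,
                 r2a0 = r2a0, r2b0 = r2b0, field_mhz = field_mhz),
            class = "exchange_system")
}

#' @export
print.exchange_system <- function(x, ...) {
  cat("Two-site exchange system\n")
  cat(sprintf("  pA = %.4f, pB = %.4f\n", x$pA, 1 - x$pA))
  cat(sprintf("  kex = %.6g 1/s\n", x$kex))
  cat(sprintf("  delta_omega = %.4g ppm (%.6g rad/s at %.3f MHz)\n",
              x$delta_omega_ppm, delta_omega_rad(x), x$field_mhz))
  cat(sprintf("  R2A0 = %.6g, R2B0 = %.6g 1/s\n", x$r2a0, x$r2b0))
  invisible(x)
}

# angular shift difference in rad/s
delta_omega_rad <- function(sys) {
  2 * pi * sys$field_mhz * sys$delta_omega_ppm
}

#' Identifiable parameter set of the fast-exchange dispersion model
#'
#' In the fast-exchange limit (`kex >> delta_omega`), a two-site CPMG
#' dispersion curve only constrains the exchange rate `kex`, the exchange
#' amplitude `phi_ex = pA * pB * delta_omega^2` (rad^2/s^2), and a per-field
#' plateau rate `R2^0`. `phi_ex` scales with the square of the static field;
#' it is stored at a declared reference field and rescaled on evaluation.
#'
#' @param kex Exchange rate in 1/s, shared across fields (positive).
#' @param phi_ex_ref Exchange amplitude `pA*pB*delta_omega^2` at
#'   `ref_field_mhz`, in 1/s^2 (non-negative).
#' @param r20_by_field Named numeric vector of plateau rates `R2^0` (1/s),
#'   one per field; names are the 19F frequencies in MHz (e.g. `"564.686"`).
#' @param ref_field_mhz Reference field for `phi_ex_ref`, in MHz.
#' @return An object of class `"fast_exchange_params"`.
#' @export
fast_exchange_params <- function(kex, phi_ex_ref, r20_by_field, ref_field_mhz) {
  stopifnot(is.numeric(kex), length(kex) == 1L, kex > 0,
            is.numeric(phi_ex_ref), length(phi_ex_ref) == 1L, phi_ex_ref >= 0,
            is.numeric(r20_by_field), length(r20_by_field) >= 1L,
            all(r20_by_field > 0), !is.null(names(r20_by_field)),
            is.numeric(ref_field_mhz), ref_field_mhz > 0)
  structure(list(kex = kex, phi_ex_ref = phi_ex_ref,
                 r20_by_field = r20_by_field,
                 ref_field_mhz = ref_field_mhz),
            class = "fast_exchange_params")
}

#' @export
print.fast_exchange_params <- function(x, ...) {
  cat("Fast-exchange (Luz-Meiboom) parameters\n")
  cat(sprintf("  kex     = %.6g 1/s\n", x$kex))
  cat(sprintf("  phi_ex  = %.6g 1/s^2 at %.3f MHz\n",
              x$phi_ex_ref, x$ref_field_mhz))
  for (f in names(x$r20_by_field))
    cat(sprintf("  R2^0(%s MHz) = %.6g 1/s\n", f, x$r20_by_field[[f]]))
  invisible(x)
}

# locate the R2^0 entry for a numeric field, tolerant of name formatting
match_field_r20 <- function(params, field) {
  fields <- as.numeric(names(params$r20_by_field))
  i <- which(abs(fields - field) < 1e-6 * field)
  if (length(i) != 1L) return(NA_real_)
  unname(params$r20_by_field[[i]])
}

#' Effective transverse relaxation rate in the fast-exchange limit
#'
#' Closed-form (Luz-Meiboom) effective rate of a two-site system under a CPMG
#' train, valid when `kex` greatly exceeds the shift difference:
#' \deqn{R_{2,eff}(\nu) = R_2^0 + \frac{\Phi_{ex}}{k_{ex}}
#'   \left[1 - \frac{4\nu}{k_{ex}} \tanh\!\frac{k_{ex}}{4\nu}\right]}
#' with `phi_ex` rescaled to the requested field by the squared field ratio.
#' The curve decreases monotonically from `R2^0 + phi_ex/kex` (slow pulsing)
#' to `R2^0` (fast pulsing).
#'
#' The CPMG frequency convention throughout the package is
#' `nu_cpmg = 1 / (4 * tau_cp)`, where `2 * tau_cp` is the delay between
#' successive 180-degree pulses.
#'
#' @param params A [fast_exchange_params()] object.
#' @param nu CPMG frequency (or vector of frequencies) in Hz; must be > 0.
#' @param field 19F frequency in MHz at which to evaluate.
#' @param r20 Optional plateau rate override in 1/s; required when `field` is
#'   not present in `params$r20_by_field`.
#' @return Numeric vector of effective rates R2eff in 1/s, same length as
#'   `nu`.
#' @examples
#' p <- fast_exchange_params(kex = 2970, phi_ex_ref = 3e5,
#'                           r20_by_field = c("564.686" = 204),
#'                           ref_field_mhz = 564.686)
#' luz_meiboom_r2(p, nu = c(25, 200, 2000), field = 564.686)
#' @export
luz_meiboom_r2 <- function(params, nu, field, r20 = NULL) {
  stopifnot(inherits(params, "fast_exchange_params"),
            is.numeric(nu), length(nu) >= 1L,
            is.numeric(field), length(field) == 1L, field > 0)
  if (any(nu <= 0)) stop("CPMG frequencies `nu` must be positive")
  if (is.null(r20)) {
    r20 <- match_field_r20(params, field)
    if (is.na(r20))
      stop(sprintf("no R2^0 declared for field %.3f MHz; supply `r20`", field))
  }
  phi <- params$phi_ex_ref * (field / params$ref_field_mhz)^2
  x <- params$kex / (4 * nu)
  r20 + (phi / params$kex) * (1 - tanh(x) / x)
}

#' CPMG schedule
#'
#' Describes a constant-time CPMG experiment: the set of CPMG frequencies and
#' the total relaxation period. The convention is `nu_cpmg = 1/(4 * tau_cp)`
#' with `2 * tau_cp` the inter-180-pulse delay; the number of 180-degree
#' pulses spent in `t_relax` is `n = 2 * t_relax * nu_cpmg`, rounded to a
#' positive even integer (so the echo train ends refocused).
#'
#' @param nu_cpmg Strictly increasing vector of CPMG frequencies in Hz (> 0).
#' @param t_relax Total relaxation period in s (default 0.04).
#' @return An object of class `"cpmg_schedule"` with elements `nu_cpmg`,
#'   `t_relax`, `tau_cp` (half echo delays, s) and `n_pulses`.
#' @export
cpmg_schedule <- function(nu_cpmg, t_relax = 0.04) {
  stopifnot(is.numeric(nu_cpmg), length(nu_cpmg) >= 1L)
  if (any(nu_cpmg <= 0)) stop("nu_cpmg must be positive")
  if (is.unsorted(nu_cpmg, strictly = TRUE))
    stop("nu_cpmg must be strictly increasing")
  if (!is.numeric(t_relax) || length(t_relax) != 1L || t_relax <= 0)
    stop("t_relax must be a single positive number")
  n <- pmax(2L, 2L * as.integer(round(t_relax * nu_cpmg)))
  structure(list(nu_cpmg = nu_cpmg, t_relax = t_relax,
                 tau_cp = t_relax / (2 * n), n_pulses = n),
            class = "cpmg_schedule")
}

# expm of a 2x2 complex matrix via eigendecomposition
expm2 <- function(m) {
  e <- eigen(m)
  e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors)
}

#' Numerical CPMG dispersion curve from the Bloch-McConnell equations
#'
#' Propagates the transverse magnetization of a two-site exchanging system
#' through the `tau_cp - 180 - tau_cp` blocks of a constant-time CPMG train
#' and converts the surviving signal into an effective rate,
#' `R2eff = -log(I / I0) / t_relax`. This is the package's numerical oracle:
#' it makes no timescale approximation and is used to validate (and bound the
#' error of) the fast-exchange closed form [luz_meiboom_r2()].
#'
#' Free evolution of the coherence vector `(MA+, MB+)` follows a 2x2 complex
#' Liouvillian with shift offsets at `+/- delta_omega/2`, per-state intrinsic
#' relaxation and first-order exchange (`kAB = pB*kex`, `kBA = pA*kex`);
#' ideal 180-degree pulses act as complex conjugation. The detected amplitude
#' is `|MA + MB|` at the end of the train.
#'
#' @param sys An [exchange_system()].
#' @param sched A [cpmg_schedule()].
#' @return A [dispersion_curve()] data frame with one R2eff per `nu_cpmg`.
#'   Points where the surviving signal underflows (`I/I0 < 1e-12`) are
#'   flagged in the logical column `underflow` and their R2eff set to `NA`.
#' @examples
#' sys <- exchange_system(pA = 0.9, kex = 3000, delta_omega_ppm = 0.05,
#'                        r2a0 = 200, r2b0 = 200, field_mhz = 564.686)
#' bloch_mcconnell_r2eff(sys, cpmg_schedule(c(50, 200, 1000)))
#' @export
bloch_mcconnell_r2eff <- function(sys, sched) {
  stopifnot(inherits(sys, "exchange_system"), inherits(sched, "cpmg_schedule"))
  r2 <- vapply(seq_along(sched$nu_cpmg), function(i) {
    I <- bloch_mcconnell_intensity(sys, sched$tau_cp[i], sched$n_pulses[i])
    -log(I) / sched$t_relax
  }, numeric(1))
  under <- is.finite(r2) & (-r2 * sched$t_relax < log(1e-12))
  under[!is.finite(r2)] <- TRUE
  r2[under] <- NA_real_
  dc <- dispersion_curve(field_mhz = sys$field_mhz, nu_cpmg = sched$nu_cpmg,
                         r2eff = r2)
  dc$underflow <- under
  dc
}

# surviving relative signal |MA+MB| after n pulses with half-delay tau
bloch_mcconnell_intensity <- function(sys, tau, n) {
  pB <- 1 - sys$pA
  dw <- delta_omega_rad(sys)
  kAB <- sys$kex * pB
  kBA <- sys$kex * sys$pA
  L <- matrix(c(-1i * (dw / 2) - sys$r2a0 - kAB, kAB,
                kBA, 1i * (dw / 2) - sys$r2b0 - kBA),
              nrow = 2)
  P <- expm2(L * tau)
  M <- c(sys$pA, pB)
  for (j in seq_len(n)) M <- P %*% Conj(P %*% M)
  Mod(sum(M))
}

#' Effective rate from constant-time signal intensities
#'
#' Standard constant-time CPMG conversion `R2eff = -log(i / i0) / t_relax`,
#' where `i0` is the reference intensity recorded without the relaxation
#' period.
#'
#' @param i Signal intensity after the relaxation period (> 0); vectorized.
#' @param i0 Reference intensity (> 0).
#' @param t_relax Constant relaxation time in s (> 0).
#' @return R2eff in 1/s.
#' @export
r2eff_from_intensities <- function(i, i0, t_relax) {
  if (!is.numeric(t_relax) || length(t_relax) != 1L || t_relax <= 0)
    stop("t_relax must be a single positive number")
  if (any(!is.numeric(i) | i <= 0) || any(!is.numeric(i0) | i0 <= 0))
    stop("intensities must be positive")
  -log(i / i0) / t_relax
}
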
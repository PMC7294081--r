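#' Relaxation series container
#'
#' A set of (delay, intensity) observations from a T1 inversion-recovery or
#' T2 CPMG-decay experiment, optionally with per-point uncertainties and a
#' replicate tag (acquisitions are typically collected in duplicate on a
#' shared delay grid).
#'
#' @param kind `"inversion_recovery"` or `"cpmg_decay"`.
#' @param times Delays (T1) or spin-echo evolution times (T2) in s; strictly
#'   increasing within each replicate.
#' @param intensities Signal intensities (arbitrary units).
#' @param sigma Optional per-point standard deviations.
#' @param replicate_id Integer replicate tag, recycled (default 1).
#' @return A data frame of class `"relaxation_series"` with columns
#'   `time_s`, `intensity`, `sigma`, `replicate_id` and attribute `kind`.
#' @export
relaxation_series <- function(kind = c("inversion_recovery", "cpmg_decay"),
                              times, intensities, sigma = NULL,
                              replicate_id = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(times), is.numeric(intensities),
            length(times) == length(intensities), all(times >= 0))
  rep_id <- rep_len(as.integer(replicate_id), length(times))
  for (r in unique(rep_id)) {
    tt <- times[rep_id == r]
    if (is.unsorted(tt, strictly = TRUE))
      stop("times must be strictly increasing within each replicate")
  }
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(times), all(sigma > 0))
  } else sigma <- rep(NA_real_, length(times))
  out <- data.frame(time_s = times, intensity = intensities, sigma = sigma,
                    replicate_id = rep_id)
  attr(out, "kind") <- kind
  class(out) <- c("relaxation_series", "data.frame")
  out
}

#' Read/write relaxation series as CSV
#'
#' Columns: `kind`, `replicate_id`, `time_s`, `intensity`, `sigma`.
#'
#' @param series A [relaxation_series()].
#' @param path File path.
#' @return `read_relaxation()`: a [relaxation_series()];
#'   `write_relaxation()`: `path`, invisibly.
#' @export
write_relaxation <- function(series, path) {
  stopifnot(inherits(series, "relaxation_series"))
  d <- data.frame(kind = attr(series, "kind"),
                  replicate_id = series$replicate_id,
                  time_s = series$time_s, intensity = series$intensity,
                  sigma = series$sigma)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_relaxation
#' @export
read_relaxation <- function(path) {
  d <- utils::read.csv(path)
  d <- d[order(d$replicate_id, d$time_s), ]
  sg <- if (all(is.finite(d$sigma))) d$sigma else NULL
  relaxation_series(d$kind[1], d$time_s, d$intensity, sigma = sg,
                    replicate_id = d$replicate_id)
}

# shared weighted-LM wrapper returning par, stderr, chi2, dof
.relax_lm <- function(par0, resid_fn, lower, upper, n_points, weighted) {
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  chi2 <- sum(fit$fvec^2)
  dof <- n_points - length(par0)
  cov <- .pinv(fit$hessian)
  s2 <- if (weighted) 1 else chi2 / max(1L, dof)
  se <- sqrt(pmax(diag(cov), 0) * s2)
  list(fit = fit, chi2 = chi2, dof = dof, stderr = se)
}

#' Fit a T1 inversion-recovery series
#'
#' Three-parameter exponential recovery
#' `I(t) = I_inf * (1 - 2 f exp(-t / T1))`, with the inversion efficiency
#' `f` bounded to `[0.5, 1]` (`f = 1` is perfect inversion, `f = 0.5` the
#' saturation-recovery limit, whose null time is 0). With `f = 1` the fitted
#' curve crosses zero at `t_null = T1 * log(2)`.
#'
#' @param series A [relaxation_series()] of kind `"inversion_recovery"` with
#'   at least 4 points. Weighted least squares when `sigma` is present.
#' @param f_init Starting inversion efficiency (default 0.98).
#' @return A list of class `"relaxation_fit"`: `rate` (1/T1, 1/s), `t1`,
#'   `i_inf`, `f`, `stderr` (named), `chi2`, `dof`, `kind`, `flags`.
#' @export
fit_inversion_recovery <- function(series, f_init = 0.98) {
  stopifnot(inherits(series, "relaxation_series"))
  if (!identical(attr(series, "kind"), "inversion_recovery"))
    stop("series is not an inversion-recovery experiment")
  if (nrow(series) < 4L) stop("need at least 4 points")
  t <- series$time_s; y <- series$intensity
  # a recovery must trend upward; a monotone-decreasing series is the wrong model
  agg <- stats::aggregate(y, list(t = t), mean)
  if (all(diff(agg$x) < 0))
    stop("series decreases monotonically; not an inversion recovery")
  weighted <- all(is.finite(series$sigma))
  w <- if (weighted) 1 / series$sigma else rep(1, nrow(series))

  i_inf0 <- max(y)
  # crude T1 from the zero crossing (t_null ~ T1 ln 2 for full inversion)
  zc <- which(diff(sign(agg$x)) > 0)
  r10 <- if (length(zc)) log(2) / max(agg$t[zc[1] + 1L], 1e-6) else
    1 / max(stats::median(t), .Machine$double.eps)
  resid_fn <- function(par) {
    w * (y - par[2] * (1 - 2 * par[3] * exp(-t * par[1])))
  }
  res <- .relax_lm(c(r10, i_inf0, f_init), resid_fn,
                   lower = c(1e-9, -Inf, 0.5), upper = c(Inf, Inf, 1),
                   n_points = nrow(series), weighted = weighted)
  par <- res$fit$par
  out <- list(kind = "inversion_recovery", rate = par[1], t1 = 1 / par[1],
              i_inf = par[2], f = par[3],
              stderr = stats::setNames(res$stderr, c("rate", "i_inf", "f")),
              chi2 = res$chi2, dof = res$dof,
              converged = res$fit$info %in% 1:4, flags = character(0))
  class(out) <- "relaxation_fit"
  out
}

#' Fit a T2 CPMG-decay series
#'
#' Mono-exponential decay `I(t) = I0 * exp(-t / T2)`, initialized from a
#' log-linear regression and refined by (optionally weighted) least squares.
#' A series that does not decay within tolerance is returned with a
#' `"non-relaxing"` flag and a rate approaching zero rather than an error.
#'
#' @param series A [relaxation_series()] of kind `"cpmg_decay"` with at
#'   least 3 strictly positive intensities.
#' @return A list of class `"relaxation_fit"`: `rate` (1/T2), `t2`, `i0`,
#'   `stderr`, `chi2`, `dof`, `flags`.
#' @export
fit_cpmg_decay <- function(series) {
  stopifnot(inherits(series, "relaxation_series"))
  if (!identical(attr(series, "kind"), "cpmg_decay"))
    stop("series is not a CPMG decay experiment")
  if (nrow(series) < 3L) stop("need at least 3 points")
  t <- series$time_s; y <- series$intensity
  if (any(y <= 0)) stop("CPMG decay intensities must be positive")
  weighted <- all(is.finite(series$sigma))
  w <- if (weighted) 1 / series$sigma else rep(1, nrow(series))

  ll <- stats::lm(log(y) ~ t)
  r20 <- max(-unname(stats::coef(ll)[2]), 1e-9)
  i00 <- exp(unname(stats::coef(ll)[1]))
  resid_fn <- function(par) w * (y - par[2] * exp(-t * par[1]))
  res <- .relax_lm(c(r20, i00), resid_fn,
                   lower = c(0, 1e-12), upper = c(Inf, Inf),
                   n_points = nrow(series), weighted = weighted)
  par <- res$fit$par
  flags <- character(0)
  if (par[1] * max(t) < 1e-3) flags <- "non-relaxing"
  out <- list(kind = "cpmg_decay", rate = par[1],
              t2 = if (par[1] > 0) 1 / par[1] else Inf, i0 = par[2],
              stderr = stats::setNames(res$stderr, c("rate", "i0")),
              chi2 = res$chi2, dof = res$dof,
              converged = res$fit$info %in% 1:4, flags = flags)
  class(out) <- "relaxation_fit"
  out
}

#' @export
print.relaxation_fit <- function(x, ...) {
  lab <- if (x$kind == "inversion_recovery") "T1" else "T2"
  cat(sprintf("%s fit: rate = %.6g +/- %.3g 1/s (%s = %.6g s)\n",
              lab, x$rate, x$stderr[["rate"]], lab, 1 / x$rate))
  if (x$kind == "inversion_recovery")
    cat(sprintf("  I_inf = %.6g, f = %.4f\n", x$i_inf, x$f))
  else
    cat(sprintf("  I0 = %.6g\n", x$i0))
  cat(sprintf("  chi2 = %.4g (dof %d)\n", x$chi2, x$dof))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
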
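#' CPMG relaxation-dispersion curve
#'
#' One dispersion experiment: effective transverse rates as a function of
#' CPMG frequency at a single static field, optionally with per-point
#' uncertainties.
#'
#' @param field_mhz 19F frequency in MHz.
#' @param nu_cpmg Strictly increasing CPMG frequencies in Hz.
#' @param r2eff Effective rates in 1/s, same length as `nu_cpmg`.
#' @param sigma Optional per-point standard deviations in 1/s.
#' @param label Optional residue/protein tag (e.g. `"prethrombin2_W51"`).
#' @return A data frame of class `"dispersion_curve"` with columns
#'   `field_mhz`, `nu_cpmg`, `r2eff`, `sigma` and attribute `label`.
#' @export
dispersion_curve <- function(field_mhz, nu_cpmg, r2eff, sigma = NULL,
                             label = NULL) {
  stopifnot(is.numeric(field_mhz), length(field_mhz) == 1L, field_mhz > 0,
            is.numeric(nu_cpmg), is.numeric(r2eff),
            length(nu_cpmg) == length(r2eff))
  if (is.unsorted(nu_cpmg, strictly = TRUE))
    stop("nu_cpmg must be strictly increasing")
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(nu_cpmg), all(sigma > 0))
  } else {
    sigma <- rep(NA_real_, length(nu_cpmg))
  }
  out <- data.frame(field_mhz = field_mhz, nu_cpmg = nu_cpmg,
                    r2eff = r2eff, sigma = sigma)
  attr(out, "label") <- label
  class(out) <- c("dispersion_curve", "data.frame")
  out
}

#' Read/write dispersion curves as CSV
#'
#' The on-disk format is a plain CSV with header columns `field_mhz`,
#' `nu_cpmg_hz`, `r2eff_s1`, `sigma_s1` (empty `sigma_s1` permitted). A file
#' may hold several fields; `read_dispersion()` returns one
#' [dispersion_curve()] per field.
#'
#' @param curves A single [dispersion_curve()] or a list of them.
#' @param path File path.
#' @return `read_dispersion()`: a list of [dispersion_curve()] objects;
#'   `write_dispersion()`: `path`, invisibly.
#' @export
write_dispersion <- function(curves, path) {
  if (inherits(curves, "dispersion_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(dc) {
    data.frame(field_mhz = dc$field_mhz, nu_cpmg_hz = dc$nu_cpmg,
               r2eff_s1 = dc$r2eff, sigma_s1 = dc$sigma)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dispersion
#' @export
read_dispersion <- function(path) {
  d <- utils::read.csv(path)
  need <- c("field_mhz", "nu_cpmg_hz", "r2eff_s1")
  if (!all(need %in% names(d)))
    stop("dispersion CSV must have columns field_mhz, nu_cpmg_hz, r2eff_s1")
  lapply(split(d, d$field_mhz), function(g) {
    g <- g[order(g$nu_cpmg_hz), ]
    sg <- if ("sigma_s1" %in% names(g) && all(is.finite(g$sigma_s1)))
      g$sigma_s1 else NULL
    dispersion_curve(g$field_mhz[1], g$nu_cpmg_hz, g$r2eff_s1, sigma = sg)
  })
}

# Moore-Penrose pseudo-inverse; near-singular Hessians (weak dispersion)
# otherwise make solve() fail or return negative variances
.pinv <- function(m, tol = 1e-12) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  di <- ifelse(pos, 1 / s$d, 0)
  s$v %*% (di * t(s$u))
}

# shape function g(nu; kex) multiplying phi_ex/kex in the closed form
.lm_shape <- function(nu, kex) {
  x <- kex / (4 * nu)
  (1 - tanh(x) / x) / kex
}

# stack curves into one fitting table with a field index
.stack_curves <- function(curves) {
  if (inherits(curves, "dispersion_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L)
  d <- do.call(rbind, lapply(curves, function(dc) as.data.frame(dc)))
  fields <- sort(unique(d$field_mhz))
  d$fidx <- match(d$field_mhz, fields)
  list(data = d, fields = fields)
}

# given kex, solve phi and per-field R2^0 by weighted linear least squares
.linear_solve_given_kex <- function(d, fields, ref_field, kex, w) {
  scale2 <- (d$field_mhz / ref_field)^2
  g <- .lm_shape(d$nu_cpmg, kex) * scale2
  X <- cbind(g, outer(d$fidx, seq_along(fields), `==`) + 0)
  fit <- stats::lm.wfit(X, d$r2eff, w = w)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(phi = max(0, beta[1]), r20 = pmax(1e-12, beta[-1]))
}

.disp_residuals <- function(par, d, fields, ref_field, w) {
  kex <- par[1]
  phi <- par[2]
  r20 <- par[-(1:2)]
  pred <- r20[d$fidx] + phi * (d$field_mhz / ref_field)^2 *
    .lm_shape(d$nu_cpmg, kex)
  sqrt(w) * (d$r2eff - pred)
}

#' Global two-field fast-exchange dispersion fit
#'
#' Fits one or more dispersion curves (typically the same residue recorded at
#' two static fields) jointly to the fast-exchange closed form of
#' [luz_meiboom_r2()]: a single exchange rate `kex` shared across fields, one
#' plateau rate `R2^0` per field, and one exchange amplitude `phi_ex`
#' referenced to the lowest field and tied to the other fields by the squared
#' field ratio.
#'
#' The optimizer is Levenberg-Marquardt (`minpack.lm::nls.lm`) started from a
#' log-spaced grid of `kex` values spanning 1e2-1e6 1/s; at each start the
#' amplitude and plateaus (which enter the model linearly once `kex` is
#' fixed) are solved exactly by weighted linear least squares. The lowest
#' chi-square solution is returned, with ties (delta chi-square < 1e-6)
#' broken toward smaller `kex`. Points are weighted `1/sigma^2` when
#' uncertainties are present, unweighted otherwise.
#'
#' Identifiability is checked after the fit: when the fitted dispersion
#' amplitude `phi_ex/kex` is below twice the median point uncertainty the
#' result carries a `"no dispersion"` flag and `kex` must be regarded as
#' unconstrained.
#'
#' @param curves A [dispersion_curve()] or list of them covering >= 1 field;
#'   all curves must refer to the same residue.
#' @param kex_grid Multistart grid for `kex` in 1/s; default 9 log-spaced
#'   values from 1e2 to 1e6.
#' @param ref_field_mhz Field at which `phi_ex` is referenced (default the
#'   lowest field present). The choice is a pure reparameterization: `kex`,
#'   the plateau rates and the chi-square are unchanged by it.
#' @return An object of class `"dispersion_fit"`: a list with elements
#'   `params` ([fast_exchange_params()]), `stderr` (named vector), `chi2`,
#'   `chi2_reduced`, `dof`, `n_restarts`, `converged`, `flags` (character)
#'   and `data` (the stacked fitting table).
#' @examples
#' p <- fast_exchange_params(2970, 3e5,
#'        c("564.686" = 204, "658.780" = 260), 564.686)
#' nu <- exp(seq(log(25), log(2000), length.out = 12))
#' dc <- lapply(c(564.686, 658.780), function(f)
#'   dispersion_curve(f, nu, luz_meiboom_r2(p, nu, f)))
#' fit <- fit_dispersion_global(dc)
#' fit$params$kex
#' @export
fit_dispersion_global <- function(curves,
                                  kex_grid = 10^seq(2, 6, length.out = 9),
                                  ref_field_mhz = NULL) {
  st <- .stack_curves(curves)
  d <- st$data
  fields <- st$fields
  ref_field <- if (is.null(ref_field_mhz)) min(fields) else ref_field_mhz
  n_par <- 2L + length(fields)
  if (nrow(d) <= n_par)
    stop("fewer data points than parameters; cannot fit")
  for (f in fields) {
    if (sum(d$field_mhz == f) < 4L)
      stop("each dispersion curve needs at least 4 points")
  }
  has_sigma <- all(is.finite(d$sigma))
  w <- if (has_sigma) 1 / d$sigma^2 else rep(1, nrow(d))

  best <- NULL
  for (k0 in sort(kex_grid)) {
    lin <- .linear_solve_given_kex(d, fields, ref_field, k0, w)
    par0 <- c(k0, lin$phi, lin$r20)
    fit <- try(minpack.lm::nls.lm(
      par = par0, fn = .disp_residuals,
      d = d, fields = fields, ref_field = ref_field, w = w,
      lower = c(1e-3, 0, rep(1e-9, length(fields))),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2 - 1e-6 ||
        (abs(chi2 - best$chi2) <= 1e-6 && fit$par[1] < best$fit$par[1])) {
      best <- list(fit = fit, chi2 = chi2)
    }
  }
  if (is.null(best)) stop("all multistart fits failed")

  fit <- best$fit
  kex <- fit$par[1]
  phi <- fit$par[2]
  r20 <- fit$par[-(1:2)]
  names(r20) <- formatC(fields, format = "f", digits = 3)
  dof <- nrow(d) - n_par
  chi2 <- best$chi2

  # stderr from the LM covariance; rescale by residual variance if unweighted
  cov <- .pinv(fit$hessian)
  s2 <- if (has_sigma) 1 else chi2 / max(1L, dof)
  se <- sqrt(pmax(diag(cov), 0) * s2)
  names(se) <- c("kex", "phi_ex_ref", paste0("r20_", names(r20)))

  flags <- character(0)
  amp <- phi / kex
  med_sig <- if (has_sigma) stats::median(d$sigma)
             else sqrt(chi2 / max(1L, dof))
  if (amp < 2 * med_sig) flags <- c(flags, "no dispersion")
  conv <- fit$info %in% 1:4

  structure(list(
    params = fast_exchange_params(kex, phi, r20, ref_field),
    stderr = se, chi2 = chi2, chi2_reduced = chi2 / max(1L, dof),
    dof = dof, n_restarts = length(kex_grid), converged = conv,
    flags = flags, weighted = has_sigma, data = d, fields = fields),
    class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("Global fast-exchange dispersion fit\n")
  cat(sprintf("  kex        = %.6g +/- %.3g 1/s\n", x$params$kex,
              x$stderr[["kex"]]))
  cat(sprintf("  phi_ex     = %.6g +/- %.3g 1/s^2 (at %.3f MHz)\n",
              x$params$phi_ex_ref, x$stderr[["phi_ex_ref"]],
              x$params$ref_field_mhz))
  for (f in names(x$params$r20_by_field))
    cat(sprintf("  R2^0(%s)   = %.6g 1/s\n", f, x$params$r20_by_field[[f]]))
  cat(sprintf("  chi2 = %.4g (reduced %.4g, dof %d), converged: %s\n",
              x$chi2, x$chi2_reduced, x$dof, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Flat report of a dispersion fit
#'
#' Serializes the fitted parameters, standard errors, chi-square and flags of
#' a [fit_dispersion_global()] result as a flat JSON object.
#'
#' @param fit A `"dispersion_fit"` object.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
dispersion_fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dispersion_fit"))
  rep <- c(
    list(kex = fit$params$kex, phi_ex_ref = fit$params$phi_ex_ref,
         ref_field_mhz = fit$params$ref_field_mhz),
    as.list(fit$params$r20_by_field),
    list(stderr = as.list(fit$stderr), chi2 = fit$chi2,
         chi2_reduced = fit$chi2_reduced, dof = fit$dof,
         converged = fit$converged, flags = fit$flags)
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' One-dimensional chi-square profile of a fitted dispersion parameter
#'
#' Re-fits the global dispersion model on a grid of fixed values of one
#' parameter (all other parameters re-optimized at each grid point) and
#' locates the 68.3% confidence interval from `delta chi2 = 1`. For
#' unweighted fits the profile is scaled by the residual variance at the
#' optimum so that `delta chi2 = 1` again corresponds to one standard error.
#'
#' @param fit A converged `"dispersion_fit"`.
#' @param curves The curves the fit was computed from.
#' @param param One of `"kex"` or `"phi_ex_ref"`.
#' @param span Multiplicative half-range of the grid around the optimum
#'   (default 4: grid from value/4 to value*4).
#' @param n_grid Number of grid points (default 41).
#' @return A list of class `"chi2_profile"`: `param`, `grid`, `chi2`,
#'   `ci` (lower/upper, `NA` when unbounded on that side within the grid),
#'   `unbounded` flag.
#' @export
profile_uncertainty <- function(fit, curves, param = c("kex", "phi_ex_ref"),
                                span = 4, n_grid = 41) {
  stopifnot(inherits(fit, "dispersion_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing to profile a non-converged fit")
  param <- match.arg(param)
  st <- .stack_curves(curves)
  d <- st$data
  fields <- st$fields
  ref_field <- min(fields)
  has_sigma <- all(is.finite(d$sigma))
  w <- if (has_sigma) 1 / d$sigma^2 else rep(1, nrow(d))
  opt_val <- if (param == "kex") fit$params$kex else fit$params$phi_ex_ref

  fixed_idx <- if (param == "kex") 1L else 2L
  free_idx <- setdiff(seq_len(2L + length(fields)), fixed_idx)
  par_opt <- c(fit$params$kex, fit$params$phi_ex_ref,
               unname(fit$params$r20_by_field))

  prof_fn <- function(val) {
    res_fn <- function(pfree) {
      par <- numeric(2L + length(fields))
      par[fixed_idx] <- val
      par[free_idx] <- pfree
      .disp_residuals(par, d, fields, ref_field, w)
    }
    lw <- c(1e-3, 0, rep(1e-9, length(fields)))[free_idx]
    f <- try(minpack.lm::nls.lm(
      par = par_opt[free_idx], fn = res_fn, lower = lw,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(f, "try-error")) return(NA_real_)
    sum(f$fvec^2)
  }

  grid <- exp(seq(log(opt_val / span), log(opt_val * span),
                  length.out = n_grid))
  grid <- sort(unique(c(grid, opt_val)))
  chi2 <- vapply(grid, prof_fn, numeric(1))

  s2 <- if (has_sigma) 1 else fit$chi2 / max(1L, fit$dof)
  dchi2 <- (chi2 - min(chi2, na.rm = TRUE)) / s2

  # interval endpoints by linear interpolation of the delta-chi2 = 1 crossing
  cross <- function(side) {
    io <- which.min(abs(grid - opt_val))
    idx <- if (side == "lower") rev(seq_len(io)) else io:length(grid)
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b <- idx[j + 1L]
      if (is.na(dchi2[a]) || is.na(dchi2[b])) next
      if (dchi2[a] <= 1 && dchi2[b] > 1) {
        t <- (1 - dchi2[a]) / (dchi2[b] - dchi2[a])
        return(grid[a] + t * (grid[b] - grid[a]))
      }
    }
    NA_real_
  }
  ci <- c(lower = cross("lower"), upper = cross("upper"))
  structure(list(param = param, grid = grid, chi2 = chi2, dchi2 = dchi2,
                 optimum = opt_val, ci = ci,
                 unbounded = any(is.na(ci))),
            class = "chi2_profile")
}

#' @export
print.chi2_profile <- function(x, ...) {
  cat(sprintf("chi-square profile of %s: optimum %.6g, 68.3%% CI [%.6g, %.6g]%s\n",
              x$param, x$optimum, x$ci[["lower"]], x$ci[["upper"]],
              if (x$unbounded) " (unbounded within grid)" else ""))
  invisible(x)
}
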
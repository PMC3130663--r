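#' Biexponential vascular input function parameters
#'
#' Plasma contrast-agent concentration following a bolus is modelled as
#' `Cp(t) = A1*exp(-m1*t) + A2*exp(-m2*t)`. Defaults are the population
#' input function of the emulated experiment: amplitudes 3.57 and 1.45 mM
#' with decay rates 0.025 and 0.0074 1/s.
#'
#' @param A1,A2 Amplitudes in mM (>= 0).
#' @param m1,m2 Decay rates in 1/s (> 0).
#' @return An object of class `vif_params`.
#' @export
vif_params <- function(A1 = 3.57, m1 = 0.025, A2 = 1.45, m2 = 0.0074) {
  assert_scalar_number(A1, "A1", lower = 0)
  assert_scalar_number(A2, "A2", lower = 0)
  assert_scalar_number(m1, "m1", lower = 1e-12)
  assert_scalar_number(m2, "m2", lower = 1e-12)
  structure(list(A1 = A1, m1 = m1, A2 = A2, m2 = m2), class = "vif_params")
}

#' @export
print.vif_params <- function(x, ...) {
  cat(sprintf("<vif_params> Cp(t) = %.3f mM exp(-%g t) + %.3f mM exp(-%g t)\n",
              x$A1, x$m1, x$A2, x$m2))
  invisible(x)
}

#' Tofts model kinetic parameters
#'
#' One-compartment Tofts parameters for a voxel: the volume transfer
#' constant `ktrans` (1/s), the extravascular extracellular volume fraction
#' `ve`, and the derived efflux rate `kep = ktrans/ve` (1/s).
#'
#' @param ktrans Transfer constant, 1/s (>= 0).
#' @param ve Extracellular volume fraction, in (0, 1].
#' @return An object of class `tofts_params` with fields `ktrans`, `ve`,
#'   `kep`.
#' @export
tofts_params <- function(ktrans, ve) {
  assert_scalar_number(ktrans, "ktrans", lower = 0)
  assert_scalar_number(ve, "ve", lower = 1e-12, upper = 1)
  structure(list(ktrans = ktrans, ve = ve, kep = ktrans / ve),
            class = "tofts_params")
}

conc_series <- function(times, conc) {
  stopifnot(length(times) == length(conc), length(times) >= 1)
  if (any(diff(times) <= 0)) stop_validation("times must be strictly ascending")
  if (times[1] < 0) stop_validation("times must start at or after 0")
  structure(list(times = as.numeric(times), conc = as.numeric(conc)),
            class = "conc_series")
}

#' Vascular input function concentration
#'
#' @param t Times since injection, s (>= 0).
#' @param vif A [vif_params()].
#' @return Plasma concentration in mM, same length as `t`.
#' @examples
#' vif_concentration(0, vif_params())  # 5.02 mM at bolus arrival
#' @export
vif_concentration <- function(t, vif = vif_params()) {
  if (any(t < 0)) stop_validation("negative time passed to vif_concentration")
  vif$A1 * exp(-vif$m1 * t) + vif$A2 * exp(-vif$m2 * t)
}

#' Closed-form Tofts tissue concentration
#'
#' Evaluates `Ct(t) = ktrans * integral_0^t Cp(tau) exp(-kep (t - tau)) dtau`
#' for a biexponential input function, using the analytic solution
#' `ktrans * sum_i Ai (exp(-mi t) - exp(-kep t)) / (kep - mi)`. When
#' `|kep - mi|` falls below `degenerate_tol` the limiting form
#' `Ai * ktrans * t * exp(-mi t)` is used.
#'
#' @param params A [tofts_params()].
#' @param vif A [vif_params()].
#' @param times Sampling times in s, strictly ascending, starting >= 0.
#' @param degenerate_tol Switch-over tolerance on `|kep - mi|`, 1/s.
#' @return A `conc_series` (fields `times`, `conc` in mM).
#' @export
tofts_forward_closed <- function(params, vif = vif_params(), times,
                                 degenerate_tol = 1e-9) {
  stopifnot(inherits(params, "tofts_params"), inherits(vif, "vif_params"))
  if (length(times) == 0) stop_validation("empty time grid")
  kep <- params$kep
  term <- function(A, m) {
    if (abs(kep - m) < degenerate_tol) {
      A * times * exp(-m * times)
    } else {
      A * (exp(-m * times) - exp(-kep * times)) / (kep - m)
    }
  }
  ct <- params$ktrans * (term(vif$A1, vif$m1) + term(vif$A2, vif$m2))
  conc_series(times, ct)
}

#' Numeric-convolution Tofts tissue concentration
#'
#' Discrete convolution of the input function with the impulse response
#' `ktrans * exp(-kep t)` on a fine uniform grid (trapezoid-corrected, FFT
#' accelerated), linearly resampled to `times`. Serves as an independent
#' numerical route to the same curve as [tofts_forward_closed()].
#'
#' @inheritParams tofts_forward_closed
#' @param dt Fine-grid step in s; must not exceed the smallest spacing of
#'   `times`.
#' @return A `conc_series`.
#' @export
tofts_forward_numeric <- function(params, vif = vif_params(), times, dt = 0.1) {
  stopifnot(inherits(params, "tofts_params"))
  if (length(times) == 0) stop_validation("empty time grid")
  assert_scalar_number(dt, "dt", lower = 1e-9)
  if (length(times) > 1 && dt > min(diff(times))) {
    stop_validation("dt = %g exceeds the minimum spacing of 'times'", dt)
  }
  tmax <- max(times)
  grid <- seq(0, tmax + dt, by = dt)
  cp <- vif_concentration(grid, vif)
  h <- params$ktrans * exp(-params$kep * grid)
  n <- length(grid)
  full <- stats::convolve(cp, rev(h), type = "open")[seq_len(n)] * dt
  # trapezoid end-point correction: halve the j = 0 and j = i contributions
  ct_grid <- full - dt / 2 * (cp[1] * h + cp * h[1])
  ct_grid[1] <- 0
  ct <- stats::approx(grid, ct_grid, xout = times)$y
  conc_series(times, ct)
}

#' Dynamic signal series with pre-contrast frames
#'
#' @param times Acquisition times in s, strictly ascending.
#' @param signal Signal intensities, arbitrary units.
#' @param n_pre Number of pre-contrast frames (>= 1; acquisition default 5).
#' @return An object of class `signal_series`.
#' @export
signal_series <- function(times, signal, n_pre = 5L) {
  stopifnot(length(times) == length(signal))
  if (any(diff(times) <= 0)) stop_validation("times must be strictly ascending")
  n_pre <- as.integer(n_pre)
  if (n_pre < 1L || n_pre >= length(times)) {
    stop_validation("n_pre must be >= 1 and leave at least one dynamic frame")
  }
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 n_pre = n_pre), class = "signal_series")
}

#' Convert a dynamic T1-weighted signal series to tracer concentration
#'
#' Linear fast-exchange conversion: the pre-contrast baseline `S0` is the
#' mean of the `n_pre` pre-contrast frames and
#' `C(t) = (S(t)/S0 - 1) / (r1 * t10)`. Times are shifted so the first
#' post-injection frame is `t = 0`.
#'
#' @param sig A [signal_series()].
#' @param r1 Contrast-agent longitudinal relaxivity, 1/(s mM).
#' @param t10 Pre-contrast longitudinal relaxation time T1(0), s.
#' @return A `conc_series` of the post-injection frames (mM).
#' @export
signal_to_concentration <- function(sig, r1 = 4.5, t10 = 1.5) {
  stopifnot(inherits(sig, "signal_series"))
  assert_scalar_number(r1, "r1", lower = 1e-12)
  assert_scalar_number(t10, "t10", lower = 1e-12)
  s0 <- mean(sig$signal[seq_len(sig$n_pre)])
  if (!is.finite(s0) || s0 <= 0) {
    stop_validation("non-positive pre-contrast baseline signal")
  }
  post <- (sig$n_pre + 1L):length(sig$signal)
  conc <- (sig$signal[post] / s0 - 1) / (r1 * t10)
  conc_series(sig$times[post] - sig$times[post[1]], conc)
}

#' Generate the dynamic signal corresponding to a concentration curve
#'
#' Exact inverse of [signal_to_concentration()]: prepends `n_pre`
#' pre-contrast frames at the baseline level `s0` and maps concentration
#' back to signal via `S = s0 * (1 + C * r1 * t10)`.
#'
#' @param conc A `conc_series` (post-injection frames, first at t = 0).
#' @param s0 Baseline signal level, arbitrary units (> 0).
#' @inheritParams signal_to_concentration
#' @param n_pre Number of pre-contrast frames to prepend.
#' @param dt_pre Spacing of the pre-contrast frames, s.
#' @return A [signal_series()].
#' @export
concentration_to_signal <- function(conc, s0 = 1000, r1 = 4.5, t10 = 1.5,
                                    n_pre = 5L, dt_pre = 12) {
  stopifnot(inherits(conc, "conc_series"))
  assert_scalar_number(s0, "s0", lower = 1e-12)
  pre_t <- conc$times[1] - dt_pre * (n_pre:1)
  sig <- c(rep(s0, n_pre), s0 * (1 + conc$conc * r1 * t10))
  signal_series(c(pre_t, conc$times), sig, n_pre = n_pre)
}

#' Fit the Tofts model to a single voxel's concentration curve
#'
#' Bounded nonlinear least squares over `(ktrans, ve)` by
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) from a coarse multi-start
#' grid; the start(s) with the lowest forward-model residual sum of squares
#' seed the optimizer and the best refined fit is returned. A voxel never
#' throws on fit failure: if every start fails, the best grid point is
#' returned with `converged = FALSE`.
#'
#' @param conc A `conc_series` with at least 8 time points.
#' @param vif A [vif_params()].
#' @param lower,upper Bounds on `(ktrans, ve)`; defaults `c(0, 1e-3)` and
#'   `c(0.1, 1)` cover the physiological range in 1/s units.
#' @param start_grid List with elements `ktrans` and `ve` giving the coarse
#'   start values.
#' @param n_refine Number of best grid starts refined by the optimizer.
#' @return A list of class `tofts_fit`: `params` ([tofts_params()]), `rss`
#'   (mM^2), `converged`, `n_iter`.
#' @export
fit_tofts_voxel <- function(conc, vif = vif_params(),
                            lower = c(ktrans = 0, ve = 1e-3),
                            upper = c(ktrans = 0.1, ve = 1),
                            start_grid = list(ktrans = c(1e-4, 1e-3, 5e-3, 1e-2),
                                              ve = c(0.1, 0.3, 0.6)),
                            n_refine = 3L) {
  stopifnot(inherits(conc, "conc_series"))
  if (length(conc$times) < 8) {
    stop_validation("at least 8 time points are required to fit the model")
  }
  resid_fn <- function(p) {
    tofts_forward_closed(tofts_params(p[1], p[2]), vif, conc$times)$conc -
      conc$conc
  }
  starts <- expand.grid(ktrans = start_grid$ktrans, ve = start_grid$ve,
                        KEEP.OUT.ATTRS = FALSE)
  rss0 <- vapply(seq_len(nrow(starts)),
                 function(i) sum(resid_fn(as.numeric(starts[i, ]))^2),
                 numeric(1))
  ord <- order(rss0)[seq_len(min(n_refine, nrow(starts)))]
  best <- list(par = as.numeric(starts[ord[1], ]), rss = rss0[ord[1]],
               converged = FALSE, n_iter = 0L)
  for (i in ord) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-14, ptol = 1e-14, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:4
    if (rss < best$rss || (ok && !best$converged && rss <= best$rss)) {
      best <- list(par = fit$par, rss = rss, converged = ok,
                   n_iter = fit$niter)
    }
  }
  structure(list(params = tofts_params(max(best$par[1], 0),
                                       min(max(best$par[2], 1e-3), 1)),
                 rss = best$rss, converged = best$converged,
                 n_iter = best$n_iter),
            class = "tofts_fit")
}

#' @export
print.tofts_fit <- function(x, ...) {
  cat(sprintf("<tofts_fit> ktrans = %.4g 1/s, ve = %.3f, rss = %.4g, %s\n",
              x$params$ktrans, x$params$ve, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the Tofts model voxel-by-voxel over a concentration matrix
#'
#' @param conc_mat Matrix of concentrations, voxels in rows, time in
#'   columns (mM).
#' @param times Sampling times in s (length `ncol(conc_mat)`).
#' @param vif A [vif_params()].
#' @param ... Passed to [fit_tofts_voxel()].
#' @return A data.frame with one row per voxel: `ktrans`, `ve`, `rss`,
#'   `converged`, `n_iter`.
#' @export
fit_tofts_batch <- function(conc_mat, times, vif = vif_params(), ...) {
  stopifnot(is.matrix(conc_mat), ncol(conc_mat) == length(times))
  fits <- lapply(seq_len(nrow(conc_mat)), function(i) {
    f <- fit_tofts_voxel(conc_series(times, conc_mat[i, ]), vif, ...)
    data.frame(ktrans = f$params$ktrans, ve = f$params$ve, rss = f$rss,
               converged = f$converged, n_iter = f$n_iter)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

#' ROI-mean Ktrans over converged voxel fits
#'
#' Arithmetic mean of fitted `ktrans` over the converged voxels inside the
#' ROI; the fraction of excluded (non-converged) voxels is attached as the
#' `excluded_fraction` attribute.
#'
#' @param results Data.frame from [fit_tofts_batch()].
#' @param roi An [roi_mask()] of voxel row indices (default: all voxels).
#' @return Mean Ktrans in 1/s.
#' @export
roi_mean_ktrans <- function(results, roi = roi_mask(seq_len(nrow(results)))) {
  stopifnot(is.data.frame(results), inherits(roi, "roi_mask"))
  idx <- unclass(roi)
  if (any(idx > nrow(results))) stop_validation("ROI index outside the batch")
  ok <- results$converged[idx]
  if (!any(ok)) {
    stop_validation("no converged voxel fits inside the ROI")
  }
  out <- mean(results$ktrans[idx][ok])
  attr(out, "excluded_fraction") <- mean(!ok)
  out
}
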
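#' Simulate a diffusion-weighted voxel stack with known ground truth
#'
#' Forward mono-exponential model `S(b, dir) = s0 * exp(-b * ADC)` per
#' voxel, isotropic by construction (identical across directions before
#' noise), with noise applied independently to every (voxel, b, direction)
#' measurement. With Rician noise the output is non-negative; Gaussian
#' noise may produce non-positive values for attenuated signals, which the
#' ADC estimator flags rather than clips.
#'
#' @param adc_true Per-voxel ground-truth ADC, mm^2/s (>= 0).
#' @param s0 Per-voxel unattenuated signal (scalar or per-voxel vector).
#' @param b_values Diffusion weightings in s/mm^2; must contain 0 once.
#'   Acquisition default: 0 and 100.
#' @param directions Gradient direction matrix ([default_directions()]).
#' @param noise A [noise_model()].
#' @param seed Optional integer seed for the noise draws.
#' @return A [dw_stack()].
#' @examples
#' st <- simulate_dw_stack(rep(1e-3, 4), 1000)
#' compute_adc_map(st)$adc
#' @export
simulate_dw_stack <- function(adc_true, s0 = 1000, b_values = c(0, 100),
                              directions = default_directions(),
                              noise = noise_model("none"), seed = NULL) {
  if (any(adc_true < 0)) stop_validation("adc_true must be non-negative")
  if (any(b_values < 0)) stop_validation("negative b-value")
  n_vox <- length(adc_true)
  s0 <- rep_len(s0, n_vox)
  n_dir <- nrow(directions)
  clean <- outer(seq_len(n_vox), seq_along(b_values),
                 function(i, j) s0[i] * exp(-b_values[j] * adc_true[i]))
  sig <- array(rep(clean, n_dir), dim = c(n_vox, length(b_values), n_dir))
  sig <- if (is.null(seed)) apply_noise(sig, noise) else {
    with_seed(seed, apply_noise(sig, noise))
  }
  dw_stack(sig, b_values, directions)
}

#' Simulate a DCE concentration time series for one voxel
#'
#' Noise-free curve from the closed-form Tofts solution with the given
#' input function; noise (Gaussian by convention, since concentration is a
#' signed derived quantity) added pointwise.
#'
#' @param params A [tofts_params()].
#' @param vif A [vif_params()].
#' @param times Sampling times in s, ascending from 0. Acquisition default:
#'   12-s resolution over 20 min.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed for the noise draws.
#' @return A `conc_series`.
#' @export
simulate_dce_series <- function(params, vif = vif_params(),
                                times = seq(0, 1200, by = 12),
                                noise = noise_model("none"), seed = NULL) {
  if (length(times) == 0) stop_validation("empty time grid")
  ct <- tofts_forward_closed(params, vif, times)
  conc <- if (is.null(seed)) apply_noise(ct$conc, noise) else {
    with_seed(seed, apply_noise(ct$conc, noise))
  }
  conc_series(times, conc)
}
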
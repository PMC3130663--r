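#' Measurement-noise model for simulated MR signals
#'
#' Describes the noise added to simulated voxel signals. Magnitude MR images
#' carry Rician noise (the envelope of complex Gaussian noise); derived, signed
#' quantities such as tracer concentration carry additive Gaussian noise.
#'
#' @param kind One of `"none"`, `"gaussian"`, `"rician"`.
#' @param sigma Noise standard deviation, in the units of the signal it
#'   corrupts (for Rician noise, the per-channel Gaussian sigma of the
#'   underlying complex noise). Must be non-negative.
#'
#' @return An object of class `noise_model`.
#' @examples
#' noise_model("rician", sigma = 50)
#' @export
noise_model <- function(kind = c("none", "gaussian", "rician"), sigma = 0) {
  kind <- match.arg(kind)
  assert_scalar_number(sigma, "sigma", lower = 0)
  if (kind == "none" && sigma != 0) sigma <- 0
  structure(list(kind = kind, sigma = sigma), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> kind = %s, sigma = %g\n", x$kind, x$sigma))
  invisible(x)
}

# Apply a noise model to a vector/array of noise-free signal values.
# Rician: magnitude of (signal + n1) + i*n2 with n1, n2 ~ N(0, sigma^2);
# output is non-negative by construction. Gaussian output may go negative,
# which downstream ADC computation flags rather than clips.
apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "none" || noise$sigma == 0) return(x)
  n <- length(x)
  if (noise$kind == "gaussian") {
    return(x + stats::rnorm(n, sd = noise$sigma))
  }
  if (any(x < 0)) {
    stop_validation("rician noise applies to magnitude (non-negative) signals")
  }
  re <- x + stats::rnorm(n, sd = noise$sigma)
  im <- stats::rnorm(n, sd = noise$sigma)
  out <- sqrt(re^2 + im^2)
  attributes(out) <- attributes(x)
  out
}
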
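# Independent oracles used across the suite. Each is deliberately written
# differently from the package implementation it checks.

# Analytic mean of a Rician-distributed magnitude with underlying signal A
# and per-channel noise sigma: sigma*sqrt(pi/2)*L_{1/2}(-A^2/(2 sigma^2)),
# with the generalized Laguerre polynomial expressed through Bessel I.
rician_mean_analytic <- function(A, sigma) {
  x <- -A^2 / (2 * sigma^2)
  laguerre_half <- exp(x / 2) *
    ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * laguerre_half
}

# Central finite-difference gradient of the network cost over all weights
# and biases, flattened in the package's parameter order.
fd_gradient <- function(net, x, y, h = 1e-6) {
  theta <- mriresponse:::net_flatten(net)
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    ep <- bpnn_loss(mriresponse:::net_unflatten(tp, net), x, y)$E
    em <- bpnn_loss(mriresponse:::net_unflatten(tm, net), x, y)$E
    g[i] <- (ep - em) / (2 * h)
  }
  g
}

# Matrix-free per-node network evaluation: loops over nodes and incoming
# edges with scalar arithmetic only.
node_forward_oracle <- function(net, xrow) {
  a <- as.numeric(xrow)
  L <- length(net$W)
  for (l in seq_len(L)) {
    out <- numeric(ncol(net$W[[l]]))
    for (j in seq_along(out)) {
      s <- net$b[[l]][j]
      for (i in seq_along(a)) s <- s + a[i] * net$W[[l]][i, j]
      out[j] <- if (l < L && net$activation == "tanh") tanh(s) else s
    }
    a <- out
  }
  a
}

# Mean over a masked subset, written with an explicit accumulation loop.
mask_mean_oracle <- function(values, valid, idx) {
  tot <- 0; n <- 0L
  for (i in idx) {
    if (valid[i]) { tot <- tot + values[i]; n <- n + 1L }
  }
  tot / n
}

# A small cohort-shaped data.frame whose outcome is an exact linear
# function of its features (for realizable-limit pipeline tests).
make_linear_cohort <- function(n_per_group = 16, seed = 1) {
  cfg <- generator_config(n_per_group = n_per_group,
                          latent_outcome_scale = 0,
                          outcome_noise_sd = 0,
                          measurement_sd = 0.05)
  coh <- simulate_cohort(cfg, seed = seed)
  # overwrite the outcome with an exact linear function of the features
  fm <- build_features(coh, "all")
  x <- as.matrix(fm[, attr(fm, "feature_names")])
  beta <- c(0.5, 1.0, -0.3, 0.2, 0.8, -0.5, 0.4, -0.2, 5, 2, 1.2, 0.9)
  coh$V_d30 <- coh$V_d0 * as.numeric(2 + x %*% beta[seq_len(ncol(x))])
  stopifnot(all(coh$V_d30 > 0))
  coh
}
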
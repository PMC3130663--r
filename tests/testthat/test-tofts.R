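test_that("the input function evaluates to the printed amplitudes", {
  expect_equal(vif_concentration(0), 5.02)
  expect_lt(vif_concentration(1e6), 1e-8)
  expect_equal(vif_concentration(100, vif_params(A1 = 0, A2 = 0)), 0)
  expect_error(vif_concentration(-1), "negative time")
})

test_that("closed-form solution handles zero transfer and the degenerate rate", {
  tt <- seq(0, 1200, by = 12)
  expect_true(all(tofts_forward_closed(tofts_params(0, 0.3), times = tt)$conc == 0))
  # kep exactly equal to m1 with a single-exponential input function
  vif1 <- vif_params(A1 = 3.57, m1 = 0.025, A2 = 0, m2 = 0.0074)
  p <- tofts_params(ktrans = 0.025 * 0.3, ve = 0.3)   # kep = 0.025 = m1
  got <- tofts_forward_closed(p, vif1, tt)$conc
  expect_equal(got, p$ktrans * 3.57 * tt * exp(-0.025 * tt), tolerance = 1e-12)
  # and the limit agrees with the convolution oracle
  orc <- tofts_forward_numeric(p, vif1, tt, dt = 0.05)
  expect_lt(max(abs(got - orc$conc)) / max(got), 0.005)
})

test_that("closed form matches numeric convolution across the parameter box", {
  tt <- seq(0, 1200, by = 12)
  for (kt in c(1e-4, 1e-3, 1e-2)) {
    for (ve in c(0.05, 0.3, 0.6)) {
      p <- tofts_params(kt, ve)
      a <- tofts_forward_closed(p, times = tt)$conc
      b <- tofts_forward_numeric(p, times = tt, dt = 0.1)$conc
      expect_lt(max(abs(a - b)) / max(a), 0.005)
    }
  }
  expect_error(tofts_forward_numeric(tofts_params(1e-3, 0.3),
                                     times = tt, dt = 30), "spacing")
})

test_that("signal-concentration conversion is linear and invertible", {
  tt <- seq(-60, 600, by = 12)
  sig <- signal_series(tt, rep(1000, length(tt)), n_pre = 5)
  expect_true(all(signal_to_concentration(sig)$conc == 0))

  s2 <- signal_series(tt, c(rep(1000, 5), rep(1500, length(tt) - 5)), n_pre = 5)
  conc <- signal_to_concentration(s2, r1 = 4.5, t10 = 1.5)
  expect_equal(conc$conc, rep(0.5 / (4.5 * 1.5), length(tt) - 5))
  expect_equal(conc$times[1], 0)

  p <- tofts_params(5e-3, 0.3)
  truth <- tofts_forward_closed(p, times = seq(0, 1200, by = 12))
  sig3 <- concentration_to_signal(truth, s0 = 1200, r1 = 4.5, t10 = 1.5)
  back <- signal_to_concentration(sig3, r1 = 4.5, t10 = 1.5)
  expect_equal(back$conc, truth$conc, tolerance = 1e-9)

  bad <- signal_series(tt, c(rep(0, 5), rep(100, length(tt) - 5)), n_pre = 5)
  expect_error(signal_to_concentration(bad), "non-positive")
})

test_that("noise-free voxel fits recover the transfer constant", {
  tt <- seq(0, 1200, by = 12)
  for (kt in c(1e-3, 5e-3)) {
    truth <- tofts_forward_closed(tofts_params(kt, 0.3), times = tt)
    fit <- fit_tofts_voxel(truth)
    expect_true(fit$converged)
    expect_lt(abs(fit$params$ktrans - kt) / kt, 1e-6)
    expect_lt(abs(fit$params$ve - 0.3) / 0.3, 1e-5)
  }
  zero <- conc_series(tt, rep(0, length(tt)))
  fz <- fit_tofts_voxel(zero)
  expect_true(fz$converged)
  expect_equal(fz$params$ktrans, 0)
  expect_error(fit_tofts_voxel(conc_series(c(0, 12, 24), c(0, 0.1, 0.2))),
               "at least 8")
})

test_that("fitted parameters are invariant to a joint concentration scale", {
  tt <- seq(0, 1200, by = 12)
  p <- tofts_params(3e-3, 0.25)
  base <- tofts_forward_closed(p, times = tt)
  f1 <- fit_tofts_voxel(base)
  cc <- 2.7
  vif_scaled <- vif_params(A1 = 3.57 * cc, m1 = 0.025,
                           A2 = 1.45 * cc, m2 = 0.0074)
  f2 <- fit_tofts_voxel(conc_series(tt, base$conc * cc), vif_scaled)
  expect_equal(f2$params$ktrans, f1$params$ktrans, tolerance = 1e-6)
  expect_equal(f2$params$ve, f1$params$ve, tolerance = 1e-6)
})

test_that("batch fits under Gaussian noise keep median Ktrans error low", {
  tt <- seq(0, 1200, by = 12)
  p <- tofts_params(5e-3, 0.3)
  clean <- tofts_forward_closed(p, times = tt)$conc
  n_vox <- 40
  cm <- matrix(rep(clean, each = n_vox), nrow = n_vox)
  cm <- mriresponse:::with_seed(51, apply_noise(cm, noise_model("gaussian", 0.05)))
  fits <- fit_tofts_batch(cm, tt)
  expect_true(mean(fits$converged) > 0.9)
  err <- abs(fits$ktrans - p$ktrans) / p$ktrans
  expect_lt(median(err), 0.10)
})

test_that("ROI-mean Ktrans averages converged voxels and flags empty ROIs", {
  res <- data.frame(ktrans = c(1e-3, 3e-3, 9e-3), ve = 0.3, rss = 0,
                    converged = c(TRUE, TRUE, FALSE), n_iter = 1)
  out <- roi_mean_ktrans(res, roi_mask(1:3))
  expect_equal(as.numeric(out), 2e-3)
  expect_equal(attr(out, "excluded_fraction"), 1 / 3)
  expect_error(roi_mean_ktrans(res, roi_mask(3)), "no converged")
})
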
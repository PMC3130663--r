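test_that("weight initialization is deterministic, zeroable, and uniform", {
  n0 <- bpnn_init(3, 4, 1, init_scale = 0)
  expect_true(all(unlist(n0$W) == 0) && all(unlist(n0$b) == 0))
  a <- bpnn_init(5, 6, 1, seed = 3)
  b <- bpnn_init(5, 6, 1, seed = 3)
  expect_identical(a, b)
  big <- bpnn_init(400, 250, 1, init_scale = 0.2, seed = 9)
  draws <- as.numeric(big$W[[1]])       # 1e5 draws
  ks <- suppressWarnings(ks.test(draws, "punif", -0.2, 0.2))
  expect_gt(ks$p.value, 0.01)
})

test_that("forward pass matches hand-computed and per-node oracle values", {
  net <- bpnn_init(2, 2, 1, init_scale = 0)
  expect_equal(as.numeric(bpnn_forward(net, c(3, -1))), 0)
  # single path, hand arithmetic: o = w2 * tanh(w1*x + b1) + b2
  n1 <- bpnn_init(1, 1, 1, init_scale = 0)
  n1$W[[1]][] <- 0.7; n1$b[[1]][] <- 0.1; n1$W[[2]][] <- -1.3; n1$b[[2]][] <- 0.2
  expect_equal(as.numeric(bpnn_forward(n1, 2)),
               -1.3 * tanh(0.7 * 2 + 0.1) + 0.2, tolerance = 1e-15)
  for (k in 1:5) {
    net <- bpnn_init(4, c(5, 3), 2, init_scale = 0.8, seed = k)
    x <- mriresponse:::with_seed(k, rnorm(4))
    expect_equal(as.numeric(bpnn_forward(net, x)),
                 node_forward_oracle(net, x), tolerance = 1e-12)
  }
  expect_error(bpnn_forward(bpnn_init(3, 2, 1), c(1, 2)), "features")
})

test_that("cost function follows the half-sum-of-squares definition", {
  net <- bpnn_init(2, 2, 1, init_scale = 0.3, seed = 1)
  x <- matrix(rnorm(10), 5, 2)
  y <- bpnn_forward(net, x)
  perfect <- bpnn_loss(net, x, y)
  expect_equal(perfect$E, 0)
  expect_equal(perfect$rmse, 0)
  # M = 2 patterns, N = 1 output, errors {1, -1}: E = 1, RMSE = 1
  n0 <- bpnn_init(1, 1, 1, init_scale = 0)
  got <- bpnn_loss(n0, matrix(c(0, 0), 2, 1), matrix(c(1, -1), 2, 1))
  expect_equal(got$E, 1)
  expect_equal(got$rmse, 1)
  yr <- y + matrix(rnorm(5), 5, 1)
  expect_equal(bpnn_loss(net, x, yr)$E,
               0.5 * sum((yr - bpnn_forward(net, x))^2))
})

test_that("back-propagated gradient matches central finite differences", {
  for (k in 1:10) {
    net <- bpnn_init(3, 6, 1, init_scale = 0.6, seed = 40 + k)
    x <- mriresponse:::with_seed(60 + k, matrix(rnorm(15), 5, 3))
    y <- mriresponse:::with_seed(70 + k, matrix(rnorm(5), 5, 1))
    g <- bpnn_gradient(net, x, y)
    flat <- c(unlist(g$W, use.names = FALSE), unlist(g$b, use.names = FALSE))
    fd <- fd_gradient(net, x, y)
    expect_lt(max(abs(flat - fd)) / max(abs(fd)), 1e-6)
  }
  # zero-error dataset: gradient vanishes
  net <- bpnn_init(2, 3, 1, init_scale = 0.4, seed = 5)
  x <- matrix(rnorm(8), 4, 2)
  g0 <- bpnn_gradient(net, x, bpnn_forward(net, x))
  expect_true(all(abs(unlist(g0)) < 1e-14))
})

test_that("linear-network gradient matches the analytic least-squares form", {
  net <- bpnn_init(3, 4, 1, init_scale = 0.5, seed = 2, activation = "identity")
  x <- mriresponse:::with_seed(81, matrix(rnorm(30), 10, 3))
  y <- mriresponse:::with_seed(82, matrix(rnorm(10), 10, 1))
  H <- x %*% net$W[[1]] + rep(net$b[[1]], each = 10)
  O <- H %*% net$W[[2]] + rep(net$b[[2]], each = 10)
  r <- O - y
  g <- bpnn_gradient(net, x, y)
  expect_equal(g$W[[2]], crossprod(H, r), tolerance = 1e-12)
  expect_equal(g$b[[2]], colSums(r), tolerance = 1e-12)
  expect_equal(g$W[[1]], crossprod(x, r %*% t(net$W[[2]])), tolerance = 1e-12)
  expect_equal(g$b[[1]], colSums(r %*% t(net$W[[2]])), tolerance = 1e-12)
})

test_that("one sequential epoch with a small learning rate approximates a batch step", {
  net <- bpnn_init(3, 4, 1, init_scale = 0.5, seed = 6)
  x <- mriresponse:::with_seed(91, matrix(rnorm(24), 8, 3))
  y <- mriresponse:::with_seed(92, matrix(rnorm(8), 8, 1))
  eta <- 1e-6
  stepped <- mriresponse:::sgd_epoch(net, x, y, eta, 1:8)
  g <- bpnn_gradient(net, x, y)
  got <- (mriresponse:::net_flatten(stepped) - mriresponse:::net_flatten(net)) / eta
  want <- -c(unlist(g$W, use.names = FALSE), unlist(g$b, use.names = FALSE))
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-3)
})

test_that("a realizable linear target is driven to near-zero training error", {
  set.seed(10)
  x <- matrix(runif(90, -1, 1), 30, 3)
  y <- x %*% c(1, -2, 0.5) + 1
  run <- bpnn_train(bpnn_init(3, 4, 1, seed = 2, activation = "identity"),
                    scale(x), scale(y), max_epochs = 200, conv_tol = 1e-9)
  expect_equal(run$stopped_reason, "converged")
  expect_lt(tail(run$trace$train_rmse, 1), 1e-9)
  expect_equal(run$best_epoch, nrow(run$trace))
})

test_that("training respects boundary settings and the early-stopping contract", {
  set.seed(11)
  x <- matrix(rnorm(60), 20, 3)
  y <- matrix(rnorm(20), 20, 1)
  one <- bpnn_train(bpnn_init(3, 4, 1, seed = 1), x, y,
                    x[1:4, ], y[1:4, , drop = FALSE],
                    max_epochs = 1, patience = 0)
  expect_equal(nrow(one$trace), 1L)
  # early stopping always returns the recorded validation minimum
  for (k in 1:5) {
    cohort <- simulate_cohort(generator_config(), seed = 500 + k)
    fm <- build_features(cohort, "all")
    xx <- scale(as.matrix(fm[, attr(fm, "feature_names")]))
    yy <- scale(log(fm$target))
    run <- bpnn_train(bpnn_init(ncol(xx), 6, 1, seed = k), xx[1:16, ], yy[1:16, ],
                      xx[17:24, ], yy[17:24, , drop = FALSE],
                      max_epochs = 150, patience = 20)
    expect_equal(run$trace$val_rmse[run$best_epoch], min(run$trace$val_rmse))
    expect_equal(bpnn_loss(run$net, xx[17:24, ], yy[17:24, ])$rmse,
                 min(run$trace$val_rmse), tolerance = 1e-12)
  }
})

test_that("with constant features the prediction converges to the target mean", {
  x <- matrix(1, 40, 2)
  set.seed(12)
  y <- rnorm(40, mean = 3)
  fit <- bpnn(x, y, max_epochs = 200, seed = 4)
  expect_equal(unname(predict(fit, matrix(1, 1, 2))), mean(y),
               tolerance = 1e-3)
})

test_that("sequential mode diverges loudly at an excessive learning rate", {
  set.seed(13)
  x <- matrix(rnorm(600, sd = 3), 50, 12)
  y <- matrix(rnorm(50, sd = 5), 50, 1)
  expect_error(
    bpnn_train(bpnn_init(12, 6, 1, seed = 1), x, y,
               eta = 0.9, optimizer = "sequential", max_epochs = 200),
    "diverged")
  expect_error(
    bpnn_train(bpnn_init(12, 6, 1, seed = 1), x, y, eta = 1.5,
               optimizer = "sequential"),
    "eta")
})

test_that("both optimizers reduce the training cost on the same problem", {
  set.seed(14)
  x <- matrix(runif(60, -1, 1), 20, 3)
  y <- tanh(x %*% c(1, -1, 0.5))
  net0 <- bpnn_init(3, 4, 1, seed = 3)
  e0 <- bpnn_loss(net0, x, y)$E
  for (opt in c("scg", "sequential")) {
    run <- bpnn_train(net0, x, y, optimizer = opt, eta = 0.05,
                      max_epochs = 50)
    expect_lt(tail(run$trace$train_rmse, 1)^2, 2 * e0 / 20)
    expect_lt(bpnn_loss(run$net, x, y)$E, e0 / 4)
  }
})

test_that("stratified splitting gives 16/8/8 with proportional group counts", {
  groups <- factor(rep(c("a", "b", "c", "d"), each = 8))
  sp <- split_data(groups, seed = 2)
  expect_equal(lengths(sp)[c("train", "validation", "test")],
               c(train = 16L, validation = 8L, test = 8L))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    expect_equal(sum(sp$train %in% idx), 4L)
    expect_equal(sum(sp$validation %in% idx), 2L)
    expect_equal(sum(sp$test %in% idx), 2L)
  }
  expect_identical(split_data(groups, seed = 2), sp)
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, seq_along(groups))
  expect_error(split_data(factor(rep("a", 8)), c(0.9, 0.05, 0.05)),
               "0 records")
})
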
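# Feed-forward back-propagation network, written from scratch.
#
# Weight layout: W[[l]] is (n_in x n_out) for layer l, b[[l]] length n_out.
# Hidden activation tanh, identity output. The cost is
# E = 1/2 * sum_i sum_j (y_ij - o_ij)^2 over M patterns and N output nodes,
# reported alongside RMSE = sqrt(2 E / (M N)).

#' Initialize network weights
#'
#' Weights drawn uniformly on `[-init_scale, +init_scale]`, biases zero;
#' deterministic given `seed`.
#'
#' @param n_inputs Number of input nodes.
#' @param hidden Integer vector of hidden-layer sizes (default one layer of
#'   six hidden units).
#' @param n_outputs Number of output nodes (default 1).
#' @param init_scale Half-width of the uniform initialization interval.
#' @param seed Integer seed.
#' @param activation Hidden-layer nonlinearity: `"tanh"` (default) or
#'   `"identity"` (a purely linear network).
#' @return A list of class `bpnn_net` with elements `W`, `b`, `sizes`,
#'   `activation`.
#' @export
bpnn_init <- function(n_inputs, hidden = 6L, n_outputs = 1L,
                      init_scale = 0.2, seed = 1L,
                      activation = c("tanh", "identity")) {
  activation <- match.arg(activation)
  sizes <- c(n_inputs, hidden, n_outputs)
  stopifnot(all(sizes >= 1), init_scale >= 0)
  with_seed(substream_seed(seed, 7L), {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L],
                                    -init_scale, init_scale),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
  })
  structure(list(W = W, b = b, sizes = sizes, activation = activation),
            class = "bpnn_net")
}

act_fun <- function(net, z) if (net$activation == "tanh") tanh(z) else z
# derivative of the activation expressed through the activation value
act_deriv <- function(net, a) if (net$activation == "tanh") 1 - a^2 else 1

#' Forward pass through the network
#'
#' @param net A `bpnn_net`.
#' @param x Numeric matrix (patterns in rows) or a single pattern vector
#'   with `n_inputs` entries.
#' @return Matrix of network outputs (patterns in rows).
#' @export
bpnn_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$sizes[1]) {
    stop_validation("input has %d features, network expects %d",
                    ncol(x), net$sizes[1])
  }
  a <- x
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a))
    a <- if (l < L) act_fun(net, z) else z
  }
  a
}

# forward keeping all layer activations (for backprop)
bpnn_forward_full <- function(net, x) {
  a <- list(x)
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- a[[l]] %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a[[l]]))
    a[[l + 1L]] <- if (l < L) act_fun(net, z) else z
  }
  a
}

#' Network cost and RMSE on a dataset
#'
#' `E = 1/2 * sum over the M patterns and N output nodes of the squared
#' output differences`; `RMSE = sqrt(2 E / (M N))`.
#'
#' @param net A `bpnn_net`.
#' @param x Pattern matrix.
#' @param y Target matrix (or vector for a single output node).
#' @return List with elements `E` and `rmse`.
#' @export
bpnn_loss <- function(net, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  y <- as.matrix(y)
  if (nrow(y) == 0) stop_validation("empty dataset")
  o <- bpnn_forward(net, x)
  E <- 0.5 * sum((y - o)^2)
  list(E = E, rmse = sqrt(2 * E / (nrow(y) * ncol(y))))
}

#' Exact gradient of the cost by back-propagation
#'
#' @inheritParams bpnn_loss
#' @return A list with weight-shaped elements `W` and `b`: the gradient of
#'   `E` with respect to every weight and bias.
#' @export
bpnn_gradient <- function(net, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  y <- as.matrix(y)
  if (nrow(y) == 0) stop_validation("empty dataset")
  a <- bpnn_forward_full(net, x)
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- a[[L + 1L]] - y                    # dE/dz at the identity output
  for (l in L:1) {
    gW[[l]] <- crossprod(a[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * act_deriv(net, a[[l]])
    }
  }
  list(W = gW, b = gb)
}

net_flatten <- function(net) {
  c(unlist(net$W, use.names = FALSE), unlist(net$b, use.names = FALSE))
}

net_unflatten <- function(theta, net) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  net
}

# one epoch of sequential (per-pattern) gradient descent, order fixed upstream
sgd_epoch <- function(net, x, y, eta, order) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (i in order) {
    xi <- x[i, , drop = FALSE]
    a <- bpnn_forward_full(net, xi)
    delta <- a[[L + 1L]] - y[i, , drop = FALSE]
    for (l in L:1) {
      gW[[l]] <- crossprod(a[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * act_deriv(net, a[[l]])
    }
    for (l in seq_len(L)) {
      net$W[[l]] <- net$W[[l]] - eta * gW[[l]]
      net$b[[l]] <- net$b[[l]] - eta * gb[[l]]
    }
  }
  net
}

#' Train a back-propagation network with validation-based early stopping
#'
#' Core training routine behind [bpnn()]. Two optimizers are available:
#' `"sequential"` per-pattern gradient descent with learning rate `eta`
#' (pattern order reshuffled deterministically each epoch), and `"scg"`,
#' Moller's scaled conjugate gradient on the full batch (no learning
#' rate). After every epoch the validation RMSE is recorded; the returned
#' network is the snapshot from the epoch with the smallest validation
#' RMSE (earliest such epoch on ties). Training stops when the validation
#' RMSE has not improved for `patience` epochs, when the training RMSE
#' falls below `conv_tol`, or at `max_epochs`.
#'
#' @param net A `bpnn_net` starting state.
#' @param x,y Training patterns and targets.
#' @param x_val,y_val Validation patterns and targets (may be `NULL`: no
#'   early stopping, the final state is returned).
#' @param eta Learning rate in (0, 1); default 0.4. Sequential mode only.
#' @param optimizer `"scg"` (Moller scaled conjugate gradient, default)
#'   or `"sequential"` per-pattern gradient descent.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs.
#' @param conv_tol Training RMSE below which training is declared
#'   converged.
#' @param seed Integer seed controlling pattern order.
#' @return List with `net` (best snapshot), `trace` (data.frame of
#'   per-epoch `train_rmse`, `val_rmse`), `best_epoch`, `stopped_reason`
#'   (`"converged"`, `"early_stop"` or `"max_epochs"`).
#' @export
bpnn_train <- function(net, x, y, x_val = NULL, y_val = NULL,
                       eta = 0.4, optimizer = c("scg", "sequential"),
                       max_epochs = 300L, patience = 25L, conv_tol = 1e-8,
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (optimizer == "sequential") {
    assert_scalar_number(eta, "eta", lower = 1e-12, upper = 1 - 1e-12)
  }
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 1)
  has_val <- !is.null(x_val)
  if (has_val) {
    x_val <- as.matrix(x_val); y_val <- as.matrix(y_val)
    stopifnot(nrow(x_val) == nrow(y_val), nrow(x_val) >= 1)
  }
  n <- nrow(x)
  train_rmse <- val_rmse <- numeric(0)
  best_val <- Inf
  best_net <- net
  best_epoch <- 0L
  stopped <- "max_epochs"
  scg <- if (optimizer == "scg") scg_state_init(net, x, y) else NULL

  for (epoch in seq_len(max_epochs)) {
    if (optimizer == "sequential") {
      ord <- with_seed(substream_seed(seed, 100L + epoch), sample.int(n))
      net <- sgd_epoch(net, x, y, eta, ord)
    } else {
      scg <- scg_step(scg)
      net <- net_unflatten(scg$w, net)
    }
    tr <- bpnn_loss(net, x, y)
    if (!is.finite(tr$E)) {
      stop_validation("training diverged (non-finite cost) at epoch %d", epoch)
    }
    train_rmse[epoch] <- tr$rmse
    if (has_val) {
      vl <- bpnn_loss(net, x_val, y_val)
      val_rmse[epoch] <- vl$rmse
      if (vl$rmse < best_val) {
        best_val <- vl$rmse
        best_net <- net
        best_epoch <- epoch
      }
      if (epoch - best_epoch >= patience && patience > 0) {
        stopped <- "early_stop"
        break
      }
    } else {
      val_rmse[epoch] <- NA_real_
      best_net <- net
      best_epoch <- epoch
    }
    if (tr$rmse < conv_tol) {
      stopped <- "converged"
      break
    }
  }
  list(net = best_net,
       trace = data.frame(epoch = seq_along(train_rmse),
                          train_rmse = train_rmse, val_rmse = val_rmse),
       best_epoch = best_epoch,
       stopped_reason = stopped)
}

# --- Moller scaled conjugate gradient (full batch) ----------------------

scg_state_init <- function(net, x, y) {
  w <- net_flatten(net)
  fg <- function(theta) {
    nt <- net_unflatten(theta, net)
    g <- bpnn_gradient(nt, x, y)
    list(E = bpnn_loss(nt, x, y)$E,
         g = c(unlist(g$W, use.names = FALSE), unlist(g$b, use.names = FALSE)))
  }
  e0 <- fg(w)
  list(fg = fg, w = w, E = e0$E, r = -e0$g, p = -e0$g,
       lambda = 1e-6, lambda_bar = 0, success = TRUE,
       sigma0 = 1e-4, k = 1L, n_par = length(w))
}

scg_step <- function(st) {
  p2 <- sum(st$p^2)
  if (p2 < .Machine$double.eps) return(st)  # gradient vanished; fixed point
  if (st$success) {
    sigma <- st$sigma0 / sqrt(p2)
    g_plus <- st$fg(st$w + sigma * st$p)$g
    st$s <- (g_plus - (-st$r)) / sigma
    st$delta <- sum(st$p * st$s)
  }
  st$delta <- st$delta + (st$lambda - st$lambda_bar) * p2
  if (st$delta <= 0) {
    st$lambda_bar <- 2 * (st$lambda - st$delta / p2)
    st$delta <- -st$delta + st$lambda * p2
    st$lambda <- st$lambda_bar
  }
  mu <- sum(st$p * st$r)
  alpha <- mu / st$delta
  w_new <- st$w + alpha * st$p
  e_new <- st$fg(w_new)
  Delta <- 2 * st$delta * (st$E - e_new$E) / mu^2
  if (is.finite(Delta) && Delta >= 0) {
    r_new <- -e_new$g
    st$lambda_bar <- 0
    st$success <- TRUE
    if (st$k %% st$n_par == 0L) {
      st$p <- r_new                      # restart along steepest descent
    } else {
      beta <- (sum(r_new^2) - sum(r_new * st$r)) / mu
      st$p <- r_new + beta * st$p
    }
    st$w <- w_new
    st$E <- e_new$E
    st$r <- r_new
    st$k <- st$k + 1L
    if (Delta >= 0.75) st$lambda <- st$lambda / 4
  } else {
    st$lambda_bar <- st$lambda
    st$success <- FALSE
  }
  if (!is.finite(Delta) || Delta < 0.25) {
    st$lambda <- st$lambda + st$delta * (1 - max(Delta, -1)) / p2
  }
  st
}

# --- stratified data splitting ------------------------------------------

#' Stratified train/validation/test split
#'
#' Random split into train/validation/test sets (default proportions
#' 50/25/25), stratified so each treatment group contributes proportional
#' counts to each split (largest-remainder allocation within each group).
#'
#' @param groups Factor of group labels, one per record (a plain integer
#'   `n` is treated as a single stratum of size `n`).
#' @param fractions Length-3 positive fractions summing to 1.
#' @param seed Integer seed.
#' @return List of class `split_indices` with integer index vectors
#'   `train`, `validation`, `test`; disjoint with union covering all
#'   records.
#' @export
split_data <- function(groups, fractions = c(0.5, 0.25, 0.25), seed = 1L) {
  if (length(groups) == 1L && is.numeric(groups)) {
    groups <- factor(rep("all", groups))
  }
  groups <- as.factor(groups)
  n <- length(groups)
  if (n < 4) stop_validation("need at least 4 records to split")
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop_validation("fractions must sum to 1")
  }
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(substream_seed(seed, 11L), {
    for (g in levels(groups)) {
      idx <- sample(which(groups == g))
      ng <- length(idx)
      ideal <- ng * fractions
      base <- floor(ideal)
      rem <- ideal - base
      extra <- order(rem, decreasing = TRUE)[seq_len(ng - sum(base))]
      counts <- base
      counts[extra] <- counts[extra] + 1L
      splits <- rep(1:3, counts)
      out$train <- c(out$train, idx[splits == 1])
      out$validation <- c(out$validation, idx[splits == 2])
      out$test <- c(out$test, idx[splits == 3])
    }
  })
  if (any(lengths(out) == 0)) {
    stop_validation("a split received 0 records; enlarge the cohort")
  }
  structure(lapply(out, sort), class = "split_indices")
}

# --- the user-facing fitted-model interface -----------------------------

#' Fit a back-propagation neural network
#'
#' Classic regression interface to the from-scratch back-propagation
#' network: one hidden layer of six tanh units by default, identity
#' output, trained by full-batch scaled conjugate gradient (default) or by
#' sequential (per-pattern) gradient descent with learning rate
#' `eta = 0.4`. Inputs and the target are standardized on the training set
#' (inverted on prediction). If validation data are supplied, the
#' returned model is the snapshot from the epoch with minimum validation
#' RMSE (early stopping).
#'
#' @param x Numeric feature matrix (or a formula; see
#'   [bpnn.formula()]).
#' @param y Numeric response vector or single-column matrix.
#' @param hidden Hidden-layer layout (vector of unit counts); default 6.
#' @param eta Learning rate in (0, 1), default 0.4; sequential mode only.
#' @param optimizer `"scg"` (default) or `"sequential"`.
#' @param max_epochs,patience,conv_tol Stopping controls; see
#'   [bpnn_train()].
#' @param init_scale Half-width of the uniform weight initialization;
#'   the small default starts the network near-linear, which stabilizes
#'   scaled-conjugate-gradient training on standardized inputs.
#' @param activation Hidden nonlinearity, `"tanh"` (default) or
#'   `"identity"`.
#' @param seed Integer seed (weight init and pattern order).
#' @param validation Optional list with elements `x` and `y`: held-out
#'   data for early stopping.
#' @param scale_x,scale_y Standardize inputs / target on the training set
#'   (default `TRUE`).
#' @param ... Unused.
#' @return An object of class `bpnn` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `fitted` and `residuals` methods. The `trace`
#'   element holds per-epoch train/validation RMSE (the learning-curve
#'   analogue used to diagnose overtraining), `best_epoch` the selected
#'   epoch, and `stopped_reason` why training ended.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(120), 40, 3)
#' y <- x %*% c(1, -2, 0.5)
#' fit <- bpnn(x, y, max_epochs = 50, seed = 2)
#' cor(predict(fit, x), y)
#' @export
bpnn <- function(x, ...) UseMethod("bpnn")

#' @rdname bpnn
#' @export
bpnn.default <- function(x, y, hidden = 6L, eta = 0.4,
                         optimizer = c("scg", "sequential"),
                         max_epochs = 300L, patience = 25L, conv_tol = 1e-8,
                         init_scale = 0.2, activation = c("tanh", "identity"),
                         seed = 1L, validation = NULL,
                         scale_x = TRUE, scale_y = TRUE, ...) {
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  xc <- if (scale_x) colMeans(x) else numeric(ncol(x))
  xs <- if (scale_x) pmax(apply(x, 2, stats::sd), 1e-12) else rep(1, ncol(x))
  yc <- if (scale_y) colMeans(y) else numeric(ncol(y))
  ys <- if (scale_y) pmax(apply(y, 2, stats::sd), 1e-12) else rep(1, ncol(y))
  xt <- sweep(sweep(x, 2, xc), 2, xs, "/")
  yt <- sweep(sweep(y, 2, yc), 2, ys, "/")
  vx <- vy <- NULL
  if (!is.null(validation)) {
    vx <- sweep(sweep(as.matrix(validation$x), 2, xc), 2, xs, "/")
    vy <- sweep(sweep(as.matrix(validation$y), 2, yc), 2, ys, "/")
  }
  net0 <- bpnn_init(ncol(x), hidden, ncol(y), init_scale, seed,
                    activation = match.arg(activation))
  run <- bpnn_train(net0, xt, yt, vx, vy, eta = eta, optimizer = optimizer,
                    max_epochs = max_epochs, patience = patience,
                    conv_tol = conv_tol, seed = seed)
  obj <- structure(list(
    net = run$net, trace = run$trace, best_epoch = run$best_epoch,
    stopped_reason = run$stopped_reason,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    hidden = hidden, eta = eta, optimizer = optimizer, seed = seed,
    call = match.call()), class = "bpnn")
  obj$fitted.values <- predict(obj, x)
  obj$residuals <- as.numeric(y) - obj$fitted.values
  obj
}

#' Formula interface to [bpnn()]
#'
#' @param formula Model formula; the intercept is dropped (the network has
#'   biases of its own).
#' @param data Data frame holding the variables.
#' @param ... Passed to [bpnn.default()].
#' @export
#' @method bpnn formula
bpnn.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  mt <- attr(mf, "terms")
  x <- stats::model.matrix(mt, mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  y <- stats::model.response(mf)
  fit <- bpnn.default(x, y, ...)
  fit$terms <- mt
  fit$call <- match.call()
  fit
}

#' @rdname bpnn
#' @param object,newdata A fitted `bpnn` and new feature data (matrix or,
#'   for formula fits, a data frame).
#' @export
predict.bpnn <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    x <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  } else {
    x <- as.matrix(newdata)
  }
  xt <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, "/")
  o <- bpnn_forward(object$net, xt)
  drop(sweep(sweep(o, 2, object$y_scale, "*"), 2, object$y_center, "+"))
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> %s network, optimizer = %s\n",
              paste(x$net$sizes, collapse = "-"), x$optimizer))
  cat(sprintf("  selected epoch %d of %d (%s)\n", x$best_epoch,
              nrow(x$trace), x$stopped_reason))
  if (any(is.finite(x$trace$val_rmse))) {
    cat(sprintf("  train RMSE %.4g, validation RMSE %.4g at selected epoch\n",
                x$trace$train_rmse[x$best_epoch],
                x$trace$val_rmse[x$best_epoch]))
  } else {
    cat(sprintf("  final train RMSE %.4g\n",
                x$trace$train_rmse[nrow(x$trace)]))
  }
  invisible(x)
}

#' @export
summary.bpnn <- function(object, ...) {
  out <- list(sizes = object$net$sizes, optimizer = object$optimizer,
              eta = object$eta, n_weights = length(net_flatten(object$net)),
              best_epoch = object$best_epoch,
              stopped_reason = object$stopped_reason,
              trace = object$trace,
              train_rmse = object$trace$train_rmse[object$best_epoch],
              val_rmse = object$trace$val_rmse[object$best_epoch])
  class(out) <- "summary.bpnn"
  out
}

#' @export
print.summary.bpnn <- function(x, ...) {
  cat(sprintf("Back-propagation network %s (%d weights+biases), %s\n",
              paste(x$sizes, collapse = "-"), x$n_weights, x$optimizer))
  if (x$optimizer == "sequential") cat(sprintf("  learning rate eta = %g\n", x$eta))
  cat(sprintf("  epochs run: %d; selected: %d (%s)\n",
              nrow(x$trace), x$best_epoch, x$stopped_reason))
  cat(sprintf("  RMSE at selected epoch: train %.4g, validation %s\n",
              x$train_rmse,
              ifelse(is.finite(x$val_rmse), sprintf("%.4g", x$val_rmse), "n/a")))
  invisible(x)
}

#' @export
coef.bpnn <- function(object, ...) {
  th <- net_flatten(object$net)
  nm <- character(0)
  for (l in seq_along(object$net$W)) {
    d <- dim(object$net$W[[l]])
    nm <- c(nm, sprintf("W%d[%d,%d]", l, rep(seq_len(d[1]), d[2]),
                        rep(seq_len(d[2]), each = d[1])))
  }
  for (l in seq_along(object$net$b)) {
    nm <- c(nm, sprintf("b%d[%d]", l, seq_along(object$net$b[[l]])))
  }
  stats::setNames(th, nm)
}

#' @export
residuals.bpnn <- function(object, ...) object$residuals

#' Plot the training and validation RMSE learning curves
#'
#' The per-epoch RMSE trace with the selected (early-stopping) epoch
#' marked — the standard overtraining diagnostic: the validation curve
#' rising while the training curve still falls indicates overtraining.
#'
#' @param x A fitted [bpnn()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bpnn <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$train_rmse, tr$val_rmse), type = "l",
                    lty = c(1, 2), col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "RMSE", ...)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
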
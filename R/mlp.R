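#' Configuration for the multilayer-perceptron regressor
#'
#' A single hidden layer of `hidden` tanh units with a linear output unit,
#' trained to minimize mean squared error. Inputs and the response are
#' min-max scaled to \[-1, 1\] before training. The optional cascade
#' variant adds direct input-to-output skip connections.
#'
#' @param hidden Number of hidden units (>= 1).
#' @param trainer `"levenberg_marquardt"` (damped Gauss-Newton on the
#'   residual Jacobian) or `"bfgs"` (quasi-Newton on the training MSE).
#' @param fractions Train/validation/test fractions; must sum to 1.
#' @param seed Integer seed controlling the data split and weight init.
#' @param max_epochs Maximum number of weight updates.
#' @param patience Validation checks without improvement before stopping.
#' @param cascade Add input-to-output skip connections.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(hidden = 5L,
                       trainer = c("levenberg_marquardt", "bfgs"),
                       fractions = c(0.70, 0.15, 0.15),
                       seed = 1L, max_epochs = 100L, patience = 6L,
                       cascade = FALSE) {
  trainer <- match.arg(trainer)
  stopifnot(hidden >= 1L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-9, max_epochs >= 1L, patience >= 1L)
  structure(
    list(hidden = as.integer(hidden), trainer = trainer,
         fractions = fractions, seed = as.integer(seed),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), cascade = isTRUE(cascade)),
    class = "mlp_config"
  )
}

#' Seeded train/validation/test split
#'
#' Indices are shuffled reproducibly and allocated as
#' `round(n * f_train)` to training, `floor(n * f_val)` to validation and
#' the remainder to test, so 17 points under 0.70/0.15/0.15 give 12/2/3.
#'
#' @param n Number of observations (>= 5).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(n >= 5L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-9)
  n_train <- round(n * fractions[1L])
  n_val <- floor(n * fractions[2L])
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L) {
    stop("split would leave an empty partition", call. = FALSE)
  }
  idx <- withr_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(n_train)]),
       validation = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[n_train + n_val + seq_len(n_test)]))
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

n_params <- function(hidden, n_in, cascade) {
  hidden * n_in + hidden + hidden + 1L + if (cascade) n_in else 0L
}

mlp_unpack <- function(theta, hidden, n_in, cascade) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(hidden * n_in)], hidden, n_in); i <- i + hidden * n_in
  b1 <- theta[i + seq_len(hidden)]; i <- i + hidden
  w2 <- theta[i + seq_len(hidden)]; i <- i + hidden
  b2 <- theta[i + 1L]; i <- i + 1L
  w3 <- if (cascade) theta[i + seq_len(n_in)] else NULL
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, w3 = w3)
}

#' Forward pass of the perceptron on (already scaled) inputs
#'
#' Exposed so that gradient checks and hand-computed toy networks can drive
#' the network directly.
#'
#' @param theta Numeric parameter vector (hidden weights, hidden biases,
#'   output weights, output bias, then skip weights if `cascade`).
#' @param X Input matrix, one row per sample.
#' @param hidden Number of hidden units.
#' @param cascade Whether skip connections are present.
#' @return Numeric vector of network outputs.
#' @export
mlp_forward <- function(theta, X, hidden, cascade = FALSE) {
  X <- as.matrix(X)
  p <- mlp_unpack(theta, hidden, ncol(X), cascade)
  Z <- tanh(sweep(X %*% t(p$W1), 2L, p$b1, "+"))
  out <- drop(Z %*% p$w2) + p$b2
  if (cascade) out <- out + drop(X %*% p$w3)
  out
}

# Jacobian of the network output wrt theta: n x n_params
mlp_jacobian <- function(theta, X, hidden, cascade = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); n_in <- ncol(X)
  p <- mlp_unpack(theta, hidden, n_in, cascade)
  A <- sweep(X %*% t(p$W1), 2L, p$b1, "+")
  Z <- tanh(A)
  dZ <- 1 - Z^2                                   # n x hidden
  S <- sweep(dZ, 2L, p$w2, "*")                   # w2_j * (1 - z_j^2)
  JW1 <- matrix(0, n, hidden * n_in)
  for (k in seq_len(n_in)) {
    JW1[, (k - 1L) * hidden + seq_len(hidden)] <- S * X[, k]
  }
  J <- cbind(JW1, S, Z, 1)
  if (cascade) J <- cbind(J, X)
  J
}

#' Gradient of the mean-squared-error loss of the perceptron
#'
#' @inheritParams mlp_forward
#' @param y Target vector (scaled scale).
#' @return Gradient vector, same length as `theta`.
#' @export
mlp_loss_gradient <- function(theta, X, y, hidden, cascade = FALSE) {
  r <- mlp_forward(theta, X, hidden, cascade) - y
  drop(2 * crossprod(mlp_jacobian(theta, X, hidden, cascade), r)) / length(y)
}

# Nguyen-Widrow placement of the tanh units' active regions across the
# scaled input cube; the output layer starts at zero so the network begins
# as a constant and grows complexity only as the optimizer demands it.
mlp_init <- function(hidden, n_in, cascade) {
  W1 <- matrix(stats::runif(hidden * n_in, -1, 1), hidden, n_in)
  scale <- 0.7 * hidden^(1 / n_in)
  W1 <- W1 / sqrt(rowSums(W1^2)) * scale
  b1 <- scale * seq(-1, 1, length.out = hidden) * sign(W1[, 1L])
  c(as.vector(W1), b1, rep(0, hidden), 0,
    if (cascade) rep(0, n_in) else NULL)
}

minmax_scale <- function(x, lo, hi) {
  if (hi - lo == 0) return(x * 0)
  2 * (x - lo) / (hi - lo) - 1
}
minmax_unscale <- function(s, lo, hi) (s + 1) / 2 * (hi - lo) + lo

#' Train the perceptron on a designed experiment
#'
#' Minimizes the training mean squared error with either a
#' Levenberg-Marquardt update (damping multiplied by 10 on a failed step,
#' divided by 10 on success) or BFGS steps, checking the validation MSE
#' after every epoch and keeping the weights from the best validation
#' epoch. Training stops at `max_epochs`, when the damping overflows, or
#' when the validation MSE has not improved for `patience` checks.
#'
#' @param design A [bbd_design()] or numeric input matrix.
#' @param y Response vector aligned with the rows of `design`.
#' @param config An [mlp_config()].
#' @return Object of class `trained_mlp`: parameter vector `theta` (best
#'   validation epoch), scaling ranges, the split, per-epoch `history`
#'   (train and validation MSE on the scaled scale), `stopped_epoch` and
#'   `best_epoch`.
#' @export
train_mlp <- function(design, y, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"))
  X <- if (inherits(design, "bbd_design")) coded_matrix(design) else as.matrix(design)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))

  x_lo <- apply(X, 2L, min); x_hi <- apply(X, 2L, max)
  y_lo <- min(y); y_hi <- max(y)
  Xs <- mapply(function(j) minmax_scale(X[, j], x_lo[j], x_hi[j]),
               seq_len(ncol(X)))
  Xs <- matrix(Xs, nrow = nrow(X))
  ys <- minmax_scale(y, y_lo, y_hi)

  split <- split_data(length(y), config$fractions, config$seed)
  Xtr <- Xs[split$train, , drop = FALSE]; ytr <- ys[split$train]
  Xva <- Xs[split$validation, , drop = FALSE]; yva <- ys[split$validation]

  np <- n_params(config$hidden, ncol(X), config$cascade)
  theta <- withr_seed(config$seed + 1L,
                      mlp_init(config$hidden, ncol(X), config$cascade))

  sse <- function(th, Xm, ym) {
    r <- mlp_forward(th, Xm, config$hidden, config$cascade) - ym
    sum(r^2)
  }
  mse_va <- function(th) sse(th, Xva, yva) / length(yva)

  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  best <- list(theta = theta, val = mse_va(theta), epoch = 0L)
  bad_checks <- 0L
  lambda <- 1e-2
  epoch <- 0L

  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    cur_sse <- sse(theta, Xtr, ytr)
    if (!is.finite(cur_sse)) {
      cond <- simpleError("training diverged: non-finite loss")
      cond$history <- history
      stop(cond)
    }
    if (config$trainer == "levenberg_marquardt") {
      r <- mlp_forward(theta, Xtr, config$hidden, config$cascade) - ytr
      J <- mlp_jacobian(theta, Xtr, config$hidden, config$cascade)
      JtJ <- crossprod(J); Jtr <- crossprod(J, r)
      accepted <- FALSE
      while (!accepted && lambda < 1e12) {
        delta <- tryCatch(
          -solve(JtJ + lambda * diag(np), Jtr),
          error = function(e) NULL
        )
        if (!is.null(delta)) {
          cand <- theta + drop(delta)
          if (is.finite(sse(cand, Xtr, ytr)) && sse(cand, Xtr, ytr) < cur_sse) {
            theta <- cand; lambda <- lambda / 10; accepted <- TRUE
          }
        }
        if (!accepted) lambda <- lambda * 10
      }
      if (!accepted) break  # damping overflow: converged
    } else {
      opt <- stats::optim(theta, fn = sse, gr = function(th, Xm, ym) {
        drop(2 * crossprod(mlp_jacobian(th, Xm, config$hidden, config$cascade),
                           mlp_forward(th, Xm, config$hidden, config$cascade) - ym))
      }, Xm = Xtr, ym = ytr, method = "BFGS",
      control = list(maxit = 1, reltol = 1e-14))
      theta <- opt$par
    }

    tr_mse <- sse(theta, Xtr, ytr) / length(ytr)
    va_mse <- mse_va(theta)
    history <- rbind(history, data.frame(epoch = epoch, train_mse = tr_mse,
                                         val_mse = va_mse))
    if (va_mse < best$val - 1e-15) {
      best <- list(theta = theta, val = va_mse, epoch = epoch)
      bad_checks <- 0L
    } else {
      bad_checks <- bad_checks + 1L
      if (bad_checks >= config$patience) break
    }
  }

  structure(
    list(theta = best$theta, config = config,
         x_range = rbind(lo = x_lo, hi = x_hi),
         y_range = c(lo = y_lo, hi = y_hi),
         split = split, history = history,
         stopped_epoch = epoch, best_epoch = best$epoch),
    class = "trained_mlp"
  )
}

#' Predict from a trained perceptron
#'
#' @param object A [train_mlp()] result.
#' @param X New inputs: a coded matrix, 3-vector, or `bbd_design`.
#' @param ... Unused.
#' @return Predictions on the original response scale.
#' @export
predict.trained_mlp <- function(object, X, ...) {
  if (inherits(X, "bbd_design")) X <- coded_matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = ncol(object$x_range), byrow = TRUE)
  if (ncol(X) != ncol(object$x_range)) {
    stop("input dimension does not match the trained network", call. = FALSE)
  }
  Xs <- mapply(function(j) minmax_scale(X[, j], object$x_range["lo", j],
                                        object$x_range["hi", j]),
               seq_len(ncol(X)))
  Xs <- matrix(Xs, nrow = nrow(X))
  s <- mlp_forward(object$theta, Xs, object$config$hidden,
                   object$config$cascade)
  minmax_unscale(s, object$y_range["lo"], object$y_range["hi"])
}

#' @export
print.trained_mlp <- function(x, ...) {
  cat(sprintf(
    "MLP (%d tanh hidden units, %s%s): stopped at epoch %d, best validation epoch %d\n",
    x$config$hidden, x$config$trainer,
    if (x$config$cascade) ", cascade" else "", x$stopped_epoch, x$best_epoch))
  invisible(x)
}

#' Train over several seeds and keep the best overall fit
#'
#' Small networks on small designs are sensitive to initialization, so the
#' customary practice is a short seed sweep keeping the network with the
#' highest overall R-squared against all observations.
#'
#' @inheritParams train_mlp
#' @param seeds Integer vector of seeds to sweep.
#' @return The best `trained_mlp`, with the achieved overall R2 in
#'   `$overall_r2`.
#' @export
train_mlp_best <- function(design, y, config = mlp_config(),
                           seeds = 1:10) {
  X <- if (inherits(design, "bbd_design")) coded_matrix(design) else as.matrix(design)
  best <- NULL
  for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    m <- tryCatch(train_mlp(X, y, cfg), error = function(e) NULL)
    if (is.null(m)) next
    r2 <- 1 - sum((y - predict(m, X))^2) / sum((y - mean(y))^2)
    if (is.null(best) || r2 > best$overall_r2) {
      m$overall_r2 <- r2
      best <- m
    }
  }
  if (is.null(best)) stop("all seeds diverged", call. = FALSE)
  best
}
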
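test_that("the split allocates round/floor/remainder and is reproducible", {
  s <- split_data(17, c(0.7, 0.15, 0.15), seed = 1)
  expect_equal(lengths(s), c(train = 12L, validation = 2L, test = 3L))
  expect_equal(sort(unlist(s)), 1:17, ignore_attr = TRUE)
  s20 <- split_data(20, c(0.7, 0.15, 0.15), seed = 9)
  expect_equal(lengths(s20), c(train = 14L, validation = 3L, test = 3L))
  expect_identical(split_data(17, seed = 5), split_data(17, seed = 5))
  expect_false(identical(split_data(17, seed = 5), split_data(17, seed = 6)))
  expect_error(split_data(5, c(0.98, 0.01, 0.01)), "empty partition")
})

test_that("the forward pass matches a hand-computed two-weight network", {
  # 1 hidden unit, 1 input: y = w2 * tanh(w1 x + b1) + b2
  theta <- c(0.7, -0.2, 1.5, 0.3)  # w1, b1, w2, b2
  x <- matrix(c(-1, 0, 2), ncol = 1)
  expect_equal(mlp_forward(theta, x, hidden = 1),
               1.5 * tanh(0.7 * c(-1, 0, 2) - 0.2) + 0.3)
  # zero output layer predicts the output bias everywhere
  theta0 <- c(0.7, -0.2, 0, 0.3)
  expect_equal(mlp_forward(theta0, x, hidden = 1), rep(0.3, 3))
})

test_that("the analytic loss gradient matches central finite differences", {
  set.seed(21)
  for (cascade in c(FALSE, TRUE)) {
    X <- matrix(stats::runif(15, -1, 1), 5, 3)
    y <- stats::runif(5, -1, 1)
    np <- 4 * 4 + 5 + if (cascade) 3 else 0  # hidden 4, input 3
    theta <- stats::runif(np, -1, 1)
    ana <- mlp_loss_gradient(theta, X, y, hidden = 4, cascade = cascade)
    h <- 1e-6
    num <- vapply(seq_along(theta), function(j) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (mean((mlp_forward(tp, X, 4, cascade) - y)^2) -
         mean((mlp_forward(tm, X, 4, cascade) - y)^2)) / (2 * h)
    }, numeric(1))
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("a one-unit network learns noise-free linear data", {
  set.seed(5)
  X <- matrix(stats::runif(60, -1, 1), 20, 3)
  y <- drop(X %*% c(0.4, -0.3, 0.2)) + 0.1
  m <- train_mlp(X, y, mlp_config(hidden = 1, seed = 3))
  tr <- m$split$train
  mse <- mean((predict(m, X[tr, , drop = FALSE]) - y[tr])^2)
  expect_lt(mse, 1e-4)
})

test_that("training is reproducible for a fixed seed and early stopping returns the best epoch", {
  d <- ums_design(); y <- ums_responses()$tpc
  m1 <- train_mlp(d, y, mlp_config(seed = 2))
  m2 <- train_mlp(d, y, mlp_config(seed = 2))
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$history, m2$history)
  # returned weights correspond to the minimum recorded validation MSE
  if (m1$best_epoch > 0) {
    expect_equal(m1$best_epoch,
                 m1$history$epoch[which.min(m1$history$val_mse)])
  }
})

test_that("the bfgs trainer runs and reduces the training loss", {
  set.seed(8)
  X <- matrix(stats::runif(60, -1, 1), 20, 3)
  y <- drop(X %*% c(1, -1, 0.5))
  m <- train_mlp(X, y, mlp_config(hidden = 2, trainer = "bfgs", seed = 1,
                                  max_epochs = 60, patience = 60))
  expect_lt(utils::tail(m$history$train_mse, 1), m$history$train_mse[1])
})

test_that("predict validates input dimensions and inverts the scaling", {
  d <- ums_design(); y <- ums_responses()$tpc
  m <- train_mlp(d, y, mlp_config(seed = 4))
  p <- predict(m, d)
  expect_length(p, 17L)
  expect_true(all(is.finite(p)))
  expect_error(predict(m, matrix(0, 2, 2)), "dimension")
})
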
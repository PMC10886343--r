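test_that("refitting the phenolic-content response reproduces the printed equation", {
  fit <- fit_quadratic(ums_design(), ums_responses()$tpc, "TPC")
  b <- unname(coef(fit))
  # printed at 2 or 4 decimals; paper-side rounding is within 0.01 / 0.002
  printed_2dp <- c(1, 5, 6, 7, 9, 10)
  expect_equal(b[printed_2dp], eq_tpc_printed[printed_2dp], tolerance = 0.01)
  expect_equal(b[-printed_2dp], eq_tpc_printed[-printed_2dp],
               tolerance = 0.002)
})

test_that("refitting the flavonoid-content response reproduces the printed equation", {
  fit <- fit_quadratic(ums_design(), ums_responses()$tfc, "TFC")
  expect_equal(unname(coef(fit)), eq_tfc_printed, tolerance = 0.011)
  expect_equal(coef(fit)[["(Intercept)"]], 57.42, tolerance = 0.01)
  expect_equal(coef(fit)[["x1:x2"]], -0.1651, tolerance = 0.001)
})

test_that("noise-free synthetic responses are recovered exactly", {
  set.seed(7)
  for (i in 1:5) {
    beta <- random_coefficients()
    sim <- simulate_bbd_responses(beta, sd = 0, factors = random_factors(),
                                  seed = i)
    fit <- fit_quadratic(sim$design, sim$y)
    expect_equal(unname(coef(fit)), beta, tolerance = 1e-9)
  }
})

test_that("fitting rejects short and rank-deficient designs", {
  d <- ums_design()
  expect_error(fit_quadratic(d, 1:5), "does not match")
  # duplicate a single coded point 17 times -> rank deficient
  flat <- d
  flat$x1 <- 1; flat$x2 <- 0; flat$x3 <- 0
  expect_error(fit_quadratic(flat, ums_responses()$tpc), "singular")
})

test_that("model predictions evaluate the ten-term polynomial", {
  m12 <- quadratic_model(eq_tpc_printed, "TPC")
  expect_equal(predict(m12, c(0, 0, 0)), 75.77)
  # printed prediction columns deviate from the exact polynomial by ~0.1
  expect_equal(predict(m12, c(1, -1, 0)), 64.8887, tolerance = 1e-4)
  expect_equal(predict(m12, c(1, -1, 0)), 64.99, tolerance = 0.15)
  m13 <- quadratic_model(eq_tfc_printed, "TFC")
  expect_equal(predict(m13, c(-1, 0, 1)), 37.1591, tolerance = 1e-4)
  expect_equal(predict(m13, c(-1, 0, 1)), 37.14, tolerance = 0.15)
  # residuals orthogonal to the model columns
  fit <- fit_quadratic(ums_design(), ums_responses()$tpc)
  X <- quad_model_matrix(coded_matrix(ums_design()))
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
})

test_that("the ANOVA panel reproduces the printed per-term sums of squares", {
  an <- rsm_anova(fit_quadratic(ums_design(), ums_responses()$tpc, "TPC"))
  ss <- stats::setNames(an$terms$ss, an$terms$source)
  expect_equal(ss[["x1"]], 11.71, tolerance = 0.01)
  expect_equal(ss[["x1:x2"]], 1.58, tolerance = 0.01)
  expect_equal(ss[["x1^2"]], 277.93, tolerance = 0.01)
  expect_equal(an$r2, 0.9928, tolerance = 5e-4)
  expect_equal(an$model$f, 107.80, tolerance = 0.01)
})

test_that("partial SS of orthogonal terms equals the closed form", {
  # for a Box-Behnken layout, linear terms have Sum x^2 = 8 and
  # interactions 4; the drop-term refit must agree with beta^2 * Sxx
  set.seed(11)
  for (i in 1:5) {
    sim <- simulate_bbd_responses(random_coefficients(), sd = 1, seed = 40 + i)
    fit <- fit_quadratic(sim$design, sim$y)
    an <- rsm_anova(fit)
    b <- coef(fit)
    for (term in c("x1", "x2", "x3")) {
      expect_equal(an$terms$ss[an$terms$source == term],
                   unname(b[term])^2 * 8, tolerance = 1e-6)
    }
    for (term in c("x1:x2", "x1:x3", "x2:x3")) {
      expect_equal(an$terms$ss[an$terms$source == term],
                   unname(b[term])^2 * 4, tolerance = 1e-6)
    }
  }
})

test_that("sums of squares and degrees of freedom partition the total", {
  check_partition <- function(an, n) {
    expect_equal(an$model$ss + an$lack_of_fit$ss + an$pure_error$ss,
                 an$total$ss, tolerance = 1e-6 * an$total$ss)
    expect_equal(an$model$df + an$lack_of_fit$df + an$pure_error$df,
                 an$total$df)
    expect_equal(an$total$df, n - 1L)
    expect_true(all(c(an$terms$ss, an$lack_of_fit$ss, an$pure_error$ss) >= 0))
    expect_lte(an$pred_r2, an$r2)
  }
  check_partition(rsm_anova(fit_quadratic(ums_design(), ums_responses()$tpc)),
                  17L)
  set.seed(3)
  for (i in 1:100) {
    cp <- sample(2:6, 1)
    sim <- simulate_bbd_responses(random_coefficients(),
                                  sd = stats::runif(1, 0.1, 2),
                                  center_points = cp, seed = 500 + i)
    check_partition(rsm_anova(fit_quadratic(sim$design, sim$y)), 12L + cp)
  }
})

test_that("hat-matrix PRESS equals brute-force leave-one-out refitting", {
  d <- ums_design()
  y <- ums_responses()$tpc
  an <- rsm_anova(fit_quadratic(d, y))
  X <- quad_model_matrix(coded_matrix(d))
  press_loo <- sum(vapply(seq_along(y), function(i) {
    b <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
    (y[i] - drop(X[i, ] %*% b))^2
  }, numeric(1)))
  expect_equal(an$press, press_loo, tolerance = 1e-8)
})

test_that("lack of fit requires replicated runs", {
  sim <- simulate_bbd_responses(random_coefficients(), sd = 1, seed = 2)
  keep <- c(which(!sim$design$is_center), which(sim$design$is_center)[1])
  d <- sim$design[keep, ]
  attr(d, "factors") <- attr(sim$design, "factors")
  class(d) <- class(sim$design)
  expect_error(rsm_anova(fit_quadratic(d, sim$y[keep])), "replicated")
})

test_that("coefficient error shrinks proportionally to the noise scale", {
  beta <- c(75, 1.2, -1, 0.15, -8, -5.5, -5.7, -0.6, 0.6, 0.5)
  rmse_at <- function(sigma, seeds) {
    sq <- vapply(seeds, function(s) {
      sim <- simulate_bbd_responses(beta, sd = sigma, seed = s)
      mean((coef(fit_quadratic(sim$design, sim$y)) - beta)^2)
    }, numeric(1))
    sqrt(mean(sq))
  }
  ratio <- rmse_at(1, 1:300) / rmse_at(0.1, 301:600)
  expect_gt(ratio, 8.5)
  expect_lt(ratio, 11.5)
})
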
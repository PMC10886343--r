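test_that("the desirability ramp anchors at its limits", {
  g <- desirability_goal("y", "maximize", low = 10, high = 20)
  expect_equal(desirability(20, g), 1)
  expect_equal(desirability(10, g), 0)
  expect_equal(desirability(15, g), 0.5)
  expect_equal(desirability(c(5, 25), g), c(0, 1))
  # shape exponent bends the ramp
  g2 <- desirability_goal("y", "maximize", low = 10, high = 20, scale = 2)
  expect_equal(desirability(15, g2), 0.25)
  # minimize mirrors maximize
  gm <- desirability_goal("y", "minimize", low = 10, high = 20)
  expect_equal(desirability(10, gm), 1)
  expect_equal(desirability(20, gm), 0)
  gt <- desirability_goal("y", "target", low = 0, high = 20, target = 10)
  expect_equal(desirability(10, gt), 1)
  expect_equal(desirability(c(5, 15), gt), c(0.5, 0.5))
})

test_that("overall desirability is the weighted geometric mean", {
  expect_equal(overall_desirability(c(1, 1)), 1)
  expect_equal(overall_desirability(c(0.9, 0.4)), sqrt(0.36))
  expect_equal(overall_desirability(c(0.5, 0, 0.9)), 0)
  expect_equal(overall_desirability(c(0.9, 0.4), weights = c(3, 1)),
               (0.9^3 * 0.4)^(1 / 4))
})

test_that("a concave single-factor surface is optimized at its center", {
  m <- quadratic_model(c(1, 0, 0, 0, -1, 0, 0, 0, 0, 0), "toy")
  g <- list(toy = desirability_goal("toy", "maximize", low = -1, high = 1))
  opt <- optimize_desirability(list(toy = m), g, random_factors(), step = 0.05)
  expect_equal(opt$coded[1], 0, tolerance = 1e-6)
  expect_equal(opt$predicted[["toy"]], 1, tolerance = 1e-10)
})

test_that("with an unsaturated ramp the optimizer finds the polynomial argmax", {
  # stationary point of the quadratic solved independently from the
  # gradient system 2*A x + b = 0
  fit <- fit_quadratic(ums_design(), ums_responses()$tpc, "TPC")
  b <- coef(fit)
  A <- matrix(c(b["x1^2"], b["x1:x2"] / 2, b["x1:x3"] / 2,
                b["x1:x2"] / 2, b["x2^2"], b["x2:x3"] / 2,
                b["x1:x3"] / 2, b["x2:x3"] / 2, b["x3^2"]), 3, 3)
  stationary <- solve(-2 * A, b[c("x1", "x2", "x3")])
  g <- list(TPC = desirability_goal("TPC", "maximize", low = 0, high = 100))
  opt <- optimize_desirability(list(TPC = fit), g, ums_factors(), step = 0.05)
  expect_equal(opt$coded, unname(stationary), tolerance = 1e-3)
})

test_that("the joint optimum of the extraction study lands on the reported conditions", {
  d <- ums_design(); rs <- ums_responses()
  fits <- list(TPC = fit_quadratic(d, rs$tpc, "TPC"),
               TFC = fit_quadratic(d, rs$tfc, "TFC"))
  goals <- observed_range_goals(list(TPC = rs$tpc, TFC = rs$tfc))
  opt <- optimize_desirability(fits, goals, ums_factors())
  expect_equal(unname(opt$actual["ec_pct"]), 61.43, tolerance = 0.5)
  expect_equal(unname(opt$actual["time_min"]), 29.60, tolerance = 0.5)
  expect_equal(unname(opt$actual["temp_c"]), 50.24, tolerance = 0.5)
  expect_true(all(abs(opt$coded) <= 1))
  expect_equal(opt$D,
               overall_desirability(opt$d,
                                    vapply(opt$goals, `[[`, numeric(1),
                                           "weight")),
               tolerance = 1e-12)
})

test_that("simplex refinement never degrades the grid optimum", {
  d <- ums_design(); rs <- ums_responses()
  fits <- list(TPC = fit_quadratic(d, rs$tpc, "TPC"),
               TFC = fit_quadratic(d, rs$tfc, "TFC"))
  goals <- observed_range_goals(list(TPC = rs$tpc, TFC = rs$tfc))
  coarse_step <- 0.25
  opt <- optimize_desirability(fits, goals, ums_factors(), step = coarse_step)
  g <- seq(-1, 1, by = coarse_step)
  grid <- as.matrix(expand.grid(x1 = g, x2 = g, x3 = g))
  grid_best <- max(apply(grid, 1L, function(x) {
    overall_desirability(c(
      desirability(predict(fits$TPC, x), goals$TPC),
      desirability(predict(fits$TFC, x), goals$TFC)))
  }))
  expect_gte(opt$D, grid_best - 1e-12)
})

test_that("raising the upper anchor of a maximize goal cannot raise the optimum", {
  d <- ums_design(); rs <- ums_responses()
  fits <- list(TPC = fit_quadratic(d, rs$tpc, "TPC"))
  base <- desirability_goal("TPC", "maximize", low = 60, high = 76)
  widened <- desirability_goal("TPC", "maximize", low = 60, high = 85)
  o1 <- optimize_desirability(fits, list(TPC = base), ums_factors(),
                              step = 0.05)
  o2 <- optimize_desirability(fits, list(TPC = widened), ums_factors(),
                              step = 0.05)
  expect_lte(o2$D, o1$D + 1e-12)
})
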
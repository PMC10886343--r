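#' Define a Derringer desirability goal for one response
#'
#' Each response is mapped onto a 0-1 desirability scale by a (possibly
#' powered) linear ramp between a lower and an upper anchor. For a
#' `maximize` goal the ramp rises from `low` to `high`; for `minimize` it
#' falls; a `target` goal rises to `target` and falls again.
#'
#' @param response Name of the response the goal applies to.
#' @param goal One of `"maximize"`, `"minimize"`, `"target"`.
#' @param low,high Anchors in response units (`low < high`).
#' @param target Target value (required for `goal = "target"`).
#' @param weight Positive weight in the overall geometric mean.
#' @param scale Positive shape exponent of the ramp (1 = linear).
#' @return An object of class `desirability_goal`.
#' @examples
#' desirability_goal("TPC", "maximize", low = 60.23, high = 76.65)
#' @export
desirability_goal <- function(response, goal = c("maximize", "minimize", "target"),
                              low, high, target = NULL, weight = 1, scale = 1) {
  goal <- match.arg(goal)
  stopifnot(low < high, weight > 0, scale > 0)
  if (goal == "target") {
    stopifnot(!is.null(target), low < target, target < high)
  }
  structure(
    list(response = response, goal = goal, low = low, high = high,
         target = target, weight = weight, scale = scale),
    class = "desirability_goal"
  )
}

#' Desirability of a response value
#'
#' @param y Numeric vector of response values.
#' @param goal A [desirability_goal()].
#' @return Desirabilities in `[0, 1]`, same length as `y`.
#' @examples
#' g <- desirability_goal("y", "maximize", 0, 10)
#' desirability(c(-1, 5, 10, 12), g)  # 0, 0.5, 1, 1
#' @export
desirability <- function(y, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  ramp_up <- function(y, l, u) pmin(pmax((y - l) / (u - l), 0), 1)^goal$scale
  switch(goal$goal,
    maximize = ramp_up(y, goal$low, goal$high),
    minimize = ramp_up(-y, -goal$high, -goal$low),
    target = ifelse(y <= goal$target,
                    ramp_up(y, goal$low, goal$target),
                    ramp_up(-y, -goal$high, -goal$target))
  )
}

#' Overall desirability as a weighted geometric mean
#'
#' D = (prod d_i^w_i)^(1 / sum w_i). Any individual desirability of zero
#' annihilates the product, so a configuration unacceptable on one response
#' has overall desirability zero.
#'
#' @param d Numeric vector of per-response desirabilities in `[0, 1]`.
#' @param weights Positive weights, one per response (default equal).
#' @return A single value in `[0, 1]`.
#' @examples
#' overall_desirability(c(0.9, 0.4))  # sqrt(0.36)
#' @export
overall_desirability <- function(d, weights = rep(1, length(d))) {
  stopifnot(length(d) == length(weights), all(weights > 0),
            all(d >= 0 & d <= 1))
  if (any(d == 0)) return(0)
  exp(sum(weights * log(d)) / sum(weights))
}

#' Default maximize goals spanning the observed response range
#'
#' The conventional anchor choice when no product specification exists:
#' a linear maximize ramp from the observed minimum to the observed maximum
#' of each experimental response column.
#'
#' @param responses Named list of numeric response vectors.
#' @return Named list of [desirability_goal()] objects.
#' @export
observed_range_goals <- function(responses) {
  stats::setNames(
    lapply(names(responses), function(nm) {
      desirability_goal(nm, "maximize",
                        low = min(responses[[nm]]),
                        high = max(responses[[nm]]))
    }),
    names(responses)
  )
}

#' Jointly optimize several fitted responses by desirability
#'
#' Maximizes the overall Derringer desirability of one or more fitted
#' quadratic models over the coded cube \[-1, 1\]^3: a dense grid scan
#' (default step 0.01 coded units) locates the basin, then Nelder-Mead
#' refinement polishes the optimum (clamped to the cube). Grid ties are
#' broken toward the smallest coded norm.
#'
#' @param models Named list of `rsm_quadratic` models.
#' @param goals Named list of [desirability_goal()]s covering every model.
#' @param factors List of three [factor_spec()]s used to decode the optimum
#'   into actual units.
#' @param step Grid step in coded units.
#' @return An object of class `desirability_optimum`: list with `coded`,
#'   `actual` (named by factor), `predicted` (per response), `d` (per
#'   response), `D`, and the goals used.
#' @examples
#' d <- ums_design(); rs <- ums_responses()
#' fits <- list(TPC = fit_quadratic(d, rs$tpc, "TPC"),
#'              TFC = fit_quadratic(d, rs$tfc, "TFC"))
#' opt <- optimize_desirability(fits, observed_range_goals(list(TPC = rs$tpc, TFC = rs$tfc)),
#'                              ums_factors(), step = 0.05)
#' opt$actual
#' @export
optimize_desirability <- function(models, goals, factors, step = 0.01) {
  stopifnot(length(models) >= 1L, all(names(models) %in% names(goals)))
  goals <- goals[names(models)]
  weights <- vapply(goals, `[[`, numeric(1), "weight")

  d_at <- function(coded) {
    # coded: n x 3 matrix -> n x k matrix of per-response desirabilities
    vapply(names(models), function(nm) {
      desirability(predict(models[[nm]], coded), goals[[nm]])
    }, numeric(nrow(coded)))
  }
  D_of_d <- function(dmat) {
    dmat <- pmax(dmat, 0)
    ifelse(apply(dmat == 0, 1L, any), 0,
           exp(drop(log(dmat) %*% weights) / sum(weights)))
  }
  D_at <- function(x) {
    m <- matrix(pmin(pmax(x, -1), 1), ncol = 3L)
    D_of_d(matrix(d_at(m), nrow = nrow(m)))
  }

  g <- seq(-1, 1, by = step)
  best <- c(0, 0, 0); best_D <- -Inf
  slice <- as.matrix(expand.grid(x1 = g, x2 = g))
  for (x3 in g) {
    pts <- cbind(slice, x3 = x3)
    D <- D_at(pts)
    top <- which(D > best_D - 1e-15)
    if (length(top)) {
      # among near-ties prefer the smallest coded norm
      cand <- top[which.max(D[top] - 1e-9 * rowSums(pts[top, , drop = FALSE]^2))]
      if (D[cand] > best_D ||
          (abs(D[cand] - best_D) <= 1e-15 &&
           sum(pts[cand, ]^2) < sum(best^2))) {
        best_D <- D[cand]; best <- pts[cand, ]
      }
    }
  }

  grid_D <- best_D
  if (best_D <= 0) {
    warning("desirability surface is zero everywhere on the grid; ",
            "returning the grid point closest to the center")
    refined <- best
  } else {
    opt <- stats::optim(best, function(x) -D_at(x), method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    refined <- pmin(pmax(opt$par, -1), 1)
    if (-opt$value < grid_D) refined <- best  # refinement never degrades
  }

  coded <- as.numeric(refined)
  pred <- vapply(models, function(m) predict(m, coded), numeric(1))
  dvals <- vapply(names(models),
                  function(nm) desirability(pred[[nm]], goals[[nm]]),
                  numeric(1))
  structure(
    list(coded = coded,
         actual = stats::setNames(decode_points(coded, factors),
                                  vapply(factors, `[[`, character(1), "name")),
         predicted = pred, d = dvals,
         D = overall_desirability(dvals, weights),
         goals = goals),
    class = "desirability_optimum"
  )
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat("Desirability optimum\n")
  cat("  coded: ", paste(sprintf("%.4f", x$coded), collapse = ", "), "\n")
  cat("  actual:", paste(sprintf("%s = %.2f", names(x$actual), x$actual),
                         collapse = ", "), "\n")
  for (nm in names(x$predicted)) {
    cat(sprintf("  %s: predicted %.2f (d = %.3f)\n", nm, x$predicted[[nm]],
                x$d[[nm]]))
  }
  cat(sprintf("  overall D = %.3f\n", x$D))
  invisible(x)
}
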
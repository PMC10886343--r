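#' Coded second-order model matrix
#'
#' Expands coded factor settings into the ten-column model matrix of the
#' full quadratic: intercept, three linear terms, three pure quadratics and
#' three two-way interactions.
#'
#' @param coded Numeric matrix with columns `x1`, `x2`, `x3` (or any matrix
#'   with three columns), or a 3-vector.
#' @return An `n x 10` matrix with columns `(Intercept)`, `x1`, `x2`, `x3`,
#'   `x1^2`, `x2^2`, `x3^2`, `x1:x2`, `x1:x3`, `x2:x3`.
#' @export
quad_model_matrix <- function(coded) {
  if (!is.matrix(coded)) coded <- matrix(coded, ncol = 3L, byrow = TRUE)
  stopifnot(ncol(coded) == 3L)
  m <- cbind(1, coded, coded^2,
             coded[, 1L] * coded[, 2L],
             coded[, 1L] * coded[, 3L],
             coded[, 2L] * coded[, 3L])
  colnames(m) <- c("(Intercept)", "x1", "x2", "x3",
                   "x1^2", "x2^2", "x3^2", "x1:x2", "x1:x3", "x2:x3")
  m
}

#' Fit a second-order response-surface model on coded factors
#'
#' Ordinary least squares fit of the ten-term quadratic polynomial
#' y = b0 + sum bi xi + sum bii xi^2 + sum bij xi xj to the responses of a
#' designed experiment, with the factors on the coded -1..+1 scale.
#'
#' @param design A [bbd_design()] (or any data frame with coded columns
#'   `x1`, `x2`, `x3`).
#' @param y Numeric response vector aligned with the design rows.
#' @param response Name of the response (used in printing and reports).
#' @param units Units of the response, e.g. `"mg GAE/g"`.
#'
#' @return An object of class `rsm_quadratic` with elements `coefficients`
#'   (length 10, named), `fitted`, `residuals`, `design`, `y`, `response`,
#'   `units`.
#' @examples
#' d <- ums_design()
#' fit <- fit_quadratic(d, ums_responses()$tpc, "TPC", "mg GAE/g")
#' round(coef(fit), 2)
#' @export
fit_quadratic <- function(design, y, response = "y", units = "") {
  X <- quad_model_matrix(coded_matrix(design))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("response length does not match the design", call. = FALSE)
  }
  if (nrow(X) < ncol(X)) {
    stop("at least 10 runs are needed to fit the full quadratic", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: the coded model matrix is rank deficient",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  structure(
    list(coefficients = beta,
         fitted = as.numeric(X %*% beta),
         residuals = as.numeric(y - X %*% beta),
         design = design, y = y,
         response = response, units = units),
    class = "rsm_quadratic"
  )
}

#' Build a quadratic model directly from known coefficients
#'
#' Useful for evaluating published fitted equations without refitting.
#'
#' @param coefficients Numeric vector of 10 coefficients in model-matrix
#'   order (see [quad_model_matrix()]).
#' @inheritParams fit_quadratic
#' @return An `rsm_quadratic` without data-dependent slots.
#' @export
quadratic_model <- function(coefficients, response = "y", units = "") {
  stopifnot(length(coefficients) == 10L, all(is.finite(coefficients)))
  coefficients <- as.numeric(coefficients)
  names(coefficients) <- colnames(quad_model_matrix(rbind(c(0, 0, 0))))
  structure(
    list(coefficients = coefficients, response = response, units = units),
    class = "rsm_quadratic"
  )
}

#' @export
coef.rsm_quadratic <- function(object, ...) object$coefficients

#' @export
print.rsm_quadratic <- function(x, ...) {
  cat(sprintf("Quadratic response-surface model for %s%s\n", x$response,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a quadratic response-surface model
#'
#' @param object An `rsm_quadratic`.
#' @param coded Coded point(s): a 3-vector or an `n x 3` matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_quadratic <- function(object, coded, ...) {
  as.numeric(quad_model_matrix(coded) %*% object$coefficients)
}

# Pure-error partition: group rows by identical coded settings and sum the
# squared deviations from each replicate-group mean.
pure_error_ss <- function(coded, y) {
  key <- apply(coded, 1L, paste, collapse = "/")
  groups <- split(y, key)
  reps <- groups[vapply(groups, length, integer(1)) > 1L]
  ss <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- sum(vapply(reps, function(g) length(g) - 1L, integer(1)))
  list(ss = ss, df = df)
}

#' ANOVA panel for a quadratic response-surface fit
#'
#' Produces the full diagnostic panel customary for Box-Behnken analyses:
#' per-term partial (type III) sums of squares obtained by dropping each
#' term and refitting, the model row, the residual split into lack of fit
#' and pure error (from replicated runs), and the fit-quality summary
#' (R2, adjusted R2, PRESS-based predicted R2, CV%, adequate precision).
#'
#' @param fit An [fit_quadratic()] result (must carry its data).
#' @param adeq_p Parameter count used in the adequate-precision denominator;
#'   defaults to the 10 model parameters.
#'
#' @return An object of class `rsm_anova`: a list with `terms` (data frame
#'   of per-term rows with columns `source`, `coefficient`, `ss`, `df`,
#'   `ms`, `f`, `p`, `verdict`), `model`, `lack_of_fit`, `pure_error`,
#'   `residual` and `total` rows, and scalar statistics `r2`, `adj_r2`,
#'   `pred_r2`, `press`, `cv_pct`, `adeq_precision`.
#' @examples
#' d <- ums_design()
#' an <- rsm_anova(fit_quadratic(d, ums_responses()$tpc, "TPC"))
#' an$r2
#' @export
rsm_anova <- function(fit, adeq_p = 10L) {
  stopifnot(inherits(fit, "rsm_quadratic"))
  if (is.null(fit$y)) {
    stop("the model carries no data; refit with fit_quadratic()", call. = FALSE)
  }
  y <- fit$y
  coded <- coded_matrix(fit$design)
  X <- quad_model_matrix(coded)
  n <- length(y); p <- ncol(X)

  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  ssm <- sst - sse
  df_res <- n - p
  ms_res <- sse / df_res

  pe <- pure_error_ss(coded, y)
  if (pe$df < 1L) {
    stop("no replicated runs: lack of fit is undefined", call. = FALSE)
  }
  ss_lof <- sse - pe$ss
  df_lof <- df_res - pe$df
  f_lof <- (ss_lof / df_lof) / (pe$ss / pe$df)
  p_lof <- stats::pf(f_lof, df_lof, pe$df, lower.tail = FALSE)

  # partial (type III) SS: increase in SSE when one term is removed
  term_names <- colnames(X)[-1L]
  ss_term <- vapply(term_names, function(tn) {
    Xr <- X[, setdiff(colnames(X), tn), drop = FALSE]
    sum(stats::lm.fit(Xr, y)$residuals^2) - sse
  }, numeric(1))
  f_term <- ss_term / ms_res
  p_term <- stats::pf(f_term, 1, df_res, lower.tail = FALSE)

  verdict <- function(p) {
    ifelse(p < 0.001, "exceptionally significant",
           ifelse(p < 0.01, "highly significant",
                  ifelse(p < 0.05, "significant", "not significant")))
  }

  f_model <- (ssm / (p - 1)) / ms_res
  p_model <- stats::pf(f_model, p - 1, df_res, lower.tail = FALSE)

  h <- diag(X %*% solve(crossprod(X), t(X)))
  if (any(1 - h <= 0)) {
    stop("a leverage of 1 makes PRESS undefined", call. = FALSE)
  }
  press <- sum((fit$residuals / (1 - h))^2)
  r2 <- 1 - sse / sst

  structure(
    list(
      response = fit$response,
      terms = data.frame(
        source = term_names,
        coefficient = fit$coefficients[-1L],
        ss = ss_term, df = 1L, ms = ss_term,
        f = f_term, p = p_term, verdict = verdict(p_term),
        row.names = NULL
      ),
      model = list(ss = ssm, df = p - 1L, ms = ssm / (p - 1),
                   f = f_model, p = p_model, verdict = verdict(p_model)),
      residual = list(ss = sse, df = df_res, ms = ms_res),
      lack_of_fit = list(ss = ss_lof, df = df_lof, ms = ss_lof / df_lof,
                         f = f_lof, p = p_lof, verdict = verdict(p_lof)),
      pure_error = list(ss = pe$ss, df = pe$df, ms = pe$ss / pe$df),
      total = list(ss = sst, df = n - 1L),
      r2 = r2,
      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
      pred_r2 = 1 - press / sst,
      press = press,
      cv_pct = 100 * sqrt(ms_res) / mean(y),
      adeq_precision = (max(fit$fitted) - min(fit$fitted)) /
        sqrt(adeq_p * ms_res / n)
    ),
    class = "rsm_anova"
  )
}

#' @export
print.rsm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("ANOVA for quadratic model: %s\n", x$response))
  tab <- x$terms
  tab$coefficient <- signif(tab$coefficient, digits)
  tab$ss <- signif(tab$ss, digits); tab$ms <- signif(tab$ms, digits)
  tab$f <- signif(tab$f, digits); tab$p <- round(tab$p, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("Model:        SS %.4g on %d df, F = %.2f, p = %.4g\n",
              x$model$ss, x$model$df, x$model$f, x$model$p))
  cat(sprintf("Lack of fit:  SS %.4g on %d df, F = %.2f, p = %.4f\n",
              x$lack_of_fit$ss, x$lack_of_fit$df, x$lack_of_fit$f,
              x$lack_of_fit$p))
  cat(sprintf("Pure error:   SS %.4g on %d df\n", x$pure_error$ss,
              x$pure_error$df))
  cat(sprintf("R2 %.4f | adj R2 %.4f | pred R2 %.4f | CV%% %.2f | adeq precision %.4f\n",
              x$r2, x$adj_r2, x$pred_r2, x$cv_pct, x$adeq_precision))
  invisible(x)
}

#' Export an ANOVA panel as a tidy data frame
#'
#' One row per source (each model term, the model, lack of fit, pure error,
#' total), suitable for writing to CSV.
#'
#' @param anova_panel An [rsm_anova()] result.
#' @return A data frame with columns `source`, `coefficient`, `ss`, `df`,
#'   `ms`, `f`, `p`, `verdict`.
#' @export
anova_as_data_frame <- function(anova_panel) {
  stopifnot(inherits(anova_panel, "rsm_anova"))
  row <- function(source, l, coefficient = NA_real_) {
    data.frame(source = source, coefficient = coefficient,
               ss = l$ss, df = l$df,
               ms = if (is.null(l$ms)) NA_real_ else l$ms,
               f = if (is.null(l$f)) NA_real_ else l$f,
               p = if (is.null(l$p)) NA_real_ else l$p,
               verdict = if (is.null(l$verdict)) "" else l$verdict)
  }
  tab <- anova_panel$terms
  tab$verdict <- as.character(tab$verdict)
  rbind(
    row("model", anova_panel$model),
    cbind(tab[, c("source", "coefficient", "ss", "df", "ms", "f", "p")],
          verdict = tab$verdict),
    row("lack_of_fit", anova_panel$lack_of_fit),
    row("pure_error", anova_panel$pure_error),
    row("total", anova_panel$total)
  )
}
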
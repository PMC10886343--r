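#' Specify an extraction factor and its levels
#'
#' A factor is described by its low, center and high settings in actual
#' units (for instance percent ethanol, minutes of sonication, or degrees
#' Celsius). The center must be the midpoint of the low and high levels so
#' that coded levels -1/0/+1 map linearly onto the actual scale.
#'
#' @param name Character label for the factor.
#' @param low,high Low and high actual levels (`low < high`).
#' @param center Center actual level; defaults to the midpoint.
#'
#' @return An object of class `factor_spec` with elements `name`, `low`,
#'   `center`, `high` and `half_range`.
#' @examples
#' factor_spec("ec_pct", 40, 80)
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(low < center && center < high)) {
    stop("factor levels must satisfy low < center < high", call. = FALSE)
  }
  if (abs(center - (low + high) / 2) > 1e-9 * (high - low)) {
    stop("center must be the midpoint of low and high", call. = FALSE)
  }
  structure(
    list(name = name, low = low, center = center, high = high,
         half_range = (high - low) / 2),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: %g / %g / %g\n", x$name, x$low, x$center, x$high))
  invisible(x)
}

# The 12 edge-midpoint rows of the three-factor Box-Behnken design, in
# factor-pair blocks: (x1,x2), (x1,x3), (x2,x3). Stored as integers so that
# column sums and sums of squares are exact.
bbd_edge_rows <- function() {
  pm <- cbind(c(-1L, 1L, -1L, 1L), c(-1L, -1L, 1L, 1L))
  rbind(
    cbind(pm[, 1L], pm[, 2L], 0L),
    cbind(pm[, 1L], 0L, pm[, 2L]),
    cbind(0L, pm[, 1L], pm[, 2L])
  )
}

#' Generate a three-factor Box-Behnken design
#'
#' Builds the 12 edge-midpoint runs of the three-factor Box-Behnken layout
#' (each run sets one factor to its center and the other two to +/-1) plus
#' `center_points` replicated center runs. The canonical ordering is by
#' factor-pair block with centers last; `run_order` accepts a permutation of
#' `1:(12 + center_points)` to reproduce an externally published run sheet.
#'
#' @param factors A list of exactly three [factor_spec()] objects.
#' @param center_points Number of replicated center runs (>= 1).
#' @param run_order Optional integer permutation applied to the canonical
#'   row order.
#'
#' @return A `bbd_design`: a data frame with columns `run`, one actual-unit
#'   column per factor, coded columns `x1`, `x2`, `x3` (stored as integers),
#'   and a logical `is_center` column. The factor specifications are kept in
#'   `attr(, "factors")`.
#' @examples
#' fs <- list(factor_spec("ec_pct", 40, 80),
#'            factor_spec("time_min", 15, 45),
#'            factor_spec("temp_c", 40, 60))
#' bbd_design(fs, center_points = 5)
#' @export
bbd_design <- function(factors, center_points = 5L, run_order = NULL) {
  if (length(factors) != 3L) {
    stop("only three-factor Box-Behnken designs are supported", call. = FALSE)
  }
  lapply(factors, function(f) stopifnot(inherits(f, "factor_spec")))
  center_points <- as.integer(center_points)
  stopifnot(center_points >= 1L)

  coded <- rbind(bbd_edge_rows(),
                 matrix(0L, nrow = center_points, ncol = 3L))
  if (!is.null(run_order)) {
    if (!setequal(run_order, seq_len(nrow(coded)))) {
      stop("run_order must be a permutation of the run indices", call. = FALSE)
    }
    coded <- coded[run_order, , drop = FALSE]
  }
  actual <- decode_points(coded, factors)
  out <- data.frame(run = seq_len(nrow(coded)))
  for (j in 1:3) out[[factors[[j]]$name]] <- actual[, j]
  out$x1 <- coded[, 1L]; out$x2 <- coded[, 2L]; out$x3 <- coded[, 3L]
  out$is_center <- coded[, 1L] == 0L & coded[, 2L] == 0L & coded[, 3L] == 0L
  structure(out, factors = factors, class = c("bbd_design", "data.frame"))
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d runs (%d center replicates)\n",
              nrow(x), sum(x$is_center)))
  NextMethod()
}

#' Extract the coded design matrix of a design
#'
#' @param design A `bbd_design`.
#' @return Numeric matrix with columns `x1`, `x2`, `x3`.
#' @export
coded_matrix <- function(design) {
  m <- as.matrix(design[, c("x1", "x2", "x3")])
  storage.mode(m) <- "double"
  m
}

#' Convert between actual and coded factor levels
#'
#' Coding subtracts the factor center and divides by the half-range, so
#' low/center/high map to -1/0/+1. Points outside the factor ranges are
#' allowed and simply produce |coded| > 1.
#'
#' @param actual,coded Numeric 3-vector or a matrix with 3 columns.
#' @param factors List of three [factor_spec()] objects.
#' @return A vector or matrix of the same shape on the other scale.
#' @examples
#' fs <- list(factor_spec("ec_pct", 40, 80),
#'            factor_spec("time_min", 15, 45),
#'            factor_spec("temp_c", 40, 60))
#' code_points(c(80, 15, 50), fs)   # (+1, -1, 0)
#' @export
code_points <- function(actual, factors) {
  ctr <- vapply(factors, `[[`, numeric(1), "center")
  hr <- vapply(factors, `[[`, numeric(1), "half_range")
  if (is.matrix(actual)) {
    sweep(sweep(actual, 2L, ctr, "-"), 2L, hr, "/")
  } else {
    (actual - ctr) / hr
  }
}

#' @rdname code_points
#' @export
decode_points <- function(coded, factors) {
  ctr <- vapply(factors, `[[`, numeric(1), "center")
  hr <- vapply(factors, `[[`, numeric(1), "half_range")
  if (is.matrix(coded)) {
    sweep(sweep(coded + 0, 2L, hr, "*"), 2L, ctr, "+")
  } else {
    coded * hr + ctr
  }
}
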
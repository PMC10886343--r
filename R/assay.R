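#' Percent inhibition from control and sample absorbances
#'
#' 100 * (A - B) / A, where A is the control (radical or untreated-cell)
#' absorbance and B the sample absorbance. Used identically for radical
#' scavenging and melanin-production inhibition.
#'
#' @param control Control absorbance A (> 0).
#' @param sample Sample absorbance B (vectorized).
#' @return Percent inhibition; values outside \[0, 100\] are kept but carry
#'   a `flagged` attribute marking them.
#' @examples
#' percent_inhibition(0.8, 0.4)  # 50
#' @export
percent_inhibition <- function(control, sample) {
  if (!all(control > 0)) {
    stop("control absorbance must be positive", call. = FALSE)
  }
  out <- 100 * (control - sample) / control
  flagged <- out < 0 | out > 100
  if (any(flagged)) attr(out, "flagged") <- which(flagged)
  out
}

#' @rdname percent_inhibition
#' @param untreated Absorbance of untreated cells.
#' @param treated Absorbance of treated cells.
#' @export
melanin_inhibition <- function(untreated, treated) {
  percent_inhibition(untreated, treated)
}

#' Define a linear calibration curve
#'
#' Absorbance = slope * concentration + intercept, inverted to express
#' sample readings as equivalents of the calibration standard.
#'
#' @param slope Absorbance per concentration unit (nonzero).
#' @param intercept Absorbance at zero concentration.
#' @param r2 Reported fit quality (metadata only).
#' @param analyte Label, e.g. `"TPC"`.
#' @param unit Equivalent unit, e.g. `"mg GAE/g"`.
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r2 = NA_real_,
                              analyte = "", unit = "") {
  if (slope == 0) stop("calibration slope must be nonzero", call. = FALSE)
  structure(
    list(slope = slope, intercept = intercept, r2 = r2,
         analyte = analyte, unit = unit),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: y = %gx + %g (r2 = %s)%s\n",
              x$analyte, x$slope, x$intercept,
              ifelse(is.na(x$r2), "?", format(x$r2)),
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else ""))
  invisible(x)
}

#' Equivalent concentration from an absorbance reading
#'
#' Inverts the calibration line: x = (y - intercept) / slope.
#'
#' @param absorbance Numeric vector of readings.
#' @param curve A [calibration_curve()].
#' @return Equivalent concentrations in the curve's unit.
#' @examples
#' equivalent_concentration(0.5138, calibration_curve(0.0512, 0.0018))  # 10
#' @export
equivalent_concentration <- function(absorbance, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  (absorbance - curve$intercept) / curve$slope
}

#' IC50 by log-linear interpolation of a dose-response series
#'
#' Finds the concentration at which inhibition crosses 50%, interpolating
#' inhibition linearly against log10(concentration) between the bracketing
#' pair of points. An exact 50% reading returns that concentration. When
#' the series never crosses 50% the estimate is not available and the
#' status reports on which side the curve lies.
#'
#' @param concentration Strictly positive, strictly increasing doses.
#' @param inhibition Percent inhibition at each dose.
#' @return Object of class `ic50_estimate`: list with `ic50` (numeric or
#'   `NA`) and `status` (`"estimated"`, `"above_range"` if the curve stays
#'   below 50% so IC50 > max dose, `"below_range"` if it stays above 50%).
#' @examples
#' ic50(c(10, 100), c(25, 75))  # 31.62 ug/mL
#' @export
ic50 <- function(concentration, inhibition) {
  stopifnot(length(concentration) == length(inhibition),
            length(concentration) >= 1L)
  if (any(concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(concentration, strictly = TRUE)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  hit <- which(inhibition == 50)
  if (length(hit)) {
    return(structure(list(ic50 = concentration[hit[1L]],
                          status = "estimated"), class = "ic50_estimate"))
  }
  cross <- which(diff(sign(inhibition - 50)) != 0)
  if (!length(cross)) {
    status <- if (all(inhibition < 50)) "above_range" else "below_range"
    return(structure(list(ic50 = NA_real_, status = status),
                     class = "ic50_estimate"))
  }
  i <- cross[1L]
  lx <- log10(concentration[i:(i + 1L)])
  y <- inhibition[i:(i + 1L)]
  structure(
    list(ic50 = 10^(lx[1L] + (50 - y[1L]) * diff(lx) / diff(y)),
         status = "estimated"),
    class = "ic50_estimate"
  )
}

#' @export
print.ic50_estimate <- function(x, ...) {
  if (x$status == "estimated") {
    cat(sprintf("IC50 = %.4g\n", x$ic50))
  } else {
    cat(sprintf("IC50 not estimable (%s)\n",
                switch(x$status, above_range = "> max dose",
                       below_range = "< min dose")))
  }
  invisible(x)
}

#' Summarize an assay plate table
#'
#' Takes a tidy plate table with columns `analyte`, `concentration`,
#' `absorbance` plus control rows (`concentration = 0` or `analyte ==
#' "control"` per analyte is not assumed; instead the per-analyte control
#' absorbance is supplied) and returns inhibition and the interpolated
#' IC50 per analyte.
#'
#' @param plate Data frame with columns `analyte`, `concentration`,
#'   `absorbance`.
#' @param controls Named numeric vector of control absorbances, one per
#'   analyte.
#' @return List with `inhibition` (tidy data frame) and `ic50` (data frame
#'   with `analyte`, `ic50`, `status`).
#' @export
assay_summary <- function(plate, controls) {
  stopifnot(all(c("analyte", "concentration", "absorbance") %in% names(plate)),
            all(unique(plate$analyte) %in% names(controls)))
  plate$inhibition_pct <- unlist(lapply(seq_len(nrow(plate)), function(i) {
    as.numeric(percent_inhibition(controls[[plate$analyte[i]]],
                                  plate$absorbance[i]))
  }))
  ics <- do.call(rbind, lapply(split(plate, plate$analyte), function(d) {
    d <- d[order(d$concentration), ]
    est <- ic50(d$concentration, d$inhibition_pct)
    data.frame(analyte = d$analyte[1L], ic50 = est$ic50, status = est$status)
  }))
  rownames(ics) <- NULL
  list(inhibition = plate, ic50 = ics)
}
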
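# Packaged study data: the 17-run extraction experiment on unmature Ajwa
# date seeds (three factors, TPC/TFC responses) and its 104-compound
# negative-mode metabolite library.

# Table-order permutation mapping the canonical pair-block layout onto the
# published run sheet of the seed-extraction study.
UMS_RUN_ORDER <- c(2L, 6L, 12L, 13L, 14L, 15L, 4L, 11L, 10L, 1L, 9L, 7L,
                   3L, 16L, 17L, 5L, 8L)

#' Factor specifications of the seed-extraction study
#'
#' Ethanol concentration 40-80%, sonication time 15-45 min, extraction
#' temperature 40-60 degrees C (centers 60 / 30 / 50).
#'
#' @return List of three [factor_spec()]s.
#' @export
ums_factors <- function() {
  list(factor_spec("ec_pct", 40, 80),
       factor_spec("time_min", 15, 45),
       factor_spec("temp_c", 40, 60))
}

#' The 17-run Box-Behnken design of the seed-extraction study
#'
#' Twelve edge runs plus five center replicates, in the published run
#' order.
#'
#' @return A [bbd_design()].
#' @export
ums_design <- function() {
  bbd_design(ums_factors(), center_points = 5L, run_order = UMS_RUN_ORDER)
}

#' Packaged seed-extraction design table with measured responses
#'
#' The full run sheet: factor settings, coded levels, measured total
#' phenolic content (mg GAE/g) and total flavonoid content (mg CE/g) with
#' their replicate SDs, and the response-surface and neural-network
#' predictions reported alongside.
#'
#' @return Data frame with one row per run.
#' @export
ums_design_data <- function() {
  path <- system.file("extdata", "bbd_tpc_tfc.csv", package = "uaeopt",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Measured responses of the seed-extraction study
#'
#' @return List with numeric vectors `tpc` (mg GAE/g) and `tfc` (mg CE/g),
#'   aligned with [ums_design()].
#' @export
ums_responses <- function() {
  d <- ums_design_data()
  list(tpc = d$tpc_exp, tfc = d$tfc_exp)
}

#' Packaged metabolite library of the optimized seed extract
#'
#' 104 compounds identified by negative-mode high-resolution ESI-MS/MS:
#' name, compound class, elemental formula, observed \[M-H\]- m/z,
#' semicolon-separated fragment list and identification confidence level
#' (1 = reference standard, 2 = literature MSn match, 3 = tentative).
#'
#' @return Data frame with columns `name`, `class`, `formula`,
#'   `observed_mz`, `fragments`, `confidence`.
#' @export
ums_compound_library <- function() {
  path <- system.file("extdata", "ums_compound_library.csv",
                      package = "uaeopt", mustWork = TRUE)
  read_compound_library(path)
}

#' Calibration curves used by the colorimetric assays
#'
#' Slopes and intercepts of the linear standard curves relating absorbance
#' to equivalent concentration for the phenolic, flavonoid, radical
#' scavenging and reducing-power assays.
#'
#' @return Named list of [calibration_curve()]s: `tpc`, `tfc`, `dpph`,
#'   `abts`, `cuprac`, `frap`.
#' @export
ums_calibration_curves <- function() {
  list(
    tpc = calibration_curve(0.0512, 0.0018, 0.9835, "TPC", "mg GAE/g"),
    tfc = calibration_curve(0.014, 0.0021, 0.9994, "TFC", "mg CE/g"),
    dpph = calibration_curve(0.0069, 0.035, 0.9905, "DPPH", "umol AAE/g"),
    abts = calibration_curve(0.0083, 0.0002, 0.9989, "ABTS", "umol AAE/g"),
    cuprac = calibration_curve(0.0065, 0.039, 0.9975, "CUPRAC", "mmol AAE/g"),
    frap = calibration_curve(0.013, 0.0465, 0.9889, "FRAP", "mmol AAE/g")
  )
}
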
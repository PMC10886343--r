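#' Simulate responses from a true quadratic surface on a Box-Behnken design
#'
#' Generates a design with [bbd_design()] and evaluates a known 10-term
#' quadratic at its coded points, adding i.i.d. Gaussian noise. The
#' defaults mirror a three-factor extraction study: five replicated center
#' runs and a homoscedastic noise scale of the order of the replicate
#' scatter seen in such experiments (~0.6 response units).
#'
#' @param coefficients True coefficient vector (length 10, model-matrix
#'   order).
#' @param sd Noise standard deviation (>= 0).
#' @param center_points Number of center replicates (>= 2 so that pure
#'   error is estimable).
#' @param factors Factor specifications (default [ums_factors()]).
#' @param seed Integer seed.
#' @return List with `design` (a `bbd_design`), `y` (numeric responses)
#'   and `truth` (noise-free surface values).
#' @examples
#' sim <- simulate_bbd_responses(c(75, 1, -1, 0.1, -8, -5, -6, -0.6, 0.6, 0.5),
#'                               sd = 0.6, seed = 7)
#' @export
simulate_bbd_responses <- function(coefficients, sd = 0.6, center_points = 5L,
                                   factors = ums_factors(), seed = 1L) {
  stopifnot(length(coefficients) == 10L, sd >= 0, center_points >= 2L)
  design <- bbd_design(factors, center_points = center_points)
  truth <- as.numeric(quad_model_matrix(coded_matrix(design)) %*% coefficients)
  y <- truth + withr_seed(seed, stats::rnorm(length(truth), 0, sd))
  list(design = design, y = y, truth = truth)
}

#' Simulate a mass peak list from a compound library
#'
#' Perturbs the calculated \[M-H\]- m/z of every library entry by a
#' multiplicative error drawn from N(0, ppm_sd) parts per million, and
#' appends `decoys` uniform random peaks over the observed m/z range.
#'
#' @param library Compound-library data frame with a `formula` column.
#' @param ppm_sd Standard deviation of the mass error in ppm (>= 0).
#' @param decoys Number of uniform decoy peaks.
#' @param seed Integer seed.
#' @param mz_range Range for decoy peaks (default spans the library).
#' @return Data frame with columns `mz` and `source` (`"library"` or
#'   `"decoy"`); library rows carry the originating compound `name`.
#' @export
simulate_peaklist <- function(library, ppm_sd = 2, decoys = 0L, seed = 1L,
                              mz_range = NULL) {
  stopifnot(ppm_sd >= 0, decoys >= 0L)
  calc <- vapply(library$formula, function(f) deprotonated_mz(f), numeric(1))
  withr_seed(seed, {
    mz <- calc * (1 + stats::rnorm(length(calc), 0, ppm_sd) * 1e-6)
    out <- data.frame(mz = unname(mz), source = "library",
                      name = library$name)
    if (decoys > 0L) {
      if (is.null(mz_range)) mz_range <- range(calc)
      out <- rbind(out, data.frame(
        mz = stats::runif(decoys, mz_range[1L], mz_range[2L]),
        source = "decoy", name = NA_character_))
    }
    out
  })
}

#' Simulate a four-parameter-logistic dose-response series
#'
#' Inhibition follows 100 / (1 + (ic50 / conc)^hill) with additive
#' Gaussian noise, the standard sigmoidal model for radical-scavenging
#' dose-response data.
#'
#' @param ic50 True half-maximal concentration (> 0).
#' @param hill Hill slope (> 0).
#' @param noise_sd Additive noise SD in percentage points.
#' @param concentrations Strictly increasing positive dose grid.
#' @param seed Integer seed.
#' @return Data frame with columns `concentration` and `inhibition`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, noise_sd = 0,
                                   concentrations = c(6.25, 12.5, 25, 50, 100),
                                   seed = 1L) {
  stopifnot(ic50 > 0, hill > 0, noise_sd >= 0, all(concentrations > 0),
            !is.unsorted(concentrations, strictly = TRUE))
  truth <- 100 / (1 + (ic50 / concentrations)^hill)
  inh <- truth + withr_seed(seed, stats::rnorm(length(truth), 0, noise_sd))
  data.frame(concentration = concentrations, inhibition = inh)
}
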
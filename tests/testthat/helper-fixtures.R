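# Shared fixtures built in code: printed fitted equations of the seed
# extraction study and small random-design helpers.

# Printed second-order equation coefficients (coded factors).
eq_tpc_printed <- c(75.77, 1.21, -0.9912, 0.1438, -8.12, -5.59, -5.73,
                    -0.6275, 0.5975, 0.5100)
eq_tfc_printed <- c(57.42, 1.44, 0.6375, 0.3691, -10.86, -6.81, -6.83,
                    -0.1651, 1.50, 0.5177)

random_factors <- function() {
  list(factor_spec("a", 0, 10), factor_spec("b", 100, 200),
       factor_spec("c", -1, 1))
}

# uniform random coefficient vector for synthetic quadratic surfaces
random_coefficients <- function() {
  stats::runif(10, -5, 5)
}
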
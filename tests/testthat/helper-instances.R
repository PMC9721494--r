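# shared generators for property-style tests

# random two-strategy Cobb-Douglas instance satisfying the pairwise
# competition hypotheses (both strategies above the epidemic threshold)
random_cd_instance <- function() {
  list(alpha = runif(1, 0.05, 0.95),
       c = exp(runif(1, log(0.1), log(4))),
       R_r = runif(1, 1.05, 10),
       R_m = runif(1, 1.05, 10))
}

# random dimorphic parameter set, unrestricted thresholds
random_dimorphic <- function() {
  dimorphic_params(R_r = runif(1, 0, 6), R_m = runif(1, 0, 6),
                   f = runif(1), c = exp(runif(1, log(0.2), log(5))))
}

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_true(all(abs(actual - expected) < tol),
              label = sprintf("max |diff| = %g", max(abs(actual - expected))))
}
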
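# Shared fixtures for the test suite.

tab_hra <- function() contingency_table(40, 22, 22, 177)   # N = 261, e = 62
ref_hra <- function() ref_accuracy(0.74, 0.91)

# Expected-count (fractional) table N * p_ij under conditional independence.
expected_table <- function(p, sn_it, sp_it, sn_rs, sp_rs, N = 1000) {
  pr <- cell_probabilities(scenario_spec(p, sn_it, sp_it, sn_rs, sp_rs))
  contingency_table(N * pr[["p11"]], N * pr[["p10"]],
                    N * pr[["p01"]], N * pr[["p00"]], fractional = TRUE)
}

# Random valid observed table drawn from the independence model with
# moderate parameters (margins positive with overwhelming probability).
random_valid_table <- function() {
  p <- runif(1, 0.2, 0.8)
  sn_it <- runif(1, 0.6, 0.95); sp_it <- runif(1, 0.6, 0.95)
  sn_rs <- runif(1, 0.65, 0.95); sp_rs <- runif(1, 0.65, 0.95)
  pr <- cell_probabilities(scenario_spec(p, sn_it, sp_it, sn_rs, sp_rs))
  x <- stats::rmultinom(1, 500, pr)
  list(table = contingency_table(x[1], x[2], x[3], x[4]),
       ref = ref_accuracy(sn_rs, sp_rs))
}
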
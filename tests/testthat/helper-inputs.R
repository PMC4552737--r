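# Base-case input bundles used across the suite.

base_technical <- function(level = c("high", "low"), n_fixed = 3L,
                           n_rose = 1L) {
  level <- match.arg(level)
  technical_inputs(p = if (level == "high") 0.6 else 0.3,
                   sn = 0.95, sp = 0.975,
                   n_fixed = n_fixed, n_rose = n_rose)
}

complex_operational <- function() operational_inputs(30, 2, 9)
simple_operational <- function() operational_inputs(4, 2, 9)

complex_costs <- function(...) {
  cost_inputs(rate_cytologist = 100, rate_other = 260, rate_patient = 20,
              cost_fixed = 300, cost_per_pass = 30, ...)
}

simple_costs <- function(...) {
  # palpation-guided: the cytologist performs the FNA, so both protocols
  # bill the same 130/hr team rate
  cost_inputs(rate_cytologist = 100, rate_other = 30, rate_patient = 20,
              cost_fixed = 150, cost_per_pass = 0,
              fixed_rate_override = 130, rose_rate_override = 130, ...)
}

# base values of a scenario's parameters excluding `exclude`
param_values_for_test <- function(scenario, exclude = character(0)) {
  params <- scenario$params[[1]]
  keep <- !(params$parameter %in% exclude)
  setNames(params$base[keep], params$parameter[keep])
}

# |estimate - truth| in Monte Carlo standard errors; a zero-SE quantity
# must match exactly
z_score <- function(estimate, truth, se) {
  if (se == 0) return(if (isTRUE(all.equal(estimate, truth))) 0 else Inf)
  abs(estimate - truth) / se
}
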
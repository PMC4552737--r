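test_that("sampling and procedure time compose in minutes", {
  expect_equal(sampling_time(3, 2), 6)
  expect_equal(sampling_time(0, 17), 0)
  expect_equal(round(sampling_time(1.724, 9), 1), 15.5)
  expect_equal(procedure_time(complex_operational(), 6), 36)
  expect_equal(procedure_time(operational_inputs(0, 2, 9), 12.3), 12.3)
  expect_equal(procedure_time(simple_operational(), 6), 10)
})

test_that("variable rate honors perspective, composition and overrides", {
  cc <- complex_costs()
  expect_equal(variable_rate(cc, "fixed"), 280)
  expect_equal(variable_rate(cc, "rose"), 380)
  provider <- complex_costs(perspective = "provider")
  expect_equal(variable_rate(provider, "fixed"), 260)
  expect_equal(variable_rate(provider, "rose"), 360)
  sc <- simple_costs()
  expect_equal(variable_rate(sc, "fixed"), 150)
  expect_equal(variable_rate(sc, "rose"), 150)
  expect_equal(variable_rate(simple_costs(perspective = "provider"), "rose"),
               130)
})

test_that("cost per procedure reproduces the complex fixed base case", {
  perf <- sampling_performance(base_technical("high"), "fixed")
  expect_equal(cost_per_procedure(perf, complex_operational(),
                                  complex_costs()), 558)
  zeros <- cost_inputs(0, 0, 0, cost_fixed = 0, cost_per_pass = 0)
  expect_equal(cost_per_procedure(perf, complex_operational(), zeros), 0)
  perf_r <- sampling_performance(base_technical("high"), "rose")
  expect_equal(round(cost_per_procedure(perf_r, complex_operational(),
                                        complex_costs()), 1), 640.0)
})

test_that("cost per case multiplies procedure cost by expected procedures", {
  expect_equal(round(cost_per_case(558, 1 / 0.936), 1), 596.2)
  expect_equal(cost_per_case(321.5, 1), 321.5)
  expect_equal(round(cost_per_case(639.98, 1 / 0.9836066), 0), 651)
})

test_that("evaluate_policy yields an internally consistent outcome", {
  for (protocol in c("fixed", "rose")) {
    out <- evaluate_policy(base_technical("low"), complex_operational(),
                           complex_costs(), protocol)
    expect_equal(out$t_procedure, 30 + out$t_sample)
    expect_equal(out$cost_per_case,
                 out$cost_per_procedure * out$sampling$expected_procedures)
    expect_gte(out$cost_per_case, out$cost_per_procedure)
    expect_equal(out$cost_variable, out$t_procedure / 60 * out$rate)
  }
  fx <- evaluate_policy(base_technical("high"), complex_operational(),
                        complex_costs(), "fixed")
  rs <- evaluate_policy(base_technical("high"), complex_operational(),
                        complex_costs(), "rose")
  expect_equal(round(fx$cost_per_case), 596)
  expect_equal(round(rs$cost_per_case), 651)
  expect_equal(round(cost_difference(rs, fx)), 55)
  expect_error(cost_difference(fx, rs), "matching")
})

test_that("adding a patient wage shifts costs monotonically upward", {
  for (protocol in c("fixed", "rose")) {
    without <- evaluate_policy(base_technical("low"), complex_operational(),
                               complex_costs(perspective = "provider"),
                               protocol)
    with_pat <- evaluate_policy(base_technical("low"), complex_operational(),
                                complex_costs(), protocol)
    expect_gt(with_pat$cost_per_case, without$cost_per_case)
  }
})

test_that("cost-difference derivative in c_fixed equals the procedure gap", {
  # d(delta)/d(c_fixed) = Nproc(rose) - Nproc(fixed), negative whenever
  # ROSE has the higher adequacy
  delta_at <- function(c_fixed, level) {
    cc <- cost_inputs(100, 260, 20, cost_fixed = c_fixed, cost_per_pass = 30)
    t <- base_technical(level)
    cost_difference(
      evaluate_policy(t, complex_operational(), cc, "rose"),
      evaluate_policy(t, complex_operational(), cc, "fixed"))
  }
  for (level in c("high", "low")) {
    t <- base_technical(level)
    gap <- sampling_performance(t, "rose")$expected_procedures -
      sampling_performance(t, "fixed")$expected_procedures
    h <- 1e-4
    fd <- (delta_at(300 + h, level) - delta_at(300 - h, level)) / (2 * h)
    expect_equal(fd, gap, tolerance = 1e-6)
    expect_lt(gap, 0)
  }
})

test_that("cost difference is monotone in ROSE pass time, cytologist rate
           and setup time", {
  t <- base_technical("low")
  delta_for <- function(o = complex_operational(), cc = complex_costs()) {
    cost_difference(evaluate_policy(t, o, cc, "rose"),
                    evaluate_policy(t, o, cc, "fixed"))
  }
  by_tpr <- vapply(c(6, 8, 10, 12), function(tp)
    delta_for(o = operational_inputs(30, 2, tp)), numeric(1))
  expect_true(all(diff(by_tpr) > 0))
  by_cyto <- vapply(c(75, 100, 125), function(r)
    delta_for(cc = cost_inputs(r, 260, 20, cost_fixed = 300,
                               cost_per_pass = 30)), numeric(1))
  expect_true(all(diff(by_cyto) > 0))
  # ROSE has higher adequacy here, so longer setup favors ROSE
  by_setup <- vapply(c(10, 20, 30, 40), function(ts)
    delta_for(o = operational_inputs(ts, 2, 9)), numeric(1))
  expect_true(all(diff(by_setup) < 0))
})

test_that("minute-based computation matches an all-hours computation", {
  perf <- sampling_performance(base_technical("high"), "rose")
  minutes <- cost_per_procedure(perf, complex_operational(), complex_costs())
  t_samp_hr <- perf$expected_passes * (9 / 60)
  hours <- (30 / 60 + t_samp_hr) * 380 + 300 + perf$expected_passes * 30
  expect_equal(minutes, hours)
})
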
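test_that("binomial pmf matches hand-computed values and normalizes", {
  expect_equal(binomial_pmf(0, 3, 0.3), 0.343)
  expect_equal(binomial_pmf(0, 1, 0.5), 0.5)
  for (case in list(c(4, 0.2), c(7, 0.55), c(1, 0.9))) {
    n <- case[1]
    total <- sum(vapply(0:n, binomial_pmf, numeric(1), n = n, p = case[2]))
    expect_equal(total, 1)
  }
  expect_error(binomial_pmf(4, 3, 0.5), "outside")
  expect_error(binomial_pmf(-1, 3, 0.5), "outside")
})

test_that("fixed-protocol adequacy follows 1 - (1-p)^n", {
  expect_equal(adequacy_fixed(0.3, 3), 0.657)
  expect_equal(adequacy_fixed(0.6, 3), 0.936)
  expect_equal(adequacy_fixed(0.5, 1), 0.5)
  # strictly increasing in p and in the number of passes
  p_grid <- seq(0.1, 0.9, by = 0.2)
  for (n in 1:4) {
    a_p <- vapply(p_grid, adequacy_fixed, numeric(1), n_fixed = n)
    expect_true(all(diff(a_p) > 0))
  }
  for (p in p_grid) {
    a_n <- vapply(1:5, function(n) adequacy_fixed(p, n), numeric(1))
    expect_true(all(diff(a_n) > 0))
  }
})

test_that("ROSE adequacy follows the failure-odds closed form", {
  expect_equal(round(adequacy_rose(0.6, 0.975, 1), 4), 0.9836)
  expect_equal(round(adequacy_rose(0.3, 0.975, 1), 4), 0.9449)
  # a perfectly specific cytologist never stops on an inadequate sample
  for (p in c(0.1, 0.5, 0.9)) expect_equal(adequacy_rose(p, 1, 2), 1)
  # strictly increasing in p, sp and n_rose; never depends on sn
  expect_true(all(diff(vapply(seq(0.1, 0.9, 0.2), adequacy_rose,
                              numeric(1), sp = 0.9, n_rose = 1)) > 0))
  expect_true(all(diff(vapply(c(0.8, 0.9, 0.95, 0.99), function(sp)
    adequacy_rose(0.3, sp, 1), numeric(1))) > 0))
  expect_true(all(diff(vapply(1:4, function(nr)
    adequacy_rose(0.3, 0.9, nr), numeric(1))) > 0))
  perf_lo_sn <- sampling_performance(
    technical_inputs(p = 0.3, sn = 0.5, sp = 0.9, n_rose = 2), "rose")
  perf_hi_sn <- sampling_performance(
    technical_inputs(p = 0.3, sn = 1.0, sp = 0.9, n_rose = 2), "rose")
  expect_equal(perf_lo_sn$adequacy, perf_hi_sn$adequacy)
})

test_that("expected ROSE passes follow the positive-call rate", {
  expect_equal(round(expected_passes_rose(base_technical("high")), 3), 1.724)
  expect_equal(
    round(expected_passes_rose(base_technical("low", n_rose = 2L)), 2), 6.61)
  # perfect cytologist: geometric / negative binomial limit n_rose / p
  for (p in c(0.2, 0.5, 0.8)) for (nr in 1:2) {
    t <- technical_inputs(p = p, sn = 1, sp = 1, n_rose = nr)
    expect_equal(expected_passes_rose(t), nr / p)
  }
  # strictly decreasing in p and sn, strictly increasing in n_rose
  by_p <- vapply(seq(0.1, 0.9, 0.2), function(p)
    expected_passes_rose(technical_inputs(p = p, sn = 0.9, sp = 0.9)),
    numeric(1))
  expect_true(all(diff(by_p) < 0))
  by_sn <- vapply(c(0.5, 0.7, 0.9, 1), function(sn)
    expected_passes_rose(technical_inputs(p = 0.3, sn = sn, sp = 0.9)),
    numeric(1))
  expect_true(all(diff(by_sn) < 0))
  by_nr <- vapply(1:4, function(nr)
    expected_passes_rose(technical_inputs(p = 0.3, n_rose = nr)), numeric(1))
  expect_true(all(diff(by_nr) > 0))
})

test_that("expected passes and procedures handle the simple identities", {
  expect_identical(expected_passes_fixed(3), 3.0)
  expect_identical(expected_passes_fixed(1), 1.0)
  expect_equal(round(expected_procedures(0.9449), 2), 1.06)
  expect_equal(expected_procedures(1), 1)
  expect_equal(round(expected_procedures(0.936), 2), 1.07)
  expect_error(expected_procedures(0), "zero-adequacy")
})

test_that("sampling_performance composes a consistent triple", {
  perf_f <- sampling_performance(base_technical("low"), "fixed")
  expect_equal(perf_f$adequacy, 0.657)
  expect_equal(perf_f$expected_passes, 3)
  expect_equal(perf_f$expected_procedures, 1 / 0.657)
  perf_r <- sampling_performance(base_technical("high"), "rose")
  expect_equal(round(perf_r$adequacy, 4), 0.9836)
  expect_equal(round(perf_r$expected_passes, 3), 1.724)
  expect_equal(round(perf_r$expected_procedures, 4), 1.0167)
  expect_equal(perf_r$expected_procedures, 1 / perf_r$adequacy)
  perf_perfect <- sampling_performance(
    technical_inputs(p = 0.4, sn = 1, sp = 1, n_rose = 1), "rose")
  expect_equal(perf_perfect$adequacy, 1)
  expect_equal(perf_perfect$expected_passes, 1 / 0.4)
  expect_equal(perf_perfect$expected_procedures, 1)
})

test_that("degenerate technical inputs are rejected, not clamped", {
  expect_error(technical_inputs(p = 0), "outside")
  expect_error(technical_inputs(p = 1), "outside")
  expect_error(technical_inputs(p = 0.5, sn = 0), "outside")
  expect_error(technical_inputs(p = 0.5, sp = 0), "outside")
  expect_error(technical_inputs(p = 0.5, n_fixed = 0), "integer")
  expect_error(technical_inputs(p = 0.5, n_rose = 1.5), "integer")
})
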
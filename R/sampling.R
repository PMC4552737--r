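# Closed-form sampling performance for fixed and ROSE protocols.
#
# Every needle pass is a Bernoulli trial with success (adequate sample)
# probability p. A procedure succeeds if at least one collected sample is
# truly adequate. Under ROSE an imperfect cytologist calls each pass
# adequate with probability sn (if truly adequate) or 1 - sp (if not), and
# sampling stops at the n_rose-th positive call; a false-positive call can
# therefore end a procedure with no adequate material, while an adequate
# sample miscalled negative still rescues the case at final processing.

#' Binomial probability mass function
#'
#' Probability of observing exactly `k` adequate samples in `n` independent
#' needle passes with per-pass adequacy `p`. A thin, domain-checked wrapper
#' around [stats::dbinom()].
#'
#' @param k Number of adequate samples, integer in `0..n`.
#' @param n Number of needle passes, integer >= 1.
#' @param p Per-pass adequacy probability.
#' @return The probability `choose(n, k) p^k (1-p)^(n-k)`.
#' @examples
#' binomial_pmf(0, 3, 0.3)  # 0.343: all three passes fail
#' @export
binomial_pmf <- function(k, n, p) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k))
    stop("`k` must be a single integer", call. = FALSE)
  check_count(n, "n")
  check_prob(p, "p")
  if (k < 0 || k > n)
    stop(sprintf("`k` = %d outside 0..%d", as.integer(k), as.integer(n)),
         call. = FALSE)
  dbinom(as.integer(k), as.integer(n), p)
}

#' Per-case adequacy of a fixed sampling protocol
#'
#' A fixed protocol fails only if all `n_fixed` passes fail, so the per-case
#' adequacy (probability of at least one adequate sample) is
#' `1 - (1 - p)^n_fixed`.
#'
#' @inheritParams binomial_pmf
#' @param n_fixed Number of needle passes taken.
#' @return Per-case adequacy probability.
#' @examples
#' adequacy_fixed(0.3, 3)  # 0.657
#' adequacy_fixed(0.6, 3)  # 0.936
#' @export
adequacy_fixed <- function(p, n_fixed) {
  check_prob(p, "p", lower_open = TRUE, upper_open = TRUE)
  check_count(n_fixed, "n_fixed")
  1 - (1 - p)^n_fixed
}

#' Per-case adequacy of a ROSE protocol
#'
#' Sampling stops at the `n_rose`-th positive adequacy call. A procedure
#' fails only if every collected sample is inadequate and the cytologist's
#' false-positive calls exhaust the stopping rule; per stopping cycle the
#' failure odds are `(1 - sp)(1 - p) / (1 - sp (1 - p))`, so the adequacy is
#' `1 - [ (1 - sp)(1 - p) / (1 - sp (1 - p)) ]^n_rose`. The result does not
#' depend on the cytologist's sensitivity: a missed adequate sample costs
#' passes, not the case.
#'
#' @inheritParams binomial_pmf
#' @param sp Specificity of the cytologist's adequacy call.
#' @param n_rose Positive calls required to stop.
#' @return Per-case adequacy probability.
#' @examples
#' adequacy_rose(0.6, 0.975, 1)  # 0.9836
#' adequacy_rose(0.3, 0.975, 1)  # 0.9449
#' @export
adequacy_rose <- function(p, sp, n_rose) {
  check_prob(p, "p", lower_open = TRUE, upper_open = TRUE)
  check_prob(sp, "sp", lower_open = TRUE)
  check_count(n_rose, "n_rose")
  odds <- ((1 - sp) * (1 - p)) / (1 - sp * (1 - p))
  1 - odds^n_rose
}

#' Expected needle passes of a fixed protocol
#'
#' The fixed protocol always takes exactly `n_fixed` passes; there is no
#' variation.
#'
#' @param n_fixed Number of needle passes taken.
#' @return `n_fixed`, as a double.
#' @export
expected_passes_fixed <- function(n_fixed) {
  as.numeric(check_count(n_fixed, "n_fixed"))
}

#' Expected needle passes of a ROSE protocol
#'
#' Each pass draws a positive adequacy call with probability
#' `(1 - sp)(1 - p) + p sn` (false positive or detected adequate), so the
#' pass count to the `n_rose`-th positive call is negative binomial with
#' mean `n_rose / ((1 - sp)(1 - p) + p sn)`.
#'
#' @param t A [technical_inputs()] object.
#' @return Expected number of needle passes per procedure.
#' @examples
#' expected_passes_rose(technical_inputs(p = 0.6, sn = 0.95, sp = 0.975,
#'                                       n_rose = 1))  # 1.724
#' @export
expected_passes_rose <- function(t) {
  stopifnot(inherits(t, "technical_inputs"))
  call_rate <- (1 - t$sp) * (1 - t$p) + t$p * t$sn
  if (call_rate <= 0)
    stop("positive-call rate is zero: sampling would never stop ",
         "(sn = 0 with sp = 1)", call. = FALSE)
  t$n_rose / call_rate
}

#' Expected procedures per case
#'
#' A failed procedure is repeated, so the number of procedures until success
#' is geometric with mean `1 / adequacy`.
#'
#' @param adequacy Per-case adequacy probability, in (0, 1].
#' @return Expected number of procedures per case.
#' @examples
#' expected_procedures(0.9449)  # 1.058
#' @export
expected_procedures <- function(adequacy) {
  check_prob(adequacy, "adequacy")
  if (adequacy == 0)
    stop("`adequacy` must be > 0: a zero-adequacy protocol never succeeds",
         call. = FALSE)
  1 / adequacy
}

#' Closed-form sampling performance of a protocol
#'
#' Bundles per-case adequacy, expected needle passes per procedure, and
#' expected procedures per case for the requested protocol.
#'
#' @param t A [technical_inputs()] object.
#' @param protocol `"fixed"` or `"rose"`.
#' @return An object of class `sampling_performance` with fields `adequacy`,
#'   `expected_passes`, `expected_procedures`, `protocol`.
#' @examples
#' sampling_performance(technical_inputs(p = 0.3), "fixed")
#' @export
sampling_performance <- function(t, protocol = c("fixed", "rose")) {
  stopifnot(inherits(t, "technical_inputs"))
  protocol <- match.arg(protocol)
  if (protocol == "fixed") {
    adequacy <- adequacy_fixed(t$p, t$n_fixed)
    passes <- expected_passes_fixed(t$n_fixed)
  } else {
    adequacy <- adequacy_rose(t$p, t$sp, t$n_rose)
    passes <- expected_passes_rose(t)
  }
  structure(
    list(protocol = protocol, adequacy = adequacy, expected_passes = passes,
         expected_procedures = expected_procedures(adequacy)),
    class = "sampling_performance"
  )
}

#' @export
print.sampling_performance <- function(x, ...) {
  cat(sprintf("Sampling performance (%s protocol)\n", x$protocol))
  cat(sprintf("  per-case adequacy      : %.4f\n", x$adequacy))
  cat(sprintf("  expected passes/proc   : %.3f\n", x$expected_passes))
  cat(sprintf("  expected procedures    : %.3f\n", x$expected_procedures))
  invisible(x)
}
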
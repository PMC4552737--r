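# Procedure-time and micro-costing models.
#
# The procedure is two periods, setup then sampling; variable (hourly) cost
# is assumed constant across both. Per procedure:
#   cost = (t_setup + t_sample)/60 * rate + cost_fixed + passes * cost_per_pass
# and per case the procedure cost is multiplied by the expected number of
# procedures (failures are repeated). Durations are minutes, rates per hour;
# the /60 conversion happens once, at the rate product.

#' Expected duration of the sampling period
#'
#' @param expected_passes Expected needle passes per procedure.
#' @param t_pass Time per needle pass, minutes.
#' @return Sampling time in minutes.
#' @examples
#' sampling_time(3, 2)  # 6 minutes
#' @export
sampling_time <- function(expected_passes, t_pass) {
  check_nonneg(expected_passes, "expected_passes")
  check_nonneg(t_pass, "t_pass")
  expected_passes * t_pass
}

#' Expected total procedure time
#'
#' Setup plus sampling. Setup time is the same for both protocols.
#'
#' @param o An [operational_inputs()] object.
#' @param t_sample Sampling time in minutes (see [sampling_time()]).
#' @return Total procedure time in minutes.
#' @export
procedure_time <- function(o, t_sample) {
  stopifnot(inherits(o, "operational_inputs"))
  check_nonneg(t_sample, "t_sample")
  o$t_setup + t_sample
}

#' Effective hourly variable rate of a protocol
#'
#' Composes the protocol's hourly rate from the cost inputs: the
#' non-cytologist team rate, plus the cytologist under ROSE, plus the
#' patient wage under the societal perspective. A rate override, when
#' present, replaces the pre-patient sum (see [cost_inputs()]).
#'
#' @param c A [cost_inputs()] object.
#' @param protocol `"fixed"` or `"rose"`.
#' @return Hourly rate in currency per hour.
#' @examples
#' cc <- cost_inputs(rate_cytologist = 100, rate_other = 260,
#'                   rate_patient = 20)
#' variable_rate(cc, "fixed")  # 280
#' variable_rate(cc, "rose")   # 380
#' @export
variable_rate <- function(c, protocol = c("fixed", "rose")) {
  stopifnot(inherits(c, "cost_inputs"))
  protocol <- match.arg(protocol)
  override <- if (protocol == "fixed") c$fixed_rate_override else c$rose_rate_override
  pre_patient <- if (!is.null(override)) {
    override
  } else if (protocol == "fixed") {
    c$rate_other
  } else {
    c$rate_other + c$rate_cytologist
  }
  pre_patient + if (c$perspective == "societal") c$rate_patient else 0
}

#' Expected total cost per procedure
#'
#' Variable (time-based) cost over setup and sampling, plus the fixed
#' per-procedure cost, plus the expected needle-pass cost.
#'
#' @param perf A [sampling_performance()] object.
#' @param o An [operational_inputs()] object.
#' @param c A [cost_inputs()] object.
#' @param protocol `"fixed"` or `"rose"`; defaults to the protocol carried
#'   by `perf`.
#' @return Cost per procedure.
#' @examples
#' t <- technical_inputs(p = 0.6, n_fixed = 3)
#' o <- operational_inputs(30, 2, 9)
#' cc <- cost_inputs(100, 260, 20, cost_fixed = 300, cost_per_pass = 30)
#' cost_per_procedure(sampling_performance(t, "fixed"), o, cc)  # 558
#' @export
cost_per_procedure <- function(perf, o, c, protocol = perf$protocol) {
  stopifnot(inherits(perf, "sampling_performance"),
            inherits(o, "operational_inputs"),
            inherits(c, "cost_inputs"))
  protocol <- check_protocol(protocol)
  t_pass <- if (protocol == "fixed") o$t_pass_fixed else o$t_pass_rose
  t_samp <- sampling_time(perf$expected_passes, t_pass)
  rate <- variable_rate(c, protocol)
  procedure_time(o, t_samp) / 60 * rate + c$cost_fixed +
    perf$expected_passes * c$cost_per_pass
}

#' Expected total cost per case
#'
#' Cost per procedure times the expected number of procedures (failed
#' procedures are repeated).
#'
#' @param cost_per_procedure Cost of one procedure.
#' @param expected_procedures Expected procedures per case (>= 1).
#' @return Cost per case.
#' @export
cost_per_case <- function(cost_per_procedure, expected_procedures) {
  check_nonneg(cost_per_procedure, "cost_per_procedure")
  if (!is.numeric(expected_procedures) || expected_procedures < 1)
    stop("`expected_procedures` must be >= 1", call. = FALSE)
  cost_per_procedure * expected_procedures
}

#' Evaluate one sampling policy end to end
#'
#' Runs the full pipeline — sampling performance, procedure time, cost per
#' procedure, cost per case — for one protocol at one parameter set.
#'
#' @param t A [technical_inputs()] object.
#' @param o An [operational_inputs()] object.
#' @param c A [cost_inputs()] object.
#' @param protocol `"fixed"` or `"rose"`.
#' @return An object of class `policy_outcome` with fields `protocol`,
#'   `sampling` (a `sampling_performance`), `t_sample`, `t_procedure`
#'   (minutes), `rate` (per hour), `cost_variable`, `cost_per_procedure`
#'   and `cost_per_case`.
#' @examples
#' t <- technical_inputs(p = 0.6, n_fixed = 3, n_rose = 1)
#' o <- operational_inputs(30, 2, 9)
#' cc <- cost_inputs(100, 260, 20, cost_fixed = 300, cost_per_pass = 30)
#' evaluate_policy(t, o, cc, "rose")
#' @export
evaluate_policy <- function(t, o, c, protocol = c("fixed", "rose")) {
  protocol <- match.arg(protocol)
  perf <- sampling_performance(t, protocol)
  t_pass <- if (protocol == "fixed") o$t_pass_fixed else o$t_pass_rose
  t_samp <- sampling_time(perf$expected_passes, t_pass)
  t_proc <- procedure_time(o, t_samp)
  rate <- variable_rate(c, protocol)
  cvar <- t_proc / 60 * rate
  cproc <- cvar + c$cost_fixed + perf$expected_passes * c$cost_per_pass
  structure(
    list(protocol = protocol, sampling = perf,
         t_sample = t_samp, t_procedure = t_proc, rate = rate,
         cost_variable = cvar, cost_per_procedure = cproc,
         cost_per_case = cost_per_case(cproc, perf$expected_procedures)),
    class = "policy_outcome"
  )
}

#' @export
print.policy_outcome <- function(x, ...) {
  cat(sprintf("Policy outcome (%s protocol)\n", x$protocol))
  cat(sprintf("  adequacy / passes / procedures : %.3f / %.2f / %.3f\n",
              x$sampling$adequacy, x$sampling$expected_passes,
              x$sampling$expected_procedures))
  cat(sprintf("  sampling / procedure time      : %.1f / %.1f min\n",
              x$t_sample, x$t_procedure))
  cat(sprintf("  cost per procedure / per case  : %.1f / %.1f\n",
              x$cost_per_procedure, x$cost_per_case))
  invisible(x)
}

#' Expected cost difference between ROSE and fixed sampling
#'
#' ROSE cost per case minus fixed cost per case; negative values favor
#' ROSE.
#'
#' @param rose A `policy_outcome` for the ROSE protocol.
#' @param fixed A `policy_outcome` for the fixed protocol.
#' @return The cost difference per case.
#' @export
cost_difference <- function(rose, fixed) {
  stopifnot(inherits(rose, "policy_outcome"), inherits(fixed, "policy_outcome"))
  if (rose$protocol != "rose" || fixed$protocol != "fixed")
    stop("`rose` and `fixed` must be policy outcomes for the matching ",
         "protocols", call. = FALSE)
  rose$cost_per_case - fixed$cost_per_case
}
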
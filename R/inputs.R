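# Input bundles: technical (sampling), operational (time), cost.

check_prob <- function(x, name, lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single numeric value", name), call. = FALSE)
  lo_ok <- if (lower_open) x > 0 else x >= 0
  hi_ok <- if (upper_open) x < 1 else x <= 1
  if (!lo_ok || !hi_ok)
    stop(sprintf(
      "`%s` = %g is outside %s0, 1%s", name, x,
      if (lower_open) "(" else "[", if (upper_open) ")" else "]"
    ), call. = FALSE)
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative number", name), call. = FALSE)
  as.numeric(x)
}

check_protocol <- function(protocol) {
  match.arg(protocol, c("fixed", "rose"))
}

#' Technical inputs of the sampling model
#'
#' Bundles the five quantities that determine sampling performance: the
#' per-pass adequacy rate `p`, the cytologist's sensitivity `sn` and
#' specificity `sp` (adequacy call judged against the final laboratory
#' assessment), and the stopping rules `n_fixed` (passes taken by the fixed
#' protocol) and `n_rose` (adequate calls required to stop ROSE).
#'
#' `p = 0` is rejected because the expected number of passes would be
#' infinite, and `sp = 0` with `p < 1` is rejected because the ROSE failure
#' odds become ill-defined. Violations raise errors; values are never
#' clamped.
#'
#' @param p Per-pass probability that a needle pass yields an adequate
#'   sample, in (0, 1).
#' @param sn Sensitivity of the cytologist's on-site adequacy call, in
#'   (0, 1].
#' @param sp Specificity of the cytologist's on-site adequacy call, in
#'   (0, 1].
#' @param n_fixed Number of needle passes taken by the fixed protocol
#'   (integer >= 1).
#' @param n_rose Number of positive adequacy calls at which ROSE stops
#'   (integer >= 1, set before sampling).
#' @return An object of class `technical_inputs`.
#' @examples
#' technical_inputs(p = 0.3, sn = 0.95, sp = 0.975, n_fixed = 3, n_rose = 1)
#' @export
technical_inputs <- function(p, sn = 0.95, sp = 0.975, n_fixed = 3L,
                             n_rose = 1L) {
  check_prob(p, "p", lower_open = TRUE, upper_open = TRUE)
  check_prob(sn, "sn", lower_open = TRUE)
  check_prob(sp, "sp", lower_open = TRUE)
  structure(
    list(
      p = as.numeric(p), sn = as.numeric(sn), sp = as.numeric(sp),
      n_fixed = check_count(n_fixed, "n_fixed"),
      n_rose = check_count(n_rose, "n_rose")
    ),
    class = "technical_inputs"
  )
}

#' @export
print.technical_inputs <- function(x, ...) {
  cat("Technical inputs\n")
  cat(sprintf("  per-pass adequacy p : %.3f\n", x$p))
  cat(sprintf("  cytologist sn / sp  : %.3f / %.3f\n", x$sn, x$sp))
  cat(sprintf("  stopping rules      : n_fixed = %d, n_rose = %d\n",
              x$n_fixed, x$n_rose))
  invisible(x)
}

#' Operational inputs of the procedure-time model
#'
#' The procedure is divided into a setup period (identical for both
#' protocols) and a sampling period. Durations are in minutes. The time per
#' needle pass is typically longer with ROSE because each pass waits on the
#' on-site assessment; a shorter ROSE pass time is unusual but permitted
#' (with a warning).
#'
#' @param t_setup Setup time, minutes.
#' @param t_pass_fixed Time per needle pass under the fixed protocol,
#'   minutes.
#' @param t_pass_rose Time per needle pass under ROSE, minutes.
#' @return An object of class `operational_inputs`.
#' @examples
#' operational_inputs(t_setup = 30, t_pass_fixed = 2, t_pass_rose = 9)
#' @export
operational_inputs <- function(t_setup, t_pass_fixed, t_pass_rose) {
  check_nonneg(t_setup, "t_setup")
  check_nonneg(t_pass_fixed, "t_pass_fixed")
  check_nonneg(t_pass_rose, "t_pass_rose")
  if (t_pass_rose < t_pass_fixed)
    warning("t_pass_rose < t_pass_fixed: ROSE passes are usually slower",
            call. = FALSE)
  structure(
    list(t_setup = as.numeric(t_setup),
         t_pass_fixed = as.numeric(t_pass_fixed),
         t_pass_rose = as.numeric(t_pass_rose)),
    class = "operational_inputs"
  )
}

#' Cost inputs of the micro-costing model
#'
#' Time-based (variable) costs are expressed in currency per hour, fixed
#' costs in currency per procedure, and the needle-pass cost in currency per
#' pass. `rate_other` carries the full hourly cost of the non-cytologist
#' procedure team (specialist, assistants, room opportunity cost);
#' `rate_cytologist` is the hourly cost a ROSE protocol adds. Under the
#' societal perspective the patient's hourly wage `rate_patient` is added to
#' the effective rate of both protocols; the provider perspective drops it.
#'
#' `fixed_rate_override` / `rose_rate_override`, when supplied, replace the
#' composed pre-patient hourly total for the respective protocol. They
#' express staffing models the additive composition cannot — e.g. a simple
#' palpation-guided procedure where the cytologist performs the aspiration,
#' so ROSE adds no personnel and both protocols bill the same team rate.
#' `rate_patient` is still added under the societal perspective.
#'
#' `cost_per_pass` is the expected cost attached to one needle pass: supplies
#' plus the probability-weighted cost of per-pass adverse events. No
#' adverse-event sub-model is built; the expectation is a single input.
#'
#' @param rate_cytologist Hourly cost of the on-site cytologist.
#' @param rate_other Hourly cost of everything else that scales with time.
#' @param rate_patient Patient hourly wage (societal perspective only).
#' @param cost_fixed Per-procedure cost independent of duration (final
#'   cytopathology, special supplies).
#' @param cost_per_pass Expected cost per needle pass.
#' @param perspective `"societal"` (default, includes patient time) or
#'   `"provider"`.
#' @param fixed_rate_override,rose_rate_override Optional direct pre-patient
#'   hourly totals replacing the composed rate.
#' @return An object of class `cost_inputs`.
#' @examples
#' cost_inputs(rate_cytologist = 100, rate_other = 260, rate_patient = 20,
#'             cost_fixed = 300, cost_per_pass = 30)
#' @export
cost_inputs <- function(rate_cytologist, rate_other, rate_patient = 0,
                        cost_fixed = 0, cost_per_pass = 0,
                        perspective = c("societal", "provider"),
                        fixed_rate_override = NULL,
                        rose_rate_override = NULL) {
  perspective <- match.arg(perspective)
  for (nm in c("rate_cytologist", "rate_other", "rate_patient",
               "cost_fixed", "cost_per_pass"))
    check_nonneg(get(nm), nm)
  if (!is.null(fixed_rate_override))
    check_nonneg(fixed_rate_override, "fixed_rate_override")
  if (!is.null(rose_rate_override))
    check_nonneg(rose_rate_override, "rose_rate_override")
  structure(
    list(
      rate_cytologist = as.numeric(rate_cytologist),
      rate_other = as.numeric(rate_other),
      rate_patient = as.numeric(rate_patient),
      cost_fixed = as.numeric(cost_fixed),
      cost_per_pass = as.numeric(cost_per_pass),
      perspective = perspective,
      fixed_rate_override =
        if (is.null(fixed_rate_override)) NULL else as.numeric(fixed_rate_override),
      rose_rate_override =
        if (is.null(rose_rate_override)) NULL else as.numeric(rose_rate_override)
    ),
    class = "cost_inputs"
  )
}

#' @export
print.cost_inputs <- function(x, ...) {
  cat("Cost inputs (", x$perspective, " perspective)\n", sep = "")
  cat(sprintf("  cytologist / other / patient rate : %g / %g / %g per hr\n",
              x$rate_cytologist, x$rate_other, x$rate_patient))
  cat(sprintf("  fixed per procedure / per pass    : %g / %g\n",
              x$cost_fixed, x$cost_per_pass))
  if (!is.null(x$fixed_rate_override) || !is.null(x$rose_rate_override))
    cat(sprintf("  rate overrides (fixed / rose)     : %s / %s per hr\n",
                if (is.null(x$fixed_rate_override)) "-" else x$fixed_rate_override,
                if (is.null(x$rose_rate_override)) "-" else x$rose_rate_override))
  invisible(x)
}
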
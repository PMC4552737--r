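# Stochastic per-case simulator of the sampling process.
#
# Event semantics: every needle pass is truly adequate with probability p.
# Under ROSE the cytologist calls a pass positive with probability sn if it
# is adequate and 1 - sp if it is not; sampling stops at the n_rose-th
# positive call. The procedure succeeds iff at least one collected sample
# is truly adequate — an adequate sample miscalled negative still rescues
# the case at final processing, while a run of false positives can end a
# procedure with no usable material. A failed procedure is repeated. The
# simulator is the brute-force oracle for the closed-form sampling model.

#' Simulate a batch of procedures
#'
#' Runs `n` independent procedures under one protocol, pass by pass.
#' Vectorized over procedures: each iteration draws one pass for every
#' still-active procedure.
#'
#' @param t A [technical_inputs()] object.
#' @param protocol `"fixed"` or `"rose"`.
#' @param n Number of procedures.
#' @param max_passes Safety cap on passes per procedure; a ROSE procedure
#'   hitting the cap is recorded as truncated (and failed unless it already
#'   holds adequate material), never silently extended.
#' @return A tibble with one row per procedure: `success`, `passes`,
#'   `truncated`.
#' @examples
#' t <- technical_inputs(p = 0.6, sn = 0.95, sp = 0.975, n_rose = 1)
#' sim <- simulate_procedures(t, "rose", n = 1000)
#' mean(sim$success)
#' @export
simulate_procedures <- function(t, protocol = c("fixed", "rose"), n,
                                max_passes = 10000L) {
  stopifnot(inherits(t, "technical_inputs"))
  protocol <- match.arg(protocol)
  n <- check_count(n, "n")
  max_passes <- check_count(max_passes, "max_passes")
  if (protocol == "fixed") {
    adequate <- rbinom(n, t$n_fixed, t$p)
    return(tibble::tibble(success = adequate > 0L,
                          passes = rep(as.integer(t$n_fixed), n),
                          truncated = rep(FALSE, n)))
  }
  positives <- integer(n)
  passes <- integer(n)
  any_adequate <- logical(n)
  active <- seq_len(n)
  while (length(active)) {
    m <- length(active)
    adeq <- runif(m) < t$p
    # positive-call probability: sn if adequate, 1 - sp otherwise
    called <- runif(m) < ((1 - t$sp) + adeq * (t$sn - (1 - t$sp)))
    passes[active] <- passes[active] + 1L
    any_adequate[active] <- any_adequate[active] | adeq
    positives[active] <- positives[active] + called
    done <- positives[active] >= t$n_rose | passes[active] >= max_passes
    active <- active[!done]
  }
  truncated <- passes >= max_passes & positives < t$n_rose
  tibble::tibble(success = any_adequate, passes = passes,
                 truncated = truncated)
}

#' Simulate a batch of cases
#'
#' A case repeats the procedure until one succeeds (or the procedure cap is
#' reached). Vectorized over cases: each round simulates one procedure for
#' every still-unresolved case.
#'
#' @inheritParams simulate_procedures
#' @param n_cases Number of cases.
#' @param seed Optional integer seed; when given, the run is reproducible
#'   and the caller's RNG state is left untouched.
#' @param max_procedures Safety cap on procedures per case.
#' @return A tibble with one row per case: `procedures`, `passes_total`,
#'   `adequate_obtained`, `truncated` (a pass- or procedure-cap hit
#'   anywhere in the case).
#' @examples
#' t <- technical_inputs(p = 0.3, n_fixed = 3)
#' sim <- simulate_cases(t, "fixed", n_cases = 1000, seed = 1)
#' mean(sim$procedures)  # close to 1 / (1 - 0.7^3) = 1.522
#' @export
simulate_cases <- function(t, protocol = c("fixed", "rose"), n_cases,
                           seed = NULL, max_passes = 10000L,
                           max_procedures = 1000L) {
  protocol <- match.arg(protocol)
  n_cases <- check_count(n_cases, "n_cases")
  max_procedures <- check_count(max_procedures, "max_procedures")
  run <- function() {
    procedures <- integer(n_cases)
    passes_total <- integer(n_cases)
    resolved <- logical(n_cases)
    truncated <- logical(n_cases)
    active <- seq_len(n_cases)
    while (length(active)) {
      sim <- simulate_procedures(t, protocol, length(active), max_passes)
      procedures[active] <- procedures[active] + 1L
      passes_total[active] <- passes_total[active] + sim$passes
      truncated[active] <- truncated[active] | sim$truncated
      resolved[active] <- sim$success
      capped <- procedures[active] >= max_procedures
      truncated[active] <- truncated[active] | (capped & !sim$success)
      active <- active[!sim$success & !capped]
    }
    tibble::tibble(procedures = procedures, passes_total = passes_total,
                   adequate_obtained = resolved, truncated = truncated)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a single case with a per-pass event log
#'
#' Scalar companion to [simulate_cases()] that records every pass: which
#' procedure it belonged to, whether the sample was truly adequate, and
#' (under ROSE) whether the cytologist called it positive.
#'
#' @inheritParams simulate_cases
#' @return A list with `procedures`, `passes_total`, `adequate_obtained`,
#'   `truncated`, and `pass_log`, a tibble with columns `procedure`,
#'   `truly_adequate`, `called_positive`.
#' @export
simulate_case <- function(t, protocol = c("fixed", "rose"), seed = NULL,
                          max_passes = 10000L, max_procedures = 1000L) {
  stopifnot(inherits(t, "technical_inputs"))
  protocol <- match.arg(protocol)
  run <- function() {
    log_proc <- integer(0); log_adeq <- logical(0); log_call <- logical(0)
    procedures <- 0L; success <- FALSE; truncated <- FALSE
    while (!success && procedures < max_procedures) {
      procedures <- procedures + 1L
      passes <- 0L; positives <- 0L; proc_adequate <- FALSE
      repeat {
        passes <- passes + 1L
        adeq <- runif(1) < t$p
        call <- if (protocol == "rose")
          runif(1) < (if (adeq) t$sn else 1 - t$sp)
        else NA
        proc_adequate <- proc_adequate || adeq
        positives <- positives + isTRUE(call)
        log_proc <- c(log_proc, procedures)
        log_adeq <- c(log_adeq, adeq)
        log_call <- c(log_call, call)
        if (protocol == "fixed" && passes >= t$n_fixed) break
        if (protocol == "rose" && positives >= t$n_rose) break
        if (passes >= max_passes) { truncated <- TRUE; break }
      }
      success <- proc_adequate
    }
    if (!success) truncated <- TRUE
    list(procedures = procedures, passes_total = length(log_proc),
         adequate_obtained = success, truncated = truncated,
         pass_log = tibble::tibble(procedure = log_proc,
                                   truly_adequate = log_adeq,
                                   called_positive = log_call))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Empirical policy outcome from simulated cases
#'
#' Monte Carlo analogue of [evaluate_policy()]: simulates cases, prices
#' each one from its event counts — every procedure incurs the setup-time
#' cost and the fixed cost, every pass the pass-time cost and the per-pass
#' cost — and returns the empirical mean and Monte Carlo standard error of
#' each policy-outcome field.
#'
#' @param t A [technical_inputs()] object.
#' @param o An [operational_inputs()] object.
#' @param c A [cost_inputs()] object.
#' @param protocol `"fixed"` or `"rose"`.
#' @param n_cases Number of simulated cases.
#' @param seed Optional integer seed.
#' @param max_passes,max_procedures Safety caps, as in [simulate_cases()].
#' @return A list with `protocol`, `n_cases`, `n_truncated`, and a
#'   `summary` tibble with one row per quantity (`adequacy`,
#'   `passes_per_procedure`, `procedures_per_case`, `t_sample`,
#'   `cost_per_case`) holding the empirical `mean` and `se`.
#' @examples
#' t <- technical_inputs(p = 0.6, n_fixed = 3, n_rose = 1)
#' o <- operational_inputs(30, 2, 9)
#' cc <- cost_inputs(100, 260, 20, cost_fixed = 300, cost_per_pass = 30)
#' simulate_policy(t, o, cc, "fixed", n_cases = 2000, seed = 1)$summary
#' @export
simulate_policy <- function(t, o, c, protocol = c("fixed", "rose"), n_cases,
                            seed = NULL, max_passes = 10000L,
                            max_procedures = 1000L) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(o, "operational_inputs"), inherits(c, "cost_inputs"))
  sim <- simulate_cases(t, protocol, n_cases, seed, max_passes,
                        max_procedures)
  t_pass <- if (protocol == "fixed") o$t_pass_fixed else o$t_pass_rose
  rate <- variable_rate(c, protocol)
  cost <- sim$procedures * (o$t_setup / 60 * rate + c$cost_fixed) +
    sim$passes_total * (t_pass / 60 * rate + c$cost_per_pass)
  t_sample_case <- sim$passes_total * t_pass
  # per-procedure quantities use ratio estimators over all procedures run
  n_proc <- sum(sim$procedures)
  passes_pp <- sum(sim$passes_total) / n_proc
  adequacy <- sum(sim$adequate_obtained) / n_proc
  mc <- function(x) c(mean = mean(x), se = sd(x) / sqrt(length(x)))
  proc_mc <- mc(sim$procedures)
  cost_mc <- mc(cost)
  tsamp_mc <- mc(t_sample_case)
  summary <- tibble::tibble(
    quantity = c("adequacy", "passes_per_procedure", "procedures_per_case",
                 "t_sample", "cost_per_case"),
    mean = c(adequacy, passes_pp, proc_mc["mean"], tsamp_mc["mean"],
             cost_mc["mean"]),
    se = c(sqrt(adequacy * (1 - adequacy) / n_proc),
           sd(sim$passes_total / sim$procedures) / sqrt(n_cases),
           proc_mc["se"], tsamp_mc["se"], cost_mc["se"])
  )
  list(protocol = protocol, n_cases = n_cases,
       n_truncated = sum(sim$truncated), summary = summary)
}
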
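# Benchmark scenario catalogue and paired protocol comparisons.
#
# A scenario is identified by the 4-tuple (procedure type, adequacy level,
# n_rose, n_fixed); the default configuration's cross-product
# 2 x 2 x 2 x 4 yields the 32 packaged scenarios. Each carries the full
# parameter table (base, low, high) needed downstream by the sensitivity
# module.

#' Build the scenario catalogue
#'
#' Enumerates every combination of procedure type (simple, complex),
#' per-pass adequacy level (low, high) and stopping-rule pair from the
#' configuration — 32 scenarios under the default config. Ordering is
#' type, then level, then `n_rose`, then `n_fixed`.
#'
#' @param config A `model_config` from [load_model_config()], or a fixture
#'   name / path accepted by it.
#' @return A tibble with one row per scenario: `scenario_id`, `label`,
#'   `procedure_type`, `adequacy_level`, `n_rose`, `n_fixed`,
#'   `cytologist_in_fixed`, rate overrides, and a `params` list-column
#'   holding each scenario's parameter table (`parameter`, `base`, `low`,
#'   `high`).
#' @examples
#' cat32 <- scenario_catalogue()
#' nrow(cat32)  # 32
#' @export
scenario_catalogue <- function(config = "default") {
  if (!inherits(config, "model_config"))
    config <- load_model_config(config)
  grid <- expand.grid(
    n_fixed = config$stopping$n_fixed,
    n_rose = config$stopping$n_rose,
    adequacy_level = c("low", "high"),
    procedure_type = c("simple", "complex"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # expand.grid varies the first column fastest; reorder columns for reading
  grid <- grid[, c("procedure_type", "adequacy_level", "n_rose", "n_fixed")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pt <- config$procedure[[g$procedure_type]]
    spec_rows <- function(nm, spec) {
      tibble::tibble(parameter = nm, base = spec$base,
                     low = spec$low, high = spec$high)
    }
    params <- rbind(
      spec_rows("p", config$adequacy[[g$adequacy_level]]),
      do.call(rbind, mapply(spec_rows, names(config$shared), config$shared,
                            SIMPLIFY = FALSE)),
      do.call(rbind, lapply(PROCEDURE_SYMBOLS, function(nm)
        spec_rows(nm, pt[[nm]]))),
      spec_rows("n_fixed", list(base = g$n_fixed,
                                low = min(config$stopping$n_fixed),
                                high = max(config$stopping$n_fixed))),
      spec_rows("n_rose", list(base = g$n_rose,
                               low = min(config$stopping$n_rose),
                               high = max(config$stopping$n_rose)))
    )
    tibble::tibble(
      scenario_id = i,
      label = sprintf("%s/%s nR=%d nF=%d", g$procedure_type,
                      g$adequacy_level, g$n_rose, g$n_fixed),
      procedure_type = g$procedure_type,
      adequacy_level = g$adequacy_level,
      n_rose = as.integer(g$n_rose),
      n_fixed = as.integer(g$n_fixed),
      cytologist_in_fixed = pt$cytologist_in_fixed,
      fixed_rate_override = list(pt$fixed_rate_override),
      rose_rate_override = list(pt$rose_rate_override),
      params = list(params)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_catalogue", class(out))
  out
}

#' Pick one scenario from a catalogue
#'
#' @param catalogue A catalogue from [scenario_catalogue()].
#' @param procedure_type `"simple"` or `"complex"`.
#' @param adequacy_level `"low"` or `"high"`.
#' @param n_rose,n_fixed Stopping rules identifying the scenario.
#' @return A one-row scenario tibble.
#' @export
get_scenario <- function(catalogue, procedure_type, adequacy_level,
                         n_rose, n_fixed) {
  hit <- catalogue$procedure_type == procedure_type &
    catalogue$adequacy_level == adequacy_level &
    catalogue$n_rose == n_rose & catalogue$n_fixed == n_fixed
  if (sum(hit) != 1L)
    stop(sprintf("scenario (%s, %s, n_rose=%d, n_fixed=%d) matched %d rows",
                 procedure_type, adequacy_level, n_rose, n_fixed, sum(hit)),
         call. = FALSE)
  catalogue[hit, ]
}

param_values <- function(scenario, at = "base") {
  params <- scenario$params[[1L]]
  setNames(params[[at]], params$parameter)
}

#' Assemble the input bundles of a scenario
#'
#' Translates one scenario row into the [technical_inputs()],
#' [operational_inputs()] and [cost_inputs()] objects that
#' [evaluate_policy()] consumes. When the scenario's staffing model puts
#' the cytologist on the base team (`cytologist_in_fixed`), both protocols
#' receive the same composed rate override `c_var_o + c_var_c`, recomputed
#' from the current component values so sensitivity variation flows
#' through.
#'
#' @param scenario A one-row scenario tibble.
#' @param values Optional named vector of parameter values replacing the
#'   scenario's base values (used by the sensitivity module).
#' @param perspective `"societal"` or `"provider"`.
#' @return A list with elements `technical`, `operational`, `cost`.
#' @export
scenario_inputs <- function(scenario, values = NULL,
                            perspective = "societal") {
  v <- param_values(scenario)
  if (!is.null(values)) {
    check_symbols(names(values), MODEL_SYMBOLS, "`values`")
    v[names(values)] <- values
  }
  team <- unname(v["c_var_o"] + v["c_var_c"])
  fixed_override <- scenario$fixed_rate_override[[1L]]
  rose_override <- scenario$rose_rate_override[[1L]]
  if (scenario$cytologist_in_fixed) {
    if (is.null(fixed_override)) fixed_override <- team
    if (is.null(rose_override)) rose_override <- team
  }
  list(
    technical = technical_inputs(p = v[["p"]], sn = v[["sn"]], sp = v[["sp"]],
                                 n_fixed = v[["n_fixed"]],
                                 n_rose = v[["n_rose"]]),
    operational = operational_inputs(t_setup = v[["t_setup"]],
                                     t_pass_fixed = v[["t_pass_fixed"]],
                                     t_pass_rose = v[["t_pass_rose"]]),
    cost = cost_inputs(rate_cytologist = v[["c_var_c"]],
                       rate_other = v[["c_var_o"]],
                       rate_patient = v[["c_pat"]],
                       cost_fixed = v[["c_fixed"]],
                       cost_per_pass = v[["c_np"]],
                       perspective = perspective,
                       fixed_rate_override = fixed_override,
                       rose_rate_override = rose_override)
  )
}

#' Compare ROSE against fixed sampling in one scenario
#'
#' Evaluates both policies at the scenario's base values and collects the
#' paired outcomes plus rose-minus-fixed differences.
#'
#' @param scenario A one-row scenario tibble from [scenario_catalogue()].
#' @param values,perspective Passed to [scenario_inputs()].
#' @return An object of class `protocol_comparison`: the scenario, the two
#'   `policy_outcome`s, `delta_cost` (ROSE minus fixed cost per case;
#'   negative favors ROSE) and a `deltas` named vector over adequacy,
#'   expected passes, expected procedures, sampling time and cost per
#'   procedure.
#' @examples
#' cat32 <- scenario_catalogue()
#' cmp <- compare_protocols(get_scenario(cat32, "complex", "high", 1, 3))
#' cmp$delta_cost
#' @export
compare_protocols <- function(scenario, values = NULL,
                              perspective = "societal") {
  inp <- scenario_inputs(scenario, values, perspective)
  fixed <- evaluate_policy(inp$technical, inp$operational, inp$cost, "fixed")
  rose <- evaluate_policy(inp$technical, inp$operational, inp$cost, "rose")
  structure(
    list(
      scenario = scenario,
      fixed = fixed, rose = rose,
      delta_cost = cost_difference(rose, fixed),
      deltas = c(
        adequacy = rose$sampling$adequacy - fixed$sampling$adequacy,
        expected_passes = rose$sampling$expected_passes -
          fixed$sampling$expected_passes,
        expected_procedures = rose$sampling$expected_procedures -
          fixed$sampling$expected_procedures,
        t_sample = rose$t_sample - fixed$t_sample,
        cost_per_procedure = rose$cost_per_procedure - fixed$cost_per_procedure,
        cost_per_case = rose$cost_per_case - fixed$cost_per_case
      )
    ),
    class = "protocol_comparison"
  )
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat(sprintf("Protocol comparison — %s\n", x$scenario$label))
  cat(sprintf("  cost per case: ROSE %.1f vs fixed %.1f (delta %+.1f, %s)\n",
              x$rose$cost_per_case, x$fixed$cost_per_case, x$delta_cost,
              if (x$delta_cost < 0) "ROSE saves" else "fixed cheaper"))
  invisible(x)
}

#' Base-case comparison table
#'
#' Renders a set of protocol comparisons as a report table: six outcome
#' rows (cost per case, needle passes, adequacy, procedures per case, cost
#' per procedure, sampling duration), each with a ROSE, fixed and
#' difference line, one column per scenario. All computation is carried at
#' full precision; rounding is applied exactly once here, at render time
#' (costs to whole currency units, passes and durations to one decimal,
#' adequacy and procedure counts to two).
#'
#' @param comparisons A list of `protocol_comparison` objects (or a single
#'   one).
#' @return A tibble with columns `outcome`, `protocol`, then one column per
#'   scenario label.
#' @export
base_case_table <- function(comparisons) {
  if (inherits(comparisons, "protocol_comparison"))
    comparisons <- list(comparisons)
  rows <- list(
    list("Expected total cost per case", "cost_per_case", 0),
    list("Needle passes per procedure", "expected_passes", 1),
    list("Adequacy rate", "adequacy", 2),
    list("Procedures per case", "expected_procedures", 2),
    list("Cost per procedure", "cost_per_procedure", 0),
    list("Duration of sampling period (min)", "t_sample", 1)
  )
  pick <- function(cmp, field, protocol) {
    out <- cmp[[protocol]]
    switch(field,
      cost_per_case = out$cost_per_case,
      cost_per_procedure = out$cost_per_procedure,
      t_sample = out$t_sample,
      adequacy = out$sampling$adequacy,
      expected_passes = out$sampling$expected_passes,
      expected_procedures = out$sampling$expected_procedures
    )
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    vals <- lapply(c("rose", "fixed"), function(pr)
      vapply(comparisons, pick, numeric(1), field = r[[2]], protocol = pr))
    diff <- vals[[1]] - vals[[2]]
    block <- rbind(round(vals[[1]], r[[3]]), round(vals[[2]], r[[3]]),
                   round(diff, r[[3]]))
    colnames(block) <- vapply(comparisons, function(cmp)
      cmp$scenario$label, character(1))
    cbind(tibble::tibble(outcome = r[[1]],
                         protocol = c("rose", "fixed", "difference")),
          tibble::as_tibble(block))
  }))
  tibble::as_tibble(tab)
}
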
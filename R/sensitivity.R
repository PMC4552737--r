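# One-way (tornado) and probabilistic (Monte Carlo) sensitivity analysis
# of the per-case cost difference, delta TC = TC(rose) - TC(fixed).

# Continuous model parameters eligible for variation. The stopping rules
# n_fixed / n_rose are integers that define the scenario being compared and
# are held at the scenario's values unless explicitly requested.
CONTINUOUS_SYMBOLS <- c("p", "sn", "sp", "t_setup", "t_pass_fixed",
                        "t_pass_rose", "c_var_o", "c_var_c", "c_pat",
                        "c_np", "c_fixed")
PSA_SYMBOLS <- c("p", "t_setup", "t_pass_fixed", "t_pass_rose",
                 "c_var_o", "c_var_c", "c_pat", "c_np", "c_fixed")

# Vectorized closed-form pipeline over named parameter vectors. `v` is a
# list/environment of equal-length (or length-1) numeric vectors for all 13
# model symbols. Returns the per-draw cost difference.
delta_tc_vectorized <- function(v, cytologist_in_fixed,
                                fixed_rate_override = NULL,
                                rose_rate_override = NULL,
                                societal = TRUE) {
  pat <- if (societal) v$c_pat else 0
  team <- v$c_var_o + v$c_var_c
  rate_f <- if (!is.null(fixed_rate_override)) fixed_rate_override
            else if (cytologist_in_fixed) team else v$c_var_o
  rate_r <- if (!is.null(rose_rate_override)) rose_rate_override
            else if (cytologist_in_fixed) team else team
  rate_f <- rate_f + pat
  rate_r <- rate_r + pat

  a_f <- 1 - (1 - v$p)^v$n_fixed
  tc_proc_f <- (v$t_setup + v$n_fixed * v$t_pass_fixed) / 60 * rate_f +
    v$c_fixed + v$n_fixed * v$c_np
  tc_f <- tc_proc_f / a_f

  odds <- ((1 - v$sp) * (1 - v$p)) / (1 - v$sp * (1 - v$p))
  a_r <- 1 - odds^v$n_rose
  n_pass_r <- v$n_rose / ((1 - v$sp) * (1 - v$p) + v$p * v$sn)
  tc_proc_r <- (v$t_setup + n_pass_r * v$t_pass_rose) / 60 * rate_r +
    v$c_fixed + n_pass_r * v$c_np
  tc_r <- tc_proc_r / a_r

  tc_r - tc_f
}

scenario_delta_env <- function(scenario, perspective) {
  base <- param_values(scenario)
  list(base = base,
       cytologist_in_fixed = scenario$cytologist_in_fixed,
       fixed_rate_override = scenario$fixed_rate_override[[1L]],
       rose_rate_override = scenario$rose_rate_override[[1L]],
       societal = identical(perspective, "societal"))
}

#' One-way (tornado) sensitivity analysis of the cost difference
#'
#' Evaluates the per-case cost difference (ROSE minus fixed) at the low and
#' high bound of each parameter's plausible range, all other parameters at
#' base. Parameters are returned in tornado order: descending span
#' (`|delta_at_high - delta_at_low|`), ties broken by name. By default the
#' continuous parameters are varied; the integer stopping rules define the
#' scenario and are excluded unless `include_stopping_rules = TRUE`.
#' Parameters whose configured range has zero width yield a zero span;
#' a parameter with no usable range is skipped with a message.
#'
#' @param scenario A one-row scenario tibble from [scenario_catalogue()].
#' @param parameters Character vector of parameters to vary; default all
#'   continuous symbols.
#' @param include_stopping_rules Also vary `n_fixed` / `n_rose` across
#'   their configured integer ranges.
#' @param perspective `"societal"` or `"provider"`.
#' @return A tibble with columns `parameter`, `low`, `high`,
#'   `delta_at_low`, `delta_at_high`, `delta_base`, `span`, sorted in
#'   tornado order.
#' @examples
#' cat32 <- scenario_catalogue()
#' ow <- one_way_sensitivity(get_scenario(cat32, "complex", "low", 1, 3))
#' head(ow, 3)
#' @export
one_way_sensitivity <- function(scenario, parameters = NULL,
                                include_stopping_rules = FALSE,
                                perspective = "societal") {
  params <- scenario$params[[1L]]
  if (is.null(parameters)) {
    parameters <- CONTINUOUS_SYMBOLS
    if (include_stopping_rules)
      parameters <- c(parameters, "n_fixed", "n_rose")
  } else {
    check_symbols(parameters, MODEL_SYMBOLS, "`parameters`")
  }
  delta_at <- function(values)
    compare_protocols(scenario, values, perspective)$delta_cost
  delta_base <- delta_at(NULL)
  rows <- lapply(parameters, function(nm) {
    row <- params[params$parameter == nm, ]
    if (nrow(row) != 1L || any(is.na(c(row$low, row$high)))) {
      message(sprintf("one_way_sensitivity: no range for `%s`; skipped", nm))
      return(NULL)
    }
    is_int <- nm %in% c("n_fixed", "n_rose")
    lo <- if (is_int) round(row$low) else row$low
    hi <- if (is_int) round(row$high) else row$high
    d_lo <- delta_at(setNames(lo, nm))
    d_hi <- delta_at(setNames(hi, nm))
    tibble::tibble(parameter = nm, low = lo, high = hi,
                   delta_at_low = d_lo, delta_at_high = d_hi,
                   delta_base = delta_base, span = abs(d_hi - d_lo))
  })
  out <- do.call(rbind, rows)
  out[order(-out$span, out$parameter), ]
}

#' Probabilistic sensitivity analysis of the cost difference
#'
#' Draws the continuous model parameters independently and uniformly from
#' their plausible ranges (the minimal-information choice given ranges
#' only), propagates each draw through the full closed-form pipeline, and
#' summarizes the distribution of the per-case cost difference. The
#' stopping rules `n_fixed` / `n_rose` stay at the scenario's values: they
#' define the protocols being compared. The cytologist accuracy `sn` / `sp`
#' is likewise held at base; the nine varied symbols are `p`, `t_setup`,
#' `t_pass_fixed`, `t_pass_rose`, `c_var_o`, `c_var_c`, `c_pat`, `c_np`
#' and `c_fixed`.
#'
#' @param scenario A one-row scenario tibble from [scenario_catalogue()].
#' @param n_draws Number of Monte Carlo draws (default 100,000).
#' @param seed Integer seed; required, so every summary is reproducible.
#' @param perspective `"societal"` or `"provider"`.
#' @param distributions Optional named list mapping a parameter to a
#'   function `f(n, low, high)` returning its draws, replacing the uniform.
#' @return An object of class `psa_result`: the scenario label and id,
#'   `n_draws`, `seed`, the vector of `deltas`, and `summary` (mean, sd,
#'   quantiles 2.5/25/50/75/97.5%, and `prob_rose_saves`, the fraction of
#'   draws with a negative difference).
#' @examples
#' cat32 <- scenario_catalogue()
#' res <- psa(get_scenario(cat32, "complex", "low", 1, 3),
#'            n_draws = 1000, seed = 7)
#' res$summary$prob_rose_saves
#' @export
psa <- function(scenario, n_draws = 1e5, seed, perspective = "societal",
                distributions = NULL) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for reproducible draws", call. = FALSE)
  n_draws <- check_count(n_draws, "n_draws")
  env <- scenario_delta_env(scenario, perspective)
  params <- scenario$params[[1L]]
  if (!is.null(distributions))
    check_symbols(names(distributions), PSA_SYMBOLS, "`distributions`")
  draws <- withr::with_seed(seed, {
    lapply(setNames(PSA_SYMBOLS, PSA_SYMBOLS), function(nm) {
      row <- params[params$parameter == nm, ]
      if (row$low == row$high) return(rep(row$base, n_draws))
      f <- distributions[[nm]]
      if (is.null(f)) runif(n_draws, row$low, row$high)
      else f(n_draws, row$low, row$high)
    })
  })
  v <- c(draws, as.list(env$base[setdiff(MODEL_SYMBOLS, PSA_SYMBOLS)]))
  deltas <- delta_tc_vectorized(v, env$cytologist_in_fixed,
                                env$fixed_rate_override,
                                env$rose_rate_override, env$societal)
  q <- quantile(deltas, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(
    list(
      scenario_id = scenario$scenario_id, label = scenario$label,
      n_draws = n_draws, seed = seed, deltas = deltas,
      summary = tibble::tibble(
        mean = mean(deltas), sd = sd(deltas),
        q2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4], q97.5 = q[5],
        prob_rose_saves = mean(deltas < 0)
      )
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA — %s (%d draws, seed %d)\n", x$label, x$n_draws, x$seed))
  s <- x$summary
  cat(sprintf("  delta cost per case: mean %.1f (sd %.1f), 95%% interval [%.1f, %.1f]\n",
              s$mean, s$sd, s$q2.5, s$q97.5))
  cat(sprintf("  fraction of draws favoring ROSE: %.3f\n", s$prob_rose_saves))
  invisible(x)
}
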
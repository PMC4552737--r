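# Declarative model configuration: YAML in, validated parameter tables out.
#
# A configuration names every model symbol once, with a base value and the
# [low, high] range used for sensitivity analysis. Durations are minutes,
# rates currency per hour, fixed costs currency per procedure, the
# needle-pass cost currency per pass. Two fixtures ship with the package:
# "default" (the canonical assumption set) and "variant" (an alternate set
# with a more specific cytologist and shorter setup times).

MODEL_SYMBOLS <- c("p", "sn", "sp", "n_fixed", "n_rose",
                   "t_setup", "t_pass_fixed", "t_pass_rose",
                   "c_var_o", "c_var_c", "c_pat", "c_np", "c_fixed")

SHARED_SYMBOLS <- c("sn", "sp", "c_pat", "t_pass_fixed", "t_pass_rose")
PROCEDURE_SYMBOLS <- c("t_setup", "c_var_o", "c_var_c", "c_np", "c_fixed")

as_param_spec <- function(x, name) {
  if (is.numeric(x) && length(x) == 1L)
    x <- list(base = x, low = x, high = x)
  if (!is.list(x) || !all(c("base", "low", "high") %in% names(x)))
    stop(sprintf("parameter `%s` must be a number or a {base, low, high} map",
                 name), call. = FALSE)
  spec <- list(base = as.numeric(x$base), low = as.numeric(x$low),
               high = as.numeric(x$high))
  if (!(spec$low <= spec$base && spec$base <= spec$high))
    stop(sprintf("parameter `%s`: need low <= base <= high, got (%g, %g, %g)",
                 name, spec$low, spec$base, spec$high), call. = FALSE)
  spec
}

check_symbols <- function(nms, allowed, where) {
  bad <- setdiff(nms, allowed)
  if (length(bad))
    stop(sprintf("unknown parameter(s) in %s: %s. Valid symbols: %s",
                 where, paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  invisible(nms)
}

#' Load a model configuration
#'
#' Reads a declarative parameter configuration from a YAML file, or one of
#' the packaged fixtures by name: `"default"` (the canonical assumption
#' set, cytologist specificity 0.975) or `"variant"` (an alternate set with
#' specificity 0.99, shorter setup times, and a direct ROSE rate total for
#' complex procedures). Every parameter is validated against the model's
#' symbol list; unknown names are rejected with the list of valid symbols.
#'
#' @param source Path to a YAML file, or a fixture name.
#' @param overrides Optional named list of base-value overrides, e.g.
#'   `list(sp = 0.99)`. An override of `p` replaces the base of both
#'   adequacy levels. Unknown names are rejected.
#' @return An object of class `model_config`: a validated list with
#'   elements `name`, `shared`, `adequacy`, `procedure` and `stopping`.
#' @examples
#' cfg <- load_model_config("default")
#' cfg$shared$sp$base  # 0.975
#' @export
load_model_config <- function(source = "default", overrides = NULL) {
  path <- if (file.exists(source)) {
    source
  } else {
    p <- system.file("extdata", paste0(source, ".yaml"), package = "rosecost")
    if (!nzchar(p))
      stop(sprintf("no config file or packaged fixture named '%s'", source),
           call. = FALSE)
    p
  }
  raw <- yaml::read_yaml(path)
  cfg <- validate_model_config(raw)
  if (!is.null(overrides))
    cfg <- apply_overrides(cfg, overrides)
  cfg
}

validate_model_config <- function(raw) {
  for (section in c("shared", "adequacy", "procedure", "stopping"))
    if (is.null(raw[[section]]))
      stop(sprintf("config is missing the `%s` section", section),
           call. = FALSE)
  check_symbols(names(raw$shared), SHARED_SYMBOLS, "`shared`")
  if (!setequal(names(raw$shared), SHARED_SYMBOLS))
    stop("`shared` must define exactly: ",
         paste(SHARED_SYMBOLS, collapse = ", "), call. = FALSE)
  shared <- lapply(seq_along(raw$shared), function(i)
    as_param_spec(raw$shared[[i]], names(raw$shared)[i]))
  names(shared) <- names(raw$shared)

  if (!setequal(names(raw$adequacy), c("low", "high")))
    stop("`adequacy` must define levels `low` and `high`", call. = FALSE)
  adequacy <- lapply(c(low = "low", high = "high"), function(lv)
    as_param_spec(raw$adequacy[[lv]]$p, paste0("p (", lv, ")")))

  if (!setequal(names(raw$procedure), c("simple", "complex")))
    stop("`procedure` must define types `simple` and `complex`", call. = FALSE)
  procedure <- lapply(c(simple = "simple", complex = "complex"), function(ty) {
    pt <- raw$procedure[[ty]]
    extras <- c("cytologist_in_fixed", "fixed_rate_override",
                "rose_rate_override")
    check_symbols(setdiff(names(pt), extras), PROCEDURE_SYMBOLS,
                  sprintf("`procedure$%s`", ty))
    if (!all(PROCEDURE_SYMBOLS %in% names(pt)))
      stop(sprintf("`procedure$%s` must define: %s", ty,
                   paste(PROCEDURE_SYMBOLS, collapse = ", ")), call. = FALSE)
    out <- lapply(PROCEDURE_SYMBOLS, function(nm)
      as_param_spec(pt[[nm]], paste0(ty, "$", nm)))
    names(out) <- PROCEDURE_SYMBOLS
    out$cytologist_in_fixed <- isTRUE(pt$cytologist_in_fixed)
    out$fixed_rate_override <-
      if (is.null(pt$fixed_rate_override)) NULL else as.numeric(pt$fixed_rate_override)
    out$rose_rate_override <-
      if (is.null(pt$rose_rate_override)) NULL else as.numeric(pt$rose_rate_override)
    out
  })

  st <- raw$stopping
  if (is.null(st$n_fixed) || is.null(st$n_rose))
    stop("`stopping` must define `n_fixed` and `n_rose` value sets",
         call. = FALSE)
  stopping <- list(n_fixed = as.integer(st$n_fixed),
                   n_rose = as.integer(st$n_rose))
  if (any(stopping$n_fixed < 1) || any(stopping$n_rose < 1))
    stop("stopping rules must be integers >= 1", call. = FALSE)

  structure(
    list(name = if (is.null(raw$name)) "unnamed" else raw$name,
         description = raw$description,
         shared = shared, adequacy = adequacy, procedure = procedure,
         stopping = stopping),
    class = "model_config"
  )
}

apply_overrides <- function(cfg, overrides) {
  if (!is.list(overrides) || is.null(names(overrides)) ||
      any(!nzchar(names(overrides))))
    stop("`overrides` must be a named list", call. = FALSE)
  check_symbols(names(overrides), MODEL_SYMBOLS, "`overrides`")
  for (nm in names(overrides)) {
    val <- as.numeric(overrides[[nm]])
    if (nm %in% names(cfg$shared)) {
      cfg$shared[[nm]]$base <- val
      cfg$shared[[nm]]$low <- min(cfg$shared[[nm]]$low, val)
      cfg$shared[[nm]]$high <- max(cfg$shared[[nm]]$high, val)
    } else if (nm == "p") {
      for (lv in c("low", "high")) {
        cfg$adequacy[[lv]]$base <- val
        cfg$adequacy[[lv]]$low <- min(cfg$adequacy[[lv]]$low, val)
        cfg$adequacy[[lv]]$high <- max(cfg$adequacy[[lv]]$high, val)
      }
    } else if (nm %in% PROCEDURE_SYMBOLS) {
      for (ty in c("simple", "complex")) {
        cfg$procedure[[ty]][[nm]]$base <- val
        cfg$procedure[[ty]][[nm]]$low <- min(cfg$procedure[[ty]][[nm]]$low, val)
        cfg$procedure[[ty]][[nm]]$high <- max(cfg$procedure[[ty]][[nm]]$high, val)
      }
    } else if (nm %in% c("n_fixed", "n_rose")) {
      cfg$stopping[[nm]] <- as.integer(val)
    }
  }
  cfg$overrides <- overrides
  cfg
}

#' Write a model configuration back to YAML
#'
#' The written file round-trips: [load_model_config()] on the result
#' reproduces every value.
#'
#' @param cfg A `model_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  out <- list(
    name = cfg$name, description = cfg$description,
    shared = cfg$shared,
    adequacy = list(low = list(p = cfg$adequacy$low),
                    high = list(p = cfg$adequacy$high)),
    procedure = lapply(cfg$procedure, function(pt) {
      keep <- pt[PROCEDURE_SYMBOLS]
      keep$cytologist_in_fixed <- pt$cytologist_in_fixed
      if (!is.null(pt$fixed_rate_override))
        keep$fixed_rate_override <- pt$fixed_rate_override
      if (!is.null(pt$rose_rate_override))
        keep$rose_rate_override <- pt$rose_rate_override
      keep
    }),
    stopping = cfg$stopping
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Model configuration '%s'\n", x$name))
  cat(sprintf("  sn %.3f, sp %.3f; p low %.2f / high %.2f\n",
              x$shared$sn$base, x$shared$sp$base,
              x$adequacy$low$base, x$adequacy$high$base))
  cat(sprintf("  stopping rules: n_fixed in {%s}, n_rose in {%s}\n",
              paste(x$stopping$n_fixed, collapse = ", "),
              paste(x$stopping$n_rose, collapse = ", ")))
  invisible(x)
}
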
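# Internal helpers: classed conditions and seeded evaluation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers (and the CLI) can dispatch on failure kind:
#   scbli_config_error, scbli_format_error, scbli_parse_error,
#   scbli_validation_error, scbli_coverage_error, scbli_alignment_error,
#   scbli_domain_error, scbli_model_error, scbli_data_error,
#   scbli_guess_error, scbli_dof_error, scbli_convergence_error,
#   scbli_uncertainty_error
scbli_error <- function(msg, class, ...) {
  stop(structure(
    class = c(paste0("scbli_", class, "_error"), "scbli_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

scbli_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("scbli_", class, "_warning"), "scbli_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0)
    scbli_error(sprintf("'%s' must be a finite positive number", name),
                "validation")
}
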
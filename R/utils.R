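#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can react to specific failures
# without parsing messages.
oct_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "octspeckle_error"),
                      call = call))
}

oct_warn <- function(message, class = "octspeckle_warning") {
  warning(warningCondition(message, class = c(class, "octspeckle_warning")))
}

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so library calls never disturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != trunc(x))
    oct_error(sprintf("`%s` must be a single integer >= %d", name, min),
              "octspeckle_domain_error")
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    oct_error(sprintf("`%s` must be a single finite positive number", name),
              "octspeckle_domain_error")
  as.numeric(x)
}
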
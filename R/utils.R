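#' @keywords internal
"_PACKAGE"

## Seed hygiene: every stochastic entry point takes an explicit seed and
## restores the caller's RNG state on exit, so seeded calls are pure
## functions of their arguments.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("structnet_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("structnet_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("structnet_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("structnet_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

## Order by decreasing magnitude, ties broken by ascending flat index.
## Shared by sparsification, pruning and the human-connectome threshold so
## every selection in the package is deterministic given its input.
order_by_magnitude <- function(x) {
  order(-abs(x), seq_along(x))
}
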
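# Internal helpers: classed error conditions (so the CLI can map condition
# class -> exit code) and a local-seed guard that never leaks RNG state.

ccpop_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ccpop_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

config_error <- function(message) ccpop_error("ccpop_config_error", message)
data_error <- function(message) ccpop_error("ccpop_data_error", message)
bracket_error <- function(message) ccpop_error("ccpop_bracket_error", message)
state_error <- function(message) ccpop_error("ccpop_state_error", message)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    config_error("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L) {
    config_error(sprintf("%s must be a single number", name))
  }
  if (finite && !is.finite(x)) {
    config_error(sprintf("%s must be finite", name))
  }
  if (positive && !(x > 0)) {
    config_error(sprintf("%s must be > 0", name))
  }
  invisible(x)
}
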
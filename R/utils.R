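# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# global RNG state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("period3_format_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("period3_input_error", "error")))
}

stop_bounds <- function(...) {
  stop(errorCondition(paste0(...), class = c("period3_bounds_error", "period3_input_error", "error")))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
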
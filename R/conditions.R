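# Classed conditions used across the package. Every error raised by
# canopydyn carries a subclass so callers (and the pipeline driver) can
# distinguish e.g. an empty container from a malformed layout.

cd_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("canopydyn_", class), "canopydyn_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

stop_invalid_input <- function(msg) cd_stop(msg, "invalid_input")
stop_invalid_layout <- function(msg) cd_stop(msg, "invalid_layout")
stop_no_plant <- function(msg) cd_stop(msg, "no_plant")
stop_no_separation <- function(msg) cd_stop(msg, "no_separation")
stop_insufficient_data <- function(msg) cd_stop(msg, "insufficient_data")
stop_degenerate_trace <- function(msg) cd_stop(msg, "degenerate_trace")
stop_invalid_trace <- function(msg) cd_stop(msg, "invalid_trace")
stop_invalid_spec <- function(msg) cd_stop(msg, "invalid_spec")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the expression uses (and
# advances) the global stream, so generators stay usable inside larger
# seeded simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid_input("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
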
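# internal helpers shared across modules

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# strictly increasing check with informative failure
check_increasing <- function(x, name) {
  if (any(diff(x) <= 0))
    stop(sprintf("`%s` must be strictly increasing", name), call. = FALSE)
  invisible(x)
}
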
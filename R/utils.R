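# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

max_norm <- function(x, y = 0) max(abs(x - y))

is_named_numeric <- function(x) {
  is.numeric(x) && !is.null(names(x)) && all(nzchar(names(x))) &&
    !anyDuplicated(names(x))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never disturbs user-level reproducibility.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stop_config <- function(..., call. = FALSE) {
  stop(paste0(...), call. = call.)
}
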
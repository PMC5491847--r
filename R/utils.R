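# Run an expression under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seeds below 2^31, derived from a master seed and
# a stream label (e.g. subject/task/loading/repetition), via a small
# multiplicative hash.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(p) else as.numeric(p)
  })))
  # multiplier kept small so h * 8191 + p stays below 2^53 (exact doubles)
  h <- 0
  for (p in parts) h <- (h * 8191 + p + 1) %% 2147483629
  as.integer(h)
}
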
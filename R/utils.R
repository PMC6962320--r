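# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
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

# Mirror-reflect 1-based indices into 1..n (edge voxels not repeated).
reflect_index <- function(v, n) {
  if (n == 1L) return(rep(1L, length(v)))
  period <- 2L * (n - 1L)
  t <- (v - 1L) %% period
  t <- ifelse(t > n - 1L, period - t, t)
  as.integer(t + 1L)
}

stop_lungtex <- function(msg, class) {
  stop(structure(class = c(class, "lungtex_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
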
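# internal helpers shared across modules

# run `expr` under a locally-set RNG seed when `seed` is not NULL,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-item substream seeds below 2^31, so adding items
# never perturbs earlier items
derive_seed <- function(seed, i, stream = 0L) {
  (as.double(seed) * 48271 + as.double(i) * 7919 + as.double(stream) * 104729) %%
    2147483647 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
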
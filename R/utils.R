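# small internal helpers shared across modules

# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-stream seeds (kept under 2^31): one global seed fans out
# to independent per-stage / per-item streams
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + as.double(k) * 104729 + 11) %%
               2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x > 0
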
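# run expr under a deterministic RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# deterministic per-iteration seed derived from a run seed (kept < 2^31)
.iter_seed <- function(seed, iteration) {
  as.integer((as.double(seed) * 7919 + as.double(iteration) * 104729) %%
             2147483647)
}
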
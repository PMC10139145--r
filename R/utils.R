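## Run code under a given RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic child-seed mix: stable across platforms, stays < 2^31 - 1.
## (1000003 * 2^31 < 2^53, so the products are exact in doubles.)
.childSeed <- function(seed, i) {
  s <- (1000003 * (as.numeric(seed) %% 2147483647) + 7919 * as.numeric(i)) %%
    2147483647
  as.integer(s + 1)
}
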
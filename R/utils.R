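# evaluate expr under a temporary RNG seed, restoring the caller's
# random stream afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) saved <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% (2^31 - 1)))
  on.exit({
    if (has_seed) assign(".Random.seed", saved, envir = globalenv())
  })
  expr
}
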
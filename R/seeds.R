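# One root seed fanned out into named substreams, so pipeline stages can be
# re-run independently yet reproducibly.

.subseed <- function(seed, name) {
  b <- utf8ToInt(name)
  h <- sum(b * seq_along(b))
  as.integer(((abs(as.integer(seed)) %% 65536L) * 32003 + h * 97) %%
               2147483647)
}

# Evaluate `expr` under the RNG substream (seed, name), restoring the
# caller's RNG state afterwards.
.withSubstream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(.subseed(seed, name))
  expr
}
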
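# Deterministic per-cell RNG substreams. A single user seed plus a cell
# key string is hashed to a 31-bit seed, so adding or removing design
# cells never perturbs the draws of the cells that remain. Arithmetic
# stays below 2^53, so the hash is exact in doubles on every platform.

.SUBSTREAM_MOD <- 2147480009 # prime < 2^31

.substream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% .SUBSTREAM_MOD
  as.integer((h + (as.numeric(seed) %% .SUBSTREAM_MOD) * 69069) %% .SUBSTREAM_MOD)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG
# state afterwards so library code never clobbers a user's stream.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  expr
}
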
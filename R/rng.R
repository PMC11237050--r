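# Deterministic seed streams.
#
# Each simulated subject gets its own named stream derived from the master
# seed, so a subject's data is reproducible independently of cohort order.
# The derivation is a 32-bit FNV-1a hash of "<seed>/<key>", folded into
# [1, 2^31 - 2] so it is always a valid R integer seed.

fnv1a32 <- function(text) {
  bytes <- utf8ToInt(text)
  h <- 2166136261
  for (b in bytes) {
    # xor the low byte (values stay exact in double arithmetic)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619; split the multiply
    # so intermediates stay below 2^53
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

derive_seed <- function(seed, key) {
  h <- fnv1a32(paste0(format(seed), "/", key))
  as.integer(h %% 2147483645) + 1L
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
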
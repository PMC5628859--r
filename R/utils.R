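# Internal helpers: reproducible RNG scoping and seed derivation.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit string hash (polynomial rolling hash in double precision;
# 131 * 2^31 < 2^53 so no precision loss).
str_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  h
}

# Derive a per-(id, index) substream seed from a base seed, kept below 2^31.
# All arithmetic in double; intermediate values stay below 2^53.
derive_seed <- function(seed, id, index = 0L) {
  h <- ((seed %% 2147483647) * 7919) %% 2147483647
  h <- (h + str_hash(id) * 31 + as.numeric(index)) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
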
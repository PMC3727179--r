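# Internal helpers: seeding, deterministic ordering, light hashing.

# Counter-based derivation of per-stage / per-run seeds from one master seed.
# Adding later streams never perturbs earlier ones. Result is a valid 32-bit
# R seed in [0, 2^31 - 2].
derive_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1,
            is.numeric(stream), length(stream) == 1)
  m <- as.double(master_seed) %% 2147483647
  s <- as.double(stream) %% 2147483647
  # two rounds of a multiplicative mix, exact in double precision
  x <- (m * 48271 + s + 1) %% 2147483647
  x <- (x * 16807 + 17) %% 2147483647
  as.integer(x)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
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
  code
}

# Locale-independent lexicographic sort (byte order), so tie-breaking by gene
# id is identical on every platform.
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

# Small stable string hash (FNV-style, 31-bit) for config digests in reports.
string_digest <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x01"))
  d <- 0
  for (b in bytes) d <- (d * 131 + b) %% 2147483647
  sprintf("%010d", d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
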
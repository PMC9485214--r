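# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 32-bit FNV-1a hash of a character scalar, kept below 2^31 so
# it is always a valid R integer seed. Used to split one root seed into
# independent per-stratum seeds: adding strata never reshuffles the draws of
# existing ones.
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2147483647)
}

# Derive a child seed from a root seed and a stratum key.
derive_seed <- function(root_seed, key) {
  as.integer((as.numeric(root_seed) + as.numeric(string_hash(key))) %% 2147483647L) + 1L
}

# Trapezoid weights for a (possibly non-uniform) increasing grid.
trapezoid_weights <- function(t) {
  d <- diff(t)
  c(d / 2, 0) + c(0, d / 2)
}

# Age grid of evaluation points covering [lo, hi] with step `step`,
# guaranteeing both endpoints are present.
fine_grid <- function(lo, hi, step) {
  t <- seq(lo, hi, by = step)
  if (t[length(t)] < hi) t <- c(t, hi)
  t
}
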
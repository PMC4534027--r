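# Internal helpers shared across modules.

MEDIA_LEVELS <- c("none", "rnalater", "rnalater_kan", "rnalater_cipro")
MAJOR_PHYLA <- c("Actinobacteria", "Bacteroidetes", "Firmicutes", "Proteobacteria")

# Fold an arbitrary sequence of non-negative integers into a single seed in
# [0, 2^31 - 2]. The multiplier is small enough that intermediate products
# stay exactly representable in doubles.
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(h)
}

# Stable integer hash of a string, so per-sample RNG substreams depend on the
# sample id rather than its position in the table.
hash_string <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
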
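## Internal helpers shared across modules.

# Derive an independent substream seed from the master seed and a facet label,
# so adding a generator never perturbs another generator's stream. Stays below
# 2^31 - 1.
facetSeed <- function(seed, facet) {
  off <- sum(utf8ToInt(facet) * seq_along(utf8ToInt(facet)))
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2011 + off) %% 2147483647L
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic largest-remainder apportionment of n items over proportions p.
largestRemainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
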
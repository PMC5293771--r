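## Independently coded brute-force oracles. Each is written as a literal
## restatement of the rule it checks (if-chains, direct sums, exhaustive
## enumeration), deliberately not sharing code with the implementation.

# step-up FDR adjustment, spelled out
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# single-record DE truth table
statusOracle <- function(fdr, log2fc, maxmean, fdr_max = 0.1, min_fold = 2,
                         min_reads = 50) {
  if (fdr >= fdr_max) return("not_de")
  if (maxmean < min_reads) return("not_de")
  if (log2fc >= log2(min_fold)) return("up")
  if (log2fc <= -log2(min_fold)) return("down")
  "not_de"
}

# per-timepoint behavior truth table
tpOracle <- function(focal, other_status, fc, band = 0.4) {
  if (other_status == "not_de") {
    if (fc > -band && fc < band) return("differing")
    return("indeterminate")
  }
  if (other_status == focal) return("coincident")
  "differing"
}

consensusOracle <- function(a, b) {
  if (a == "differing" && b == "differing") return("departing")
  if (a == "coincident" && b == "coincident") return("coincident")
  "ambiguous"
}

# upper-tail hypergeometric probability by explicit enumeration
hyperOracle <- function(k, n, K, N) {
  tot <- 0
  for (j in k:min(n, K)) {
    if (n - j > N - K) next
    tot <- tot + choose(K, j) * choose(N - K, n - j)
  }
  tot / choose(N, n)
}

# global-alignment optimum by bottom-up dynamic programming (score only),
# coded independently of the C++ traceback implementation
nwOracleScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  F <- matrix(0, la + 1, lb + 1)
  F[, 1] <- gap * 0:la
  F[1, ] <- gap * 0:lb
  for (i in seq_len(la))
    for (j in seq_len(lb)) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      F[i + 1, j + 1] <- max(F[i, j] + s, F[i, j + 1] + gap,
                             F[i + 1, j] + gap)
    }
  F[la + 1, lb + 1]
}

# presence-category truth table for the 9-species fixture below, written as a
# literal if-chain over explicit species sets
presenceOracle <- function(present) {
  sp <- names(present)
  mamm <- c("s1", "s2", "s3")
  amn <- c("s1", "s2", "s3", "s4", "s5", "s6")
  tet <- c(amn, "s7")
  fish <- c("s8", "s9")
  absent <- sp[!present]
  if (length(absent) == 0) return("universal")
  if (all(present[amn]) && all(!present[setdiff(sp, amn)]))
    return("amniote_specific")
  if (all(present[tet]) && all(!present[fish]))
    return("tetrapod_innovation_candidate")
  if (setequal(absent, mamm) || setequal(absent, amn) ||
      setequal(absent, tet) || setequal(absent, fish))
    return("clade_absence")
  if (length(absent) == 1) return("single_species_absence")
  "other_scattered"
}

# fixture matching presenceOracle: 9 abstract species, focal kept off-matrix
oracleClades <- function() {
  amn <- c("s1", "s2", "s3", "s4", "s5", "s6")
  list(mammals = c("s1", "s2", "s3"), amniotes = amn,
       tetrapods = c(amn, "s7"), fish = c("s8", "s9"))
}

presenceMatrixFromVectors <- function(pres_mat) {
  status <- ifelse(pres_mat, "present", "absent")
  identity <- ifelse(pres_mat, 90, NA_real_)
  presenceMatrix(status, identity, oracleClades(), focal = "external_focal")
}

# Newman-Girvan modularity as the full double sum over node pairs
modularityOracle <- function(network, partition) {
  nodes <- nodeIds(network)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- edgeTable(network)
  for (r in seq_len(nrow(e))) {
    A[e$node_a[r], e$node_b[r]] <- A[e$node_a[r], e$node_b[r]] + 1
    A[e$node_b[r], e$node_a[r]] <- A[e$node_b[r], e$node_a[r]] + 1
  }
  m <- nrow(e)
  if (m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in nodes)
    for (j in nodes)
      if (partition[i] == partition[j])
        q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  unname(q) / (2 * m)
}

# all set partitions of 1..n as restricted growth strings
allPartitions <- function(n) {
  out <- list()
  rec <- function(assign, kmax) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (g in seq_len(kmax + 1)) rec(c(assign, g), max(kmax, g))
  }
  rec(integer(0), 0)
  out
}

# enumerate all sequences of given lengths over an alphabet
allSeqs <- function(lens, alphabet = c("A", "C")) {
  unlist(lapply(lens, function(l) {
    grid <- do.call(expand.grid, replicate(l, alphabet, simplify = FALSE))
    apply(grid, 1, paste, collapse = "")
  }), use.names = FALSE)
}
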
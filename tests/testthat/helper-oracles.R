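# Independent brute-force oracles. These deliberately re-derive results
# with naive quadratic/linear algorithms and stay independent of the
# package implementation paths they check.

# Affine-gap Smith-Waterman score by naive O(nm) dynamic programming.
# First gap base costs open + ext, each further base ext.
sw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Affine-gap Needleman-Wunsch (end gaps penalized) score oracle.
nw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Sliding-window trimming by direct per-window loop.
trim_oracle <- function(qual, window = 50, minq = 20) {
  L <- length(qual)
  if (L < window) return(if (mean(qual) >= minq) L else 0L)
  for (i in 1:(L - window + 1)) {
    if (mean(qual[i:(i + window - 1)]) < minq) return(i - 1L)
  }
  L
}

# Exhaustive species-vote recount.
vote_oracle <- function(per_gene_hits) {
  species <- unique(unlist(lapply(per_gene_hits, function(h) h$species)))
  counts <- vapply(species, function(sp)
    sum(vapply(per_gene_hits, function(h) sp %in% h$species, TRUE)), 1L)
  setNames(counts, species)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
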
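## Independent reference implementations used to cross-check the
## package; deliberately naive and kept apart from the code they test.

## Full-scan exact matcher: every placement of each read (both
## orientations) found with Biostrings::matchPattern, one read at a
## time.
naiveMapOracle <- function(seqs, genome) {
  rows <- list()
  for (i in seq_along(seqs)) {
    for (rep in names(genome)) {
      for (orient in c("fwd", "rev")) {
        pat <- if (orient == "fwd") seqs[[i]] else
          Biostrings::reverseComplement(seqs[[i]])
        m <- Biostrings::matchPattern(pat, genome[[rep]])
        if (length(m))
          rows[[length(rows) + 1L]] <- data.frame(
            read = i, replicon = rep, start = Biostrings::start(m))
      }
    }
  }
  if (!length(rows))
    return(data.frame(read = integer(), replicon = character(),
                      start = integer()))
  unique(do.call(rbind, rows))
}

## Benjamini-Hochberg step-up computed directly from the definition:
## sort, scale p_(i) by n/i, enforce monotonicity from the largest
## down, cap at 1, return in the original order.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Upper-tail hypergeometric probability as a direct sum of binomial
## coefficients, P(X >= m) for X ~ Hypergeom(N, M, n).
hyperOracle <- function(N, M, n, m) {
  if (m == 0) return(1)
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

## Correspondence analysis recomputed from scratch: standardized
## residuals, SVD, principal coordinates.
caOracle <- function(mat) {
  P <- mat / sum(mat)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  list(row = diag(1 / sqrt(r)) %*% sv$u %*% diag(sv$d, length(sv$d)),
       col = diag(1 / sqrt(cc)) %*% sv$v %*% diag(sv$d, length(sv$d)),
       inertia = sv$d^2)
}

## Tiny CoverageTrack from plain numeric vectors.
makeTrack <- function(depths, sampleId = "s", normalized = TRUE) {
  CoverageTrack(depths, sampleId = sampleId, normalized = normalized)
}
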
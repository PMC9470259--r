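# Independent oracles used across the suite. These re-derive expected
# behaviour from first principles (bit arithmetic on doubles, brute-force
# scans) and never call the implementation paths they check.

# bit matrix (n x 32, LSB first) of 32-bit words stored as doubles
bit_matrix <- function(w) {
  sapply(0:31, function(k) (w %/% 2^k) %% 2)
}

words_from_bits <- function(B) as.numeric(B %*% 2^(0:31))

rand_words <- function(n) floor(runif(n) * 2^32)

# truth-table oracle: which of the nine operations does o represent on (a, b)?
oracle_ops_matrix <- function(o, a, b) {
  O <- bit_matrix(o); A <- bit_matrix(a); B <- bit_matrix(b)
  eq <- function(X) rowSums(O != X) == 0
  cbind(
    NOT   = eq(1 - A) | eq(1 - B),
    NAND  = eq(1 - A * B),
    AND   = eq(A * B),
    OR_N  = eq(pmax(A, 1 - B)) | eq(pmax(B, 1 - A)),
    OR    = eq(pmax(A, B)),
    AND_N = eq(A * (1 - B)) | eq(B * (1 - A)),
    NOR   = eq(1 - pmax(A, B)),
    XOR   = eq((A + B) %% 2),
    EQU   = eq(1 - (A + B) %% 2)
  )
}

# brute-force tandem-repeat scan: same rule as the detector (leftmost start,
# largest full-period coverage, smallest period on ties, non-overlapping),
# derived by direct block comparison
oracle_runs <- function(x) {
  n <- length(x)
  out <- data.frame(start = integer(0), period = integer(0),
                    count = integer(0))
  s <- 1
  while (s <= n) {
    bestlen <- 0; bestp <- 0; bestk <- 0
    maxp <- (n - s + 1) %/% 2
    p <- 1
    while (p <= maxp) {
      k <- 1
      while (s + (k + 1) * p - 1 <= n &&
             all(x[s:(s + p - 1)] ==
                 x[(s + k * p):(s + k * p + p - 1)]))
        k <- k + 1
      if (k >= 2 && k * p > bestlen) {
        bestlen <- k * p; bestp <- p; bestk <- k
      }
      p <- p + 1
    }
    if (bestlen > 0) {
      out <- rbind(out, data.frame(start = s - 1L, period = bestp,
                                   count = bestk))
      s <- s + bestlen
    } else {
      s <- s + 1
    }
  }
  out
}

# small deterministic environment/limits used by many tests
test_envs <- function(n = 20, seed = 42) environment_set(n, seed)
ref_env <- function(seed = 42) env_spec(0, seed)
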
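# independent oracles used across the suite: explicit restricted-DFT
# matrices, brute-force coherence, random complex data

# explicit restricted DFT matrix F~ (m x n): row t in schedule, column k,
# entry exp(+2i*pi*k*t/n)/sqrt(n) — the matrix the package only ever
# represents implicitly via FFTs
explicit_Ft <- function(sched) {
  n <- sched$n
  exp(2i * pi * outer(sched$indices, 0:(n - 1L)) / n) / sqrt(n)
}

# brute-force coherence from the explicit matrix with unit-normalized columns
oracle_mu <- function(sched) {
  A <- explicit_Ft(sched)
  A <- sweep(A, 2, sqrt(colSums(Mod(A)^2)), "/")
  G <- Mod(Conj(t(A)) %*% A)
  diag(G) <- 0
  max(G)
}

# brute-force s-column coherence: per-row sum of the s largest off-diagonal
# Gram magnitudes, maximized over rows
oracle_mu_s <- function(sched, s) {
  A <- explicit_Ft(sched)
  A <- sweep(A, 2, sqrt(colSums(Mod(A)^2)), "/")
  G <- Mod(Conj(t(A)) %*% A)
  diag(G) <- 0
  max(apply(G, 1, function(r) sum(sort(r, decreasing = TRUE)[seq_len(s)])))
}

# exhaustive subset form of mu_s (tiny n only): max over i and all subsets
# S of [n]\{i} with |S| <= s of sum_{j in S} |<f_i, f_j>|
oracle_mu_s_subsets <- function(sched, s) {
  A <- explicit_Ft(sched)
  A <- sweep(A, 2, sqrt(colSums(Mod(A)^2)), "/")
  G <- Mod(Conj(t(A)) %*% A)
  n <- ncol(G)
  best <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    for (k in seq_len(s)) {
      for (S in utils::combn(others, k, simplify = FALSE)) {
        best <- max(best, sum(G[i, S]))
      }
    }
  }
  best
}

rcplx <- function(k) complex(real = stats::rnorm(k), imaginary = stats::rnorm(k))

l2_vec <- function(v) sqrt(sum(Mod(v)^2))

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))

# peak magnitude within +/- w bins of bin b (zero-based)
peak_window <- function(values, b, w = 4L) {
  max(Mod(values[(b - w):(b + w) + 1L]))
}
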
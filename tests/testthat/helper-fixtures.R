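# Shared fixtures and independent oracles used across the test files.

# Four-block chain with bound-dominant populations of the magnitude seen in
# galectin-3/LacNAc macrostate tables: U 35.27%, I1 0.37%, I2 0.44%, B 63.92%.
table_like_spec <- function(n_micro = 20, intra = 0.2, inter = 2e-4,
                            seed = 1L) {
  planted_chain_spec(
    n_micro,
    rep(c("U", "I1", "I2", "B"), each = n_micro / 4),
    c(U = 0.3527, I1 = 0.0037, I2 = 0.0044, B = 0.6392),
    intra_rate = intra, inter_rate = inter, seed = seed)
}

# Small irreducible reversible 3-state chain with known transition matrix.
three_state_chain <- function() {
  spec <- planted_chain_spec(3, c("a", "b", "c"),
                             c(a = 0.2, b = 0.3, c = 0.5),
                             intra_rate = 0.5, inter_rate = 0.15, seed = 1)
  build_reversible_chain(spec)
}

# Birth-death chain helpers: closed-form committor and MFPT oracles.
# p[i] = P(i -> i+1), q[i] = P(i -> i-1) for i = 1..n (boundary entries 0).
birth_death_T <- function(p, q) {
  n <- length(p)
  tm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) tm[i, i + 1] <- p[i]
    if (i > 1) tm[i, i - 1] <- q[i]
  }
  diag(tm) <- 1 - rowSums(tm)
  tm
}

# Committor q+(i) from state 1 (source) to state n (sink) for a birth-death
# chain: q+(i) = sum_{k<i} prod_{j<=k}(q_j/p_j) / sum_{k<n} prod(...)
bd_committor <- function(p, q) {
  n <- length(p)
  rho <- c(1, cumprod(q[2:(n - 1)] / p[2:(n - 1)]))
  qq <- c(0, cumsum(rho)[1:(n - 1)]) / sum(rho)
  qq
}

# MFPT from state 1 to state n via the standard step-time recursion:
# E_k (time from k to k+1) = 1/p_k + (q_k/p_k) E_{k-1}; MFPT = sum E_k.
bd_mfpt_1_to_n <- function(p, q) {
  n <- length(p)
  e <- numeric(n - 1)
  e[1] <- 1 / p[1]
  if (n > 2)
    for (k in 2:(n - 1)) e[k] <- 1 / p[k] + (q[k] / p[k]) * e[k - 1]
  sum(e)
}

# Seeded random point on the probability simplex (bounded away from 0).
runif_simplex <- function(seed, k) {
  set.seed(seed)
  x <- rexp(k) + 0.2
  x / sum(x)
}

# Stationary distribution by eigendecomposition (independent of the
# package's detailed-balance construction path).
stationary_eigen <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}
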
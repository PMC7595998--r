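# Shared fixtures, built in code.

# Flat-Dirichlet point on the simplex.
random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Canonical worked parameter set: beta = 2, gamma + r = 1, k = 1 -> R0 = 2,
# S* = T* = 0.5, I* = D* = 0.25, mu = 1, Theta = 1/7, xi = 1.75.
params2 <- function(N = 2) epi_params(beta = 2, gamma = 0.5, r = 0.5, N = N)

eq2 <- function(N = 2) neutral_equilibrium(params2(N), k = 1)

# Random full_state on the simplex (not necessarily near equilibrium).
random_full_state <- function(N, infected = 0.6) {
  I <- stats::runif(N)
  Icc <- matrix(stats::runif(N * N), N, N)
  tot <- sum(I) + sum(Icc)
  I <- I / tot * infected
  Icc <- Icc / tot * infected
  full_state(S = 1 - infected, I = I, Icc = Icc)
}

# Independent brute-force replicator RHS straight from the component-sum
# definition (loops, explicit exclusions), used as an oracle.
replicator_rhs_bruteforce <- function(z, Lambda, Theta = 1) {
  N <- length(z)
  Q <- 0
  for (j in seq_len(N)) for (kk in seq_len(N)) if (kk != j)
    Q <- Q + Lambda[j, kk] * z[j] * z[kk]
  dz <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(N)) if (j != i) s <- s + Lambda[i, j] * z[j]
    dz[i] <- Theta * z[i] * (s - Q)
  }
  dz
}

# Entrywise invasion fitness from the scalar definition (oracle for the
# vectorized constructor).
lambda_entry <- function(A, mu, i, j) {
  A[j, i] - A[j, j] + mu * (A[j, i] - A[i, j])
}
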
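test_that("invasion fitness matches the entrywise definition", {
  # hand evaluation at mu = 1, alpha_12 = 1, all else 0
  A <- matrix(c(0, 0, 1, 0), 2, 2)  # A[1,2] = 1
  L <- invasion_fitness_matrix(A, mu = 1)
  expect_equal(L[2, 1], 2)   # invader 2 into resident 1
  expect_equal(L[1, 2], -1)  # invader 1 into resident 2
  expect_equal(diag(L), c(0, 0))
  # neutral case
  expect_equal(unclass(invasion_fitness_matrix(matrix(0, 3, 3), 1))[, ],
               matrix(0, 3, 3), ignore_attr = TRUE)
  # entrywise oracle on random input
  set.seed(41)
  A <- matrix(rnorm(25), 5, 5)
  mu <- 0.7
  L <- invasion_fitness_matrix(A, mu)
  for (i in 1:5) for (j in 1:5)
    expect_equal(L[i, j], if (i == j) 0 else lambda_entry(A, mu, i, j))
})

test_that("symmetric interactions with neutral diagonal give a symmetric fitness matrix", {
  set.seed(42)
  K <- structured_interaction_matrix(4, "symmetric_special1", k = 1, epsilon = 0.1)
  # decompose about the structural reference (K_ii = k = 1), so alpha_ii = 0
  d <- decompose_interactions(K, reference = 1)
  L <- invasion_fitness_matrix(d$A, mu = 1.3)
  expect_equal(L[, ], t(L[, ]), tolerance = 1e-12)
  # lambda_i^j = alpha_ij in this structure
  off <- !diag(4)
  expect_equal(L[off], d$A[off], tolerance = 1e-10)
})

test_that("the payoff form has the same quadratic form as A and the same RHS", {
  set.seed(43)
  A <- matrix(rnorm(36), 6, 6)
  mu <- 0.4
  M <- payoff_matrix(A, mu)
  expect_equal(payoff_matrix(t(A) + A, mu), t(t(A) + A))  # symmetric A: M = A
  for (rep_i in 1:20) {
    z <- random_simplex(6)
    expect_lt(abs(t(z) %*% M %*% z - t(z) %*% A %*% z), 1e-12)
    # RHS via payoff form equals RHS via invasion-fitness form
    L <- invasion_fitness_matrix(A, mu)
    rhs_M <- z * (as.vector(M %*% z) - as.numeric(t(z) %*% M %*% z))
    expect_equal(rhs_M, replicator_rhs(z, L), tolerance = 1e-12)
  }
})

test_that("replicator RHS: vertices are equilibria and components sum to zero", {
  set.seed(44)
  L <- canonical_lambda(5, "random")
  for (i in 1:5) {
    e_i <- replace(rep(0, 5), i, 1)
    expect_equal(replicator_rhs(e_i, L), rep(0, 5))
  }
  for (rep_i in 1:20) {
    z <- random_simplex(5)
    expect_lt(abs(sum(replicator_rhs(z, L, Theta = 2.3))), 1e-14)
  }
})

test_that("the three slow-dynamics formulations agree on random inputs", {
  set.seed(45)
  for (rep_i in 1:50) {
    N <- sample(2:8, 1)
    A <- matrix(rnorm(N * N), N, N)
    mu <- stats::runif(1, 0.1, 3)
    z <- random_simplex(N)
    Theta <- stats::runif(1, 0.1, 2)
    # direct A/mu/q form
    bracket <- sapply(seq_len(N), function(i)
      sum((mu * (A[, i] - A[i, ]) + A[, i]) * z))
    q <- as.numeric(t(z) %*% A %*% z)
    rhs_A <- Theta * z * (bracket - q)
    # payoff form
    M <- payoff_matrix(A, mu)
    rhs_M <- Theta * z * (as.vector(M %*% z) - as.numeric(t(z) %*% M %*% z))
    # invasion-fitness form (brute-force oracle with explicit exclusions)
    L <- invasion_fitness_matrix(A, mu)
    rhs_L <- replicator_rhs_bruteforce(z, L, Theta)
    expect_equal(rhs_A, rhs_M, tolerance = 1e-12)
    expect_equal(rhs_M, rhs_L, tolerance = 1e-12)
    expect_equal(replicator_rhs(z, L, Theta), rhs_L, tolerance = 1e-12)
  }
})

test_that("zero fitness freezes frequencies; two-strain dynamics find the interior equilibrium", {
  z0 <- c(0.3, 0.2, 0.5)
  tr <- simulate_replicator(z0, matrix(0, 3, 3), taus = seq(0, 50, 5))
  expect_equal(tr$z[nrow(tr$z), ], z0)
  # N = 2, lambda_1^2 = 1, lambda_2^1 = 3: interior equilibrium z1* = 1/4
  L <- matrix(c(0, 3, 1, 0), 2, 2)  # L[1,2] = 1, L[2,1] = 3
  tr <- simulate_replicator(c(0.9, 0.1), L, Theta = 1, taus = seq(0, 200, 1))
  expect_equal(tr$z[nrow(tr$z), 1], 0.25, tolerance = 1e-8)
  # analytic RHS zero there
  expect_equal(replicator_rhs(c(0.25, 0.75), L), c(0, 0))
})

test_that("simplex sum is conserved over long integrations", {
  set.seed(46)
  L <- canonical_lambda(10, "random")
  z0 <- random_simplex(10)
  tr <- simulate_replicator(z0, L, Theta = 1, taus = seq(0, 500, 1))
  # renormalization is drift control only; verify raw conservation by
  # integrating without the output renormalization path being exercised much
  expect_true(all(abs(rowSums(tr$z) - 1) <= 1e-9))
  expect_true(all(tr$z >= -1e-12 & tr$z <= 1 + 1e-12))
})

test_that("mean fitness Q follows its quadratic form", {
  # hand evaluation: N = 2, z = (1/2, 1/2), lambdas 1 and 3
  L <- matrix(c(0, 3, 1, 0), 2, 2)
  expect_equal(mean_fitness(c(0.5, 0.5), L), 1)
  # vertex: Q = 0
  expect_equal(mean_fitness(c(1, 0), L), 0)
  # antisymmetric: Q = 0 for every z
  set.seed(47)
  La <- canonical_lambda(6, "antisymmetric")
  for (rep_i in 1:10) expect_lt(abs(mean_fitness(random_simplex(6), La)), 1e-14)
  # Q = sum_j lambda_bar_j z_j
  z <- random_simplex(6)
  Lr <- canonical_lambda(6, "random")
  expect_equal(mean_fitness(z, Lr), sum(mean_invasion_fitness(z, Lr) * z))
})

test_that("effective interaction coefficient tracks q(z)", {
  expect_equal(effective_interaction(c(0.5, 0.5), k = 1, epsilon = 0,
                                     A = matrix(c(1, -1, -1, 1), 2, 2))$k_effective, 1)
  A <- matrix(c(1, -1, -1, 1), 2, 2)
  ei <- effective_interaction(c(0.5, 0.5), k = 1, epsilon = 0.1, A = A)
  expect_equal(ei$q, 0)
  expect_equal(ei$k_effective, 1)
  # identity Q = q - sum_j alpha_jj z_j with the mu-matched Lambda
  set.seed(48)
  for (rep_i in 1:20) {
    N <- 5
    A <- matrix(rnorm(N * N), N, N)
    mu <- stats::runif(1, 0.2, 2)
    z <- random_simplex(N)
    Q <- mean_fitness(z, invasion_fitness_matrix(A, mu))
    q <- effective_interaction(z, 1, 0.1, A)$q
    expect_equal(Q, q - sum(diag(A) * z), tolerance = 1e-12)
  }
})

test_that("slow and real time convert explicitly", {
  expect_equal(slow_time(10, 0.1), 1)
  expect_equal(real_time(1, 0.1), 10)
  expect_error(slow_time(1, 0))
})
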
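test_that("pairwise outcomes follow the sign pattern of mutual invasion fitness", {
  expect_equal(classify_edge(2, -1)$class, "exclusion_i_wins")
  expect_equal(classify_edge(0.5, 0.5)$class, "coexistence")
  expect_equal(classify_edge(-0.5, -0.1)$class, "bistability")
  expect_equal(classify_edge(-2, 1)$class, "exclusion_j_wins")
  expect_equal(classify_edge(0, 1)$class, "marginal")
  expect_equal(classify_edge(1, 1e-12, tol = 1e-9)$class, "marginal")
})

test_that("edge classification is antisymmetric under argument swap", {
  set.seed(51)
  swap <- c(coexistence = "coexistence", bistability = "bistability",
            exclusion_i_wins = "exclusion_j_wins",
            exclusion_j_wins = "exclusion_i_wins", marginal = "marginal")
  for (rep_i in 1:50) {
    l1 <- stats::runif(1, -1, 1); l2 <- stats::runif(1, -1, 1)
    a <- classify_edge(l1, l2)$class
    b <- classify_edge(l2, l1)$class
    expect_equal(b, unname(swap[a]))
  }
})

test_that("structured interaction matrices map to their canonical fitness class", {
  mapping <- list(
    symmetric_special1 = "symmetric",
    symmetric_special2 = "invader_driven",
    diagonal = "resident_driven",
    colonizer_driven = "antisymmetric",
    cocolonizer_driven = "antisymmetric",
    antisymmetric = "antisymmetric"
  )
  for (s in names(mapping)) {
    K <- structured_interaction_matrix(6, s, k = 1, epsilon = 0.05,
                                       seed = match(s, names(mapping)))
    d <- decompose_interactions(K)
    L <- invasion_fitness_matrix(d$A, mu = 1.2)
    expect_equal(classify_structure(L)$label, mapping[[s]],
                 label = paste("class for structure", s))
  }
  # the general symmetric K gives a Lambda outside all special classes
  K <- structured_interaction_matrix(6, "symmetric_general", k = 1,
                                     epsilon = 0.05, seed = 99)
  d <- decompose_interactions(K)
  L <- invasion_fitness_matrix(d$A, mu = 1.2)
  # mu terms cancel: lambda_i^j = alpha_ji - alpha_jj
  off <- !diag(6)
  expected <- t(d$A) - matrix(diag(d$A), 6, 6, byrow = TRUE)
  expect_equal(L[off], expected[off], tolerance = 1e-12)
})

test_that("entrywise Table-of-structures identities hold for the driven cases", {
  mu <- 0.8
  # colonizer-driven: lambda_i^j = mu (alpha_j - alpha_i), alpha_i the row value
  K <- structured_interaction_matrix(5, "colonizer_driven", k = 1,
                                     epsilon = 0.05, seed = 2)
  d <- decompose_interactions(K)
  a <- d$A[, 1]  # rows of A are constant
  L <- invasion_fitness_matrix(d$A, mu)
  expect_equal(unclass_mat <- L[, ], mu * outer(-a, a, `+`) , tolerance = 1e-10,
               ignore_attr = TRUE)
  # cocolonizer-driven: lambda_i^j = (mu + 1)(alpha_i - alpha_j)
  K <- structured_interaction_matrix(5, "cocolonizer_driven", k = 1,
                                     epsilon = 0.05, seed = 3)
  d <- decompose_interactions(K)
  a <- d$A[1, ]  # columns of A are constant
  L <- invasion_fitness_matrix(d$A, mu)
  expect_equal(L[, ], (mu + 1) * outer(a, a, `-`), tolerance = 1e-10,
               ignore_attr = TRUE)
  # antisymmetric K about k: lambda_i^j = (1 + 2 mu) alpha_ji
  K <- structured_interaction_matrix(5, "antisymmetric", k = 1,
                                     epsilon = 0.05, seed = 4)
  d <- decompose_interactions(K)
  L <- invasion_fitness_matrix(d$A, mu)
  expect_equal(L[, ], (1 + 2 * mu) * t(d$A), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the zero matrix is reported as neutral/degenerate", {
  expect_equal(classify_structure(matrix(0, 3, 3))$label, "neutral/degenerate")
})

test_that("canonical generators produce matrices of their own class", {
  for (cl in c("symmetric", "invader_driven", "resident_driven", "antisymmetric")) {
    L <- canonical_lambda(8, cl, seed = 7)
    expect_true(all(abs(L) <= 1))
    expect_equal(diag(L), rep(0, 8))
    expect_equal(classify_structure(L)$label, cl, label = paste("class", cl))
  }
  La <- canonical_lambda(8, "almost_antisymmetric", seed = 8, perturbation = 0.05)
  expect_lt(classify_structure(La)$deviations[["antisymmetric"]], 0.1)
})

test_that("antisymmetric ensembles keep mean fitness at exactly zero", {
  ens <- run_canonical_ensemble("antisymmetric", N = 6, reps = 5, seed = 9,
                                taus = seq(0, 30, 1))
  expect_lt(max(abs(ens$summary$Q)), 1e-9)
})

test_that("symmetric ensembles have non-decreasing mean fitness (Fisher property)", {
  ens <- run_canonical_ensemble("symmetric", N = 6, reps = 5, seed = 10,
                                taus = seq(0, 30, 1))
  worst <- ens$summary |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(min_step = min(diff(Q)))
  expect_true(all(worst$min_step >= -1e-8))
})

test_that("resident-driven ensembles drive mean fitness toward zero with few survivors", {
  ens <- run_canonical_ensemble("resident_driven", N = 6, reps = 5, seed = 11,
                                taus = seq(0, 200, 2))
  fin <- dplyr::filter(ens$summary, tau == max(tau))
  expect_lt(max(abs(fin$Q)), 0.05)
  expect_true(all(fin$n_extant <= 3))
})

test_that("the invasion network enumerates and classifies all unordered pairs", {
  # single coexistence edge
  L <- matrix(c(0, 3, 1, 0), 2, 2)
  net <- invasion_network(L)
  expect_equal(nrow(net), 1L)
  expect_equal(net$outcome, "coexistence")
  expect_equal(net$lambda_ij, 1)
  # all-marginal neutral network
  net0 <- invasion_network(matrix(0, 3, 3))
  expect_equal(net0$outcome, rep("marginal", 3))
  # N = 6 random regime: 15 mixed edges
  K <- random_interaction_matrix(6, k = 1, epsilon = 0.1, seed = 12)
  d <- decompose_interactions(K)
  net6 <- invasion_network(invasion_fitness_matrix(d$A, 1), labels = d$labels)
  expect_equal(nrow(net6), 15L)
  expect_gt(length(unique(net6$outcome)), 1L)
})
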
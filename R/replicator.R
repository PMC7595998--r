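#' Pairwise invasion fitness matrix
#'
#' Entry `(i, j)` is `lambda_i^j`, the rescaled exponential growth rate of a
#' rare invader strain i introduced at the single-resident endemic
#' equilibrium of strain j:
#' `lambda_i^j = alpha_ji - alpha_jj + mu (alpha_ji - alpha_ij)`.
#' The first term is how much the resident facilitates the invader in
#' co-colonization, the second how much the resident facilitates itself, and
#' the `mu`-weighted term the asymmetry of mixed co-colonization, amplified
#' by the single- to co-colonization ratio `mu = I*/D*`. The diagonal is
#' exactly zero. In the degenerate neutral case (`A = 0`) the matrix is zero
#' and strain frequencies are frozen.
#'
#' @param A N x N normalized deviation matrix (or a
#'   `similarity_decomposition`, whose `A` is used).
#' @param mu Single- to co-colonization ratio `I*/D*`, > 0 (or a
#'   `neutral_equilibrium`, whose `mu` is used).
#' @return An N x N matrix of class `invasion_fitness_matrix` with attribute
#'   `mu`; rows index the invader, columns the resident.
#' @examples
#' A <- matrix(c(0, 0, 1, 0), 2, 2)  # alpha_12 = 1
#' invasion_fitness_matrix(A, mu = 1)
#' @export
invasion_fitness_matrix <- function(A, mu) {
  if (inherits(A, "similarity_decomposition")) A <- A$A
  if (inherits(mu, "neutral_equilibrium")) mu <- mu$mu
  stopifnot(is.matrix(A), nrow(A) == ncol(A), is.numeric(mu), mu > 0)
  N <- nrow(A)
  Lambda <- t(A) - matrix(diag(A), N, N, byrow = TRUE) + mu * (t(A) - A)
  diag(Lambda) <- 0
  dimnames(Lambda) <- dimnames(A)
  structure(Lambda, mu = mu, class = c("invasion_fitness_matrix", "matrix", "array"))
}

#' @export
print.invasion_fitness_matrix <- function(x, ...) {
  cat("Pairwise invasion fitness matrix (rows: invader, columns: resident; mu =",
      format(attr(x, "mu")), ")\n")
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(x) {
  attr(x, "mu") <- NULL
  class(x) <- NULL
  x
}

#' @export
tidy.invasion_fitness_matrix <- function(x, ...) {
  N <- nrow(x)
  lab <- rownames(x) %||% paste0("strain_", seq_len(N))
  tibble::tibble(
    invader = rep(lab, times = N),
    resident = rep(lab, each = N),
    lambda = as.vector(unclass_matrix(x))
  )
}

#' Replicator payoff matrix
#'
#' The payoff form of the slow dynamics uses `M = mu (A^T - A) + A^T`, so that
#' `dz_i/dtau = Theta z_i ((M z)_i - z^T M z)`. Because the antisymmetric part
#' contributes nothing to a quadratic form, `z^T M z = z^T A z = q(z)` for
#' every z.
#'
#' @inheritParams invasion_fitness_matrix
#' @return N x N numeric matrix.
#' @export
payoff_matrix <- function(A, mu) {
  if (inherits(A, "similarity_decomposition")) A <- A$A
  if (inherits(mu, "neutral_equilibrium")) mu <- mu$mu
  stopifnot(is.matrix(A), nrow(A) == ncol(A), mu > 0)
  mu * (t(A) - A) + t(A)
}

#' Replicator right-hand side
#'
#' `dz_i/dtau = Theta z_i (sum_{j != i} lambda_i^j z_j -
#' sum sum_{kappa != j} lambda_j^kappa z_j z_kappa)`: each strain grows in
#' proportion to the gap between its frequency-weighted mean invasion fitness
#' and the community mean fitness Q. Components sum to zero, so the simplex
#' is invariant.
#'
#' @param z Simplex vector of strain frequencies.
#' @param Lambda Invasion fitness matrix (diagonal ignored/treated as zero).
#' @param Theta Clock rate of the slow dynamics (default 1, the conventional
#'   arbitrary time scaling).
#' @return Length-N derivative vector.
#' @export
replicator_rhs <- function(z, Lambda, Theta = 1) {
  L <- as.matrix(Lambda)
  diag(L) <- 0
  Lz <- as.vector(L %*% z)
  Theta * z * (Lz - sum(z * Lz))
}

#' Mean invasion fitness of each strain
#'
#' `lambda_bar_j = sum_{kappa != j} lambda_j^kappa z_kappa`: strain j's
#' frequency-weighted invasion success against the current community.
#'
#' @inheritParams replicator_rhs
#' @return Length-N numeric vector.
#' @export
mean_invasion_fitness <- function(z, Lambda) {
  L <- as.matrix(Lambda)
  diag(L) <- 0
  as.vector(L %*% z)
}

#' Community mean fitness Q
#'
#' `Q = z^T Lambda z = sum_j lambda_bar_j z_j`, the mean pairwise
#' invasibility of the system. `Q > 0` means each strain's net growth is
#' suppressed within the group but the community resists outside invasion;
#' `Q < 0` the reverse. Q vanishes identically for antisymmetric Lambda
#' (zero-sum games) and is non-decreasing along trajectories when Lambda is
#' symmetric (the Fisher property).
#'
#' @inheritParams replicator_rhs
#' @return Scalar.
#' @export
mean_fitness <- function(z, Lambda) {
  sum(z * mean_invasion_fitness(z, Lambda))
}

#' Effective mean interaction coefficient
#'
#' The community-weighted mean co-colonization trait is
#' `k_effective = k + epsilon q(z)` with `q(z) = z^T A z`: a negative q
#' signals a drift toward more mutual inhibition among extant strains, a
#' positive q toward more facilitation.
#'
#' @param z Simplex vector of strain frequencies.
#' @param k Reference interaction coefficient.
#' @param epsilon Deviation scale.
#' @param A Normalized deviation matrix.
#' @return A list with `q` and `k_effective`.
#' @export
effective_interaction <- function(z, k, epsilon, A) {
  if (inherits(A, "similarity_decomposition")) {
    if (missing(k)) k <- A$k
    if (missing(epsilon)) epsilon <- A$epsilon
    A <- A$A
  }
  q <- as.numeric(t(z) %*% A %*% z)
  list(q = q, k_effective = k + epsilon * q)
}

#' Integrate the replicator dynamics
#'
#' Solves `dz/dtau = Theta z ((Lambda z)_i - z^T Lambda z)` on the simplex
#' with [deSolve::ode()]. The boundary is absorbing analytically and no
#' extinction floor is applied; to control round-off drift, each output state
#' is renormalized to sum 1 whenever `|sum(z) - 1| > 1e-12`, and the number
#' of renormalizations is recorded in attribute `renormalized`.
#'
#' @param z0 Simplex start (`sum(z0) == 1`, non-negative).
#' @param Lambda Invasion fitness matrix.
#' @param Theta Clock rate; use 1 for conventionally rescaled time, or the
#'   value from [neutral_equilibrium()] for calendar slow time.
#' @param taus Slow-time output grid.
#' @param rtol,atol Solver tolerances.
#' @param method Solver method.
#' @return An object of class `replicator_trajectory`: list with `tau`,
#'   `z` (matrix, rows = times), `Lambda`, `Theta`.
#' @export
simulate_replicator <- function(z0, Lambda, Theta = 1, taus,
                                rtol = 1e-10, atol = 1e-12, method = "lsoda") {
  z0 <- as.numeric(z0)
  if (any(z0 < 0) || abs(sum(z0) - 1) > 1e-9)
    stop("`z0` must be a non-negative vector summing to 1.", call. = FALSE)
  L <- as.matrix(Lambda)
  diag(L) <- 0
  stopifnot(nrow(L) == length(z0))
  deriv <- function(t, z, parms) {
    Lz <- as.vector(L %*% z)
    list(Theta * z * (Lz - sum(z * Lz)))
  }
  sol <- deSolve::ode(y = z0, times = taus, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("Replicator integration failed; see deSolve diagnostics.", call. = FALSE)
  z <- unname(sol[, -1L, drop = FALSE])
  sums <- rowSums(z)
  drift <- abs(sums - 1) > 1e-12
  if (any(drift)) z[drift, ] <- z[drift, , drop = FALSE] / sums[drift]
  structure(
    list(tau = sol[, 1L], z = z, Lambda = L, Theta = Theta),
    renormalized = sum(drift),
    raw_sums = sums,  # solver output sums before drift control
    class = "replicator_trajectory"
  )
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  cat(sprintf("Replicator trajectory: N = %d strains, %d time points (tau in [%g, %g], Theta = %g)\n",
              ncol(x$z), length(x$tau), min(x$tau), max(x$tau), x$Theta))
  invisible(x)
}

#' @export
tidy.replicator_trajectory <- function(x, ...) {
  N <- ncol(x$z)
  tibble::tibble(
    tau = rep(x$tau, times = N),
    strain = rep(seq_len(N), each = length(x$tau)),
    z = as.vector(x$z)
  )
}

#' Mean fitness Q along a replicator trajectory
#'
#' @param traj A `replicator_trajectory`.
#' @return A tibble with columns `tau` and `Q`.
#' @export
trajectory_mean_fitness <- function(traj) {
  Q <- apply(traj$z, 1L, mean_fitness, Lambda = traj$Lambda)
  tibble::tibble(tau = traj$tau, Q = Q)
}

#' Convert between slow and real time
#'
#' The slow timescale is `tau = epsilon * t`. These helpers make the
#' conversion explicit rather than implicit.
#'
#' @param t Real time(s).
#' @param tau Slow time(s).
#' @param epsilon Deviation scale, > 0.
#' @return Numeric vector.
#' @export
slow_time <- function(t, epsilon) {
  stopifnot(epsilon > 0)
  epsilon * t
}

#' @rdname slow_time
#' @export
real_time <- function(tau, epsilon) {
  stopifnot(epsilon > 0)
  tau / epsilon
}
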
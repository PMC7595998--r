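#' Construct a full model state
#'
#' The full system tracks 1 + N + N^2 host compartments: susceptibles `S`,
#' singly colonized fractions `I[i]`, and co-colonized fractions `Icc[i, j]`
#' ordered by acquisition (first strain i, then strain j; same-strain double
#' carriage `Icc[i, i]` is included). Because recruitment equals mortality,
#' the compartments sum to 1 and the dynamics conserve that sum.
#'
#' @param S Susceptible fraction.
#' @param I Length-N vector of single-colonization fractions.
#' @param Icc N x N matrix of co-colonization fractions.
#' @param tol Tolerance on the simplex constraint `S + sum(I) + sum(Icc) == 1`.
#' @return An object of class `full_state`.
#' @export
full_state <- function(S, I, Icc, tol = 1e-8) {
  N <- length(I)
  stopifnot(length(S) == 1L, is.matrix(Icc), nrow(Icc) == N, ncol(Icc) == N)
  if (any(!is.finite(c(S, I, Icc)))) stop("State must be finite.", call. = FALSE)
  if (any(c(S, I, Icc) < -tol)) stop("State components must be non-negative.", call. = FALSE)
  total <- S + sum(I) + sum(Icc)
  if (abs(total - 1) > tol)
    stop(sprintf("State is not on the unit simplex: components sum to %.12g.", total),
         call. = FALSE)
  structure(list(S = S, I = I, Icc = Icc, N = N), class = "full_state")
}

# Internal packed ordering for the integrator, stable across versions:
# [S, I_1..I_N, I_11, I_12, ..., I_1N, I_21, ..., I_NN] (Icc row-major).
pack_state <- function(state) {
  c(state$S, state$I, as.vector(t(state$Icc)))
}

unpack_state <- function(y, N) {
  list(S = y[1L],
       I = y[1L + seq_len(N)],
       Icc = matrix(y[-seq_len(1L + N)], N, N, byrow = TRUE),
       N = N)
}

state_names <- function(N) {
  c("S", paste0("I_", seq_len(N)),
    paste0("I_", rep(seq_len(N), each = N), "_", rep(seq_len(N), times = N)))
}

#' Force of infection of each strain
#'
#' `F_i = beta * (I_i + sum_j (I_ij + I_ji) / 2) = beta * J_i`: co-colonized
#' hosts transmit each carried strain at half the single-host rate.
#'
#' @param state A `full_state` (or list with `I`, `Icc`).
#' @param params An `epi_params`.
#' @return Length-N numeric vector.
#' @export
force_of_infection <- function(state, params) {
  params$beta * (state$I + 0.5 * (rowSums(state$Icc) + colSums(state$Icc)))
}

#' Aggregate a full state
#'
#' Aggregated variables: `J_i = I_i + sum_j (I_ij + I_ji)/2` (fraction of
#' hosts transmitting strain i), total single colonization `I`, total
#' co-colonization `D`, and total colonization `T = I + D = sum(J)`.
#'
#' @param state A `full_state` (or list with `S`, `I`, `Icc`).
#' @return A list of class `aggregated_state` with `J`, `I`, `D`, `T`, `S`.
#' @export
aggregate_state <- function(state) {
  J <- state$I + 0.5 * (rowSums(state$Icc) + colSums(state$Icc))
  I <- sum(state$I)
  D <- sum(state$Icc)
  structure(list(J = J, I = I, D = D, T = I + D, S = state$S),
            class = "aggregated_state")
}

#' Right-hand side of the full compartmental system
#'
#' With `m = gamma + r` and forces of infection `F_j = beta * J_j`:
#' `dS = m (1 - S) - S sum_j F_j`;
#' `dI_i = F_i S - I_i sum_j K_ij F_j - m I_i`;
#' `dI_ij = I_i K_ij F_j - m I_ij`.
#' The derivatives sum to zero whenever the state sums to one, so total host
#' density is conserved.
#'
#' @param state A `full_state`.
#' @param params An `epi_params`.
#' @param K Interaction matrix with `nrow(K) == length(state$I)`.
#' @return A list with components `S`, `I`, `Icc` holding the derivatives.
#' @export
full_rhs <- function(state, params, K) {
  N <- length(state$I)
  if (!is.matrix(K) || nrow(K) != N || ncol(K) != N)
    stop(sprintf("`K` must be %d x %d to match the state.", N, N), call. = FALSE)
  m <- params$m
  Fi <- force_of_infection(state, params)
  dS <- m * (1 - state$S) - state$S * sum(Fi)
  dI <- Fi * state$S - state$I * as.vector(K %*% Fi) - m * state$I
  dIcc <- state$I * K * matrix(Fi, N, N, byrow = TRUE) - m * state$Icc
  list(S = dS, I = dI, Icc = dIcc)
}

#' Initial state on or off the slow manifold
#'
#' Builds a full state from target strain frequencies `z0`. With
#' `mode = "manifold"` hosts are placed at the neutral endemic proportions
#' (`S = S*`, `I_i = I* z0_i`, `I_ij = D* z0_i z0_j`), i.e. on the slow
#' manifold, so the fast transient is already resolved. With
#' `mode = "off_manifold"` the single/double split is deliberately distorted
#' (singles at half, doubles topped up into `S`) to exercise the fast
#' dynamics.
#'
#' @param z0 Simplex vector of target strain frequencies.
#' @param eq A `neutral_equilibrium` (see [neutral_equilibrium()]).
#' @param mode "manifold" or "off_manifold".
#' @return A `full_state`.
#' @export
initial_state <- function(z0, eq, mode = c("manifold", "off_manifold")) {
  mode <- match.arg(mode)
  stopifnot(abs(sum(z0) - 1) < 1e-10, all(z0 >= 0))
  if (mode == "manifold") {
    I <- eq$I_star * z0
    Icc <- eq$D_star * outer(z0, z0)
  } else {
    I <- 0.5 * eq$I_star * z0
    Icc <- eq$D_star * outer(z0, z0)
  }
  S <- 1 - sum(I) - sum(Icc)
  full_state(S = S, I = I, Icc = Icc)
}

#' Integrate the full compartmental system
#'
#' Solves the 1 + N + N^2 system with [deSolve::ode()] (default `lsoda`,
#' rtol 1e-8 / atol 1e-10; the fast transient makes the system mildly stiff).
#' The right-hand side is never clamped; tiny negative undershoots are set to
#' zero only in the returned trajectory and counted in the `clamped`
#' attribute.
#'
#' @param init A `full_state` on the unit simplex.
#' @param params An `epi_params`.
#' @param K Interaction matrix.
#' @param times Numeric vector of output times (starting at the initial time).
#' @param rtol,atol Solver tolerances.
#' @param method Solver method passed to [deSolve::ode()].
#' @return An object of class `full_trajectory`: list with `times`, `states`
#'   (matrix, one row per time, columns in the packed ordering), `N`,
#'   `params`, `K`. Use [tidy()] for a long tibble or
#'   [trajectory_aggregates()] / [trajectory_frequencies()] for summaries.
#' @export
simulate_full <- function(init, params, K, times,
                          rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  if (!inherits(init, "full_state")) stop("`init` must be a `full_state`.", call. = FALSE)
  N <- init$N
  if (!is.matrix(K) || nrow(K) != N || ncol(K) != N)
    stop("`K` dimension does not match the initial state.", call. = FALSE)
  validate_interaction_matrix(K)
  total0 <- init$S + sum(init$I) + sum(init$Icc)
  if (abs(total0 - 1) > 1e-8)
    stop("Initial state must lie on the unit simplex.", call. = FALSE)
  m <- params$m
  beta <- params$beta
  deriv <- function(t, y, parms) {
    S <- y[1L]
    I <- y[1L + seq_len(N)]
    Icc <- matrix(y[-seq_len(1L + N)], N, N, byrow = TRUE)
    Fi <- beta * (I + 0.5 * (rowSums(Icc) + colSums(Icc)))
    dS <- m * (1 - S) - S * sum(Fi)
    dI <- Fi * S - I * as.vector(K %*% Fi) - m * I
    dIcc <- I * K * matrix(Fi, N, N, byrow = TRUE) - m * Icc
    list(c(dS, dI, as.vector(t(dIcc))))
  }
  sol <- deSolve::ode(y = pack_state(init), times = times, func = deriv,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE solver failed; see deSolve diagnostics above.", call. = FALSE)
  states <- unname(sol[, -1L, drop = FALSE])
  n_clamped <- sum(states < 0)
  if (n_clamped > 0) states[states < 0] <- 0
  structure(
    list(times = sol[, 1L], states = states, N = N, params = params, K = K),
    clamped = n_clamped,
    class = "full_trajectory"
  )
}

#' @export
print.full_trajectory <- function(x, ...) {
  cat(sprintf("Full-system trajectory: N = %d strains, %d compartments, %d time points (t in [%g, %g])\n",
              x$N, 1 + x$N + x$N^2, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
tidy.full_trajectory <- function(x, ...) {
  nm <- state_names(x$N)
  tibble::tibble(
    time = rep(x$times, times = length(nm)),
    compartment = rep(nm, each = length(x$times)),
    value = as.vector(x$states)
  )
}

# Extract the state at row index idx as a plain list.
state_at <- function(traj, idx) {
  unpack_state(traj$states[idx, ], traj$N)
}

#' Aggregated time series of a trajectory
#'
#' @param traj A `full_trajectory`.
#' @return A tibble with columns `time`, `S`, `I`, `D`, `T` and one
#'   `J_i` column per strain.
#' @export
trajectory_aggregates <- function(traj) {
  N <- traj$N
  Ivals <- traj$states[, 1L + seq_len(N), drop = FALSE]
  Icc <- traj$states[, -seq_len(1L + N), drop = FALSE]
  # row-major blocks: column (i-1)*N + j is I_ij
  rowsum_i <- sapply(seq_len(N), function(i) rowSums(Icc[, (i - 1L) * N + seq_len(N), drop = FALSE]))
  colsum_j <- sapply(seq_len(N), function(j) rowSums(Icc[, (seq_len(N) - 1L) * N + j, drop = FALSE]))
  if (length(traj$times) == 1L) {
    rowsum_i <- matrix(rowsum_i, nrow = 1L)
    colsum_j <- matrix(colsum_j, nrow = 1L)
  }
  J <- Ivals + 0.5 * (rowsum_i + colsum_j)
  colnames(J) <- paste0("J_", seq_len(N))
  Itot <- rowSums(Ivals)
  D <- rowSums(Icc)
  out <- tibble::tibble(time = traj$times, S = traj$states[, 1L],
                        I = Itot, D = D, T = Itot + D)
  dplyr::bind_cols(out, tibble::as_tibble(J))
}

#' Strain frequencies along a trajectory
#'
#' Uses the best-conditioned frequency definition `z_i = J_i / T` (the three
#' candidate definitions `J_i/T`, `I_i/I`, `D_i/D` agree after the fast
#' transient).
#'
#' @param traj A `full_trajectory`.
#' @return A tibble with columns `time` and `z_1 ... z_N`.
#' @export
trajectory_frequencies <- function(traj) {
  agg <- trajectory_aggregates(traj)
  J <- as.matrix(agg[, paste0("J_", seq_len(traj$N)), drop = FALSE])
  z <- J / agg$T
  colnames(z) <- paste0("z_", seq_len(traj$N))
  dplyr::bind_cols(tibble::tibble(time = agg$time), tibble::as_tibble(z))
}
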
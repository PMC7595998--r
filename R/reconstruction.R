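#' Reconstruct epidemiological variables from strain frequencies
#'
#' Maps a slow-timescale frequency trajectory back to the full compartmental
#' variables using the conservation laws of the reduction: `S(t) = S*` and
#' `T(t) = T*` are constant, while `I_i(t) = I* z_i(tau)` and
#' `I_ij(t) = D* z_i(tau) z_j(tau)` with `tau = epsilon t`. The reconstructed
#' totals satisfy `sum(I_i) = I*` and `sum(I_ij) = D*` exactly for any
#' simplex z, so the state stays on the unit simplex.
#'
#' @param z_traj A `replicator_trajectory` (or a list with `tau` and a
#'   row-per-time matrix `z`).
#' @param eq A `neutral_equilibrium`.
#' @param epsilon Deviation scale, > 0 (sets the slow-to-real time mapping).
#' @return A `full_trajectory` whose `times` are real times `tau / epsilon`.
#' @export
reconstruct_epidemiology <- function(z_traj, eq, epsilon) {
  stopifnot(inherits(eq, "neutral_equilibrium"), epsilon > 0)
  z <- z_traj$z
  N <- ncol(z)
  nt <- nrow(z)
  states <- matrix(0, nt, 1L + N + N^2)
  states[, 1L] <- eq$S_star
  states[, 1L + seq_len(N)] <- eq$I_star * z
  for (t in seq_len(nt)) {
    zz <- outer(z[t, ], z[t, ])
    states[t, -seq_len(1L + N)] <- eq$D_star * as.vector(t(zz))
  }
  structure(
    list(times = z_traj$tau / epsilon, states = states, N = N,
         params = eq$params, K = recompose_interactions(
           structure(list(k = eq$k, epsilon = 0, A = matrix(0, N, N), N = N,
                          neutral = TRUE, labels = NULL),
                     class = "similarity_decomposition"))),
    class = "full_trajectory"
  )
}

#' Co-colonization pair prevalence product law
#'
#' On the slow manifold, pair prevalence is multiplicative in the single
#' prevalences despite the interactions:
#' `I_ij = k R0 (1 + k (R0 - 1)) I_i I_j`.
#' The prefactor equals `D*/(I*)^2` exactly, so the law is equivalent to
#' `I_ij = D* z_i z_j` given `I_i = I* z_i`. Observed co-occurrence below the
#' independence expectation always indicates mean competition (`k < 1`);
#' co-occurrence above it can reflect either cooperation or competition
#' depending on `R0`.
#'
#' @param I_i,I_j Single-colonization prevalences of the two strains.
#' @param R0 Basic reproduction number, > 1.
#' @param k Reference interaction coefficient, > 0.
#' @return Predicted pair prevalence `I_ij` (vectorized over inputs).
#' @export
cocolonization_product_law <- function(I_i, I_j, R0, k) {
  stopifnot(all(I_i >= 0), all(I_j >= 0), R0 > 1, k > 0)
  product_law_prefactor(R0, k) * I_i * I_j
}

#' @rdname cocolonization_product_law
#' @export
product_law_prefactor <- function(R0, k) {
  stopifnot(R0 > 1, k >= 0)
  k * R0 * (1 + k * (R0 - 1))
}

#' Quasi-neutrality diagnostics of a full-system trajectory
#'
#' The reduction predicts two invariants that hold past the fast transient,
#' independently of the complexity of the slow dynamics: (a) each strain's
#' share of single colonization equals its share of total carriage
#' (`I_i / I == J_i / T`), and (b) pair prevalences follow the product law
#' `I_ij = k R0 (1 + k (R0 - 1)) I_i I_j`. This function reports both
#' deviations over time as a practical quasi-neutrality test: (a) as
#' `max_i |I_i/I - J_i/T|`; (b) as `max_ij |I_ij - predicted|` relative to
#' the mean pair prevalence `D / N^2`.
#'
#' @param traj A `full_trajectory` (its `params` and `K` supply `R0` and the
#'   reference `k`, taken as `mean(K)` unless overridden).
#' @param k Optional reference interaction coefficient.
#' @param window_start Time from which to report (default `5 / xi`, five
#'   fast e-folding times); earlier points are dropped.
#' @return A tibble with columns `time`, `freq_deviation`,
#'   `product_law_deviation`. Warns if no time point lies past the window.
#' @export
quasi_neutrality_test <- function(traj, k = NULL, window_start = NULL) {
  stopifnot(inherits(traj, "full_trajectory"))
  k <- k %||% mean(traj$K)
  eq <- neutral_equilibrium(traj$params, k)
  window_start <- window_start %||% (min(traj$times) + 5 / eq$xi)
  keep <- traj$times >= window_start
  if (!any(keep)) {
    warning("Trajectory too short: no time points past the fast-transient window; reporting all points.",
            call. = FALSE)
    keep <- rep(TRUE, length(traj$times))
  }
  pref <- product_law_prefactor(traj$params$R0, k)
  N <- traj$N
  idx <- which(keep)
  rows <- purrr::map_dfr(idx, function(ti) {
    st <- state_at(traj, ti)
    ag <- aggregate_state(st)
    dev_freq <- max(abs(st$I / ag$I - ag$J / ag$T))
    predicted <- pref * outer(st$I, st$I)
    dev_prod <- max(abs(st$Icc - predicted)) / (ag$D / N^2)
    tibble::tibble(time = traj$times[ti], freq_deviation = dev_freq,
                   product_law_deviation = dev_prod)
  })
  rows
}

#' Full-versus-reduced approximation error over an epsilon ladder
#'
#' For each deviation scale `epsilon`, builds `K = k + epsilon A`, integrates
#' the full system from a slow-manifold start at `z0`, integrates the reduced
#' pipeline (neutral equilibrium + replicator + reconstruction) from the same
#' `z0`, and reports the sup-norm over output times of the strain-frequency
#' difference (`z_full = J_i / T` against the replicator `z`) and of the
#' compartment difference (singles and doubles against their reconstruction).
#' As `epsilon` decreases the reduction error should shrink; at `epsilon = 0`
#' it is at solver tolerance.
#'
#' @param params An `epi_params` with `R0 > 1`.
#' @param A Normalized deviation matrix (mean 0, Frobenius norm N for the
#'   default decomposition).
#' @param k Reference interaction coefficient.
#' @param z0 Simplex start.
#' @param epsilons Vector of deviation scales (>= 0), e.g. `c(0.2, 0.1, 0.05)`.
#' @param tau_max Slow-time horizon shared by all scales (default 5).
#' @param n_out Number of output points (default 101).
#' @param rtol,atol Full-system solver tolerances.
#' @return A tibble with columns `epsilon`, `freq_error`,
#'   `compartment_error`.
#' @export
approximation_error <- function(params, A, k, z0, epsilons,
                                tau_max = 5, n_out = 101,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "epi_params"), all(epsilons >= 0))
  eq <- neutral_equilibrium(params, k)
  Lambda <- NULL
  purrr::map_dfr(epsilons, function(eps) {
    taus <- seq(0, tau_max, length.out = n_out)
    if (eps > 0) {
      times <- taus / eps
      K <- k + eps * A
    } else {
      times <- seq(0, 100, length.out = n_out)
      K <- matrix(k, nrow(A), ncol(A))
    }
    init <- initial_state(z0, eq, mode = "manifold")
    full <- simulate_full(init, params, K, times, rtol = rtol, atol = atol)
    zf <- as.matrix(trajectory_frequencies(full)[, -1L])
    if (eps > 0) {
      red <- simulate_replicator(z0, invasion_fitness_matrix(A, eq$mu),
                                 Theta = eq$Theta, taus = taus)
      zr <- red$z
    } else {
      zr <- matrix(z0, length(times), length(z0), byrow = TRUE)
    }
    freq_error <- max(abs(zf - zr))
    # compartment error: singles and doubles vs reconstruction
    N <- length(z0)
    comp_err <- 0
    for (ti in seq_along(times)) {
      st <- state_at(full, ti)
      comp_err <- max(comp_err,
                      max(abs(st$I - eq$I_star * zr[ti, ])),
                      max(abs(st$Icc - eq$D_star * outer(zr[ti, ], zr[ti, ]))))
    }
    tibble::tibble(epsilon = eps, freq_error = freq_error,
                   compartment_error = comp_err)
  })
}
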
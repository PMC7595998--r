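#' Neutral endemic equilibrium
#'
#' In the neutral model (all interaction coefficients equal to `k`) the
#' aggregated variables reach a closed-form endemic equilibrium when
#' `R0 > 1`:
#' `S* = 1/R0`, `T* = 1 - 1/R0`, `I* = m T* / (m + beta k T*)` (equivalently
#' `(R0 - 1) / (R0 (1 + k (R0 - 1)))`), `D* = T* - I*`. Two derived constants
#' drive the reduced dynamics: `mu = I*/D* = 1/(k (R0 - 1))`, the single- to
#' co-colonization ratio that amplifies interaction asymmetries, and `Theta`,
#' the explicit clock rate of the slow strain-frequency dynamics,
#' `Theta = beta T* I* D* / (2 T*^2 - I* D*)`, equal to
#' `beta (1 - 1/R0) mu / (2 (mu + 1)^2 - mu)`. The fast decay rate
#' `xi = -tr(A0)` of the per-strain linearization is also exposed.
#'
#' @param params An `epi_params` with `R0 > 1`.
#' @param k Reference interaction coefficient, > 0.
#' @return An object of class `neutral_equilibrium`: list with `S_star`,
#'   `T_star`, `I_star`, `D_star`, `mu`, `Theta`, `xi`, plus `params` and `k`.
#' @examples
#' eq <- neutral_equilibrium(epi_params(2, 0.5, 0.5, N = 2), k = 1)
#' eq$Theta  # 1/7
#' @export
neutral_equilibrium <- function(params, k) {
  stopifnot(inherits(params, "epi_params"), is.numeric(k), length(k) == 1L)
  if (k <= 0) stop("`k` must be strictly positive.", call. = FALSE)
  if (params$R0 <= 1)
    stop(sprintf("No endemic equilibrium: R0 = %g <= 1.", params$R0), call. = FALSE)
  beta <- params$beta; m <- params$m; R0 <- params$R0
  S_star <- 1 / R0
  T_star <- 1 - S_star
  I_star <- m * T_star / (m + beta * k * T_star)
  D_star <- T_star - I_star
  mu <- I_star / D_star
  # Two algebraically equivalent forms of Theta, cross-checked:
  Theta <- beta * T_star * I_star * D_star / (2 * T_star^2 - I_star * D_star)
  Theta_mu <- beta * (1 - 1 / R0) * mu / (2 * (mu + 1)^2 - mu)
  stopifnot(abs(Theta - Theta_mu) <= 1e-10 * max(1, abs(Theta)))
  xi <- (m + beta * k * T_star) - beta * k * I_star / 2
  structure(
    list(S_star = S_star, T_star = T_star, I_star = I_star, D_star = D_star,
         mu = mu, Theta = Theta, xi = xi, k = k, params = params),
    class = "neutral_equilibrium"
  )
}

#' @export
print.neutral_equilibrium <- function(x, ...) {
  cat("Neutral endemic equilibrium (R0 =", format(x$params$R0), ", k =", format(x$k), ")\n")
  cat(sprintf("  S* = %.6g, T* = %.6g, I* = %.6g, D* = %.6g\n",
              x$S_star, x$T_star, x$I_star, x$D_star))
  cat(sprintf("  mu = %.6g, Theta = %.6g, xi = %.6g\n", x$mu, x$Theta, x$xi))
  invisible(x)
}

#' @export
glance.neutral_equilibrium <- function(x, ...) {
  tibble::tibble(S_star = x$S_star, T_star = x$T_star, I_star = x$I_star,
                 D_star = x$D_star, mu = x$mu, Theta = x$Theta, xi = x$xi,
                 R0 = x$params$R0, k = x$k)
}

#' Fast linearization of the neutral per-strain subsystem
#'
#' At the neutral equilibrium, once total single colonization has settled at
#' `I*`, each strain's pair `(I_i, J_i)` obeys an uncoupled linear system
#' with matrix
#' `A0 = [[-(m + beta k T*), m], [-beta k T* / 2, beta k I* / 2]]`.
#' `A0` is singular by construction (its kernel is the slow direction,
#' spanned by `(I*, T*)`): its eigenvalues are 0 and `-xi = tr(A0) < 0`, so
#' deviations off the slow manifold decay at rate `xi`.
#'
#' Note on the sign of the (2,1) entry: linearizing the aggregated `J_i`
#' equation at `I = I*` gives `-beta k T* / 2`; a `+` sign there would make
#' the determinant nonzero and destroy the zero eigenvalue, contradicting the
#' conserved strain frequencies of the neutral model.
#'
#' @param params An `epi_params` with `R0 > 1`.
#' @param k Reference interaction coefficient, > 0.
#' @return An object of class `neutral_fast_matrix`: list with the 2x2
#'   matrix `A0`, `eigenvalues` (decreasing), `slow_vector` (kernel,
#'   proportional to `(I*, T*)`), and `xi`.
#' @export
neutral_fast_matrix <- function(params, k) {
  eq <- neutral_equilibrium(params, k)
  beta <- params$beta; m <- params$m
  A0 <- matrix(c(-(m + beta * k * eq$T_star), m,
                 -beta * k * eq$T_star / 2, beta * k * eq$I_star / 2),
               nrow = 2, byrow = TRUE)
  ev <- eigen(A0)
  ord <- order(Re(ev$values), decreasing = TRUE)
  vals <- Re(ev$values[ord])
  slow <- Re(ev$vectors[, ord[1L]])
  slow <- slow / slow[1L] * eq$I_star  # scale kernel vector to (I*, T*)
  structure(
    list(A0 = A0, eigenvalues = vals, slow_vector = slow, xi = eq$xi,
         equilibrium = eq),
    class = "neutral_fast_matrix"
  )
}

#' @export
print.neutral_fast_matrix <- function(x, ...) {
  cat("Neutral fast linearization A0:\n")
  print(x$A0)
  cat(sprintf("  eigenvalues: %.6g, %.6g  (xi = %.6g)\n",
              x$eigenvalues[1L], x$eigenvalues[2L], x$xi))
  invisible(x)
}

#' Fast coordinates: manifold deviation H and strain frequency z
#'
#' The change of variables diagonalizing the neutral fast dynamics maps each
#' strain's `(I_i, J_i)` to `(H_i, z_i)` via the inverse of
#' `[[2 T*, I*], [D*, T*]]`:
#' `H_i = I* T* / (2 T*^2 - D* I*) * (I_i / I* - J_i / T*)` measures how far
#' strain i's share of single colonization deviates from its share of total
#' carriage (it decays to 0 at rate `xi` on the fast timescale), while
#' `z_i` is the conserved strain frequency of the neutral dynamics.
#'
#' @param I Length-N vector of single-colonization fractions `I_i`.
#' @param J Length-N vector of transmitting fractions `J_i`.
#' @param eq A `neutral_equilibrium`.
#' @return A tibble with columns `strain`, `H`, `z`.
#' @export
fast_coordinates <- function(I, J, eq) {
  stopifnot(inherits(eq, "neutral_equilibrium"), length(I) == length(J))
  delta <- 2 * eq$T_star^2 - eq$D_star * eq$I_star
  stopifnot(delta > 0)
  H <- (eq$T_star * I - eq$I_star * J) / delta
  z <- (-eq$D_star * I + 2 * eq$T_star * J) / delta
  tibble::tibble(strain = seq_along(I), H = H, z = z)
}

#' Closed-form single-colonization prevalence of the neutral model
#'
#' In the neutral model, total single colonization relaxes exponentially to
#' its equilibrium: `I(t) = I* + exp(-t (m + beta k T*)) (I(0) - I*)`.
#'
#' @param t Time(s), >= 0.
#' @param I0 Initial total single-colonization prevalence.
#' @param eq A `neutral_equilibrium`.
#' @return Numeric vector of `I(t)` values.
#' @export
neutral_single_prevalence <- function(t, I0, eq) {
  stopifnot(inherits(eq, "neutral_equilibrium"), all(t >= 0))
  p <- eq$params
  rate <- p$m + p$beta * eq$k * eq$T_star
  eq$I_star + exp(-t * rate) * (I0 - eq$I_star)
}
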
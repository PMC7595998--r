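#' @importFrom rlang %||%
NULL

#' Classify a pairwise invasion outcome
#'
#' For two strains with mutual invasion fitnesses `(lambda_ij, lambda_ji)`
#' (invader i into resident j, and vice versa) there are four generic
#' outcomes: both positive, stable coexistence; both negative, bistability
#' (a priority effect: the first established strain excludes the other);
#' one positive, competitive exclusion by the strain that can invade. When
#' either fitness is within `tol` of zero the product-sign classification
#' does not apply and the edge is reported as `"marginal"`.
#'
#' @param lambda_ij Invasion fitness of i into resident j.
#' @param lambda_ji Invasion fitness of j into resident i.
#' @param tol Non-negative tolerance below which a fitness counts as zero.
#' @return A list of class `edge_outcome` with fields `class` (one of
#'   `"coexistence"`, `"bistability"`, `"exclusion_i_wins"`,
#'   `"exclusion_j_wins"`, `"marginal"`), `lambda_ij`, `lambda_ji`.
#' @export
classify_edge <- function(lambda_ij, lambda_ji, tol = 0) {
  stopifnot(tol >= 0, is.finite(lambda_ij), is.finite(lambda_ji))
  cls <- if (abs(lambda_ij) <= tol || abs(lambda_ji) <= tol) {
    "marginal"
  } else if (lambda_ij > 0 && lambda_ji > 0) {
    "coexistence"
  } else if (lambda_ij < 0 && lambda_ji < 0) {
    "bistability"
  } else if (lambda_ij > 0) {
    "exclusion_i_wins"
  } else {
    "exclusion_j_wins"
  }
  structure(list(class = cls, lambda_ij = lambda_ij, lambda_ji = lambda_ji),
            class = "edge_outcome")
}

#' @export
print.edge_outcome <- function(x, ...) {
  cat(sprintf("Pairwise outcome: %s (lambda_i^j = %.4g, lambda_j^i = %.4g)\n",
              x$class, x$lambda_ij, x$lambda_ji))
  invisible(x)
}

frobenius <- function(M) sqrt(sum(M^2))

#' Detect the canonical structure of an invasion fitness matrix
#'
#' Measures the relative deviation (normalized Frobenius norm) of `Lambda`
#' from each canonical class and assigns the first class whose deviation
#' falls below `tol`, testing in order: antisymmetric
#' (`Lambda == -t(Lambda)`), symmetric, invader-driven (off-diagonal entries
#' constant along each row, i.e. all columns equal off the diagonal),
#' resident-driven (constant along each column), then almost-antisymmetric
#' under the looser `almost_tol`, else `"general"`. A zero matrix is both
#' symmetric and antisymmetric and is reported as `"neutral/degenerate"`.
#'
#' @param Lambda Invasion fitness matrix (diagonal treated as zero).
#' @param tol Relative tolerance for the exact classes (default 1e-9).
#' @param almost_tol Looser relative tolerance for the almost-antisymmetric
#'   class (default 0.1).
#' @return A list of class `structure_class` with fields `label` and
#'   `deviations` (named numeric vector of relative deviations).
#' @export
classify_structure <- function(Lambda, tol = 1e-9, almost_tol = 0.1) {
  L <- as.matrix(Lambda)
  diag(L) <- 0
  N <- nrow(L)
  stopifnot(N >= 2)
  nrm <- frobenius(L)
  off <- !diag(N)
  if (nrm == 0) {
    return(structure(list(label = "neutral/degenerate",
                          deviations = c(antisymmetric = 0, symmetric = 0,
                                         invader_driven = 0, resident_driven = 0)),
                     class = "structure_class"))
  }
  # invader-driven: L[i, j] depends only on the invader i off the diagonal
  row_means <- rowSums(L) / (N - 1)
  col_means <- colSums(L) / (N - 1)
  dev_inv <- L - matrix(row_means, N, N)
  dev_res <- L - matrix(col_means, N, N, byrow = TRUE)
  deviations <- c(
    antisymmetric = frobenius(L + t(L)) / (2 * nrm),
    symmetric = frobenius(L - t(L)) / (2 * nrm),
    invader_driven = frobenius(dev_inv[off]) / nrm,
    resident_driven = frobenius(dev_res[off]) / nrm
  )
  label <- if (deviations["antisymmetric"] <= tol) "antisymmetric"
  else if (deviations["symmetric"] <= tol) "symmetric"
  else if (deviations["invader_driven"] <= tol) "invader_driven"
  else if (deviations["resident_driven"] <= tol) "resident_driven"
  else if (deviations["antisymmetric"] <= almost_tol) "almost_antisymmetric"
  else "general"
  structure(list(label = label, deviations = deviations),
            class = "structure_class")
}

#' @export
print.structure_class <- function(x, ...) {
  cat("Invasion structure:", x$label, "\n")
  cat("  relative deviations:\n")
  for (nm in names(x$deviations))
    cat(sprintf("    %-16s %.3g\n", nm, x$deviations[[nm]]))
  invisible(x)
}

#' Draw a random invasion fitness matrix of a canonical class
#'
#' Free entries are uniform on \[-1, 1\] and the diagonal is forced to 0.
#' Classes: `"symmetric"`, `"invader_driven"` (columns equal off-diagonal),
#' `"resident_driven"` (rows equal off-diagonal), `"antisymmetric"`,
#' `"almost_antisymmetric"` (antisymmetric plus a symmetric perturbation of
#' relative scale `perturbation`), `"random"`.
#'
#' @param N Matrix size.
#' @param class Canonical class name.
#' @param seed Optional integer seed.
#' @param perturbation Scale of the symmetric perturbation for
#'   `"almost_antisymmetric"` (default 0.1).
#' @return N x N numeric matrix with zero diagonal.
#' @export
canonical_lambda <- function(N,
                             class = c("symmetric", "invader_driven",
                                       "resident_driven", "antisymmetric",
                                       "almost_antisymmetric", "random"),
                             seed = NULL, perturbation = 0.1) {
  class <- match.arg(class)
  stopifnot(N >= 2)
  L <- with_seed_maybe(seed, {
    up <- upper.tri(matrix(0, N, N))
    u <- function(n) stats::runif(n, -1, 1)
    switch(class,
      symmetric = { M <- matrix(0, N, N); M[up] <- u(sum(up)); M + t(M) },
      invader_driven = matrix(rep(u(N), times = N), N, N),
      resident_driven = matrix(rep(u(N), each = N), N, N),
      antisymmetric = { M <- matrix(0, N, N); M[up] <- u(sum(up)); M - t(M) },
      almost_antisymmetric = {
        M <- matrix(0, N, N); M[up] <- u(sum(up)); anti <- M - t(M)
        P <- matrix(0, N, N); P[up] <- u(sum(up)); sym <- P + t(P)
        anti + perturbation * sym
      },
      random = matrix(u(N * N), N, N)
    )
  })
  diag(L) <- 0
  L
}

#' Simulate an ensemble of replicator runs for a canonical class
#'
#' For each replicate, draws a random invasion fitness matrix of the given
#' class (entries uniform in \[-1, 1\], zero diagonal), a flat-Dirichlet
#' start on the simplex, integrates the replicator dynamics with `Theta = 1`,
#' and records the frequency paths, the mean fitness path `Q(tau)` and the
#' number of extant strains (frequency above `extinction`) over time.
#'
#' @param class Canonical class name (see [canonical_lambda()]).
#' @param N Number of strains (default 10).
#' @param reps Number of replicates (default 30).
#' @param seed Optional integer seed for the whole ensemble.
#' @param taus Slow-time grid (default `seq(0, 100, by = 0.5)`).
#' @param extinction Frequency below which a strain counts as extinct in the
#'   `n_extant` summary (default 1e-3).
#' @return A list of class `canonical_ensemble` with `summary` (tibble:
#'   `replicate`, `tau`, `Q`, `n_extant`), `trajectories` (list of
#'   `replicator_trajectory`), `lambdas` (list of matrices), `class`.
#' @export
run_canonical_ensemble <- function(class, N = 10, reps = 30, seed = NULL,
                                   taus = seq(0, 100, by = 0.5),
                                   extinction = 1e-3) {
  stopifnot(reps >= 1)
  res <- with_seed_maybe(seed, {
    purrr::map(seq_len(reps), function(rep_i) {
      L <- canonical_lambda(N, class)
      z0 <- stats::rexp(N)
      z0 <- z0 / sum(z0)  # flat Dirichlet
      traj <- simulate_replicator(z0, L, Theta = 1, taus = taus)
      Q <- trajectory_mean_fitness(traj)$Q
      n_extant <- rowSums(traj$z > extinction)
      list(L = L, traj = traj,
           summary = tibble::tibble(replicate = rep_i, tau = traj$tau,
                                    Q = Q, n_extant = n_extant))
    })
  })
  structure(
    list(class = class,
         summary = dplyr::bind_rows(purrr::map(res, "summary")),
         trajectories = purrr::map(res, "traj"),
         lambdas = purrr::map(res, "L")),
    class = "canonical_ensemble"
  )
}

#' @export
print.canonical_ensemble <- function(x, ...) {
  nrep <- length(x$trajectories)
  fin <- dplyr::filter(x$summary, .data$tau == max(.data$tau))
  cat(sprintf("Canonical ensemble: class = %s, %d replicates\n", x$class, nrep))
  cat(sprintf("  final Q: mean %.4g (range %.4g to %.4g); mean extant strains %.2f\n",
              mean(fin$Q), min(fin$Q), max(fin$Q), mean(fin$n_extant)))
  invisible(x)
}

#' Pairwise invasion network
#'
#' Classifies every unordered strain pair by its mutual invasion fitness
#' signs (see [classify_edge()]), giving the edge list of the multi-strain
#' invasion network.
#'
#' @param Lambda Invasion fitness matrix.
#' @param tol Tolerance passed to [classify_edge()].
#' @param labels Optional strain labels (defaults to row names, then
#'   `strain_1`, ...).
#' @return A tibble with one row per unordered pair: columns `i`, `j`,
#'   `lambda_ij`, `lambda_ji`, `outcome`.
#' @export
invasion_network <- function(Lambda, tol = 0, labels = NULL) {
  L <- as.matrix(Lambda)
  N <- nrow(L)
  labels <- labels %||% rownames(L) %||% paste0("strain_", seq_len(N))
  pairs <- utils::combn(N, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    ii <- pairs[1L, p]; jj <- pairs[2L, p]
    l_ij <- L[ii, jj]; l_ji <- L[jj, ii]
    out <- classify_edge(l_ij, l_ji, tol = tol)
    tibble::tibble(i = labels[ii], j = labels[jj],
                   lambda_ij = l_ij, lambda_ji = l_ji,
                   outcome = out$class)
  })
}
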
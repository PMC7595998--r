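#' Validate a co-colonization interaction matrix
#'
#' Entry `K[i, j]` is the multiplicative factor by which prior colonization
#' with strain i (row, the colonizer/resident at the host level) alters the
#' host's susceptibility to incoming co-colonizer strain j (column). Values
#' above 1 mean facilitation, below 1 inhibition. Entries must be finite and
#' non-negative.
#'
#' @param K Numeric matrix.
#' @return The validated matrix, invisibly usable downstream.
#' @keywords internal
validate_interaction_matrix <- function(K) {
  if (!is.matrix(K) || !is.numeric(K))
    stop("`K` must be a numeric matrix.", call. = FALSE)
  if (nrow(K) != ncol(K))
    stop(sprintf("`K` must be square; got %d x %d.", nrow(K), ncol(K)),
         call. = FALSE)
  if (any(!is.finite(K)))
    stop("`K` must contain only finite values.", call. = FALSE)
  if (any(K < 0))
    stop("`K` must be non-negative: a negative susceptibility factor is unphysical.",
         call. = FALSE)
  K
}

#' Similarity decomposition of an interaction matrix
#'
#' Splits a co-colonization interaction matrix into `K = k + epsilon * A`:
#' a common reference coefficient `k` (by default the mean of all N^2
#' entries), a deviation scale `epsilon` (the root-mean-square distance of
#' the entries from `k`, i.e. their standard deviation when `k` is the mean),
#' and a normalized deviation matrix `A = (K - k) / epsilon`. With the
#' default reference, `A` has entrywise mean 0 and Frobenius norm exactly N.
#' A constant matrix (`epsilon = 0`) is flagged neutral and `A` is set to the
#' zero matrix by convention; `epsilon` is never divided by.
#'
#' The reference is mathematically non-unique: a user-supplied `reference`
#' is accepted, in which case `epsilon` is recomputed as the RMS distance
#' from that reference (and `A` need not have mean zero).
#'
#' @param K Square numeric matrix of non-negative, finite entries.
#' @param reference Optional reference coefficient `k`; defaults to
#'   `mean(K)`.
#' @return An object of class `similarity_decomposition`: list with fields
#'   `k`, `epsilon`, `A`, `N`, `neutral` (TRUE when `epsilon == 0`) and
#'   `labels` (strain labels, possibly NULL).
#' @examples
#' K <- matrix(c(1.1, 0.9, 0.9, 1.1), 2, 2)
#' d <- decompose_interactions(K)
#' d$k        # 1
#' d$epsilon  # 0.1
#' @seealso [recompose_interactions()]
#' @export
decompose_interactions <- function(K, reference = NULL) {
  K <- validate_interaction_matrix(K)
  N <- nrow(K)
  labels <- rownames(K)
  k <- if (is.null(reference)) mean(K) else {
    stopifnot(is.numeric(reference), length(reference) == 1L, is.finite(reference))
    as.numeric(reference)
  }
  epsilon <- sqrt(mean((K - k)^2))
  neutral <- epsilon == 0
  A <- if (neutral) matrix(0, N, N) else (K - k) / epsilon
  dimnames(A) <- dimnames(K)
  structure(
    list(k = k, epsilon = epsilon, A = A, N = N,
         neutral = neutral, labels = labels),
    class = "similarity_decomposition"
  )
}

#' Rebuild an interaction matrix from its decomposition
#'
#' Inverse of [decompose_interactions()]: returns `k + epsilon * A`.
#'
#' @param d A `similarity_decomposition`.
#' @return The N x N interaction matrix.
#' @export
recompose_interactions <- function(d) {
  stopifnot(inherits(d, "similarity_decomposition"))
  K <- d$k + d$epsilon * d$A
  dimnames(K) <- dimnames(d$A)
  K
}

#' @export
print.similarity_decomposition <- function(x, ...) {
  cat("Similarity decomposition K = k + epsilon * A\n")
  cat(sprintf("  N = %d, k = %.6g, epsilon = %.6g%s\n",
              x$N, x$k, x$epsilon,
              if (x$neutral) "  (neutral: constant K)" else ""))
  if (!x$neutral)
    cat(sprintf("  mean(A) = %.3g, ||A||_F = %.6g\n",
                mean(x$A), sqrt(sum(x$A^2))))
  invisible(x)
}

#' @export
glance.similarity_decomposition <- function(x, ...) {
  tibble::tibble(N = x$N, k = x$k, epsilon = x$epsilon, neutral = x$neutral,
                 mean_A = mean(x$A), frobenius_A = sqrt(sum(x$A^2)))
}

#' @export
tidy.similarity_decomposition <- function(x, ...) {
  lab <- x$labels %||% paste0("strain_", seq_len(x$N))
  tibble::tibble(
    colonizer = rep(lab, times = x$N),
    cocolonizer = rep(lab, each = x$N),
    alpha = as.vector(x$A),
    K = as.vector(recompose_interactions(x))
  )
}

#' Generate a random interaction matrix
#'
#' Draws N^2 i.i.d. normal entries with mean `k` and standard deviation
#' `epsilon` (the regime used throughout for random ensembles, e.g. k = 1,
#' epsilon = 0.1). Negative draws are clipped to 0 with a warning, since
#' susceptibility factors cannot be negative; clipping shifts the sample
#' moments, so the realized reference and scale should be recovered with
#' [decompose_interactions()], not assumed.
#'
#' @param N Number of strains (>= 2).
#' @param k Target mean interaction coefficient.
#' @param epsilon Target entry standard deviation (>= 0).
#' @param seed Optional integer seed; identical seeds give identical matrices.
#' @return An N x N interaction matrix with strain labels.
#' @examples
#' K <- random_interaction_matrix(6, k = 1, epsilon = 0.1, seed = 42)
#' glance(decompose_interactions(K))
#' @export
random_interaction_matrix <- function(N, k = 1, epsilon = 0.1, seed = NULL) {
  stopifnot(N >= 2, N == round(N), epsilon >= 0)
  if (k < 0)
    stop("`k` must be non-negative: all entries would be negative.", call. = FALSE)
  if (k == 0 && epsilon == 0)
    stop("`k = 0` with `epsilon = 0` gives an all-zero matrix; not a valid interaction matrix.",
         call. = FALSE)
  K <- with_seed_maybe(seed, matrix(stats::rnorm(N * N, mean = k, sd = epsilon), N, N))
  if (any(K < 0)) {
    warning(sprintf("%d negative draw(s) clipped to 0; recover realized k and epsilon via decompose_interactions().",
                    sum(K < 0)), call. = FALSE)
    K[K < 0] <- 0
  }
  dimnames(K) <- list(paste0("strain_", seq_len(N)), paste0("strain_", seq_len(N)))
  K
}

#' Generate an interaction matrix with a canonical structure
#'
#' Builds an interaction matrix whose free entries are random (normal with
#' mean `k`, sd `epsilon`, seeded) but which satisfies one of the canonical
#' structural identities exactly. Each structure maps to a characteristic
#' class of the pairwise invasion fitness matrix (see
#' [classify_structure()]):
#'
#' * `symmetric_general`: `K[i,j] == K[j,i]` (general Lambda);
#' * `symmetric_special1`: symmetric with `K[i,i] == k` (symmetric Lambda);
#' * `symmetric_special2`: `K[i,j] == K[i,i] + K[j,j] - k` (invader-driven);
#' * `diagonal`: `K[i,j] == k` off-diagonal (resident-driven);
#' * `colonizer_driven`: `K[i,j] == k_i`, constant rows (antisymmetric);
#' * `cocolonizer_driven`: `K[i,j] == k_j`, constant columns (antisymmetric);
#' * `antisymmetric`: `(K[i,j] + K[j,i]) / 2 == k` (antisymmetric).
#'
#' @param N Number of strains (>= 2).
#' @param structure One of the structure names above.
#' @param k Reference interaction coefficient.
#' @param epsilon Scale of the random free entries (>= 0).
#' @param seed Optional integer seed.
#' @return An N x N interaction matrix satisfying the structure identity
#'   exactly (up to floating round-off). Entries are clipped at 0 with a
#'   warning if a draw lands negative.
#' @export
structured_interaction_matrix <- function(N,
                                          structure = c("symmetric_general",
                                                        "symmetric_special1",
                                                        "symmetric_special2",
                                                        "diagonal",
                                                        "colonizer_driven",
                                                        "cocolonizer_driven",
                                                        "antisymmetric"),
                                          k = 1, epsilon = 0.1, seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(N >= 2, N == round(N), epsilon >= 0, k >= 0)
  K <- with_seed_maybe(seed, {
    up <- upper.tri(matrix(0, N, N))
    draw <- function(n) stats::rnorm(n, mean = k, sd = epsilon)
    switch(structure,
      symmetric_general = {
        M <- matrix(0, N, N)
        M[up] <- draw(sum(up))
        M <- M + t(M)
        diag(M) <- draw(N)
        M
      },
      symmetric_special1 = {
        M <- matrix(0, N, N)
        M[up] <- draw(sum(up))
        M <- M + t(M)
        diag(M) <- k
        M
      },
      symmetric_special2 = {
        dg <- draw(N)
        M <- outer(dg, dg, function(a, b) a + b - k)
        diag(M) <- dg
        M
      },
      diagonal = {
        M <- matrix(k, N, N)
        diag(M) <- draw(N)
        M
      },
      colonizer_driven = matrix(rep(draw(N), times = N), N, N),
      cocolonizer_driven = matrix(rep(draw(N), each = N), N, N),
      antisymmetric = {
        D <- matrix(0, N, N)
        D[up] <- stats::rnorm(sum(up), mean = 0, sd = epsilon)
        M <- k + D - t(D)
        M
      }
    )
  })
  if (any(K < 0)) {
    warning(sprintf("%d negative entrie(s) clipped to 0; the structural identity may be broken where clipping occurred.",
                    sum(K < 0)), call. = FALSE)
    K[K < 0] <- 0
  }
  dimnames(K) <- list(paste0("strain_", seq_len(N)), paste0("strain_", seq_len(N)))
  K
}
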
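#' Global epidemiological parameters
#'
#' All strains share the transmission rate `beta`, the clearance rate `gamma`
#' and the host turnover rate `r` (recruitment of susceptibles equals the
#' mortality rate `d = r`, so total host density is conserved). Diversity
#' enters only through the co-colonization interaction matrix. Two derived
#' quantities are attached: the combined exit rate `m = gamma + r` and the
#' basic reproduction number `R0 = beta / m`, shared by all strains.
#'
#' @param beta Transmission rate (1/time), positive.
#' @param gamma Clearance rate (1/time), positive; equal for single and
#'   double colonization episodes.
#' @param r Host turnover rate (1/time), positive; recruitment = mortality.
#' @param N Number of strains, integer >= 1.
#'
#' @return An object of class `epi_params`: a list with fields `beta`,
#'   `gamma`, `r`, `N`, `m`, `R0`.
#' @examples
#' p <- epi_params(beta = 2, gamma = 0.5, r = 0.5, N = 6)
#' p$R0  # 2
#' @export
epi_params <- function(beta, gamma, r, N) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(N), length(N) == 1L, is.finite(N))
  if (beta <= 0 || gamma <= 0 || r <= 0)
    stop("`beta`, `gamma` and `r` must all be strictly positive.", call. = FALSE)
  if (N < 1 || N != round(N))
    stop("`N` must be an integer >= 1.", call. = FALSE)
  m <- gamma + r
  structure(
    list(beta = beta, gamma = gamma, r = r, N = as.integer(N),
         m = m, R0 = beta / m),
    class = "epi_params"
  )
}

#' @export
print.epi_params <- function(x, ...) {
  cat("Epidemiological parameters (", x$N, " strains)\n", sep = "")
  cat(sprintf("  beta = %g, gamma = %g, r = %g\n", x$beta, x$gamma, x$r))
  cat(sprintf("  m = gamma + r = %g,  R0 = beta/m = %g\n", x$m, x$R0))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.epi_params <- function(x, ...) {
  tibble::tibble(beta = x$beta, gamma = x$gamma, r = x$r, N = x$N,
                 m = x$m, R0 = x$R0)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# with seed = NULL the expression just uses the current stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
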
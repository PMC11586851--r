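#' Round half away from zero
#'
#' Decimal rounding in which exact halves are rounded away from zero
#' (0.435 -> 0.44), the convention used when quoting heritabilities and trait
#' means to a fixed number of decimals. Base \code{round()} rounds halves to
#' even, which is the wrong convention for reproducing printed tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to \code{digits} decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Heritability from a variance-component pair
#'
#' @param sigma_a2 additive genetic variance (trait units squared).
#' @param sigma_e2 residual variance (trait units squared).
#' @return h2 = sigma_a2 / (sigma_a2 + sigma_e2).
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  stopifnot(sigma_a2 >= 0, sigma_e2 >= 0, sigma_a2 + sigma_e2 > 0)
  sigma_a2 / (sigma_a2 + sigma_e2)
}

#' Genetic correlation from a 2x2 genetic covariance matrix
#'
#' @param K 2x2 additive genetic (co)variance matrix.
#' @return K[1,2] / sqrt(K[1,1] * K[2,2]).
#' @export
genetic_correlation <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == 2, ncol(K) == 2)
  K[1, 2] / sqrt(K[1, 1] * K[2, 2])
}

# Cholesky factor (lower) with a single documented jitter attempt for
# positive semi-definite matrices whose smallest eigenvalues are numerically
# negative. Errors if the jittered factorization still fails.
psd_chol_lower <- function(S, jitter = 1e-8, label = "matrix") {
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (is.null(L)) {
    eps <- jitter * mean(diag(S))
    L <- tryCatch(t(chol(S + diag(eps, nrow(S)))), error = function(e) NULL)
    if (is.null(L)) {
      stop(sprintf("%s is not positive semi-definite (Cholesky failed even after adding %.3g to the diagonal)",
                   label, eps))
    }
  }
  L
}

# Nearest symmetric PSD matrix by eigenvalue clipping.
nearest_psd <- function(S, eps = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  d <- pmax(e$values, eps)
  S2 <- e$vectors %*% (d * t(e$vectors))
  (S2 + t(S2)) / 2
}

is_psd <- function(S, tol = 1e-10) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}
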
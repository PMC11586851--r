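#' Simulate true breeding values from a relationship matrix
#'
#' Draws animal x trait breeding values from the zero-mean multivariate
#' normal with covariance \code{relationship %x% K} (animals vary by the
#' relationship matrix, traits by the genetic covariance K). In the
#' univariate case K may be given as a scalar additive variance. Simulating
#' from the relationship-matrix MVN (rather than from marker effects) makes
#' the draws match the estimation model exactly, so parameter recovery is a
#' clean test of the REML machinery.
#'
#' @param relationship symmetric PSD animal relationship matrix (A or G).
#' @param K genetic covariance matrix across traits, or a scalar variance.
#' @param seed integer seed.
#' @return matrix of breeding values, animals x traits (rownames kept from
#'   \code{relationship}).
#' @export
simulate_true_breeding_values <- function(relationship, K, seed = 1L) {
  if (!is.matrix(K)) K <- matrix(K, 1, 1)
  if (!isTRUE(all.equal(unname(relationship), unname(t(relationship)),
                        tolerance = 1e-8))) {
    stop("relationship matrix must be symmetric")
  }
  n <- nrow(relationship)
  t <- nrow(K)
  set.seed(seed)
  if (all(abs(K) == 0)) {
    u <- matrix(0, n, t)
  } else {
    La <- psd_chol_lower(relationship, label = "relationship matrix")
    Lk <- psd_chol_lower(K, label = "K")
    Z <- matrix(stats::rnorm(n * t), n, t)
    u <- La %*% Z %*% t(Lk)
  }
  rownames(u) <- rownames(relationship)
  colnames(u) <- if (!is.null(rownames(K))) rownames(K) else paste0("trait", seq_len(t))
  u
}
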
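#' Solve the training mixed model equations
#'
#' Standard GBLUP mixed model equations for the training population
#' (genotyped animals with phenotypes), with the variance components fixed
#' (two-step design: components come from the pedigree-based REML fit and
#' are not re-estimated with G):
#' \deqn{[X'X, X'Z; Z'X, Z'Z + G^{-1} \lambda] [b; u] = [X'y; Z'y]}
#' with \eqn{\lambda = \sigma_e^2/\sigma_a^2} and Z = I. Returns the GEBVs,
#' the fixed-effect solutions, and the animal block C22 of the inverse
#' coefficient matrix, whose diagonal scaled by \eqn{\sigma_e^2} is the
#' prediction error variance.
#'
#' @param y training phenotypes (one record per training animal).
#' @param X fixed-effect design (default intercept).
#' @param G_TT training-population genomic relationship matrix, invertible
#'   (stabilize with \code{\link{stabilize_G}} if needed).
#' @param sigma_a2,sigma_e2 fixed variance components (> 0).
#' @return list of class \code{gblup_fit}: \code{u_hat}, \code{beta},
#'   \code{C22}, \code{reliability} (training, = 1 - PEV/(g_ii sigma_a2)),
#'   \code{sigma_a2}, \code{sigma_e2}.
#' @export
solve_training_mme <- function(y, X = NULL, G_TT, sigma_a2, sigma_e2) {
  n <- length(y)
  stopifnot(nrow(G_TT) == n, sigma_a2 > 0, sigma_e2 > 0)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  lambda <- sigma_e2 / sigma_a2
  if (rcond(as.matrix(G_TT)) < 1e-12) {
    stop("G_TT is numerically singular (duplicate genotypes?); stabilize it (diagonal shift or A-blending) before solving the MME")
  }
  Ginv <- tryCatch(chol2inv(chol(G_TT)), error = function(e) {
    stop("G_TT is not positive definite; stabilize it (diagonal shift or A-blending) before solving the MME")
  })
  p <- ncol(X)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + Ginv * lambda))
  rhs <- c(crossprod(X, y), y)
  Cinv <- tryCatch(solve(C, tol = .Machine$double.xmin), error = function(e) {
    stop("singular MME coefficient matrix (rank-deficient fixed effects?)")
  })
  sol <- drop(Cinv %*% rhs)
  beta <- sol[seq_len(p)]
  u_hat <- sol[-seq_len(p)]
  C22 <- Cinv[(p + 1):(p + n), (p + 1):(p + n), drop = FALSE]
  rel <- 1 - diag(C22) * sigma_e2 / (diag(G_TT) * sigma_a2)
  names(u_hat) <- rownames(G_TT)
  structure(list(u_hat = u_hat, beta = beta, C22 = C22, reliability = rel,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2),
            class = "gblup_fit")
}

#' Indirect prediction of non-phenotyped animals
#'
#' GEBVs of the prediction population from the training GEBVs:
#' \deqn{\hat u_P = G_{PT} G_{TT}^{-1} \hat u_T}
#'
#' @param G_PT prediction x training genomic relationship block.
#' @param G_TT training genomic relationship matrix (invertible).
#' @param u_T training GEBVs.
#' @return vector of prediction GEBVs.
#' @export
indirect_predict <- function(G_PT, G_TT, u_T) {
  G_PT <- as.matrix(G_PT)
  if (ncol(G_PT) != nrow(G_TT) || nrow(G_TT) != length(u_T)) {
    stop("non-conformable dimensions: G_PT must be prediction x training, u_T of training length")
  }
  drop(G_PT %*% solve(G_TT, u_T))
}

#' Reliability of indirectly predicted GEBVs
#'
#' Computes, per prediction animal, the variance of the indirect GEBV
#' \deqn{G_{PT} G_{TT}^{-1} (G_{TT}\sigma_a^2 - C_{22}\sigma_e^2) G_{TT}^{-1} G_{TP}}
#' and normalizes its diagonal by \eqn{g_{ii}\sigma_a^2} (the animal's own
#' genetic variance) so the result is a reliability in [0, 1] -- the
#' squared-correlation definition rel = Var(u_hat)/Var(u). The quadratic
#' form itself is a (co)variance in trait units squared; the normalization
#' is required to make it unitless.
#'
#' @param G_PT prediction x training genomic relationship block.
#' @param G_TT training genomic relationship matrix.
#' @param C22 animal block of the inverse MME coefficient matrix (from
#'   \code{\link{solve_training_mme}}).
#' @param sigma_a2,sigma_e2 the fixed variance components.
#' @param diag_GPP diagonal of the prediction-population genomic
#'   relationship matrix (g_ii per prediction animal).
#' @param tol tolerance beyond [0, 1] treated as an error (signals an
#'   inconsistent C22/G pairing); values within tol are clamped.
#' @return vector of reliabilities in [0, 1].
#' @export
reliability_indirect <- function(G_PT, G_TT, C22, sigma_a2, sigma_e2,
                                 diag_GPP, tol = 1e-6) {
  G_PT <- as.matrix(G_PT)
  stopifnot(ncol(G_PT) == nrow(G_TT), all(dim(C22) == dim(G_TT)),
            length(diag_GPP) == nrow(G_PT), sigma_a2 > 0)
  Tm <- solve(G_TT, t(G_PT))                     # training x prediction
  M <- G_TT * sigma_a2 - C22 * sigma_e2
  q <- colSums(Tm * (M %*% Tm))                  # diag(T' M T)
  rel <- q / (diag_GPP * sigma_a2)
  if (any(rel < -tol) || any(rel > 1 + tol)) {
    stop(sprintf("reliability outside [0, 1] (range %.4f..%.4f): C22 and G are inconsistent",
                 min(rel), max(rel)))
  }
  pmin(pmax(rel, 0), 1)
}

#' One-call GBLUP with indirect prediction
#'
#' Convenience wrapper: solves the training MME, indirectly predicts the
#' prediction animals and computes both reliability sets from one full
#' genomic relationship matrix.
#'
#' @param y training phenotypes, names = training animal ids.
#' @param G full genomic relationship matrix over training + prediction
#'   animals (dimnames required).
#' @param training_ids,prediction_ids animal id vectors.
#' @param sigma_a2,sigma_e2 fixed variance components.
#' @param X optional fixed-effect design for the training records.
#' @return data.frame \code{animal_id, gebv, reliability, population}
#'   ("training"/"prediction"), with the \code{gblup_fit} attached as
#'   attribute \code{fit}.
#' @export
gblup_predict <- function(y, G, training_ids, prediction_ids,
                          sigma_a2, sigma_e2, X = NULL) {
  ids <- rownames(G)
  stopifnot(!is.null(ids), all(training_ids %in% ids),
            all(prediction_ids %in% ids), length(y) == length(training_ids))
  ti <- match(as.character(training_ids), ids)
  pi <- match(as.character(prediction_ids), ids)
  G_TT <- G[ti, ti, drop = FALSE]
  G_PT <- G[pi, ti, drop = FALSE]
  fit <- solve_training_mme(y, X, G_TT, sigma_a2, sigma_e2)
  u_p <- indirect_predict(G_PT, G_TT, fit$u_hat)
  rel_p <- reliability_indirect(G_PT, G_TT, fit$C22, sigma_a2, sigma_e2,
                                diag(G)[pi])
  out <- rbind(
    data.frame(animal_id = as.character(training_ids), gebv = unname(fit$u_hat),
               reliability = unname(fit$reliability), population = "training",
               stringsAsFactors = FALSE),
    data.frame(animal_id = as.character(prediction_ids), gebv = unname(u_p),
               reliability = unname(rel_p), population = "prediction",
               stringsAsFactors = FALSE))
  attr(out, "fit") <- fit
  out
}
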
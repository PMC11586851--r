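#' Univariate animal-model REML (average information)
#'
#' Fits y = X b + Z u + e with u ~ N(0, A sigma_a2) and e ~ N(0, I sigma_e2)
#' by restricted maximum likelihood. The phenotypic covariance
#' V = Z A Z' sigma_a2 + I sigma_e2 is rotated by the eigendecomposition of
#' Z A Z', which makes V diagonal so every AI iteration costs O(n p^2).
#' Updates are average-information (quasi-Newton) steps with step-halving
#' onto an ascent path; when an AI step leaves the parameter space an
#' EM-style gradient-scaled step is taken instead, so the restricted
#' log-likelihood never decreases across iterations. Estimates at the
#' sigma_a2 = 0 boundary are flagged, not fatal.
#'
#' @param y numeric response vector (one record per row of Z).
#' @param relationship animal relationship matrix (A or G) covering all
#'   animals with records.
#' @param X fixed-effect design matrix (default: intercept only). Must have
#'   full column rank.
#' @param Z records x animals incidence matrix (default: identity, one
#'   record per animal in relationship order).
#' @param start optional starting values c(sigma_a2, sigma_e2).
#' @param max_iter maximum AI iterations.
#' @param tol convergence tolerance on the relative parameter change.
#' @param eig optional precomputed \code{eigen(Z A Z', symmetric = TRUE)};
#'   lets replicate studies over a fixed pedigree reuse the decomposition.
#' @return object of class \code{reml_uv}: \code{sigma_a2}, \code{sigma_e2},
#'   \code{h2}, \code{h2_se} (delta method), \code{loglik},
#'   \code{ai_inverse} (asymptotic covariance of the components),
#'   \code{converged}, \code{boundary}, \code{trace} (per-iteration
#'   components and log-likelihood).
#' @export
reml_univariate <- function(y, relationship, X = NULL, Z = NULL,
                            start = NULL, max_iter = 200, tol = 1e-8,
                            eig = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  if (is.null(eig)) {
    S <- as.matrix(relationship)
    if (!is.null(Z)) {
      Z <- as.matrix(Z)
      stopifnot(nrow(Z) == n, ncol(Z) == nrow(S))
      S <- Z %*% S %*% t(Z)
    } else {
      stopifnot(nrow(S) == n)
    }
    eig <- eigen(S, symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  vary <- stats::var(stats::lm.fit(X, y)$residuals)
  if (!is.finite(vary) || vary <= 0) vary <- max(stats::var(y), 1e-8)
  theta <- if (!is.null(start)) as.numeric(start) else c(vary / 2, vary / 2)
  lb <- c(0, 1e-10 * vary)

  obj <- function(th) {
    v <- th[1] * d + th[2]
    if (any(v <= 0)) return(list(ll = -Inf))
    w <- 1 / v
    B <- crossprod(Xs * w, Xs)
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(list(ll = -Inf))
    beta <- backsolve(cB, forwardsolve(t(cB), crossprod(Xs, w * ys)))
    e <- ys - drop(Xs %*% beta)
    ve <- w * e
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cB))) + sum(e * ve))
    list(ll = ll, v = v, w = w, B = B, cB = cB, beta = beta, e = e, ve = ve)
  }

  bsolve <- function(cB, M) backsolve(cB, forwardsolve(t(cB), M))

  st <- obj(theta)
  if (!is.finite(st$ll)) stop("invalid starting values for REML")
  trace <- data.frame(iter = 0L, sigma_a2 = theta[1], sigma_e2 = theta[2],
                      loglik = st$ll, step = "start")
  converged <- FALSE
  AI <- NULL
  dvecs <- list(d, rep(1, n))
  for (iter in seq_len(max_iter)) {
    w <- st$w; ve <- st$ve
    score <- numeric(2)
    wk <- vector("list", 2)
    Pwk <- vector("list", 2)
    for (k in 1:2) {
      dk <- dvecs[[k]]
      XVkVX <- crossprod(Xs * (w * dk * w), Xs)
      trPVk <- sum(w * dk) - sum(diag(bsolve(st$cB, XVkVX)))
      quad <- sum(ve * dk * ve)
      score[k] <- -0.5 * (trPVk - quad)
      wk[[k]] <- dk * ve
      alpha <- bsolve(st$cB, crossprod(Xs, w * wk[[k]]))
      Pwk[[k]] <- w * (wk[[k]] - drop(Xs %*% alpha))
    }
    AI <- matrix(0, 2, 2)
    for (k in 1:2) for (l in k:2) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(wk[[k]] * Pwk[[l]])
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    used <- "AI"
    if (is.null(step) || any(!is.finite(step))) {
      step <- theta^2 * (vapply(1:2, function(k) sum(ve * dvecs[[k]] * ve), 0) -
                           vapply(1:2, function(k) {
                             XVkVX <- crossprod(Xs * (w * dvecs[[k]] * w), Xs)
                             sum(w * dvecs[[k]]) - sum(diag(bsolve(st$cB, XVkVX)))
                           }, 0)) / n
      used <- "EM"
    }
    # AI proposal, projected onto the parameter space (sigma_a2 may sit at 0)
    prop <- pmax(theta + step, lb)
    if (any(theta + step < lb)) used <- paste0(used, "/clamped")
    newst <- obj(prop)
    halvings <- 0
    while ((!is.finite(newst$ll) || newst$ll < st$ll - 1e-10) && halvings < 30) {
      prop <- pmax(theta + (prop - theta) / 2, lb)
      newst <- obj(prop)
      halvings <- halvings + 1
    }
    if (!is.finite(newst$ll) || newst$ll < st$ll - 1e-10) {
      # EM-style fallback: gradient-scaled update, guaranteed interior
      em <- numeric(2)
      for (k in 1:2) {
        dk <- dvecs[[k]]
        XVkVX <- crossprod(Xs * (w * dk * w), Xs)
        trPVk <- sum(w * dk) - sum(diag(bsolve(st$cB, XVkVX)))
        em[k] <- theta[k] + theta[k]^2 * (sum(ve * dk * ve) - trPVk) / n
      }
      prop <- pmax(em, lb)
      used <- "EM"
      newst <- obj(prop)
    }
    if (!is.finite(newst$ll) || newst$ll < st$ll - 1e-10) {
      # cannot improve: treat as stalled at the current maximum
      converged <- TRUE
      break
    }
    rel_change <- max(abs(prop - theta) / pmax(abs(theta), 1e-8))
    ll_change <- newst$ll - st$ll
    theta <- prop
    st <- newst
    trace <- rbind(trace, data.frame(iter = iter, sigma_a2 = theta[1],
                                     sigma_e2 = theta[2], loglik = st$ll,
                                     step = used))
    if (rel_change < tol || (iter > 2 && ll_change < 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(structure(class = c("reml_nonconvergence", "error", "condition"),
                   list(message = sprintf("REML did not converge in %d iterations", max_iter),
                        call = sys.call(-1), trace = trace)))
  }
  ai_inv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(ai_inv) <- list(c("sigma_a2", "sigma_e2"), c("sigma_a2", "sigma_e2"))
  h2 <- theta[1] / sum(theta)
  gr <- c(theta[2], -theta[1]) / sum(theta)^2
  h2_se <- if (!anyNA(ai_inv)) sqrt(max(drop(t(gr) %*% ai_inv %*% gr), 0)) else NA_real_
  boundary <- theta[1] <= lb[1] + 1e-8 * vary
  structure(list(sigma_a2 = theta[1], sigma_e2 = theta[2], h2 = h2,
                 h2_se = h2_se, loglik = st$ll, ai_inverse = ai_inv,
                 converged = converged, boundary = boundary,
                 iterations = max(trace$iter), trace = trace),
            class = "reml_uv")
}

#' @export
print.reml_uv <- function(x, ...) {
  cat(sprintf("Univariate AI-REML: sigma_a2 = %.4f, sigma_e2 = %.4f, h2 = %.3f (SE %.3f), logL = %.3f, %d iterations%s\n",
              x$sigma_a2, x$sigma_e2, x$h2, x$h2_se, x$loglik, x$iterations,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

# 2x2 symmetric basis matrices for the unstructured (co)variance parameters
.E2 <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 1, 1, 0), 2),
            matrix(c(0, 0, 0, 1), 2))

.theta_to_KR <- function(theta) {
  list(K = matrix(theta[c(1, 2, 2, 3)], 2),
       R = matrix(theta[c(4, 5, 5, 6)], 2))
}

.KR_valid <- function(theta, strict = 1e-12) {
  kr <- .theta_to_KR(theta)
  ok <- function(M) M[1, 1] > 0 && M[2, 2] > 0 && det(M) > strict
  ok(kr$K) && ok(kr$R)
}

#' Bivariate animal-model REML
#'
#' Fits the two-trait animal model y = X b + u + e with
#' u ~ N(0, A (x) K) (each animal contributes a 2x2 genetic covariance K
#' scaled by its relationship row) and e ~ N(0, R (x) I), estimating the
#' unstructured K and R by average-information REML. Fixed effects default
#' to a mean per trait. Complete two-trait records are handled through the
#' eigendecomposition of A (2x2-block-diagonal rotated covariance, O(n) per
#' iteration); animals missing one trait (NA in \code{Y}) are handled by a
#' dense-matrix AI-REML over the observed records.
#'
#' @param Y n x 2 matrix of trait records, rows aligned with
#'   \code{relationship}; NA = trait not observed for that animal.
#' @param relationship animal relationship matrix (A or G).
#' @param start optional starting values as list(K = , R = ).
#' @param max_iter,tol as in \code{\link{reml_univariate}}.
#' @param eig optional precomputed \code{eigen(relationship)} (complete-record
#'   path only).
#' @return object of class \code{reml_bv}: \code{K}, \code{R}, \code{rg},
#'   \code{rg_se} (delta method), \code{loglik}, \code{ai_inverse} (6x6,
#'   parameter order K11 K21 K22 R11 R21 R22), \code{converged},
#'   \code{projected} (TRUE if K was projected to the nearest PSD matrix),
#'   \code{trace}.
#' @export
reml_bivariate <- function(Y, relationship, start = NULL,
                           max_iter = 200, tol = 1e-8, eig = NULL) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 2)
  if (anyNA(Y)) {
    return(.reml_bivariate_dense(Y, relationship, start, max_iter, tol))
  }
  n <- nrow(Y)
  if (is.null(eig)) {
    stopifnot(nrow(Y) == nrow(relationship))
    eig <- eigen(as.matrix(relationship), symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Ys <- crossprod(U, Y)
  one <- drop(crossprod(U, rep(1, n)))

  C0 <- stats::cov(Y)
  theta <- if (!is.null(start)) {
    c(start$K[1, 1], start$K[2, 1], start$K[2, 2],
      start$R[1, 1], start$R[2, 1], start$R[2, 2])
  } else {
    c(C0[1, 1] / 2, C0[2, 1] / 2, C0[2, 2] / 2,
      C0[1, 1] / 2, C0[2, 1] / 4, C0[2, 2] / 2)
  }

  obj <- function(th) {
    kr <- .theta_to_KR(th)
    b11 <- d * kr$K[1, 1] + kr$R[1, 1]
    b21 <- d * kr$K[2, 1] + kr$R[2, 1]
    b22 <- d * kr$K[2, 2] + kr$R[2, 2]
    det_i <- b11 * b22 - b21^2
    if (any(det_i <= 0) || any(b11 <= 0) || any(b22 <= 0)) return(list(ll = -Inf))
    i11 <- b22 / det_i; i21 <- -b21 / det_i; i22 <- b11 / det_i
    B <- matrix(c(sum(one^2 * i11), sum(one^2 * i21),
                  sum(one^2 * i21), sum(one^2 * i22)), 2)
    r1 <- sum(one * (i11 * Ys[, 1] + i21 * Ys[, 2]))
    r2 <- sum(one * (i21 * Ys[, 1] + i22 * Ys[, 2]))
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(list(ll = -Inf))
    beta <- backsolve(cB, forwardsolve(t(cB), c(r1, r2)))
    E1 <- Ys[, 1] - one * beta[1]
    E2 <- Ys[, 2] - one * beta[2]
    VE1 <- i11 * E1 + i21 * E2
    VE2 <- i21 * E1 + i22 * E2
    ll <- -0.5 * (sum(log(det_i)) + 2 * sum(log(diag(cB))) +
                    sum(E1 * VE1 + E2 * VE2))
    list(ll = ll, i11 = i11, i21 = i21, i22 = i22, B = B, cB = cB,
         beta = beta, E1 = E1, E2 = E2, VE1 = VE1, VE2 = VE2)
  }

  st <- obj(theta)
  if (!is.finite(st$ll)) {
    theta <- c(C0[1, 1] / 2, 0, C0[2, 2] / 2, C0[1, 1] / 2, 0, C0[2, 2] / 2)
    st <- obj(theta)
    if (!is.finite(st$ll)) stop("invalid starting values for bivariate REML")
  }
  trace <- data.frame(iter = 0L, loglik = st$ll, step = "start")
  converged <- FALSE
  projected <- FALSE
  AI <- NULL

  for (iter in seq_len(max_iter)) {
    i11 <- st$i11; i21 <- st$i21; i22 <- st$i22
    VE1 <- st$VE1; VE2 <- st$VE2
    cfacs <- list(d, d, d, rep(1, n), rep(1, n), rep(1, n))
    eidx <- c(1, 2, 3, 1, 2, 3)
    score <- numeric(6)
    wk1 <- matrix(0, n, 6)
    wk2 <- matrix(0, n, 6)
    Pw1 <- matrix(0, n, 6)
    Pw2 <- matrix(0, n, 6)
    for (k in 1:6) {
      ck <- cfacs[[k]]
      ek <- eidx[k]
      # tr(V^-1 dVk), quadratic form, and wk = dVk V^-1 e, all in 2x2 blocks
      if (ek == 1) {
        trv <- sum(ck * i11)
        quad <- sum(ck * VE1^2)
        wk1[, k] <- ck * VE1; wk2[, k] <- 0
        m11 <- i11 * i11; m21 <- i21 * i11; m22 <- i21 * i21
      } else if (ek == 2) {
        trv <- 2 * sum(ck * i21)
        quad <- 2 * sum(ck * VE1 * VE2)
        wk1[, k] <- ck * VE2; wk2[, k] <- ck * VE1
        m11 <- 2 * i11 * i21; m21 <- i21 * i21 + i11 * i22; m22 <- 2 * i21 * i22
      } else {
        trv <- sum(ck * i22)
        quad <- sum(ck * VE2^2)
        wk1[, k] <- 0; wk2[, k] <- ck * VE2
        m11 <- i21 * i21; m21 <- i22 * i21; m22 <- i22 * i22
      }
      XM <- matrix(c(sum(one^2 * ck * m11), sum(one^2 * ck * m21),
                     sum(one^2 * ck * m21), sum(one^2 * ck * m22)), 2)
      trPVk <- trv - sum(diag(backsolve(st$cB, forwardsolve(t(st$cB), XM))))
      score[k] <- -0.5 * (trPVk - quad)
      xw <- c(sum(one * (i11 * wk1[, k] + i21 * wk2[, k])),
              sum(one * (i21 * wk1[, k] + i22 * wk2[, k])))
      alpha <- backsolve(st$cB, forwardsolve(t(st$cB), xw))
      t1 <- wk1[, k] - one * alpha[1]
      t2 <- wk2[, k] - one * alpha[2]
      Pw1[, k] <- i11 * t1 + i21 * t2
      Pw2[, k] <- i21 * t1 + i22 * t2
    }
    AI <- matrix(0, 6, 6)
    for (k in 1:6) for (l in k:6) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(wk1[, k] * Pw1[, l] + wk2[, k] * Pw2[, l])
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- score * theta[c(1, 1, 3, 4, 4, 6)]^2 / n  # crude scaled-gradient rescue
    }
    prop <- theta + step
    halvings <- 0
    newst <- if (.KR_valid(prop)) obj(prop) else list(ll = -Inf)
    while ((!is.finite(newst$ll) || newst$ll < st$ll - 1e-10) && halvings < 30) {
      prop <- theta + (prop - theta) / 2
      newst <- if (.KR_valid(prop)) obj(prop) else list(ll = -Inf)
      halvings <- halvings + 1
    }
    if (!is.finite(newst$ll) || newst$ll < st$ll - 1e-10) {
      converged <- TRUE  # stalled at the current maximum (often a boundary)
      break
    }
    rel_change <- max(abs(prop - theta) / pmax(abs(theta), 1e-6))
    ll_change <- newst$ll - st$ll
    theta <- prop
    st <- newst
    trace <- rbind(trace, data.frame(iter = iter, loglik = st$ll,
                                     step = if (halvings > 0) "AI/halved" else "AI"))
    if (rel_change < tol || (iter > 2 && ll_change < 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(structure(class = c("reml_nonconvergence", "error", "condition"),
                   list(message = sprintf("bivariate REML did not converge in %d iterations", max_iter),
                        call = sys.call(-1), trace = trace)))
  }
  kr <- .theta_to_KR(theta)
  if (!is_psd(kr$K)) {
    kr$K <- nearest_psd(kr$K)
    projected <- TRUE
  }
  ai_inv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 6, 6))
  pn <- c("K11", "K21", "K22", "R11", "R21", "R22")
  dimnames(ai_inv) <- list(pn, pn)
  rg <- kr$K[2, 1] / sqrt(kr$K[1, 1] * kr$K[2, 2])
  rg_se <- .rg_se_delta(kr$K, ai_inv)
  structure(list(K = kr$K, R = kr$R, rg = rg, rg_se = rg_se,
                 loglik = st$ll, ai_inverse = ai_inv, converged = converged,
                 projected = projected, iterations = max(trace$iter),
                 trace = trace),
            class = "reml_bv")
}

.rg_se_delta <- function(K, ai_inv) {
  if (anyNA(ai_inv)) return(NA_real_)
  k11 <- K[1, 1]; k21 <- K[2, 1]; k22 <- K[2, 2]
  s <- sqrt(k11 * k22)
  gr <- c(-k21 / (2 * k11 * s), 1 / s, -k21 / (2 * k22 * s), 0, 0, 0)
  sqrt(max(drop(t(gr) %*% ai_inv %*% gr), 0))
}

#' @export
print.reml_bv <- function(x, ...) {
  cat(sprintf("Bivariate AI-REML: rg = %.3f (SE %.3f), K = [%.3f, %.3f; ., %.3f], R = [%.3f, %.3f; ., %.3f], logL = %.3f%s\n",
              x$rg, x$rg_se, x$K[1, 1], x$K[2, 1], x$K[2, 2],
              x$R[1, 1], x$R[2, 1], x$R[2, 2], x$loglik,
              if (x$projected) " [K projected to PSD]" else ""))
  invisible(x)
}

# Dense-matrix bivariate AI-REML for records with a missing trait. Builds the
# observed-record covariance V = sum_k theta_k V_k explicitly; intended for
# moderate record counts (the eigen path covers the complete-record case).
.reml_bivariate_dense <- function(Y, relationship, start, max_iter, tol) {
  n <- nrow(Y)
  A <- as.matrix(relationship)
  obs <- which(!is.na(Y), arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  a_r <- obs[, 1]
  t_r <- obs[, 2]
  m <- nrow(obs)
  y <- Y[obs]
  X <- cbind(as.numeric(t_r == 1), as.numeric(t_r == 2))
  Asub <- A[a_r, a_r]
  same_animal <- outer(a_r, a_r, "==")
  Vlist <- vector("list", 6)
  sel <- list(outer(t_r == 1, t_r == 1),
              outer(t_r == 1, t_r == 2) | outer(t_r == 2, t_r == 1),
              outer(t_r == 2, t_r == 2))
  for (k in 1:3) Vlist[[k]] <- Asub * sel[[k]]
  for (k in 1:3) Vlist[[k + 3]] <- same_animal * sel[[k]]

  C0 <- stats::cov(Y, use = "pairwise.complete.obs")
  if (anyNA(C0)) C0 <- diag(apply(Y, 2, stats::var, na.rm = TRUE))
  theta <- if (!is.null(start)) {
    c(start$K[1, 1], start$K[2, 1], start$K[2, 2],
      start$R[1, 1], start$R[2, 1], start$R[2, 2])
  } else {
    c(C0[1, 1] / 2, C0[2, 1] / 2, C0[2, 2] / 2,
      C0[1, 1] / 2, C0[2, 1] / 4, C0[2, 2] / 2)
  }
  fit <- .ai_reml_dense(y, X, Vlist, theta, valid = .KR_valid,
                        max_iter = max_iter, tol = tol)
  kr <- .theta_to_KR(fit$theta)
  projected <- FALSE
  if (!is_psd(kr$K)) {
    kr$K <- nearest_psd(kr$K)
    projected <- TRUE
  }
  pn <- c("K11", "K21", "K22", "R11", "R21", "R22")
  dimnames(fit$ai_inverse) <- list(pn, pn)
  rg <- kr$K[2, 1] / sqrt(kr$K[1, 1] * kr$K[2, 2])
  structure(list(K = kr$K, R = kr$R, rg = rg,
                 rg_se = .rg_se_delta(kr$K, fit$ai_inverse),
                 loglik = fit$loglik, ai_inverse = fit$ai_inverse,
                 converged = fit$converged, projected = projected,
                 iterations = fit$iterations, trace = fit$trace),
            class = "reml_bv")
}

# Generic dense AI-REML over a linear covariance structure
# V(theta) = sum_k theta_k Vlist[[k]]. `valid` screens proposals; steps are
# halved onto an ascent path.
.ai_reml_dense <- function(y, X, Vlist, theta, valid = function(th) all(th > 0),
                           max_iter = 200, tol = 1e-8) {
  m <- length(y)
  p <- length(theta)
  obj <- function(th) {
    V <- Reduce(`+`, Map(`*`, th, Vlist))
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(list(ll = -Inf))
    Vinv <- chol2inv(cV)
    B <- crossprod(X, Vinv %*% X)
    cB <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(cB)) return(list(ll = -Inf))
    beta <- backsolve(cB, forwardsolve(t(cB), crossprod(X, Vinv %*% y)))
    e <- y - drop(X %*% beta)
    ve <- drop(Vinv %*% e)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cB))) + sum(e * ve))
    list(ll = ll, Vinv = Vinv, cB = cB, beta = beta, e = e, ve = ve)
  }
  st <- obj(theta)
  if (!is.finite(st$ll)) stop("invalid starting values for dense REML")
  trace <- data.frame(iter = 0L, loglik = st$ll, step = "start")
  converged <- FALSE
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    Vinv <- st$Vinv; ve <- st$ve
    VinvX <- Vinv %*% X
    score <- numeric(p)
    wk <- matrix(0, m, p)
    Pwk <- matrix(0, m, p)
    for (k in seq_len(p)) {
      Vk <- Vlist[[k]]
      VinvVk <- Vinv %*% Vk
      XVkVX <- crossprod(VinvX, Vk %*% VinvX)
      trPVk <- sum(diag(VinvVk)) -
        sum(diag(backsolve(st$cB, forwardsolve(t(st$cB), XVkVX))))
      quad <- sum(ve * drop(Vk %*% ve))
      score[k] <- -0.5 * (trPVk - quad)
      wk[, k] <- drop(Vk %*% ve)
      alpha <- backsolve(st$cB, forwardsolve(t(st$cB), crossprod(X, Vinv %*% wk[, k])))
      Pwk[, k] <- drop(Vinv %*% (wk[, k] - drop(X %*% alpha)))
    }
    AI <- matrix(0, p, p)
    for (k in seq_len(p)) for (l in k:p) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(wk[, k] * Pwk[, l])
    }
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) step <- score * abs(theta) / m
    prop <- theta + step
    newst <- if (valid(prop)) obj(prop) else list(ll = -Inf)
    halvings <- 0
    while ((!is.finite(newst$ll) || newst$ll < st$ll - 1e-10) && halvings < 30) {
      prop <- theta + (prop - theta) / 2
      newst <- if (valid(prop)) obj(prop) else list(ll = -Inf)
      halvings <- halvings + 1
    }
    if (!is.finite(newst$ll) || newst$ll < st$ll - 1e-10) {
      converged <- TRUE
      break
    }
    rel_change <- max(abs(prop - theta) / pmax(abs(theta), 1e-6))
    ll_change <- newst$ll - st$ll
    theta <- prop
    st <- newst
    trace <- rbind(trace, data.frame(iter = iter, loglik = st$ll, step = "AI"))
    if (rel_change < tol || (iter > 2 && ll_change < 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) stop(sprintf("dense REML did not converge in %d iterations", max_iter))
  ai_inv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, p, p))
  list(theta = theta, loglik = st$ll, ai_inverse = ai_inv,
       converged = converged, iterations = max(trace$iter), trace = trace)
}

#' Standard errors of derived parameters by asymptotic sampling
#'
#' Draws component vectors from the asymptotic distribution
#' MVN(estimates, acov) (acov = inverse average-information matrix),
#' evaluates the derived parameter for each draw, and returns the SD of the
#' valid draws. Draws yielding invalid components (negative variances,
#' |correlation| > 1) are rejected and counted; more than 50% rejections is
#' an error since the asymptotic normal approximation is then unreliable.
#'
#' @param estimates numeric vector of component estimates.
#' @param acov asymptotic covariance of the estimates.
#' @param fun function of a component vector returning the derived scalar.
#' @param valid function of a component vector returning TRUE if the draw is
#'   admissible (default: all variances positive).
#' @param n_draws number of draws (default 100000).
#' @param seed integer seed.
#' @return list with \code{se}, \code{n_rejected}, \code{n_draws}.
#' @export
sample_derived_se <- function(estimates, acov, fun,
                              valid = function(th) all(th > 0),
                              n_draws = 100000, seed = 1L) {
  stopifnot(length(estimates) == nrow(acov), nrow(acov) == ncol(acov))
  set.seed(seed)
  if (all(abs(acov) < .Machine$double.eps)) {
    return(list(se = 0, n_rejected = 0L, n_draws = as.integer(n_draws)))
  }
  draws <- MASS::mvrnorm(n_draws, mu = estimates,
                         Sigma = nearest_psd(acov), tol = 1e-8)
  ok <- apply(draws, 1, valid)
  if (mean(!ok) > 0.5) {
    stop(sprintf("%.1f%% of asymptotic draws were invalid; sampling SE unreliable",
                 100 * mean(!ok)))
  }
  vals <- apply(draws[ok, , drop = FALSE], 1, fun)
  vals <- vals[is.finite(vals)]
  list(se = stats::sd(vals), n_rejected = as.integer(sum(!ok)),
       n_draws = as.integer(n_draws))
}

#' Sampling-based SE of heritability from a univariate fit
#'
#' @param fit a \code{reml_uv} object.
#' @param n_draws,seed passed to \code{\link{sample_derived_se}}.
#' @return list with \code{se}, \code{n_rejected}, \code{n_draws}.
#' @export
h2_se_sampling <- function(fit, n_draws = 100000, seed = 1L) {
  stopifnot(inherits(fit, "reml_uv"))
  sample_derived_se(c(fit$sigma_a2, fit$sigma_e2), fit$ai_inverse,
                    fun = function(th) th[1] / (th[1] + th[2]),
                    valid = function(th) th[1] >= 0 && th[2] > 0,
                    n_draws = n_draws, seed = seed)
}

#' Sampling-based SE of the genetic correlation from a bivariate fit
#'
#' @param fit a \code{reml_bv} object.
#' @param n_draws,seed passed to \code{\link{sample_derived_se}}.
#' @return list with \code{se}, \code{n_rejected}, \code{n_draws}.
#' @export
rg_se_sampling <- function(fit, n_draws = 100000, seed = 1L) {
  stopifnot(inherits(fit, "reml_bv"))
  est <- c(fit$K[1, 1], fit$K[2, 1], fit$K[2, 2],
           fit$R[1, 1], fit$R[2, 1], fit$R[2, 2])
  sample_derived_se(est, fit$ai_inverse,
                    fun = function(th) th[2] / sqrt(th[1] * th[3]),
                    valid = function(th) th[1] > 0 && th[3] > 0 &&
                      abs(th[2]) <= sqrt(th[1] * th[3]) && th[4] > 0 && th[6] > 0,
                    n_draws = n_draws, seed = seed)
}
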
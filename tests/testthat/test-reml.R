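test_that("univariate REML equals the balanced one-way ANOVA decomposition", {
  # unrelated animals, repeated records: sigma_a2/sigma_e2 have the classic
  # closed form from the between/within mean squares
  set.seed(101)
  a <- 40; k <- 5
  u <- rnorm(a, 0, sqrt(2))
  y <- rep(u, each = k) + rnorm(a * k, 0, 1)
  Z <- kronecker(diag(a), matrix(1, k, 1))
  fit <- reml_univariate(y, diag(a), Z = Z)
  grp <- rep(seq_len(a), each = k)
  msb <- anova(lm(y ~ factor(grp)))$`Mean Sq`[1]
  msw <- anova(lm(y ~ factor(grp)))$`Mean Sq`[2]
  expect_equal(fit$sigma_e2, msw, tolerance = 1e-6)
  expect_equal(fit$sigma_a2, (msb - msw) / k, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("null heritability lands at or near the boundary", {
  set.seed(102)
  cfg <- sim_config(n_founders = 400, n_generations = 3, seed = 55)
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  y <- rnorm(nrow(A), 5, 1)  # no genetic signal
  fit <- reml_univariate(y, A)
  expect_lt(fit$h2, 0.05)
})

test_that("REML estimates are invariant to the fixed-effect coding", {
  set.seed(103)
  n <- 150
  cfg <- sim_config(n_founders = n, n_generations = 1, seed = 3)
  A <- diag(n)
  grp <- factor(rep(1:3, length.out = n))
  u <- rnorm(n, 0, 1)
  y <- c(0, 1, 2)[grp] + u * 0 + rnorm(n)  # fixed-effect signal only
  Z <- kronecker(diag(n / 3), matrix(1, 3, 1))  # 3 records per animal
  Arep <- diag(n / 3)
  yr <- rep(rnorm(n / 3, 0, 1.2), each = 3) + c(0, 1, 2)[grp] + rnorm(n, 0, 0.8)
  X_ref <- model.matrix(~ grp)
  X_sum <- model.matrix(~ grp, contrasts.arg = list(grp = contr.sum))
  f1 <- reml_univariate(yr, Arep, X = X_ref, Z = Z)
  f2 <- reml_univariate(yr, Arep, X = X_sum, Z = Z)
  expect_equal(f1$sigma_a2, f2$sigma_a2, tolerance = 1e-6)
  expect_equal(f1$sigma_e2, f2$sigma_e2, tolerance = 1e-6)
  # log-likelihoods differ only by the constant log-det of the basis change
  Tm <- qr.coef(qr(X_ref), X_sum)
  expect_equal(f1$loglik - f2$loglik, log(abs(det(Tm))), tolerance = 1e-6)
})

test_that("the restricted log-likelihood never decreases across iterations", {
  set.seed(104)
  cfg <- sim_config(n_founders = 200, n_generations = 2, seed = 5)
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  u <- drop(simulate_true_breeding_values(unclass(A), 1.16, seed = 6))
  y <- u + rnorm(nrow(A), 0, sqrt(1.55))
  fit <- reml_univariate(y, A, start = c(5, 0.05))  # poor start forces work
  expect_true(all(diff(fit$trace$loglik) > -1e-9))
  expect_true(fit$converged)
})

test_that("rank-deficient fixed effects are rejected", {
  X <- cbind(1, c(rep(1, 10), rep(0, 10)), c(rep(0, 10), rep(1, 10)))
  expect_error(reml_univariate(rnorm(20), diag(20), X = X), "rank deficient")
})

test_that("bivariate REML: null correlation, duplicated trait, dense-path agreement", {
  set.seed(105)
  n <- 800
  cfg <- sim_config(n_founders = n, n_generations = 1, seed = 7)
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  K0 <- diag(c(0.5, 1.0))
  U <- simulate_true_breeding_values(unclass(A), K0, seed = 8)
  Y <- U + cbind(rnorm(n, 0, 1), rnorm(n, 0, 1.2))
  fit <- reml_bivariate(Y, A)
  expect_lt(abs(fit$rg), 0.1)
  expect_true(fit$converged)

  # duplicated trait drives the genetic correlation to 1
  Ydup <- cbind(Y[, 1], Y[, 1] + rnorm(n, 0, 0.05))
  fitd <- reml_bivariate(Ydup, A)
  expect_gt(fitd$rg, 0.95)

  # dense (missing-capable) route agrees with the eigen route on complete data
  n2 <- 120
  ped2 <- simulate_pedigree(sim_config(n_founders = 60, n_generations = 2,
                                       n_per_generation = 60, seed = 9))
  A2 <- build_A(ped2)
  K <- matrix(c(0.4, 0.25, 0.25, 0.9), 2)
  U2 <- simulate_true_breeding_values(unclass(A2), K, seed = 10)
  Y2 <- U2 + cbind(rnorm(n2, 0, 0.8), rnorm(n2, 0, 1.1))
  f_eig <- reml_bivariate(Y2, A2)
  Y2na <- Y2
  Y2na[1, 2] <- NA   # one missing record routes to the dense path
  f_den <- reml_bivariate(Y2na, A2)
  expect_equal(f_eig$K, f_den$K, tolerance = 0.15)
  expect_equal(f_eig$rg, f_den$rg, tolerance = 0.1)
})

test_that("bivariate REML recovers a known genetic correlation with missing records", {
  st <- run_recovery_study("genetic_correlation", n_animals = 400,
                           n_replicates = 3, seed = 42,
                           missing_fraction = 0.1)
  expect_equal(st$n_failed, 0)
  expect_lt(abs(st$mean - 0.42), 0.25)  # small-n sanity bound
})

test_that("asymptotic-sampling SEs behave like the delta method", {
  # zero asymptotic covariance -> SE exactly 0
  out0 <- sample_derived_se(c(1, 2), matrix(0, 2, 2), function(th) th[1] / th[2])
  expect_equal(out0$se, 0)
  # scalar case: SE of c * sigma2 is |c| * SE(sigma2)
  acov <- matrix(0.04, 1, 1)
  out <- sample_derived_se(5, acov, function(th) 3 * th[1],
                           valid = function(th) th[1] > 0,
                           n_draws = 200000, seed = 2)
  expect_equal(out$se, 3 * 0.2, tolerance = 0.01)
  # Monte-Carlo stability: doubling the draws moves the SE by < 1%
  est <- c(1.16, 1.55)
  acv <- matrix(c(0.04, -0.01, -0.01, 0.017), 2)
  h2fun <- function(th) th[1] / (th[1] + th[2])
  s1 <- sample_derived_se(est, acv, h2fun, n_draws = 1e5, seed = 3)
  s2 <- sample_derived_se(est, acv, h2fun, n_draws = 2e5, seed = 4)
  expect_lt(abs(s1$se - s2$se) / s2$se, 0.01)
  # heavily invalid draws are refused
  expect_error(
    sample_derived_se(0.001, matrix(1, 1, 1), identity,
                      valid = function(th) th[1] > 0, n_draws = 1e4, seed = 5),
    "unreliable")
})

test_that("sampling SEs from fitted objects are close to the delta-method SEs", {
  set.seed(106)
  cfg <- sim_config(n_founders = 300, n_generations = 2, seed = 15)
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  u <- drop(simulate_true_breeding_values(unclass(A), 1.16, seed = 16))
  y <- u + rnorm(nrow(A), 0, sqrt(1.55))
  fit <- reml_univariate(y, A)
  s <- h2_se_sampling(fit, n_draws = 50000, seed = 1)
  expect_equal(s$se, fit$h2_se, tolerance = 0.25 * fit$h2_se)
})
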
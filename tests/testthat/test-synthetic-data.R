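test_that("pedigree generator produces founders-only and forced-mating structures", {
  cfg <- sim_config(n_founders = 10, n_generations = 1, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10)
  expect_true(all(ped$sire == 0) && all(ped$dam == 0))

  cfg2 <- sim_config(n_founders = 2, n_generations = 2,
                     n_per_generation = 1, seed = 1)
  ped2 <- simulate_pedigree(cfg2)
  off <- ped2[ped2$generation == 1, ]
  expect_equal(sort(c(off$sire, off$dam)), c(1, 2))
})

test_that("pedigree generator is deterministic and sorted parents-first", {
  cfg <- sim_config(n_founders = 40, n_generations = 4, seed = 99)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  expect_silent(validate_pedigree(p1))
  # every parent index strictly precedes its offspring
  pos <- match(p1$sire[p1$sire != 0], p1$animal)
  expect_true(all(pos < which(p1$sire != 0)))
})

test_that("an all-female founder cohort is an impossible mating structure", {
  cfg <- sim_config(n_founders = 4, n_generations = 2, seed = 1)
  expect_error(simulate_pedigree(cfg, founder_sex = rep("F", 4)),
               "impossible mating structure")
})

test_that("gene dropping is Mendelian and preserves allele frequencies", {
  cfg <- sim_config(n_founders = 6, n_generations = 3, n_snps = 5, seed = 3)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg, founder_freq = c(1, 0, 0.5, 0.5, 0.5))
  expect_true(all(gm$geno %in% 0:2))
  # fixed loci stay fixed through the drop
  expect_true(all(gm$geno[, 1] == 2))
  expect_true(all(gm$geno[, 2] == 0))
  # 0 x 0 parents -> 0 offspring at every locus
  off <- ped[ped$sire != 0, ]
  for (i in seq_len(nrow(off))) {
    gs <- gm$geno[as.character(off$sire[i]), ]
    gd <- gm$geno[as.character(off$dam[i]), ]
    go <- gm$geno[as.character(off$animal[i]), ]
    expect_true(all(go[gs == 0 & gd == 0] == 0))
    expect_true(all(go[gs == 2 & gd == 2] == 2))
  }
  # founder frequency recovered within 3 binomial SEs at large n
  cfg2 <- sim_config(n_founders = 2000, n_generations = 1, n_snps = 1, seed = 5)
  ped2 <- simulate_pedigree(cfg2)
  gm2 <- simulate_genotypes(ped2, cfg2, founder_freq = 0.3)
  phat <- mean(gm2$geno[, 1]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 2000))
  expect_lt(abs(phat - 0.3), 3 * se)
  # determinism
  expect_identical(simulate_genotypes(ped, cfg)$geno,
                   simulate_genotypes(ped, cfg)$geno)
})

test_that("breeding values follow the configured covariance structure", {
  # zero genetic covariance -> all zero
  u0 <- simulate_true_breeding_values(diag(4), matrix(0, 2, 2), seed = 1)
  expect_true(all(u0 == 0))
  # unrelated animals: sample variance near sigma_a2 = 1.16 (3 SE bound)
  n <- 5000
  u <- simulate_true_breeding_values(diag(n), 1.16, seed = 2)
  se_var <- 1.16 * sqrt(2 / n)
  expect_lt(abs(var(drop(u)) - 1.16), 3 * se_var)
  # genetically identical animals get (numerically) identical values
  twins <- matrix(1, 2, 2)
  ut <- simulate_true_breeding_values(twins, 1.0, seed = 3)
  expect_lt(abs(ut[1] - ut[2]), 1e-3)
  # asymmetric input is rejected
  bad <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(simulate_true_breeding_values(bad, 1.0), "symmetric")
})

test_that("empirical heritability of simulated phenotypes matches the configuration", {
  # var(u)/var(y) over replicates converges to h2 = 1.16/2.71
  set.seed(10)
  n <- 400
  h2_hat <- replicate(50, {
    u <- drop(simulate_true_breeding_values(diag(n), 1.16,
                                            seed = sample.int(1e6, 1)))
    y <- u + rnorm(n, 0, sqrt(1.55))
    var(u) / var(y)
  })
  se <- sd(h2_hat) / sqrt(length(h2_hat))
  expect_lt(abs(mean(h2_hat) - 1.16 / 2.71), 3 * se + 0.01)
})

test_that("daily cow record generator honours outlier_rate and seed", {
  cfg0 <- sim_config(n_founders = 8, n_generations = 1, outlier_rate = 0,
                     seed = 21)
  tbv <- stats::setNames(rep(0, 8), paste0("a", 1:8))
  sim <- simulate_cow_daily_records(tbv, cfg0)
  expect_equal(nrow(sim$injected), 0)
  expect_equal(nrow(sim$daily), 8 * 141)
  qc <- filter_daily_records(sim$daily)
  # clean generator at outlier_rate 0: nothing beyond rare natural tails
  expect_lt(qc$report$fraction_removed, 0.01)
  # reproducibility
  sim2 <- simulate_cow_daily_records(tbv, cfg0)
  expect_identical(sim$daily, sim2$daily)
})

test_that("heifer generator gives exact growth in the noise-free limit", {
  cfg <- sim_config(n_founders = 6, n_generations = 1, seed = 4)
  tbv <- stats::setNames(rep(0, 6), paste0("h", 1:6))
  sim <- simulate_heifer_records(tbv, cfg, adg_mean = 1.09, adg_sd = 0,
                                 bw_noise_sd = 0)
  rec <- summarize_heifer(sim$serial_bw, sim$daily_dmi, sim$animals)
  expect_equal(rec$adg, rep(1.09, 6), tolerance = 1e-10)
  expect_true(all(rec$avg_age >= 206 & rec$avg_age <= 437))
  # byte-identical rerun under the same seed
  sim2 <- simulate_heifer_records(tbv, cfg, adg_mean = 1.09, adg_sd = 0,
                                  bw_noise_sd = 0)
  expect_identical(sim$daily_dmi, sim2$daily_dmi)
})

test_that("simulation config rejects invalid variance structures", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  K_bad <- matrix(c(1, 2, 2, 1), 2, 2)  # implied correlation 2
  expect_error(sim_config(genetic_covariance = K_bad), "correlation")
})
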
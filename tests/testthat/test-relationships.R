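test_that("tabular A matches textbook values and the recursive kinship oracle", {
  peds <- textbook_pedigrees()
  for (nm in names(peds)) {
    A <- build_A(peds[[nm]])
    n <- nrow(A)
    expect_equal(A[seq_len(n), seq_len(n)], kinship_oracle(peds[[nm]]),
                 tolerance = 1e-12, info = nm)
  }
  A_po <- build_A(peds$parent_offspring)
  expect_equal(A_po["1", "3"], 0.5)
  A_fs <- build_A(peds$full_sibs)
  expect_equal(A_fs["3", "4"], 0.5)
  A_hs <- build_A(peds$half_sibs)
  expect_equal(A_hs["4", "5"], 0.25)
  A_in <- build_A(peds$full_sib_mating)
  expect_equal(A_in["5", "5"], 1.25)  # F = 0.25 from a full-sib mating
  expect_equal(unname(attr(A_in, "inbreeding")["5"]), 0.25)
  A_gp <- build_A(peds$grandparent)
  expect_equal(A_gp["1", "5"], 0.25)
})

test_that("A construction is permutation-equivariant in animal labels", {
  ped <- textbook_pedigrees()$three_gen_mixed
  A <- build_A(ped)
  relab <- ped
  map <- c(10, 20, 30, 40, 50, 60)
  relab$animal <- map[relab$animal]
  relab$sire <- c(0, map)[relab$sire + 1]
  relab$dam <- c(0, map)[relab$dam + 1]
  A2 <- build_A(relab)
  n <- nrow(A)
  expect_equal(unname(A[seq_len(n), seq_len(n)]),
               unname(A2[seq_len(n), seq_len(n)]))
})

test_that("A validation and truncation behave", {
  bad <- ped_df(c(1, 2, 3), c(2, 0, 0), c(0, 0, 0))  # sire after offspring
  expect_error(build_A(bad), "before its")
  # depth cutoff: a chain of 12 generations truncated at 2 makes deep
  # ancestors base animals, shrinking the top-bottom relationship
  chain <- ped_df(1:12, c(0, 1:11), rep(0, 12))
  chain$dam <- 0
  A_full <- build_A(chain, max_generations = 12)
  A_cut <- build_A(chain, max_generations = 2)
  expect_lt(A_cut["1", "12"], A_full["1", "12"])
  expect_equal(A_cut["11", "12"], A_full["11", "12"])
})

test_that("genotype QC applies the stated filters in order with inclusive boundaries", {
  set.seed(2)
  n <- 100
  geno <- matrix(rbinom(n * 40, 2, 0.4), n, 40)
  chrom <- c("X", rep("1", 39))
  # SNP 2: call rate exactly 95% (kept); SNP 3: 94% (removed)
  geno[1:5, 2] <- NA
  geno[1:6, 3] <- NA
  # SNPs 4-6: MAF 0.01 (removed)
  for (j in 4:6) geno[, j] <- rbinom(n, 1, 0.02) * 1L
  gm <- genotype_matrix(geno, chrom)
  out <- qc_genotypes(gm)
  qc <- attr(out, "qc")
  expect_equal(qc$snps_sex_chrom, 1)
  expect_equal(qc$snps_low_call_rate, 1)
  expect_equal(qc$snps_low_maf, 3)
  expect_true("snp00002" %in% out$snp$id)   # 95% boundary kept
  expect_false("snp00003" %in% out$snp$id)  # 94% removed
  expect_false(anyNA(out$geno))             # mean-imputed
  # imputed values are the expected dosage 2p
  p2 <- mean(geno[-(1:5), 2]) / 2
  expect_equal(unname(out$geno[1, "snp00002"]), 2 * p2)
  # clean matrix passes through unchanged
  clean <- genotype_matrix(matrix(rbinom(50 * 5, 2, 0.4), 50, 5))
  out2 <- qc_genotypes(clean)
  expect_equal(out2$geno, clean$geno)
  # everything removed is an explicit failure
  mono <- genotype_matrix(matrix(0L, 10, 3))
  expect_error(qc_genotypes(mono), "all SNPs removed")
})

test_that("G matches the single-SNP hand example and duplicate-row identity", {
  gm <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1,
                               dimnames = list(c("a", "b", "c"), "s1")))
  G <- build_G(gm, frequency_source = 0.5)
  # centered dosages (-1, 0, 1); denominator 2 * 0.25 = 0.5
  expect_equal(diag(G), c(a = 2, b = 0, c = 2))
  expect_equal(G["a", "c"], -2)
  # duplicated animal: off-diagonal with the copy equals its diagonal
  set.seed(3)
  M <- matrix(rbinom(40 * 50, 2, 0.3), 40, 50)
  M[2, ] <- M[1, ]
  G2 <- build_G(genotype_matrix(M))
  expect_equal(G2[1, 2], G2[1, 1])
  expect_equal(unname(G2), unname(t(G2)))
  # monomorphic-only matrix has a zero denominator
  expect_error(build_G(genotype_matrix(matrix(2L, 5, 3))), "monomorphic")
})

test_that("G from Hardy-Weinberg genotypes has mean diagonal near 1", {
  set.seed(4)
  n <- 1000
  p <- runif(300, 0.1, 0.5)
  M <- sapply(p, function(pj) rbinom(n, 2, pj))
  G <- build_G(genotype_matrix(M))
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("realized genomic relationships track pedigree expectations", {
  cfg <- sim_config(n_founders = 180, n_generations = 3, n_snps = 800, seed = 19)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  A <- build_A(ped)
  G <- build_G(qc_genotypes(gm))
  lo <- lower.tri(A)
  slope <- coef(lm(G[lo] ~ A[lo]))[2]
  expect_lt(abs(slope - 1), 0.1)
  # A is PSD by construction
  expect_gte(min(eigen(unclass(A), symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # stabilized G is PD
  Gs <- stabilize_G(G)
  expect_gt(min(eigen(unclass(Gs), symmetric = TRUE, only.values = TRUE)$values), 0)
  # A-blending alternative is also PD
  Gb <- stabilize_G(G, A = unclass(A))
  expect_gt(min(eigen(unclass(Gb), symmetric = TRUE, only.values = TRUE)$values), 0)
})
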
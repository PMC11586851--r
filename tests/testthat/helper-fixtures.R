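# Independent A-matrix oracle: recursive kinship coefficients
# f(i,j) with memoization; A = 2f off-diagonal convention a_ij = 2 f_ij,
# a_ii = 2 f_ii = 1 + F_i. Independent of the tabular implementation.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  f <- matrix(NA_real_, n, n)
  kin <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(f[i, j])) return(f[i, j])
    val <- if (i == j) {
      s <- si[i]; d <- di[i]
      0.5 * (1 + kin(ifelse(is.na(s), 0, s), ifelse(is.na(d), 0, d)))
    } else {
      # recurse on the younger animal
      if (i < j) { tmp <- i; i2 <- j; j2 <- tmp } else { i2 <- i; j2 <- j }
      s <- si[i2]; d <- di[i2]
      0.5 * (kin(ifelse(is.na(s), 0, s), j2) + kin(ifelse(is.na(d), 0, d), j2))
    }
    f[i, j] <<- val
    f[j, i] <<- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * kin(i, j)
    if (i == j) A[i, i] <- A[i, i]  # a_ii = 2 f_ii = 1 + F_i
  }
  A
}

ped_df <- function(animal, sire, dam) {
  data.frame(animal = animal, sire = sire, dam = dam)
}

# Six small pedigrees with textbook relationship structure.
textbook_pedigrees <- function() {
  list(
    parent_offspring = ped_df(1:3, c(0, 0, 1), c(0, 0, 2)),
    full_sibs = ped_df(1:4, c(0, 0, 1, 1), c(0, 0, 2, 2)),
    half_sibs = ped_df(1:5, c(0, 0, 0, 1, 1), c(0, 0, 0, 2, 3)),
    full_sib_mating = ped_df(1:5, c(0, 0, 1, 1, 3), c(0, 0, 2, 2, 4)),
    grandparent = ped_df(1:5, c(0, 0, 1, 0, 3), c(0, 0, 2, 0, 4)),
    three_gen_mixed = ped_df(1:6, c(0, 0, 1, 1, 4, 5), c(0, 0, 2, 0, 3, 2))
  )
}

# Pedigree with four male-ancestor lines at controlled depth:
# great-grandsire (gen 0) -> grandsire -> sire -> training / candidates.
# Candidates in group g share male ancestry with the training animals no
# closer than generation g (group 4 descends from a disjoint immigrant
# line). Returns the pedigree plus the id sets.
group_structure_pedigree <- function(n_training = 60, n_per_group = 15,
                                     n_lines = 3) {
  rows <- list()
  nid <- 0L
  add <- function(sire, dam, sex) {
    s <- sire; d <- dam          # force parent ids before taking a new id
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(animal = nid, sire = s, dam = d,
                               sex = sex, stringsAsFactors = FALSE)
    nid
  }
  dam <- function() add(0L, 0L, "F")
  ggs <- replicate(n_lines, add(0L, 0L, "M"))
  gs1 <- vapply(ggs, function(g) add(g, dam(), "M"), 0L)   # grandsires of training
  gs2 <- vapply(ggs, function(g) add(g, dam(), "M"), 0L)   # other sons of GGS
  s_train <- vapply(gs1, function(g) add(g, dam(), "M"), 0L)
  s_g2 <- vapply(gs1, function(g) add(g, dam(), "M"), 0L)  # share grandsire only
  s_g3 <- vapply(gs2, function(g) add(g, dam(), "M"), 0L)  # share great-grandsire only
  iggs <- add(0L, 0L, "M")                                  # immigrant line
  igs <- add(iggs, dam(), "M")
  s_g4 <- replicate(n_lines, add(igs, dam(), "M"))
  training <- vapply(seq_len(n_training), function(i)
    add(s_train[1 + (i - 1) %% n_lines], dam(), "F"), 0L)
  cand <- function(sires) vapply(seq_len(n_per_group), function(i)
    add(sires[1 + (i - 1) %% length(sires)], dam(), "F"), 0L)
  g1 <- cand(s_train)
  g2 <- cand(s_g2)
  g3 <- cand(s_g3)
  g4 <- cand(s_g4)
  ped <- do.call(rbind, rows)
  list(pedigree = ped, training = training,
       groups = list(`1` = g1, `2` = g2, `3` = g3, `4` = g4))
}

# Deterministic clean cow daily records: linear BW, flat MY/fat/protein,
# DMI with optional noise. One trial, one lactation.
make_cow_daily <- function(n_cows = 4, dims = 100:240, dmi_noise = 0,
                           bw_slope = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_cows), function(i) {
    data.frame(animal_id = paste0("cow", i), trial = 1L, lactation = 1L,
               dim = dims, age = 900 + dims,
               dmi = 20 + 0.2 * i + rnorm(length(dims), 0, dmi_noise),
               my = 30 + 0.1 * i + rnorm(length(dims), 0, dmi_noise),
               fat_pct = 4.2, prot_pct = 3.3,
               bw = 650 + 5 * i + bw_slope * (dims - min(dims)) +
                 rnorm(length(dims), 0, dmi_noise),
               stringsAsFactors = FALSE)
  }))
}

# Small genotyped herd shared across GBLUP/cohort tests.
small_herd <- function(n_founders = 60, n_generations = 3, n_snps = 400,
                       seed = 11) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_snps = n_snps, seed = seed)
  ped <- simulate_pedigree(cfg)
  gm <- simulate_genotypes(ped, cfg)
  G <- stabilize_G(build_G(qc_genotypes(gm)))
  list(cfg = cfg, ped = ped, gm = gm, G = G, A = build_A(ped))
}
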
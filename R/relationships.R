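#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds A by the tabular method over a parents-first pedigree:
#' a_ii = 1 + F_i with inbreeding F_i = a(sire_i, dam_i)/2, and
#' a_ij = (a(j, sire_i) + a(j, dam_i))/2; unknown parents contribute zero
#' (the base population is taken as unrelated and non-inbred). Pedigree
#' depth can be truncated: animals more than \code{max_generations} below
#' the deepest generation are treated as base animals.
#'
#' @param pedigree data.frame \code{animal, sire, dam} sorted parents-first.
#' @param max_generations ancestor-depth cutoff (default 10).
#' @return symmetric matrix of class \code{relationship_matrix} with
#'   dimnames = animal ids, \code{kind} attribute "pedigree" and an
#'   \code{inbreeding} attribute (diag - 1).
#' @export
build_A <- function(pedigree, max_generations = 10) {
  validate_pedigree(pedigree)
  n <- nrow(pedigree)
  id <- as.character(pedigree$animal)
  si <- match(pedigree$sire, pedigree$animal)  # NA when unknown
  di <- match(pedigree$dam, pedigree$animal)
  # ancestor-depth truncation: generation = 1 + max(parent generations)
  gen <- integer(n)
  for (i in seq_len(n)) {
    gp <- c(if (!is.na(si[i])) gen[si[i]], if (!is.na(di[i])) gen[di[i]])
    gen[i] <- if (length(gp)) 1L + max(gp) else 0L
  }
  cut <- max(gen) - max_generations
  if (cut >= 0) {
    base <- gen <= cut
    si[base] <- NA
    di[base] <- NA
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- numeric(i - 1)
      if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
      if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  structure(A, class = c("relationship_matrix", "matrix"), kind = "pedigree",
            inbreeding = stats::setNames(diag(A) - 1, id))
}

#' Genotype quality control
#'
#' Applies the standard marker filters in order: (1) drop sex chromosomes;
#' (2) drop SNPs with call rate below \code{snp_call_rate} (a call rate of
#' exactly the threshold is kept); (3) drop SNPs with minor allele frequency
#' below \code{maf} (computed from non-missing calls); (4) drop animals with
#' genotype call rate below \code{animal_call_rate}. Remaining missing
#' genotypes are replaced by their expected dosage 2 p_j (mean imputation).
#'
#' @param gm a \code{genotype_matrix}.
#' @param snp_call_rate minimum SNP call rate kept.
#' @param maf minimum minor allele frequency kept.
#' @param animal_call_rate minimum animal call rate kept.
#' @param drop_sex_chromosomes drop SNPs labelled "X" or "Y".
#' @return the filtered, imputed-complete \code{genotype_matrix}; QC counts
#'   in attribute \code{qc} (snps/animals removed per filter).
#' @export
qc_genotypes <- function(gm, snp_call_rate = 0.95, maf = 0.05,
                         animal_call_rate = 0.95,
                         drop_sex_chromosomes = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  geno <- gm$geno
  snp <- gm$snp
  qc <- list()

  if (drop_sex_chromosomes) {
    sex <- snp$chrom %in% c("X", "Y", "x", "y")
    qc$snps_sex_chrom <- sum(sex)
    geno <- geno[, !sex, drop = FALSE]
    snp <- snp[!sex, , drop = FALSE]
  }
  cr <- colMeans(!is.na(geno))
  low_cr <- cr < snp_call_rate
  qc$snps_low_call_rate <- sum(low_cr)
  geno <- geno[, !low_cr, drop = FALSE]
  snp <- snp[!low_cr, , drop = FALSE]

  p <- colMeans(geno, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  low_maf <- mafs < maf
  qc$snps_low_maf <- sum(low_maf)
  geno <- geno[, !low_maf, drop = FALSE]
  snp <- snp[!low_maf, , drop = FALSE]

  if (ncol(geno) == 0) stop("all SNPs removed by quality control")

  acr <- rowMeans(!is.na(geno))
  low_acr <- acr < animal_call_rate
  qc$animals_low_call_rate <- sum(low_acr)
  geno <- geno[!low_acr, , drop = FALSE]
  if (nrow(geno) == 0) stop("all animals removed by quality control")

  p <- colMeans(geno, na.rm = TRUE) / 2
  if (anyNA(geno)) {
    miss <- which(is.na(geno), arr.ind = TRUE)
    geno[miss] <- 2 * p[miss[, 2]]
  }
  out <- structure(list(geno = geno, snp = snp, founder_freq = gm$founder_freq),
                   class = "genotype_matrix")
  attr(out, "qc") <- qc
  out
}

#' VanRaden genomic relationship matrix
#'
#' G = (M - 2P)(M - 2P)' / (2 sum_j p_j (1 - p_j)), where M is the animals x
#' SNPs dosage matrix and column j of P holds the frequency p_j of the
#' counted allele. Base-population frequencies are unobservable; by default
#' p is computed from the genotyped set (which centres G so its mean
#' diagonal is ~1), with an option to supply external frequencies.
#'
#' @param gm a QC'd, complete \code{genotype_matrix}.
#' @param frequency_source "observed" or a numeric vector of frequencies,
#'   one per SNP.
#' @return symmetric matrix of class \code{relationship_matrix}, kind
#'   "genomic"; the frequencies used are attached as attribute \code{p}.
#' @export
build_G <- function(gm, frequency_source = "observed") {
  stopifnot(inherits(gm, "genotype_matrix"))
  M <- gm$geno
  if (anyNA(M)) stop("genotype matrix contains missing values; run qc_genotypes first")
  if (nrow(M) < 2) stop("need at least 2 animals")
  if (identical(frequency_source, "observed")) {
    p <- colMeans(M) / 2
  } else {
    p <- as.numeric(frequency_source)
    stopifnot(length(p) == ncol(M), all(p >= 0), all(p <= 1))
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic at the supplied frequencies; G denominator is zero")
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / denom
  structure(G, class = c("relationship_matrix", "matrix"), kind = "genomic",
            p = p)
}

#' Stabilize a genomic relationship matrix for inversion
#'
#' Raw G is singular whenever animals are genotypically identical (clones,
#' duplicates) or animals outnumber effective markers. Two standard remedies
#' are provided: adding a small constant to the diagonal (default
#' \code{epsilon = 0.01}) or blending with the pedigree matrix
#' (\code{weight * G + (1 - weight) * A}).
#'
#' @param G genomic relationship matrix.
#' @param epsilon diagonal shift.
#' @param A optional pedigree relationship matrix (same animals, same order).
#' @param weight blending weight on G when \code{A} is supplied.
#' @return stabilized matrix, attributes preserved.
#' @export
stabilize_G <- function(G, epsilon = 0.01, A = NULL, weight = 0.95) {
  out <- if (!is.null(A)) {
    stopifnot(all(dim(A) == dim(G)))
    weight * G + (1 - weight) * A
  } else {
    G + diag(epsilon, nrow(G))
  }
  attributes(out) <- attributes(G)[c("dim", "dimnames", "class", "kind", "p")]
  out
}
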
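#' Simulate SNP genotypes by gene dropping
#'
#' Founder genotypes at marker j are drawn as Binomial(2, p_j) with p_j
#' uniform on the configured founder-frequency range; each offspring
#' receives one allele from its sire and one from its dam, sampled from the
#' parent's allele dosage (Mendelian gene dropping). Genotypes are coded
#' 0/1/2 as copies of the counted allele. Markers are cycled over autosomes
#' 1..n_chromosomes.
#'
#' @param pedigree pedigree data.frame sorted parents-first.
#' @param config a \code{\link{sim_config}}.
#' @param founder_freq optional vector of founder allele frequencies, one
#'   per SNP (overrides the uniform draw; useful for fixation tests).
#' @return an object of class \code{genotype_matrix}: list with
#'   \code{geno} (animals x SNPs integer matrix, rownames = animal ids),
#'   \code{snp} (data.frame id/chrom), \code{founder_freq}.
#' @export
simulate_genotypes <- function(pedigree, config, founder_freq = NULL) {
  validate_pedigree(pedigree)
  set.seed(config$seed + 1L)
  m <- config$n_snps
  if (is.null(founder_freq)) {
    founder_freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  }
  stopifnot(length(founder_freq) == m, all(founder_freq >= 0),
            all(founder_freq <= 1))
  n <- nrow(pedigree)
  geno <- matrix(0L, n, m, dimnames = list(pedigree$animal, NULL))
  row_of <- match(pedigree$animal, pedigree$animal)
  idx_of <- stats::setNames(seq_len(n), pedigree$animal)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]
    d <- pedigree$dam[i]
    if (s == 0 && d == 0) {
      geno[i, ] <- stats::rbinom(m, 2L, founder_freq)
    } else {
      gs <- geno[idx_of[[as.character(s)]], ]
      gd <- geno[idx_of[[as.character(d)]], ]
      geno[i, ] <- stats::rbinom(m, 1L, gs / 2) + stats::rbinom(m, 1L, gd / 2)
    }
  }
  snp <- data.frame(
    id = sprintf("snp%05d", seq_len(m)),
    chrom = as.character(rep_len(seq_len(config$n_chromosomes), m)),
    stringsAsFactors = FALSE)
  colnames(geno) <- snp$id
  structure(list(geno = geno, snp = snp, founder_freq = founder_freq),
            class = "genotype_matrix")
}

#' Construct a genotype_matrix from raw pieces
#'
#' @param geno animals x SNPs matrix in 0/1/2 coding (NA = missing),
#'   rownames = animal ids.
#' @param chrom chromosome label per SNP (default all "1").
#' @return a \code{genotype_matrix}.
#' @export
genotype_matrix <- function(geno, chrom = rep("1", ncol(geno))) {
  stopifnot(is.matrix(geno), length(chrom) == ncol(geno))
  ok <- geno %in% c(0, 1, 2) | is.na(geno)
  if (!all(ok)) stop("genotypes must be 0/1/2 or NA")
  if (is.null(rownames(geno))) rownames(geno) <- seq_len(nrow(geno))
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("snp%05d", seq_len(ncol(geno)))
  structure(list(geno = geno,
                 snp = data.frame(id = colnames(geno), chrom = as.character(chrom),
                                  stringsAsFactors = FALSE),
                 founder_freq = NULL),
            class = "genotype_matrix")
}

#' Observed allele frequencies of the counted allele
#'
#' @param gm a \code{genotype_matrix}.
#' @return per-SNP frequency of the counted allele among non-missing calls.
#' @export
allele_frequencies <- function(gm) {
  colMeans(gm$geno, na.rm = TRUE) / 2
}

#' Write genotypes as plain text
#'
#' Writes the integer matrix as whitespace-delimited text with animal ids in
#' the first column (one row per animal), plus a PLINK-style transposed
#' variant (one row per SNP: id, chrom, then genotypes).
#'
#' @param gm a \code{genotype_matrix}.
#' @param path base path; \code{<path>.txt} and \code{<path>.tped.txt} are
#'   written.
#' @return invisibly, the two paths.
#' @export
write_genotypes <- function(gm, path) {
  p1 <- paste0(path, ".txt")
  df <- data.frame(animal = rownames(gm$geno), gm$geno, check.names = FALSE)
  utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(path, ".tped.txt")
  tdf <- data.frame(id = gm$snp$id, chrom = gm$snp$chrom,
                    t(gm$geno), check.names = FALSE)
  utils::write.table(tdf, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
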
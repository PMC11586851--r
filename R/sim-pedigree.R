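#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; each later generation is
#' produced by mating a small set of sires (reused across dams, giving the
#' paternal half-sib families that relationship-based cohort analyses need)
#' to dams drawn from the previous generation. Sexes are assigned as a
#' balanced random permutation (50/50), so a viable mating structure exists
#' whenever both sexes are present.
#'
#' @param config a \code{\link{sim_config}}.
#' @param founder_sex optional character vector of founder sexes
#'   ("M"/"F"); overrides the balanced random assignment.
#' @return a \code{data.frame} with columns \code{animal}, \code{sire},
#'   \code{dam} (0 = unknown), \code{sex} and \code{generation}, sorted so
#'   every parent precedes its offspring.
#' @export
simulate_pedigree <- function(config, founder_sex = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n0 <- config$n_founders
  if (is.null(founder_sex)) {
    founder_sex <- sample(rep(c("M", "F"), length.out = n0))
  } else {
    stopifnot(length(founder_sex) == n0, all(founder_sex %in% c("M", "F")))
  }
  ped <- data.frame(animal = seq_len(n0), sire = 0L, dam = 0L,
                    sex = founder_sex, generation = 0L,
                    stringsAsFactors = FALSE)
  if (config$n_generations > 1) {
    for (g in seq_len(config$n_generations - 1)) {
      prev <- ped[ped$generation == g - 1L, ]
      males <- prev$animal[prev$sex == "M"]
      females <- prev$animal[prev$sex == "F"]
      if (length(males) == 0 || length(females) == 0) {
        stop(sprintf(
          "impossible mating structure: generation %d has %d males and %d females",
          g - 1L, length(males), length(females)))
      }
      n_off <- config$n_per_generation
      sires <- sample(males, min(config$n_sires, length(males)))
      off_sire <- sample(sires, n_off, replace = TRUE)
      off_dam <- sample(females, n_off, replace = length(females) < n_off)
      ids <- max(ped$animal) + seq_len(n_off)
      ped <- rbind(ped, data.frame(
        animal = ids, sire = off_sire, dam = off_dam,
        sex = sample(rep(c("M", "F"), length.out = n_off)),
        generation = g, stringsAsFactors = FALSE))
    }
  }
  rownames(ped) <- NULL
  validate_pedigree(ped)
  ped
}

#' Validate a pedigree table
#'
#' Checks the parents-before-offspring ordering the tabular relationship
#' method requires: sires and dams are either 0 (unknown) or appear earlier
#' in the table than their offspring.
#'
#' @param pedigree data.frame with \code{animal}, \code{sire}, \code{dam}.
#' @return the pedigree, invisibly; errors on violation.
#' @export
validate_pedigree <- function(pedigree) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(pedigree)))
  if (anyDuplicated(pedigree$animal)) stop("duplicated animal ids in pedigree")
  for (col in c("sire", "dam")) {
    p <- pedigree[[col]]
    known <- p != 0
    idx <- match(p[known], pedigree$animal)
    if (anyNA(idx)) {
      stop(sprintf("%s ids not present in pedigree: %s", col,
                   paste(utils::head(p[known][is.na(idx)]), collapse = ", ")))
    }
    if (any(idx >= which(known))) {
      bad <- pedigree$animal[known][idx >= which(known)][1]
      stop(sprintf("animal appears before its %s in the pedigree (offspring of %s)",
                   col, bad))
    }
  }
  invisible(pedigree)
}

#' Write / read a 3-column pedigree text file
#'
#' Tab-delimited \code{animal sire dam} with 0 for unknown parents.
#'
#' @param pedigree pedigree data.frame.
#' @param path file path.
#' @return \code{write_pedigree}: the path, invisibly.
#'   \code{read_pedigree}: a pedigree data.frame.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree[, c("animal", "sire", "dam")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t")
  validate_pedigree(ped)
  ped
}
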
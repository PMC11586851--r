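# Sire-line male ancestors of an animal: sire, sire of sire, ... up to
# `depth` generations. Returns NA where the lineage is unrecorded.
.sire_line <- function(pedigree, ids, depth) {
  sire_of <- stats::setNames(pedigree$sire, pedigree$animal)
  out <- matrix(NA_integer_, length(ids), depth,
                dimnames = list(as.character(ids), paste0("gen", seq_len(depth))))
  cur <- ids
  for (g in seq_len(depth)) {
    cur <- unname(sire_of[as.character(cur)])
    cur[is.na(cur) | cur == 0] <- NA
    out[, g] <- cur
  }
  out
}

# Male ancestors at each generation, optionally including maternal-line
# males (sire of dam, etc.) via full recursion over male ancestors.
.male_ancestors <- function(pedigree, ids, depth, include_maternal = FALSE) {
  if (!include_maternal) {
    anc <- .sire_line(pedigree, ids, depth)
    return(lapply(seq_len(depth), function(g) unique(anc[!is.na(anc[, g]), g])))
  }
  sire_of <- stats::setNames(pedigree$sire, pedigree$animal)
  dam_of <- stats::setNames(pedigree$dam, pedigree$animal)
  levels <- vector("list", depth)
  cur <- as.list(ids)
  for (g in seq_len(depth)) {
    nxt <- lapply(cur, function(v) {
      parents <- c(unname(sire_of[as.character(v)]), unname(dam_of[as.character(v)]))
      parents[!is.na(parents) & parents != 0]
    })
    sires <- lapply(cur, function(v) {
      s <- unname(sire_of[as.character(v)])
      s[!is.na(s) & s != 0]
    })
    levels[[g]] <- unique(unlist(sires))
    cur <- nxt
  }
  levels
}

#' Assign prediction animals to relationship groups
#'
#' Classifies candidate animals by the closest male-ancestor generation
#' shared with the training population: Group 1 shares a sire, Group 2
#' shares a grandsire but no sire, Group 3 shares a great-grandsire but no
#' sire or grandsire, and Group 4 shares none of the three. By default only
#' sire-line male ancestors (sire, sire of sire, ...) are compared, since
#' the grouping is defined through male ancestry; maternal-line male
#' ancestors can be included. Candidates whose three-generation male
#' ancestry is not fully recorded are excluded and reported.
#'
#' @param pedigree pedigree data.frame (\code{animal, sire, dam}).
#' @param training_ids training-population animal ids.
#' @param candidate_ids candidate (prediction) animal ids.
#' @param include_maternal also compare maternal-line male ancestors.
#' @return list with \code{groups} (data.frame \code{animal_id, group,
#'   evidence}) and \code{unresolved} (candidate ids with incomplete male
#'   ancestry).
#' @export
assign_groups <- function(pedigree, training_ids, candidate_ids,
                          include_maternal = FALSE) {
  validate_pedigree(pedigree)
  tset <- .male_ancestors(pedigree, training_ids, 3, include_maternal)
  cand_anc <- if (include_maternal) {
    lapply(candidate_ids, function(id)
      .male_ancestors(pedigree, id, 3, TRUE))
  } else {
    anc <- .sire_line(pedigree, candidate_ids, 3)
    lapply(seq_along(candidate_ids), function(i)
      lapply(1:3, function(g) anc[i, g][!is.na(anc[i, g])]))
  }
  resolved <- vapply(cand_anc, function(a) all(lengths(a) > 0), logical(1))
  unresolved <- candidate_ids[!resolved]
  rows <- lapply(which(resolved), function(i) {
    a <- cand_anc[[i]]
    shared <- vapply(1:3, function(g) any(a[[g]] %in% tset[[g]]), logical(1))
    grp <- if (shared[1]) 1L else if (shared[2]) 2L else if (shared[3]) 3L else 4L
    ev <- if (grp < 4) {
      lev <- c("sire", "grandsire", "great-grandsire")[grp]
      matched <- intersect(a[[grp]], tset[[grp]])
      sprintf("shared %s: %s", lev, paste(matched, collapse = ","))
    } else "no shared male ancestors within 3 generations"
    data.frame(animal_id = candidate_ids[i], group = grp, evidence = ev,
               stringsAsFactors = FALSE)
  })
  groups <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = integer(0), group = integer(0),
               evidence = character(0))
  rownames(groups) <- NULL
  list(groups = groups, unresolved = unresolved)
}

#' Count close relatives in the training population
#'
#' A candidate's close relatives are the training animals whose genomic
#' relationship with it is at least \code{threshold} (inclusive). The
#' default 0.45 corresponds to a first-degree relationship (0.5 for
#' parent-offspring or full sibs) minus an estimation error allowance of
#' 0.05.
#'
#' @param G_cross candidates x training genomic relationship block.
#' @param threshold inclusive lower bound (default 0.45).
#' @return integer vector of counts per candidate.
#' @export
count_close_relatives <- function(G_cross, threshold = 0.45) {
  G_cross <- as.matrix(G_cross)
  as.integer(rowSums(G_cross >= threshold))
}

#' Power-curve fit of reliability on close-relative count
#'
#' Nonlinear least squares of rel = a * (n + 1)^b, where n is the number of
#' close relatives; the +1 offset makes animals with zero close relatives
#' usable. Initialization is deterministic: a log-log OLS start plus a fixed
#' grid of exponents, keeping the converged fit with the lowest residual sum
#' of squares.
#'
#' @param reliability vector of reliabilities.
#' @param n_relatives vector of close-relative counts (>= 0).
#' @param offset added to the count before exponentiation (default 1).
#' @return list of class \code{power_curve_fit}: \code{a}, \code{b},
#'   \code{rss}, \code{n}, \code{fitted}.
#' @export
fit_power_curve <- function(reliability, n_relatives, offset = 1) {
  stopifnot(length(reliability) == length(n_relatives),
            length(reliability) >= 3, all(n_relatives >= 0))
  x <- n_relatives + offset
  y <- reliability
  starts <- list()
  pos <- y > 0
  if (sum(pos) >= 2 && stats::var(log(x[pos])) > 0) {
    cf <- stats::lm.fit(cbind(1, log(x[pos])), log(y[pos]))$coefficients
    starts[[1]] <- c(a = exp(cf[1]), b = cf[2])
  }
  for (b0 in c(-0.5, 0, 0.1, 0.3, 0.5, 1)) {
    a0 <- mean(y) / mean(x^b0)
    starts[[length(starts) + 1]] <- c(a = a0, b = b0)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nls(y ~ a * x^b, start = list(a = unname(s["a"]), b = unname(s["b"])),
                 control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- stats::coef(fit)
        best <- list(a = unname(cf["a"]), b = unname(cf["b"]), rss = rss,
                     n = length(y), fitted = stats::fitted(fit))
      }
    }
  }
  if (is.null(best)) stop("power-curve fit failed to converge from every start")
  structure(best, class = "power_curve_fit")
}

#' Heifer-to-cow efficiency re-ranking cross-tabulation
#'
#' Classifies animals into most efficient (lowest RFI breeding values),
#' medium, and least efficient (highest) classes at both life stages and
#' cross-tabulates the heifer class against the cow class as row
#' percentages. Extreme class sizes default to \code{floor(n * cutoff)};
#' explicit sizes can be given. Ties are broken by position in the input
#' (stable order).
#'
#' @param ebv_heifer,ebv_cow breeding values of the same animals at the two
#'   stages (lower = more efficient).
#' @param cutoffs fractions (most, medium, least); must sum to 1.
#' @param class_sizes optional explicit c(most, least) counts, overriding
#'   the cutoffs.
#' @return list of class \code{ranking_crosstab}: \code{percent} (3x3 row
#'   percentages, rows = heifer class), \code{counts}, \code{class_sizes}.
#' @export
rank_cross_tab <- function(ebv_heifer, ebv_cow, cutoffs = c(0.10, 0.80, 0.10),
                           class_sizes = NULL) {
  n <- length(ebv_heifer)
  stopifnot(length(ebv_cow) == n, abs(sum(cutoffs) - 1) < 1e-8)
  if (is.null(class_sizes)) {
    class_sizes <- c(most = floor(n * cutoffs[1]), least = floor(n * cutoffs[3]))
  } else {
    class_sizes <- c(most = class_sizes[1], least = class_sizes[2])
  }
  if (class_sizes["most"] < 1 || class_sizes["least"] < 1 ||
      sum(class_sizes) > n) {
    stop("too few animals for the requested class resolution")
  }
  classify <- function(ebv) {
    r <- rank(ebv, ties.method = "first")
    cls <- rep("medium", n)
    cls[r <= class_sizes["most"]] <- "most"
    cls[r > n - class_sizes["least"]] <- "least"
    factor(cls, levels = c("most", "medium", "least"))
  }
  ch <- classify(ebv_heifer)
  cc <- classify(ebv_cow)
  counts <- table(heifer = ch, cow = cc)
  percent <- sweep(counts, 1, pmax(rowSums(counts), 1), "/") * 100
  structure(list(percent = unclass(percent), counts = unclass(counts),
                 class_sizes = class_sizes),
            class = "ranking_crosstab")
}

#' @export
print.ranking_crosstab <- function(x, ...) {
  cat("Heifer-to-cow efficiency re-ranking (row %):\n")
  print(round(x$percent, 1))
  invisible(x)
}
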
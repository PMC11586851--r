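#' Run the full synthetic-herd evaluation pipeline
#'
#' Orchestrates the stages in dependency order: simulate (pedigree,
#' genotypes, breeding values, daily records), phenotypes (daily-record QC,
#' trait summaries, heifer and cow RFI), matrices (pedigree A, genomic G),
#' reml (univariate cow-RFI components on A, bivariate heifer x cow fit),
#' gblup (training MME on G, indirect prediction, reliabilities) and
#' cohorts (relationship groups, close relatives, power curve, re-ranking).
#' All randomness descends from \code{config$seed} via fixed per-stage
#' offsets, so a rerun with the same config reproduces every output.
#'
#' @param config a \code{\link{sim_config}}.
#' @param outdir output directory (created if missing); CSV/JSON outputs and
#'   the run report are written there.
#' @param stages character vector of stages to run (prefix-closed: each
#'   stage needs its predecessors within the same call).
#' @param training_fraction fraction of final-generation animals given cow
#'   phenotypes (the rest form the prediction population).
#' @return a \code{run_report} list: per-stage record counts, QC summary,
#'   estimates, output-file manifest with MD5 hashes, wall time.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "phenotypes", "matrices",
                                    "reml", "gblup", "cohorts"),
                         training_fraction = 0.7) {
  stopifnot(inherits(config, "sim_config"))
  allowed <- c("simulate", "phenotypes", "matrices", "reml", "gblup", "cohorts")
  stages <- match.arg(stages, allowed, several.ok = TRUE)
  need <- allowed[seq_len(max(match(stages, allowed)))]
  if (!all(need %in% stages)) {
    stop(sprintf("stage '%s' requires earlier stage(s): %s",
                 stages[which.max(match(stages, allowed))],
                 paste(setdiff(need, stages), collapse = ", ")))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  report <- list(config_seed = config$seed, stages = stages)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  ## simulate
  ped <- simulate_pedigree(config)
  gm <- simulate_genotypes(ped, config)
  A <- build_A(ped)
  tbv <- simulate_true_breeding_values(A, config$genetic_covariance,
                                       seed = config$seed + 10L)
  write_pedigree(ped, file.path(outdir, "pedigree.tsv"))
  files <- c(files, file.path(outdir, "pedigree.tsv"))
  files <- c(files, write_genotypes(gm, file.path(outdir, "genotypes")))
  non_founder <- ped$animal[ped$generation > 0]
  n_pheno <- max(2, round(training_fraction * length(non_founder)))
  pheno_ids <- as.character(non_founder[seq_len(n_pheno)])
  pred_ids <- setdiff(as.character(non_founder), pheno_ids)
  cow_sim <- simulate_cow_daily_records(
    stats::setNames(tbv[pheno_ids, "rfi_cow"], pheno_ids), config)
  hfr_sim <- simulate_heifer_records(
    stats::setNames(tbv[pheno_ids, "rfi_heifer"], pheno_ids), config)
  wr(cow_sim$daily, "cow_daily.csv")
  report$simulate <- list(n_animals = nrow(ped), n_snps = config$n_snps,
                          n_phenotyped = length(pheno_ids),
                          n_prediction = length(pred_ids),
                          n_daily_records = nrow(cow_sim$daily))
  if (!"phenotypes" %in% stages) return(.finish_report(report, files, outdir, t0))

  ## phenotypes
  qc <- filter_daily_records(cow_sim$daily)
  cow_rec <- summarize_cow(qc$daily)
  cow_rfi <- fit_cow_rfi(cow_rec)
  hfr_rec <- summarize_heifer(hfr_sim$serial_bw, hfr_sim$daily_dmi,
                              hfr_sim$animals)
  hfr_rfi <- fit_heifer_rfi(hfr_rec)
  wr(cow_rec, "cow_records.csv")
  wr(cow_rfi, "rfi_cow.csv")
  wr(hfr_rec, "heifer_records.csv")
  wr(hfr_rfi, "rfi_heifer.csv")
  write_qc_report(qc$report, file.path(outdir, "qc_report.json"))
  files <- c(files, file.path(outdir, "qc_report.json"))
  report$phenotypes <- list(n_cows = nrow(cow_rec), n_heifers = nrow(hfr_rec),
                            fraction_daily_removed = qc$report$fraction_removed)
  if (!"matrices" %in% stages) return(.finish_report(report, files, outdir, t0))

  ## matrices
  gm_qc <- qc_genotypes(gm)
  G <- build_G(gm_qc)
  report$matrices <- list(n_snps_after_qc = ncol(gm_qc$geno),
                          mean_G_diag = mean(diag(G)),
                          mean_A_diag = mean(diag(A)))
  if (!"reml" %in% stages) return(.finish_report(report, files, outdir, t0))

  ## reml
  ids <- cow_rfi$animal_id
  A_cow <- A[ids, ids]
  uv <- reml_univariate(cow_rfi$rfi, A_cow)
  both <- intersect(cow_rfi$animal_id, hfr_rfi$animal_id)
  Y <- cbind(rfi_heifer = hfr_rfi$rfi[match(both, hfr_rfi$animal_id)],
             rfi_cow = cow_rfi$rfi[match(both, cow_rfi$animal_id)])
  bv <- reml_bivariate(Y, A[both, both])
  est <- list(sigma_a2 = uv$sigma_a2, sigma_e2 = uv$sigma_e2, h2 = uv$h2,
              h2_se = uv$h2_se, rg = bv$rg, rg_se = bv$rg_se)
  jsonlite::write_json(est, file.path(outdir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(outdir, "estimates.json"))
  report$reml <- est
  if (!"gblup" %in% stages) return(.finish_report(report, files, outdir, t0))

  ## gblup
  Gs <- stabilize_G(G)
  train <- intersect(pheno_ids, rownames(Gs))
  pred <- intersect(pred_ids, rownames(Gs))
  yv <- cow_rfi$rfi[match(train, cow_rfi$animal_id)]
  gebv <- gblup_predict(yv, Gs, train, pred, uv$sigma_a2, uv$sigma_e2)
  wr(gebv, "gebv.csv")
  rel_t <- mean(gebv$reliability[gebv$population == "training"])
  rel_p <- mean(gebv$reliability[gebv$population == "prediction"])
  report$gblup <- list(mean_rel_training = rel_t, mean_rel_prediction = rel_p)
  if (!"cohorts" %in% stages) return(.finish_report(report, files, outdir, t0))

  ## cohorts
  grp <- assign_groups(ped, train, pred)
  G_cross <- Gs[pred, train, drop = FALSE]
  n_rel <- count_close_relatives(G_cross)
  rel_pred <- gebv$reliability[match(pred, gebv$animal_id)]
  pc <- tryCatch(fit_power_curve(rel_pred, n_rel), error = function(e) NULL)
  xt <- rank_cross_tab(hfr_rfi$rfi[match(both, hfr_rfi$animal_id)],
                       cow_rfi$rfi[match(both, cow_rfi$animal_id)])
  cohort_df <- data.frame(animal_id = pred, n_close_relatives = n_rel,
                          reliability = rel_pred,
                          group = grp$groups$group[match(pred, grp$groups$animal_id)])
  wr(cohort_df, "cohorts.csv")
  report$cohorts <- list(
    group_counts = as.list(table(grp$groups$group)),
    unresolved = length(grp$unresolved),
    power_curve = if (!is.null(pc)) list(a = pc$a, b = pc$b) else NULL,
    crosstab_percent = xt$percent)
  .finish_report(report, files, outdir, t0)
}

.finish_report <- function(report, files, outdir, t0) {
  report$manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  jsonlite::write_json(
    report[setdiff(names(report), "manifest")],
    file.path(outdir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' Replicate parameter-recovery study
#'
#' Simulates data under the animal model at a configured variance structure
#' and refits it, replicating the data draw over a fixed pedigree.
#' \code{kind = "heritability"}: phenotypes y = u + e with
#' u ~ N(0, A sigma_a2), e ~ N(0, I sigma_e2); the univariate AI-REML
#' heritability estimate is collected per replicate.
#' \code{kind = "genetic_correlation"}: two-trait records with
#' u ~ N(0, A (x) K) and independent residuals e ~ N(0, R (x) I) (R
#' diagonal by default); the bivariate AI-REML genetic-correlation estimate
#' is collected. The pedigree is simulated once (three generations by
#' default) and its relationship eigendecomposition reused; replicate k uses
#' seed \code{seed + k}.
#'
#' @param kind "heritability" or "genetic_correlation".
#' @param n_animals total pedigree size.
#' @param n_replicates number of data replicates (>= 2).
#' @param seed base seed; replicate k draws with seed + k.
#' @param sigma_a2,sigma_e2 univariate components (kind "heritability").
#' @param K,R 2x2 genetic and residual covariances (kind
#'   "genetic_correlation").
#' @param n_generations pedigree generations (default 3).
#' @param missing_fraction fraction of animals with the second trait
#'   unobserved (kind "genetic_correlation"; routed to the dense REML path
#'   when > 0).
#' @return list of class \code{recovery_study}: \code{replicates}
#'   (data.frame of per-replicate estimates), \code{mean}, \code{empirical_se}
#'   (SD of replicate estimates / sqrt(replicates)), \code{sd}, \code{truth},
#'   \code{n_failed}. More than 20% failed replicates is an error.
#' @export
run_recovery_study <- function(kind = c("heritability", "genetic_correlation"),
                               n_animals, n_replicates, seed = 1L,
                               sigma_a2 = 1.16, sigma_e2 = 1.55,
                               K = NULL, R = NULL, n_generations = 3,
                               missing_fraction = 0) {
  kind <- match.arg(kind)
  stopifnot(n_replicates >= 2)
  per <- n_animals %/% n_generations
  cfg <- sim_config(n_founders = n_animals - (n_generations - 1) * per,
                    n_per_generation = per, n_generations = n_generations,
                    n_snps = 2, seed = as.integer(seed))
  ped <- simulate_pedigree(cfg)
  A <- build_A(ped)
  n <- nrow(A)
  La <- psd_chol_lower(unclass(A), label = "A")
  eig <- eigen(unclass(A), symmetric = TRUE)

  if (kind == "heritability") {
    truth <- sigma_a2 / (sigma_a2 + sigma_e2)
    one_rep <- function(k) {
      set.seed(seed + k)
      u <- sqrt(sigma_a2) * drop(La %*% stats::rnorm(n))
      y <- u + stats::rnorm(n, 0, sqrt(sigma_e2))
      fit <- reml_univariate(y, A, eig = eig)
      data.frame(replicate = k, estimate = fit$h2, sigma_a2 = fit$sigma_a2,
                 sigma_e2 = fit$sigma_e2, converged = fit$converged,
                 boundary = fit$boundary)
    }
  } else {
    if (is.null(K)) {
      K <- matrix(c(0.222, 0.42 * sqrt(0.222 * 1.16),
                    0.42 * sqrt(0.222 * 1.16), 1.16), 2)
    }
    if (is.null(R)) R <- diag(c(0.518, 1.55))
    truth <- K[2, 1] / sqrt(K[1, 1] * K[2, 2])
    Lk <- psd_chol_lower(K, label = "K")
    Lr <- psd_chol_lower(R, label = "R")
    one_rep <- function(k) {
      set.seed(seed + k)
      U <- La %*% matrix(stats::rnorm(2 * n), n, 2) %*% t(Lk)
      E <- matrix(stats::rnorm(2 * n), n, 2) %*% t(Lr)
      Y <- U + E
      if (missing_fraction > 0) {
        drop_idx <- sample.int(n, round(missing_fraction * n))
        Y[drop_idx, 2] <- NA
        fit <- reml_bivariate(Y, A)
      } else {
        fit <- reml_bivariate(Y, A, eig = eig)
      }
      data.frame(replicate = k, estimate = fit$rg, K11 = fit$K[1, 1],
                 K21 = fit$K[2, 1], K22 = fit$K[2, 2],
                 converged = fit$converged, boundary = fit$projected)
    }
  }

  rows <- list()
  failures <- 0L
  for (k in seq_len(n_replicates)) {
    res <- tryCatch(one_rep(k), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      rows[[k]] <- NULL
    } else {
      rows[[k]] <- res
    }
  }
  if (failures > 0.2 * n_replicates) {
    stop(sprintf("%d of %d replicates failed", failures, n_replicates))
  }
  reps <- do.call(rbind, rows)
  est <- reps$estimate
  structure(list(kind = kind, replicates = reps, mean = mean(est),
                 empirical_se = stats::sd(est) / sqrt(length(est)),
                 sd = stats::sd(est), truth = truth,
                 n_failed = failures, n_animals = n_animals,
                 seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Recovery study (%s, n = %d, %d replicates): mean = %.4f (empirical SE %.4f, SD %.4f), truth = %.4f%s\n",
              x$kind, x$n_animals, nrow(x$replicates), x$mean,
              x$empirical_se, x$sd, x$truth,
              if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}
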
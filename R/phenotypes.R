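#' Energy-corrected milk
#'
#' ECM standardizes milk yield for its energy content:
#' \code{0.327 * milk + 12.95 * fat + 7.2 * protein}, all in kg.
#'
#' @param milk_yield milk yield (kg).
#' @param fat_yield fat yield (kg).
#' @param protein_yield protein yield (kg).
#' @return ECM (kg). Vectorized; errors on negative input.
#' @export
compute_ecm <- function(milk_yield, fat_yield, protein_yield) {
  if (any(milk_yield < 0, na.rm = TRUE) || any(fat_yield < 0, na.rm = TRUE) ||
      any(protein_yield < 0, na.rm = TRUE)) {
    stop("yields must be non-negative")
  }
  0.327 * milk_yield + 12.95 * fat_yield + 7.2 * protein_yield
}

# Per-animal OLS residuals of a trait on day of lactation. Returns residuals
# (NA where trait missing); zero residual variance yields all-zero residuals.
.trait_residuals <- function(trait, dim) {
  ok <- !is.na(trait)
  r <- rep(NA_real_, length(trait))
  if (sum(ok) >= 2 && stats::var(dim[ok]) > 0) {
    fit <- stats::lm.fit(cbind(1, dim[ok]), trait[ok])
    r[ok] <- fit$residuals
  } else if (sum(ok) >= 1) {
    r[ok] <- trait[ok] - mean(trait[ok])
  }
  r
}

#' Screen daily cow records for outliers
#'
#' Applies the daily-record quality control used for lactating-cow feed
#' trials: (1) animals with fewer than \code{min_records} daily records of
#' BW, DMI or ECM are removed entirely; (2) per animal and trait, daily
#' records are regressed on day of lactation by OLS and days whose residual
#' lies more than 3 SD from the mean residual are flagged; (3) flagged DMI
#' days are retained when the DMI and milk-yield residuals both exceed 3 SD
#' in the same direction (an obvious biological event rather than a
#' recording error); (4) all other flagged trait-days are removed (set to
#' NA for that trait). Animals whose residual SD is zero for a trait have no
#' removals for that trait.
#'
#' @param daily data.frame with columns \code{animal_id, dim, dmi, my, bw}
#'   and either \code{ecm} or \code{fat_pct + prot_pct} (fat/protein yields
#'   are derived as percentage x milk yield / 100).
#' @param sd_limit residual SD multiple beyond which a day is flagged.
#' @param min_records minimum daily records of each of BW, DMI, ECM.
#' @return list with \code{daily} (screened records; removed trait-days NA,
#'   removed animals dropped, an \code{ecm} column added) and \code{report}
#'   (a \code{qc_report}: per-animal kept/removed counts and reasons, plus
#'   the global fraction of trait-day records removed).
#' @export
filter_daily_records <- function(daily, sd_limit = 3, min_records = 30) {
  need <- c("animal_id", "dim", "dmi", "my", "bw")
  stopifnot(all(need %in% names(daily)))
  if (!"ecm" %in% names(daily)) {
    stopifnot(all(c("fat_pct", "prot_pct") %in% names(daily)))
    daily$ecm <- compute_ecm(daily$my, pmax(daily$my, 0) * pmax(daily$fat_pct, 0) / 100,
                             pmax(daily$my, 0) * pmax(daily$prot_pct, 0) / 100)
  }
  traits <- c("bw", "dmi", "ecm")
  split_idx <- split(seq_len(nrow(daily)), daily$animal_id)

  counts <- t(vapply(split_idx, function(ix) {
    vapply(traits, function(tr) sum(!is.na(daily[[tr]][ix])), numeric(1))
  }, numeric(3)))
  too_few <- rowSums(counts < min_records) > 0
  dropped_animals <- rownames(counts)[too_few]

  keep_rows <- !(daily$animal_id %in% dropped_animals)
  out <- daily[keep_rows, , drop = FALSE]
  split_idx <- split(seq_len(nrow(out)), out$animal_id)

  removed <- matrix(0L, length(split_idx), length(traits),
                    dimnames = list(names(split_idx), traits))
  retained_exception <- stats::setNames(integer(length(split_idx)), names(split_idx))
  for (a in names(split_idx)) {
    ix <- split_idx[[a]]
    dimv <- out$dim[ix]
    res <- lapply(c(traits, "my"), function(tr) .trait_residuals(out[[tr]][ix], dimv))
    names(res) <- c(traits, "my")
    flag <- mapply(function(r, tr) {
      s <- stats::sd(r, na.rm = TRUE)
      # zero residual variance (numerically): nothing to flag
      tiny <- sqrt(.Machine$double.eps) * (1 + abs(mean(out[[tr]][ix], na.rm = TRUE)))
      if (is.na(s) || s <= tiny) rep(FALSE, length(r))
      else !is.na(r) & abs(r - mean(r, na.rm = TRUE)) > sd_limit * s
    }, res, names(res), SIMPLIFY = FALSE)
    # same-direction DMI & MY exception: keep those DMI days
    except <- flag$dmi & flag$my & (sign(res$dmi) == sign(res$my))
    flag$dmi <- flag$dmi & !except
    retained_exception[a] <- sum(except, na.rm = TRUE)
    for (tr in traits) {
      out[[tr]][ix[flag[[tr]]]] <- NA_real_
      removed[a, tr] <- sum(flag[[tr]])
    }
  }

  total_cells <- sum(!is.na(daily[keep_rows, traits])) + 0
  report <- structure(list(
    dropped_animals = dropped_animals,
    min_records = min_records,
    sd_limit = sd_limit,
    removed_by_animal = as.data.frame(removed),
    retained_dmi_my_exception = retained_exception,
    n_records_before = sum(counts[!too_few, , drop = FALSE]),
    n_records_removed = sum(removed),
    fraction_removed = if (total_cells > 0) sum(removed) / total_cells else 0
  ), class = "qc_report")
  list(daily = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Daily-record QC: %d animal(s) dropped (<%d records); %d of %d trait-day records removed (%.2f%%); %d DMI days retained by the DMI-MY same-direction exception\n",
              length(x$dropped_animals), x$min_records, x$n_records_removed,
              x$n_records_before, 100 * x$fraction_removed,
              sum(x$retained_dmi_my_exception)))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a \code{qc_report} from \code{\link{filter_daily_records}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Summarize screened daily records into per-cow trait records
#'
#' Trait averages are means over kept days. BW change over the test is the
#' per-animal OLS line of BW on day of lactation evaluated at the last minus
#' the first kept day (\code{delta_bw_mode = "fitted"}, robust to single-day
#' noise) or the raw last-minus-first record (\code{"raw"}). Average day in
#' milk and age are means over days with a kept DMI record.
#'
#' @param daily screened daily data.frame (from
#'   \code{\link{filter_daily_records}}); must also carry \code{trial},
#'   \code{lactation} and \code{age} columns.
#' @param delta_bw_mode "fitted" or "raw".
#' @return data.frame with one row per cow: \code{animal_id, trial,
#'   lactation, avg_dmi, avg_bw, avg_ecm, delta_bw, avg_dim, avg_age} and
#'   kept-record counts \code{n_bw, n_dmi, n_ecm}.
#' @export
summarize_cow <- function(daily, delta_bw_mode = c("fitted", "raw")) {
  delta_bw_mode <- match.arg(delta_bw_mode)
  stopifnot(all(c("animal_id", "trial", "lactation", "dim", "age",
                  "dmi", "bw", "ecm") %in% names(daily)))
  res <- lapply(split(daily, daily$animal_id), function(d) {
    okb <- !is.na(d$bw)
    delta_bw <- NA_real_
    if (sum(okb) >= 2) {
      if (delta_bw_mode == "fitted" && stats::var(d$dim[okb]) > 0) {
        fit <- stats::lm.fit(cbind(1, d$dim[okb]), d$bw[okb])
        delta_bw <- fit$coefficients[2] * (max(d$dim[okb]) - min(d$dim[okb]))
      } else {
        delta_bw <- d$bw[okb][sum(okb)] - d$bw[okb][1]
      }
    } else if (sum(okb) == 1) delta_bw <- 0
    okd <- !is.na(d$dmi)
    data.frame(animal_id = d$animal_id[1], trial = d$trial[1],
               lactation = d$lactation[1],
               avg_dmi = mean(d$dmi, na.rm = TRUE),
               avg_bw = mean(d$bw, na.rm = TRUE),
               avg_ecm = mean(d$ecm, na.rm = TRUE),
               delta_bw = unname(delta_bw),
               avg_dim = mean(d$dim[okd]),
               avg_age = mean(d$age[okd]),
               n_bw = sum(okb), n_dmi = sum(okd), n_ecm = sum(!is.na(d$ecm)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize heifer trial records
#'
#' Average daily gain is the OLS slope of the serial body weights on trial
#' day; metabolic body weight is the mean of the fitted daily BW raised to
#' \code{mbw_exponent} over the observed day range; average DMI is the mean
#' of the daily intake records.
#'
#' @param serial_bw data.frame \code{animal_id, day, bw} (>= 2 weighings per
#'   animal; a single weighing is an error since the gain slope is
#'   undefined).
#' @param daily_dmi data.frame \code{animal_id, day, dmi}.
#' @param animals data.frame \code{animal_id, trial, age_start}.
#' @param mbw_exponent exponent of metabolic body weight (default 0.75).
#' @return data.frame \code{animal_id, trial, avg_dmi, mbw, adg, avg_age}.
#' @export
summarize_heifer <- function(serial_bw, daily_dmi, animals,
                             mbw_exponent = 0.75) {
  stopifnot(all(c("animal_id", "day", "bw") %in% names(serial_bw)),
            all(c("animal_id", "day", "dmi") %in% names(daily_dmi)),
            all(c("animal_id", "trial", "age_start") %in% names(animals)))
  bw_split <- split(serial_bw, serial_bw$animal_id)
  dmi_split <- split(daily_dmi, daily_dmi$animal_id)
  res <- lapply(animals$animal_id, function(a) {
    bwd <- bw_split[[as.character(a)]]
    if (is.null(bwd) || nrow(bwd) < 2) {
      stop(sprintf("animal %s has fewer than 2 serial BW records; ADG slope undefined", a))
    }
    fit <- stats::lm.fit(cbind(1, bwd$day), bwd$bw)
    adg <- unname(fit$coefficients[2])
    days <- seq(min(bwd$day), max(bwd$day))
    fitted_bw <- fit$coefficients[1] + fit$coefficients[2] * days
    if (any(fitted_bw <= 0)) stop(sprintf("animal %s has non-positive fitted BW", a))
    mbw <- mean(fitted_bw^mbw_exponent)
    dmid <- dmi_split[[as.character(a)]]
    if (is.null(dmid) || nrow(dmid) < 1) {
      stop(sprintf("animal %s has no daily DMI records", a))
    }
    info <- animals[animals$animal_id == a, ]
    data.frame(animal_id = a, trial = info$trial[1],
               avg_dmi = mean(dmid$dmi), mbw = mbw, adg = adg,
               avg_age = info$age_start[1] + mean(dmid$day),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Shared helper: OLS with explicit rank check naming collinear columns.
.ols_residuals <- function(X, y, context) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design in %s; collinear column(s): %s",
                 context, paste(dropped, collapse = ", ")))
  }
  list(residuals = y - X %*% qr.coef(qrX, y),
       coefficients = qr.coef(qrX, y))
}

#' Heifer residual feed intake
#'
#' Within each trial, average DMI is regressed (OLS, with intercept) on
#' average daily gain, metabolic body weight and age; RFI is the residual:
#' intake not explained by growth, maintenance and age. Negative = efficient.
#'
#' @param records heifer trait records from \code{\link{summarize_heifer}}.
#' @param min_per_trial minimum animals per trial (default 5).
#' @return data.frame \code{animal_id, trial, rfi} plus a
#'   \code{coefficients} attribute (per-trial regression coefficients).
#' @export
fit_heifer_rfi <- function(records, min_per_trial = 5) {
  stopifnot(all(c("animal_id", "trial", "avg_dmi", "adg", "mbw", "avg_age")
                %in% names(records)))
  out <- lapply(split(records, records$trial), function(d) {
    if (nrow(d) < min_per_trial) {
      stop(sprintf("trial %s has %d animals (< %d required)",
                   d$trial[1], nrow(d), min_per_trial))
    }
    X <- cbind(`(Intercept)` = 1, adg = d$adg, mbw = d$mbw, age = d$avg_age)
    fit <- .ols_residuals(X, d$avg_dmi, sprintf("heifer RFI, trial %s", d$trial[1]))
    data.frame(animal_id = d$animal_id, trial = d$trial,
               rfi = as.numeric(fit$residuals), stringsAsFactors = FALSE)
  })
  coefs <- lapply(split(records, records$trial), function(d) {
    X <- cbind(`(Intercept)` = 1, adg = d$adg, mbw = d$mbw, age = d$avg_age)
    .ols_residuals(X, d$avg_dmi, "heifer RFI")$coefficients
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "coefficients") <- coefs
  res
}

#' Lactating-cow residual feed intake
#'
#' One OLS model across all cows: average DMI on trial (fixed, reference
#' coding), lactation (fixed), linear and quadratic day in milk and age, BW,
#' ECM and BW change. The residual is RFI_cow. When an animal has records in
#' both lactations only the first-lactation record is used.
#'
#' @param records cow trait records from \code{\link{summarize_cow}}.
#' @return data.frame \code{animal_id, trial, lactation, rfi}; the fitted
#'   \code{lm} object is attached as attribute \code{model}.
#' @export
fit_cow_rfi <- function(records) {
  need <- c("animal_id", "trial", "lactation", "avg_dmi", "avg_bw", "avg_ecm",
            "delta_bw", "avg_dim", "avg_age")
  stopifnot(all(need %in% names(records)))
  # first-lactation preference for repeated animals
  records <- records[order(records$animal_id, records$lactation), ]
  records <- records[!duplicated(records$animal_id), ]
  d <- records
  d$trial <- factor(d$trial)
  d$lactation <- factor(d$lactation)
  terms <- c("avg_dim", "I(avg_dim^2)", "avg_age", "I(avg_age^2)",
             "avg_bw", "avg_ecm", "delta_bw")
  if (nlevels(d$trial) > 1) terms <- c("trial", terms)
  if (nlevels(d$lactation) > 1) terms <- c("lactation", terms)
  fml <- stats::as.formula(paste("avg_dmi ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design in cow RFI model; collinear term(s): %s",
                 paste(bad, collapse = ", ")))
  }
  out <- data.frame(animal_id = d$animal_id, trial = as.character(d$trial),
                    lactation = as.character(d$lactation),
                    rfi = unname(stats::residuals(fit)),
                    stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  out
}
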
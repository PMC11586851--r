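#' Simulate daily records for lactating cows
#'
#' Builds daily DMI, milk yield, fat %, protein % and BW for each cow over
#' days in milk 100--240 (the 140-d test window) as fixed effects (trial,
#' lactation, linear/quadratic day-of-lactation trends, age) plus a cow-level
#' genetic effect on intake, a cow-level environmental intake residual, and
#' i.i.d. day-level noise. Intake is generated as a linear function of the
#' cow's realized ECM, BW and BW change, so the residual of the RFI
#' regression recovers the genetic + environmental intake effect. A
#' configured fraction of daily records is perturbed beyond the 3-SD
#' screening rule, including a share of DMI--MY same-direction co-outliers
#' that the screening is expected to retain.
#'
#' @param tbv named numeric vector of cow-intake breeding values (kg DM/d),
#'   names = animal ids; e.g. the \code{"rfi_cow"} column of
#'   \code{\link{simulate_true_breeding_values}}.
#' @param config a \code{\link{sim_config}}.
#' @param dim_range first and last day in milk recorded.
#' @return list with \code{daily} (long data.frame: animal_id, trial,
#'   lactation, dim, age, dmi, my, fat_pct, prot_pct, bw), \code{injected}
#'   (animal_id, dim, type of each injected outlier) and \code{cow}
#'   (per-cow latent values used by the generator).
#' @export
simulate_cow_daily_records <- function(tbv, config, dim_range = c(100L, 240L)) {
  stopifnot(inherits(config, "sim_config"), !is.null(names(tbv)))
  set.seed(config$seed + 2L)
  ids <- names(tbv)
  n <- length(ids)
  dims <- seq(dim_range[1], dim_range[2])
  nd <- length(dims)
  sd_day <- config$day_sd

  trial_eff <- stats::rnorm(config$n_trials_cow, 0, 0.5)       # kg DM/d
  trial_my_eff <- stats::rnorm(config$n_trials_cow, 0, 1.2)    # kg/d

  trial <- sample.int(config$n_trials_cow, n, replace = TRUE)
  lact <- 1L + stats::rbinom(n, 1L, if (config$n_lactations > 1) 420 / 2538 else 0)
  age_start <- ifelse(lact == 1, stats::rnorm(n, 875, 80), stats::rnorm(n, 1365, 140))
  bw0 <- ifelse(lact == 1, stats::rnorm(n, 655, 60), stats::rnorm(n, 725, 55))
  bw_slope <- stats::rnorm(n, 0.3, 0.15)                        # kg/d
  my_level <- 31 + 6 * (lact == 2) + trial_my_eff[trial] + stats::rnorm(n, 0, 4)
  fat_level <- 4.27 + stats::rnorm(n, 0, 0.4)
  prot_level <- 3.33 + stats::rnorm(n, 0, 0.12)
  e_cow <- stats::rnorm(n, 0, sqrt(config$sigma_e2[["rfi_cow"]]))

  cow <- data.frame(animal_id = ids, trial = trial, lactation = lact,
                    age_start = age_start, bw0 = bw0, bw_slope = bw_slope,
                    my_level = my_level, fat_level = fat_level,
                    prot_level = prot_level, tbv = as.numeric(tbv),
                    e_cow = e_cow, stringsAsFactors = FALSE)

  idx <- rep(seq_len(n), each = nd)
  d <- rep(dims, times = n)
  ctr <- d - 170
  bw <- bw0[idx] + bw_slope[idx] * (d - dim_range[1]) +
    stats::rnorm(n * nd, 0, sd_day[["bw"]])
  my <- my_level[idx] - 0.05 * ctr - 2e-4 * ctr^2 +
    stats::rnorm(n * nd, 0, sd_day[["my"]])
  fat_pct <- fat_level[idx] + stats::rnorm(n * nd, 0, sd_day[["fat_pct"]])
  prot_pct <- prot_level[idx] + stats::rnorm(n * nd, 0, sd_day[["prot_pct"]])
  ecm <- compute_ecm(my, pmax(my, 0) * pmax(fat_pct, 0) / 100,
                     pmax(my, 0) * pmax(prot_pct, 0) / 100)
  # expected intake from the energy sinks, then genetic + cow-level +
  # day-level intake deviations
  ecm_level <- my_level * (0.327 + 12.95 * fat_level / 100 + 7.2 * prot_level / 100)
  exp_dmi <- 1.5 + 0.30 * ecm_level[idx] + 0.012 * bw0[idx] +
    0.8 * bw_slope[idx] + trial_eff[trial[idx]] + 1.2 * (lact[idx] == 2) +
    0.004 * ctr - 3e-5 * ctr^2
  dmi <- exp_dmi + tbv[idx] + e_cow[idx] + stats::rnorm(n * nd, 0, sd_day[["dmi"]])

  daily <- data.frame(animal_id = ids[idx], trial = trial[idx],
                      lactation = lact[idx], dim = d,
                      age = age_start[idx] + (d - dim_range[1]),
                      dmi = dmi, my = my, fat_pct = fat_pct,
                      prot_pct = prot_pct, bw = bw,
                      stringsAsFactors = FALSE)

  injected <- data.frame(animal_id = character(0), dim = integer(0),
                         type = character(0), stringsAsFactors = FALSE)
  n_out <- round(config$outlier_rate * nrow(daily))
  if (n_out > 0) {
    rows <- sample.int(nrow(daily), n_out)
    type <- sample(c("dmi", "bw", "ecm", "dmi_my"), n_out, replace = TRUE,
                   prob = c(0.4, 0.3, 0.15, 0.15))
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    mag <- stats::runif(n_out, 5, 8)
    for (k in seq_len(n_out)) {
      r <- rows[k]
      if (type[k] == "dmi") {
        daily$dmi[r] <- daily$dmi[r] + sgn[k] * mag[k] * sd_day[["dmi"]]
      } else if (type[k] == "bw") {
        daily$bw[r] <- daily$bw[r] + sgn[k] * mag[k] * sd_day[["bw"]]
      } else if (type[k] == "ecm") {
        daily$fat_pct[r] <- daily$fat_pct[r] + sgn[k] * mag[k] * 4 * sd_day[["fat_pct"]]
      } else {
        daily$dmi[r] <- daily$dmi[r] + sgn[k] * mag[k] * sd_day[["dmi"]]
        daily$my[r] <- daily$my[r] + sgn[k] * mag[k] * sd_day[["my"]]
      }
    }
    injected <- data.frame(animal_id = daily$animal_id[rows], dim = daily$dim[rows],
                           type = type, stringsAsFactors = FALSE)
  }
  list(daily = daily, injected = injected, cow = cow)
}

#' Simulate heifer feed-conversion trial records
#'
#' Serial body weights (biweekly over a 70-d test) with linear growth plus
#' measurement noise, daily DMI built from the standard energy sinks
#' (average daily gain, metabolic body weight, age) plus a genetic and a
#' heifer-level environmental intake deviation, and trial labels. Ages are
#' kept within the 206--437 d window typical of post-weaning feed trials.
#'
#' @param tbv named numeric vector of heifer-intake breeding values
#'   (kg DM/d), names = animal ids.
#' @param config a \code{\link{sim_config}}.
#' @param trial_days length of the test period (d).
#' @param bw_interval days between serial weighings.
#' @param adg_mean,adg_sd mean and SD of true average daily gain (kg/d).
#' @param bw_noise_sd SD of the scale measurement error (kg); 0 gives exact
#'   linear growth.
#' @param dmi_day_sd day-level intake noise SD (kg DM/d).
#' @param b coefficients of expected intake on (ADG, MBW, age).
#' @return list with \code{animals} (animal_id, trial, age_start, adg_true),
#'   \code{serial_bw} (animal_id, day, bw) and \code{daily_dmi}
#'   (animal_id, day, dmi).
#' @export
simulate_heifer_records <- function(tbv, config, trial_days = 70L,
                                    bw_interval = 14L,
                                    adg_mean = 1.09, adg_sd = 0.24,
                                    bw_noise_sd = 6, dmi_day_sd = 0.8,
                                    b = c(adg = 1.5, mbw = 0.09, age = 0.002)) {
  stopifnot(inherits(config, "sim_config"), !is.null(names(tbv)))
  set.seed(config$seed + 3L)
  ids <- names(tbv)
  n <- length(ids)
  trial <- sample.int(config$n_trials_heifer, n, replace = TRUE)
  trial_eff <- stats::rnorm(config$n_trials_heifer, 0, 0.3)
  age_start <- stats::runif(n, 206, 437 - trial_days)
  adg <- pmax(stats::rnorm(n, adg_mean, adg_sd), 0.2)
  bw0 <- stats::rnorm(n, 230, 25)
  e_hfr <- stats::rnorm(n, 0, sqrt(config$sigma_e2[["rfi_heifer"]]))

  wdays <- seq(0L, trial_days, by = bw_interval)
  serial_bw <- data.frame(
    animal_id = rep(ids, each = length(wdays)),
    day = rep(wdays, times = n),
    bw = bw0[rep(seq_len(n), each = length(wdays))] +
      adg[rep(seq_len(n), each = length(wdays))] * rep(wdays, times = n) +
      stats::rnorm(n * length(wdays), 0, bw_noise_sd),
    stringsAsFactors = FALSE)

  ddays <- seq_len(trial_days)
  idx <- rep(seq_len(n), each = trial_days)
  mbw_true <- vapply(seq_len(n), function(i) mean((bw0[i] + adg[i] * ddays)^0.75),
                     numeric(1))
  mu <- 7.98 - b[["adg"]] * adg_mean - b[["mbw"]] * 60 - b[["age"]] * 307
  dmi_mean <- mu + trial_eff[trial] + b[["adg"]] * adg + b[["mbw"]] * mbw_true +
    b[["age"]] * (age_start + trial_days / 2) + as.numeric(tbv) + e_hfr
  daily_dmi <- data.frame(
    animal_id = ids[idx],
    day = rep(ddays, times = n),
    dmi = dmi_mean[idx] + stats::rnorm(n * trial_days, 0, dmi_day_sd),
    stringsAsFactors = FALSE)

  animals <- data.frame(animal_id = ids, trial = trial, age_start = age_start,
                        adg_true = adg, tbv = as.numeric(tbv), e_env = e_hfr,
                        stringsAsFactors = FALSE)
  list(animals = animals, serial_bw = serial_bw, daily_dmi = daily_dmi)
}
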
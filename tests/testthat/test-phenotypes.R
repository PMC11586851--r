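test_that("ECM is the standard linear combination of yields", {
  expect_equal(compute_ecm(0, 0, 0), 0)
  expect_equal(compute_ecm(1, 0, 0), 0.327)
  expect_equal(compute_ecm(0, 1, 0), 12.95)
  expect_equal(compute_ecm(0, 0, 1), 7.2)
  # hand arithmetic on divergent-group means (ECM of averages)
  expect_equal(round_half_up(compute_ecm(30.84, 1.37, 1.02), 2), 35.17)
  # linearity
  a <- c(10, 0.5, 0.4); b <- c(5, 0.2, 0.15)
  expect_equal(compute_ecm(a[1] + b[1], a[2] + b[2], a[3] + b[3]),
               compute_ecm(a[1], a[2], a[3]) + compute_ecm(b[1], b[2], b[3]))
  expect_error(compute_ecm(-1, 0, 0), "non-negative")
})

test_that("daily-record screening removes 3-SD outliers but keeps DMI-MY co-outliers", {
  daily <- make_cow_daily(n_cows = 3, dmi_noise = 0.5, seed = 42)
  base <- filter_daily_records(daily)
  sd_dmi <- sd(resid(lm(dmi ~ dim, data = daily[daily$animal_id == "cow1", ])))

  # one +5 SD DMI-only day -> exactly that day removed for DMI
  d1 <- daily
  i <- which(d1$animal_id == "cow1" & d1$dim == 170)
  d1$dmi[i] <- d1$dmi[i] + 5 * sd_dmi
  out1 <- filter_daily_records(d1)
  expect_true(is.na(out1$daily$dmi[out1$daily$animal_id == "cow1" &
                                     out1$daily$dim == 170]))
  expect_equal(out1$report$removed_by_animal["cow1", "dmi"], 1)

  # +5 SD on both DMI and MY (same direction) -> retained
  d2 <- daily
  sd_my <- sd(resid(lm(my ~ dim, data = daily[daily$animal_id == "cow1", ])))
  d2$dmi[i] <- d2$dmi[i] + 5 * sd_dmi
  d2$my[i] <- d2$my[i] + 5 * sd_my
  out2 <- filter_daily_records(d2)
  expect_false(is.na(out2$daily$dmi[out2$daily$animal_id == "cow1" &
                                      out2$daily$dim == 170]))
  expect_gte(out2$report$retained_dmi_my_exception["cow1"], 1)
})

test_that("animals with under 30 daily records are dropped entirely", {
  daily <- make_cow_daily(n_cows = 2, dmi_noise = 0.2, seed = 7)
  short <- daily[daily$animal_id == "cow1" & daily$dim <= 109, ]  # 10 days
  rest <- daily[daily$animal_id == "cow2", ]
  out <- filter_daily_records(rbind(short, rest))
  expect_equal(out$report$dropped_animals, "cow1")
  expect_false("cow1" %in% out$daily$animal_id)
})

test_that("zero residual variance triggers no removals", {
  daily <- make_cow_daily(n_cows = 2, dmi_noise = 0, seed = 1)
  out <- filter_daily_records(daily)
  expect_equal(out$report$n_records_removed, 0)
  expect_equal(out$report$fraction_removed, 0)
})

test_that("cow summaries: averages and regression-based BW change", {
  # constant BW
  daily <- make_cow_daily(n_cows = 1, bw_slope = 0, dmi_noise = 0)
  daily$bw <- 650
  rec <- summarize_cow(filter_daily_records(daily)$daily)
  expect_equal(rec$avg_bw, 650)
  expect_equal(rec$delta_bw, 0)
  # exactly linear 600 -> 670 over the period
  d2 <- make_cow_daily(n_cows = 1, bw_slope = 70 / 140, dmi_noise = 0)
  d2$bw <- 600 + (d2$dim - 100) * 70 / 140
  rec2 <- summarize_cow(filter_daily_records(d2)$daily)
  expect_equal(rec2$delta_bw, 70, tolerance = 1e-10)
  # noisy linear BW: fitted-endpoint estimate matches an lm oracle
  set.seed(5)
  d3 <- make_cow_daily(n_cows = 1, bw_slope = 0.5, dmi_noise = 0)
  d3$bw <- 600 + 0.5 * (d3$dim - 100) + rnorm(nrow(d3), 0, 10)
  rec3 <- summarize_cow(filter_daily_records(d3)$daily)
  kept <- filter_daily_records(d3)$daily
  fit <- lm(bw ~ dim, data = kept[!is.na(kept$bw), ])
  oracle <- unname(coef(fit)[2]) * diff(range(kept$dim[!is.na(kept$bw)]))
  expect_equal(rec3$delta_bw, oracle, tolerance = 1e-8)
  expect_lt(abs(rec3$delta_bw - 70), 10)
  # raw-endpoint mode uses the actual first/last kept records
  rec4 <- summarize_cow(filter_daily_records(d3)$daily, delta_bw_mode = "raw")
  okb <- !is.na(kept$bw)
  expect_equal(rec4$delta_bw, kept$bw[okb][sum(okb)] - kept$bw[okb][1])
})

test_that("heifer summaries: two-point gain, metabolic weight, error cases", {
  animals <- data.frame(animal_id = "h1", trial = 1, age_start = 250)
  bw <- data.frame(animal_id = "h1", day = c(0, 70), bw = c(300, 370))
  dmi <- data.frame(animal_id = "h1", day = 1:70, dmi = 8)
  rec <- summarize_heifer(bw, dmi, animals)
  expect_equal(rec$adg, 1.0, tolerance = 1e-12)
  # constant 256 kg -> MBW = 256^0.75 = 64
  bw2 <- data.frame(animal_id = "h1", day = c(0, 35, 70), bw = 256)
  expect_equal(summarize_heifer(bw2, dmi, animals)$mbw, 64, tolerance = 1e-12)
  # a single weighing leaves the gain slope undefined
  bw3 <- data.frame(animal_id = "h1", day = 0, bw = 300)
  expect_error(summarize_heifer(bw3, dmi, animals), "fewer than 2")
})

test_that("simulated heifers in realistic covariate ranges give plausible metabolic weights", {
  cfg <- sim_config(n_founders = 40, n_generations = 1, seed = 31)
  tbv <- stats::setNames(rnorm(40, 0, sqrt(0.222)), paste0("h", 1:40))
  sim <- simulate_heifer_records(tbv, cfg)
  rec <- summarize_heifer(sim$serial_bw, sim$daily_dmi, sim$animals)
  expect_true(all(rec$mbw >= 35.22 & rec$mbw <= 84.59))
})

test_that("heifer RFI: residual properties and exact noiseless recovery", {
  set.seed(8)
  n <- 40
  rec <- data.frame(animal_id = paste0("h", 1:n),
                    trial = rep(1:2, each = n / 2),
                    adg = runif(n, 0.8, 1.4),
                    mbw = runif(n, 50, 70),
                    avg_age = runif(n, 250, 400))
  # noiseless generative model: coefficients recovered, all RFI zero
  rec$avg_dmi <- 1 + 1.5 * rec$adg + 0.09 * rec$mbw + 0.002 * rec$avg_age
  rfi0 <- fit_heifer_rfi(rec)
  expect_equal(max(abs(rfi0$rfi)), 0, tolerance = 1e-10)
  cf <- attr(rfi0, "coefficients")[["1"]]
  expect_equal(unname(cf), c(1, 1.5, 0.09, 0.002), tolerance = 1e-8)
  # with noise: residuals sum to zero within every trial
  rec$avg_dmi <- rec$avg_dmi + rnorm(n, 0, 0.5)
  rfi <- fit_heifer_rfi(rec)
  sums <- tapply(rfi$rfi, rfi$trial, sum)
  expect_equal(as.numeric(sums), c(0, 0), tolerance = 1e-10)
  # RFI variance tracks the injected residual variance
  expect_lt(abs(var(rfi$rfi) - 0.25), 0.15)
  # collinear design is named
  rec_bad <- rec
  rec_bad$mbw <- 2 * rec_bad$adg
  expect_error(fit_heifer_rfi(rec_bad), "collinear")
  # too-small trials are refused
  expect_error(fit_heifer_rfi(rec[1:3, ]), "< 5")
})

test_that("cow RFI is an OLS residual orthogonal to its energy sinks", {
  cfg <- sim_config(n_founders = 300, n_generations = 1, seed = 13)
  tbv <- stats::setNames(rnorm(300, 0, sqrt(1.16)), paste0("c", 1:300))
  sim <- simulate_cow_daily_records(tbv, cfg)
  rec <- summarize_cow(filter_daily_records(sim$daily)$daily)
  rfi <- fit_cow_rfi(rec)
  m <- match(rfi$animal_id, rec$animal_id)
  expect_equal(sum(rfi$rfi), 0, tolerance = 1e-8)
  for (v in c("avg_ecm", "avg_bw", "delta_bw", "avg_dim")) {
    expect_lt(abs(cor(rfi$rfi, rec[[v]][m])), 0.05)
  }
})

test_that("first-lactation records win and perturbing intake moves RFI by 1 - leverage", {
  cfg <- sim_config(n_founders = 120, n_generations = 1, seed = 17)
  tbv <- stats::setNames(rnorm(120, 0, 1), paste0("c", 1:120))
  sim <- simulate_cow_daily_records(tbv, cfg)
  rec <- summarize_cow(filter_daily_records(sim$daily)$daily)
  # duplicate one cow as a second-lactation record; it must be ignored
  dup <- rec[1, ]
  dup$lactation <- 2
  dup$avg_dmi <- dup$avg_dmi + 5
  rfi_a <- fit_cow_rfi(rec)
  rfi_b <- fit_cow_rfi(rbind(rec, dup))
  expect_equal(rfi_a$rfi, rfi_b$rfi)
  # hat-matrix oracle for a +1 kg/d intake perturbation
  rfi0 <- fit_cow_rfi(rec)
  h <- lm.influence(attr(rfi0, "model"), do.coef = FALSE)$hat
  k <- 7
  rec2 <- rec
  rec2$avg_dmi[k] <- rec2$avg_dmi[k] + 1
  rfi1 <- fit_cow_rfi(rec2)
  expect_equal(rfi1$rfi[k] - rfi0$rfi[k], 1 - unname(h[k]), tolerance = 1e-8)
})

test_that("divergent RFI deciles differ in intake but not in the adjusted sinks", {
  cfg <- sim_config(n_founders = 400, n_generations = 1, seed = 23)
  tbv <- stats::setNames(rnorm(400, 0, sqrt(1.16)), paste0("c", 1:400))
  sim <- simulate_cow_daily_records(tbv, cfg)
  rec <- summarize_cow(filter_daily_records(sim$daily)$daily)
  rfi <- fit_cow_rfi(rec)
  m <- match(rfi$animal_id, rec$animal_id)
  q <- quantile(rfi$rfi, c(0.1, 0.9))
  lo <- m[rfi$rfi <= q[1]]
  hi <- m[rfi$rfi >= q[2]]
  expect_lt(t.test(rec$avg_dmi[lo], rec$avg_dmi[hi])$p.value, 1e-6)
  for (v in c("avg_ecm", "avg_bw", "delta_bw")) {
    expect_gt(t.test(rec[[v]][lo], rec[[v]][hi])$p.value, 0.01)
  }
})

test_that("default outlier injection keeps daily-record losses under 5%", {
  cfg <- sim_config(n_founders = 150, n_generations = 1, seed = 29)
  tbv <- stats::setNames(rnorm(150, 0, 1), paste0("c", 1:150))
  sim <- simulate_cow_daily_records(tbv, cfg)
  qc <- filter_daily_records(sim$daily)
  expect_lt(qc$report$fraction_removed, 0.05)
  expect_gt(qc$report$n_records_removed, 0)
})
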
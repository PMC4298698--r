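test_that("the chi-square periodogram recovers planted periods", {
  ## noiseless 24.0-hr square wave over 28 days
  sq <- square_record(days = 28, on = 12, off = 24)
  pg <- chi2_periodogram(sq)
  expect_equal(attr(pg, "best_period_hr"), 24.0)
  expect_true(all(pg$Qp >= 0))
  expect_true(all(diff(pg$period_hr) > 0))

  ## planted 23.5-hr sinusoidal gating through the generator, several seeds
  best <- sapply(1:8, function(s) {
    sim <- simulate_activity(activity_sim_params("control", tau_hr = 23.5,
                                                 seed = 300 + s), sched_dd(28))
    attr(chi2_periodogram(sim$record), "best_period_hr")
  })
  expect_true(all(abs(best - 23.5) <= 0.1 + 1e-9))

  ## all-zero record: no best period, flagged
  z <- activity_record(rep(0, 28 * 240), bin_min = 6)
  pz <- chi2_periodogram(z)
  expect_true(is.na(attr(pz, "best_period_hr")))
  expect_true(attr(pz, "all_zero"))
  expect_error(chi2_periodogram(square_record(days = 2)), "twice")
})

test_that("the normalized power spectrum has unit area and finds single tones", {
  ## unit area for arbitrary records (property over random inputs)
  set.seed(401)
  for (i in 1:5) {
    rec <- activity_record(rpois(240 * sample(4:10, 1), runif(1, 1, 20)),
                           bin_min = 6)
    sp <- power_spectrum(rec)
    area <- sum(diff(sp$freq_cph) * (head(sp$density, -1) + tail(sp$density, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-9)
  }

  ## pure 24-hr sinusoid: nearly all power within one frequency step of 1/24
  sr <- sine_record(days = 12, period_hr = 24)
  sp <- power_spectrum(sr)
  step <- diff(sp$freq_cph)[1]
  near <- abs(sp$freq_cph - 1 / 24) <= step + 1e-12
  expect_gt(sum(sp$density[near]) / sum(sp$density), 0.99)
  expect_equal(attr(sp, "peak_period_hr"), 24, tolerance = 0.01)

  expect_error(power_spectrum(activity_record(rep(5, 1000), bin_min = 6)),
               "constant")
})

test_that("circadian band power separates rhythmic from ultradian signals", {
  expect_equal(1 / 30, 0.033, tolerance = 0.015)  # band edge in cycles/hr
  sp24 <- power_spectrum(sine_record(days = 12, period_hr = 24))
  expect_gt(circadian_amplitude(sp24), 0.95)
  sp7 <- power_spectrum(sine_record(days = 12, period_hr = 7, peak_hr = 3))
  expect_lt(circadian_amplitude(sp7), 0.02)
  expect_error(circadian_amplitude(sp24, band_hr = c(0.5, 30)), "band")

  ## white noise: band fraction near the flat-spectrum expectation
  set.seed(402)
  fr <- replicate(30, circadian_amplitude(
    power_spectrum(activity_record(rpois(2400, 10), bin_min = 6))))
  expect_true(abs(mean(fr) - (1 / 18 - 1 / 30)) < 0.006)
})

test_that("window allocations partition total activity", {
  rec <- activity_record(rep(6, 240 * 6), bin_min = 6)
  al <- allocation_by_windows(rec, list(day = c(0, 12), night = c(12, 24)),
                              partition = TRUE)
  expect_equal(al$percent, c(50, 50))
  expect_equal(sum(al$percent), 100)

  nt <- square_record(days = 6, on = 12, off = 24)
  al2 <- allocation_by_windows(nt, list(day = c(0, 12), night = c(12, 24)))
  expect_equal(al2$percent[al2$window == "day"], 0)

  expect_error(allocation_by_windows(rec, list(a = c(0, 13), b = c(12, 24)),
                                     partition = TRUE), "overlap")

  ## skeleton photoperiod: gated control concentrates activity in the
  ## skeleton night, ungated knockout splits it evenly
  sk <- build_light_schedule(data.frame(pattern = "LDLD 1:10:1:12", days = 10))
  win <- list(sk_day = c(1, 11), sk_night = c(12, 22))
  ctl <- simulate_activity(activity_sim_params("control", seed = 21), sk)$record
  knockout <- simulate_activity(activity_sim_params("knockout", base_rate = 8,
                                               seed = 22), sk)$record
  actl <- allocation_by_windows(ctl, win)
  aknk <- allocation_by_windows(knockout, win)
  share <- function(a) a$counts[a$window == "sk_night"] / sum(a$counts)
  expect_gt(share(actl), 0.9)
  expect_equal(share(aknk), 0.5, tolerance = 0.05)
})

test_that("masking scores quantify light suppression per half-hour bin", {
  su <- sched_ultra(13)
  ## constant rate, no light response: every bin exactly 50
  rc <- activity_record(rep(10, 13 * 240), bin_min = 6)
  expect_equal(masking_timecourse(rc, su)$score, rep(50, 7))

  ## immediate 80% suppression: every bin 100 * 0.2 / 1.2
  sim <- simulate_activity(activity_sim_params("knockout", base_rate = 20,
                                               masking_suppression = 0.8,
                                               seed = 31), sched_ultra(21))
  mc <- masking_timecourse(sim$record, sched_ultra(21), day_range = c(3, 15))
  expect_equal(mc$score, rep(100 * 0.2 / 1.2, 7), tolerance = 0.06)

  ## suppression starting 30 min into light: first bin ~50, later bins below
  del <- simulate_activity(activity_sim_params("knockout", base_rate = 20,
                                               masking_suppression = 0.8,
                                               masking_delay_min = 30,
                                               seed = 32), sched_ultra(21))
  md <- masking_timecourse(del$record, sched_ultra(21), day_range = c(3, 15))
  expect_equal(md$score[1], 50, tolerance = 2)
  expect_true(all(md$score[2:7] < 40))

  ## invariance to uniform count rescaling
  r2 <- rc; r2$counts <- r2$counts * 7
  expect_equal(masking_timecourse(r2, su)$score,
               masking_timecourse(rc, su)$score)

  ## empty bins are flagged NA, not zero
  rz <- activity_record(rep(0, 13 * 240), bin_min = 6)
  expect_true(all(is.na(masking_timecourse(rz, su)$score)))
})

test_that("FAA metrics report onset lead, fold change and daily build-up", {
  fr <- build_fr_ramp(18, 12, 2, 4, n_fr_days = 14)

  ## deterministic linear ramp from 0 at 4 hr pre-meal to max at mealtime
  bin_min <- 6
  n_days <- nrow(fr)
  t <- (seq_len(n_days * 24 * 60 / bin_min) - 0.5) * bin_min / 60
  zt <- t %% 24                # meal (food onset) at ZT6
  rate <- pmax(0, 1 - (6 - zt) / 4) * 20
  rate[!(zt >= 2 & zt < 6)] <- 0
  ramp <- activity_record(rate * bin_min, bin_min = bin_min)
  fm <- faa_metrics(ramp, fr)
  expect_equal(fm$onset_lead_hr, 2, tolerance = 0.2)

  ## constant-rate record: fold change exactly 1
  const <- activity_record(rep(12, n_days * 240), bin_min = 6)
  expect_equal(faa_metrics(const, fr)$fold_change, 1)

  ## zero baseline flags the fold change
  zb <- faa_metrics(ramp, fr)
  expect_true(is.na(zb$fold_change) && zb$flagged)

  ## planted anticipation: daily pre-meal counts rise then plateau
  sim <- simulate_activity(activity_sim_params("knockout", base_rate = 1,
                                               faa_amplitude = 25,
                                               faa_span_hr = 3,
                                               faa_growth_days = 4,
                                               masking_suppression = 0,
                                               seed = 41),
                           sched_dd(nrow(fr)), feeding = fr)
  fs <- faa_metrics(sim$record, fr)
  wc <- fs$window_counts
  early <- mean(wc[1:2]); late <- mean(wc[(length(wc) - 4):length(wc)])
  expect_gt(late, 2 * early)
  expect_lt(abs(diff(tail(wc, 2))) / late, 0.5)   # plateaued
  expect_gt(fs$fold_change, 2)

  ## fold change invariant to bin width at fixed underlying rate
  fs1 <- faa_metrics(rebin_activity(sim$record, 12), fr)
  expect_equal(fs1$fold_change, fs$fold_change, tolerance = 0.05)
})
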
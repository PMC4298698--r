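test_that("preprocessing corrects counts and applies both trim rules", {
  n <- 240 * 6 + 1                      # 240 hr at 10 min
  tr <- lumi_trace(rep(300, n), background = 100, gain = 2)
  pre <- preprocess_trace(tr)
  expect_equal(range(pre$time_hr), c(20, 192))
  expect_equal(unique(pre$value), 100)  # (300 - 100) / 2

  ## medium change truncates the support
  tr2 <- lumi_trace(rep(300, n), background = 100, gain = 2,
                    medium_change_hr = 150)
  expect_lt(max(preprocess_trace(tr2)$time_hr), 150)

  ## background equal to raw leaves zero signal, flagged
  tr3 <- lumi_trace(rep(100, n), background = 100)
  expect_true(attr(preprocess_trace(tr3), "all_zero"))

  expect_error(preprocess_trace(lumi_trace(rep(1, 60))), "shorter")
  expect_error(preprocess_trace(lumi_trace(rep(1, 540),
                                           medium_change_hr = 60)), "72 hr")
})

test_that("running-average detrending removes trends, keeps rhythms", {
  t <- seq(0, 120, by = 1 / 6)
  ## linear ramp is reproduced exactly by the centered average
  ramp <- data.frame(time_hr = t, value = 3 + 0.7 * t)
  d1 <- detrend_running_average(ramp)
  expect_lt(max(abs(d1$value)), 1e-9 * max(ramp$value))
  ## edges shortened by one window in total
  expect_equal(diff(range(d1$time_hr)), diff(range(t)) - 24, tolerance = 0.4)

  ## constant + 24-hr cosine: constant removed, rhythm passed nearly intact
  ## (the boxcar transfer at the window period is ~0)
  cosd <- data.frame(time_hr = t, value = 50 + 10 * cos(2 * pi * t / 24))
  d2 <- detrend_running_average(cosd)
  expect_equal(max(d2$value), 10, tolerance = 0.02)
  expect_lt(abs(mean(d2$value)), 0.05)

  ## white noise: output mean near zero
  set.seed(7)
  wn <- data.frame(time_hr = t, value = rnorm(length(t)))
  expect_lt(abs(mean(detrend_running_average(wn)$value)), 0.05)

  expect_error(detrend_running_average(ramp, window_hr = 100), "twice")
})

test_that("FFT-NLLS recovers exact model parameters on noiseless input", {
  tt <- seq(20, 192, by = 1 / 6)
  y <- 100 * cos(2 * pi * (tt - 30) / 24)
  fit <- fft_nlls(data.frame(time_hr = tt, value = y))
  expect_equal(fit$period_hr, 24, tolerance = 1e-3)
  expect_equal(fit$phase_hr, 30, tolerance = 0.01)
  expect_equal(fit$amplitude, 100, tolerance = 0.01)
  expect_lt(fit$rae, 0.01)
  expect_true(fit$converged)
})

test_that("FFT-NLLS flags pure noise as non-rhythmic", {
  tt <- seq(20, 192, by = 1 / 6)
  set.seed(12)
  fit <- fft_nlls(data.frame(time_hr = tt, value = rnorm(length(tt))))
  expect_equal(fit$rae, 1)
  expect_true(fit$flagged)
  ## rising noise never lowers RAE on average (QC monotonicity)
  rae_at <- function(sd) mean(sapply(1:12, function(s) {
    set.seed(1000 + s)
    y <- 60 * cos(2 * pi * (tt - 30) / 24) + rnorm(length(tt), 0, sd)
    fft_nlls(data.frame(time_hr = tt, value = y))$rae
  }))
  r <- c(rae_at(5), rae_at(40), rae_at(120))
  expect_true(all(diff(r) > 0))
})

test_that("relative amplitude is a gain-invariant ratio over 36-60 hr", {
  fit <- structure(list(period_hr = 24, phase_hr = 30, amplitude = 50,
                        damping_hr = Inf, rae = 0.1, rss = 0,
                        trend = c(500, 0), converged = TRUE, flagged = FALSE,
                        reason = NA_character_), class = "rhythm_fit")
  t <- seq(20, 192, by = 1 / 6)
  corr <- data.frame(time_hr = t, value = rep(500, length(t)))
  expect_equal(relative_amplitude(fit, corr), 0.1)  # 50 / 500

  ## doubling counts (halved gain) leaves the ratio unchanged
  fit2 <- fit; fit2$amplitude <- 100
  corr2 <- corr; corr2$value <- corr2$value * 2
  expect_equal(relative_amplitude(fit2, corr2), 0.1)

  ## damping shrinks the model half-range over the window below A
  fit3 <- fit; fit3$damping_hr <- 24
  expect_lt(relative_amplitude(fit3, corr), 0.1)

  ## non-positive window mean is undefined and flagged
  neg <- corr; neg$value <- neg$value * 0
  expect_true(is.na(relative_amplitude(fit, neg)))
  expect_true(attr(relative_amplitude(fit, neg), "flagged"))
})

test_that("QC excludes fits by RAE and circadian period range", {
  mk <- function(tau, rae) structure(
    list(period_hr = tau, phase_hr = 30, amplitude = 1, damping_hr = Inf,
         rae = rae, rss = 0, trend = c(0, 0), converged = TRUE,
         flagged = FALSE, reason = NA_character_), class = "rhythm_fit")
  expect_equal(qc_filter(mk(16.0, 0.2))$reason, "period")
  expect_equal(qc_filter(mk(24.0, 0.9))$reason, "rae")
  expect_true(qc_filter(mk(24.0, 0.5))$retained)
  expect_true(qc_filter(mk(31.5, 0.1))$reason == "period")
  expect_true(qc_filter(mk(17.0, 0.83))$retained)  # boundaries inclusive
})

test_that("the second-cycle peak counts peaks from culture start", {
  t <- seq(0, 200, by = 1 / 6)
  ## cosine peaking at 6, 30, 54, ...: second peak is 30 even though the
  ## first falls inside the usual 20-hr trim
  s <- data.frame(time_hr = t, value = 100 + 50 * cos(2 * pi * (t - 6) / 24))
  expect_equal(second_cycle_peak(s), 30, tolerance = 0.2)

  ## planted tau = 25, peaks at 10, 35, 60
  s2 <- data.frame(time_hr = t, value = 100 + 50 * cos(2 * pi * (t - 10) / 25))
  expect_equal(second_cycle_peak(s2), 35, tolerance = 0.2)

  ## monotone series has no cycle peaks
  mono <- data.frame(time_hr = t, value = t)
  expect_true(is.na(second_cycle_peak(mono)))

  ## agreement with the FFT-NLLS phase on undamped noiseless input
  tr <- simulate_trace(lumi_sim_params(amplitude0 = 200, damping_hr = 1e6,
                                       drift_per_hr = 0, noise_sd = 0))$trace
  pre <- preprocess_trace(tr)
  fit <- fft_nlls(detrend_running_average(pre))
  expect_lt(abs(second_cycle_peak(tr) - fit$phase_hr), 1)
})

test_that("duplicate explants average circularly and scalars arithmetically", {
  e <- data.frame(animal_id = "m1", tissue = "liver",
                  phase_hr = c(23.5, 0.5), period_hr = c(23.8, 24.2),
                  rel_amplitude = c(0.2, 0.4))
  avg <- average_duplicates(e)
  expect_equal(avg$phase_hr, 0)        # across midnight, not 12
  expect_equal(avg$period_hr, 24)
  expect_equal(avg$rel_amplitude, 0.3)
  expect_false(avg$discordant)

  single <- average_duplicates(data.frame(animal_id = "m2", tissue = "lung",
                                          phase_hr = 5))
  expect_equal(single$phase_hr, 5)

  far <- average_duplicates(data.frame(animal_id = "m3", tissue = "heart",
                                       phase_hr = c(2, 13)))
  expect_true(far$discordant)
})

test_that("phase maps convert peaks into ZT, CT and feeding frames", {
  peaks <- data.frame(animal_id = c("a", "a", "b", "c"),
                      tissue = c("liver", "heart", "liver", "liver"),
                      peak_hr = c(30, 30, 30, 30))
  ct <- ct_anchor(12 + 24 * (0:9))
  anchors <- list(
    a = list(frame = "ZT", culture_start_zt = 12),
    b = list(frame = "CT", anchor = ct,
             culture_start_abs = ct$predicted_onset_hr - 6),
    c = list(frame = "feeding", culture_start_zt = 12, food_start_zt = 6))
  pm <- build_phase_map(peaks, anchors)
  expect_equal(pm$phase_value[pm$animal_id == "a"], c(18, 18))
  expect_equal(pm$phase_value[pm$animal_id == "b"], 12)  # CT6 + 30 -> CT12
  expect_equal(pm$phase_value[pm$animal_id == "c"], 12)  # ZT18 re food at ZT6
  expect_equal(pm$angle, hours_to_angle(pm$phase_value))

  ## a missing anchor skips the entry with a log
  pm2 <- build_phase_map(rbind(peaks, data.frame(animal_id = "z",
                                                 tissue = "lung",
                                                 peak_hr = 10)), anchors)
  expect_equal(attr(pm2, "skipped"), "z")
  expect_equal(nrow(pm2), 4)
})

test_that("trace CSV + sidecar round-trips through read/write", {
  sim <- simulate_trace(lumi_sim_params(seed = 9), duration_hr = 120,
                        animal_id = "m7", tissue = "kidney",
                        condition = "DD", medium_change_hr = 110)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lumi(sim$trace, path)
  back <- read_lumi(path)
  expect_equal(back$counts, sim$trace$counts)
  expect_equal(back$gain, sim$trace$gain)
  expect_equal(back$tissue, "kidney")
  expect_equal(back$medium_change_hr, 110)
})
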
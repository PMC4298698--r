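## shared fixtures built in code

sched_dd <- function(days = 28)
  build_light_schedule(data.frame(pattern = "DD", days = days))

sched_ld <- function(days = 10)
  build_light_schedule(data.frame(pattern = "LD 12:12", days = days))

sched_ultra <- function(days = 21)
  build_light_schedule(data.frame(pattern = "ULTRA 3.5:3.5", days = days))

## noiseless square-wave record: rate `hi` counts/min during [on, off) ZT,
## `lo` otherwise, deterministic counts
square_record <- function(days = 10, on = 12, off = 24, hi = 10, lo = 0,
                          bin_min = 6) {
  zt <- ((seq_len(days * 24 * 60 / bin_min) - 0.5) * bin_min / 60) %% 24
  rate <- ifelse(zt >= on & zt < off, hi, lo)
  activity_record(rate * bin_min, bin_min = bin_min)
}

## pure sinusoidal-rate record (deterministic, no Poisson noise)
sine_record <- function(days = 14, period_hr = 24, peak_hr = 18,
                        mean_rate = 10, amp = 8, bin_min = 6) {
  t <- (seq_len(days * 24 * 60 / bin_min) - 0.5) * bin_min / 60
  rate <- mean_rate + amp * cos(2 * pi * (t - peak_hr) / period_hr)
  activity_record(rate * bin_min, bin_min = bin_min)
}
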
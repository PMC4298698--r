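#' Chi-square (Sokolove-Bushell) periodogram
#'
#' For each test period P covering B bins, the record is folded into K
#' complete cycles (the incomplete final fold is dropped) and
#' \deqn{Q_P = K N \sum_h (M_h - \bar M)^2 / \sum_i (x_i - \bar M)^2}
#' where \eqn{M_h} are the B column means of the fold and the sums run over
#' the N = K*B included samples. Under a white-noise null \eqn{Q_P} is
#' asymptotically chi-square with B-1 degrees of freedom; the significance
#' line is the (1 - alpha) quantile of that distribution. Test periods are
#' enumerated at the record's bin resolution.
#'
#' @param record an \code{activity_record} spanning at least twice the
#'   longest test period.
#' @param period_range_hr test-period range (hr).
#' @param alpha significance level for the chi-square exceedance line.
#' @return A \code{periodogram}: data frame with \code{period_hr}, \code{Qp},
#'   \code{df}, \code{threshold}, \code{significant}; attributes
#'   \code{best_period_hr} (argmax Qp among significant periods, \code{NA}
#'   when none exceeds the line) and \code{alpha}.
#' @export
chi2_periodogram <- function(record, period_range_hr = c(18, 30),
                             alpha = 0.001) {
  bin_hr <- record$bin_min / 60
  x <- record$counts
  n <- length(x)
  if (n * bin_hr < 2 * period_range_hr[2])
    stop("record span must be at least twice the longest test period")
  Bs <- seq(ceiling(period_range_hr[1] / bin_hr),
            floor(period_range_hr[2] / bin_hr))
  all_zero <- all(x == 0)
  Qp <- df <- numeric(length(Bs))
  for (j in seq_along(Bs)) {
    B <- Bs[j]
    K <- floor(n / B)
    xi <- x[seq_len(K * B)]
    Mh <- rowMeans(matrix(xi, nrow = B))
    Mbar <- mean(xi)
    denom <- sum((xi - Mbar)^2)
    Qp[j] <- if (denom > 0) K^2 * B * sum((Mh - Mbar)^2) / denom else 0
    df[j] <- B - 1
  }
  threshold <- stats::qchisq(1 - alpha, df)
  significant <- Qp > threshold
  out <- data.frame(period_hr = Bs * bin_hr, Qp = Qp, df = df,
                    threshold = threshold, significant = significant)
  best <- if (any(significant)) out$period_hr[which.max(ifelse(significant, Qp, -Inf))]
          else NA_real_
  structure(out, class = c("periodogram", "data.frame"),
            best_period_hr = best, alpha = alpha, all_zero = all_zero)
}

#' Normalized activity power spectrum (0-1 cycles/hr)
#'
#' The mean-removed record is Fourier transformed (no taper, no padding);
#' the discrete power spectral density is restricted to frequencies from 0
#' to 1 cycle/hr and rescaled so that its trapezoidal area is exactly 1.
#'
#' @param record an \code{activity_record} of at least 4 days.
#' @return A \code{power_spectrum}: data frame with \code{freq_cph}
#'   (cycles/hr) and \code{density}; attribute \code{peak_period_hr}, the
#'   period of the global maximum at positive frequency.
#' @export
power_spectrum <- function(record) {
  bin_hr <- record$bin_min / 60
  x <- record$counts
  if (length(x) * bin_hr < 96) stop("record must span at least 4 days")
  if (stats::var(x) == 0)
    stop("constant record: spectrum normalization undefined")
  x <- x - mean(x)
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:floor(n / 2)
  freq <- k / (n * bin_hr)
  keep <- freq <= 1
  freq <- freq[keep]
  dens <- Mod(X[k + 1][keep])^2
  area <- trapz(freq, dens)
  dens <- dens / area
  pk <- which.max(dens[-1]) + 1L
  structure(data.frame(freq_cph = freq, density = dens),
            class = c("power_spectrum", "data.frame"),
            peak_period_hr = 1 / freq[pk], bin_hr = bin_hr)
}

## trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Fraction of normalized spectral power in the circadian band
#'
#' Integrates the normalized power spectral density over the closed band
#' [1/30, 1/18] cycles/hr (18-30 hr periods) by the trapezoid rule, with
#' linear interpolation at the band edges.
#'
#' @param spectrum a \code{power_spectrum}.
#' @param band_hr period band (hr), default \code{c(18, 30)}.
#' @return Band power fraction in [0, 1].
#' @export
circadian_amplitude <- function(spectrum, band_hr = c(18, 30)) {
  f_lo <- 1 / band_hr[2]
  f_hi <- 1 / band_hr[1]
  if (f_lo < 0 || f_hi > 1)
    stop("band outside the 0-1 cycles/hr spectrum support")
  f <- spectrum$freq_cph
  d <- spectrum$density
  inside <- f > f_lo & f < f_hi
  fx <- c(f_lo, f[inside], f_hi)
  dx <- c(stats::approx(f, d, f_lo)$y, d[inside], stats::approx(f, d, f_hi)$y)
  trapz(fx, dx)
}

#' Allocate activity counts to named daily windows
#'
#' Each window is a ZT interval \code{c(start, end)} in [0, 24] (wrapping
#' past midnight allowed); counts whose bin midpoint falls inside the window
#' on any day are summed. Percentages are of the record's total counts, so
#' windows forming a partition of the day sum to 100.
#'
#' @param record an \code{activity_record} (start assumed at ZT0).
#' @param windows named list of ZT intervals.
#' @param partition if \code{TRUE}, reject overlapping windows.
#' @return Data frame with \code{window}, \code{counts}, \code{percent}.
#' @export
allocation_by_windows <- function(record, windows, partition = FALSE) {
  stopifnot(length(names(windows)) == length(windows))
  zt <- bin_mid_hr(record) %% 24
  masks <- lapply(windows, function(w) {
    if (w[1] <= w[2]) zt >= w[1] & zt < w[2] else zt >= w[1] | zt < w[2]
  })
  if (partition) {
    cover <- Reduce(`+`, lapply(masks, as.integer))
    if (any(cover > 1)) stop("overlapping windows in a partition")
  }
  counts <- vapply(masks, function(m) sum(record$counts[m]), numeric(1))
  total <- sum(record$counts)
  data.frame(window = names(windows), counts = unname(counts),
             percent = if (total > 0) 100 * unname(counts) / total else NA_real_,
             row.names = NULL)
}

#' Masking time course under an ultradian light-dark cycle
#'
#' For each half-hour offset j into the light phase, the masking score is
#' \code{100 * L_j / (L_j + D_j)}, where \code{L_j} sums counts over the
#' j-th half hour of every light phase in the analysis range and \code{D_j}
#' over the j-th half hour of the dark phase that follows it. A score of 50
#' indicates failure to mask; bins with no activity in either phase are
#' flagged \code{NA}, not zero-filled.
#'
#' @param record an \code{activity_record} starting at schedule hour 0.
#' @param schedule a \code{light_schedule} built from an ULTRA pattern.
#' @param day_range days of the schedule analysed; default all complete
#'   days of the record (an analysis of days 3-15 of a 21-day cycle passes
#'   \code{c(3, 15)}).
#' @param bin_hr scoring bin width (hr), default 0.5.
#' @return A \code{masking_course}: data frame with \code{bin},
#'   \code{offset_hr}, \code{light_counts}, \code{dark_counts}, \code{score}.
#' @export
masking_timecourse <- function(record, schedule, day_range = NULL,
                               bin_hr = 0.5) {
  if ((bin_hr * 60) %% record$bin_min != 0)
    stop("record bins must divide the scoring bin")
  if (is.null(day_range)) day_range <- c(1, floor(record_span_hr(record) / 24))
  blocks <- schedule$blocks
  t0 <- (day_range[1] - 1) * 24
  t1 <- day_range[2] * 24
  if (t1 > record_span_hr(record) + 1e-9)
    stop("analysis range extends beyond the record")
  light <- blocks[blocks$state == "light" & blocks$start_hr >= t0 &
                    blocks$end_hr <= t1, ]
  if (nrow(light) == 0) stop("no complete light phases in the analysis range")
  L_hr <- light$end_hr[1] - light$start_hr[1]
  nb <- round(L_hr / bin_hr)
  ## keep only light phases whose scored dark bins also fit in the range
  light <- light[light$end_hr + nb * bin_hr <= t1, , drop = FALSE]
  if (nrow(light) == 0) stop("no complete light/dark pairs in the analysis range")
  mid <- bin_mid_hr(record)
  cpb <- record$counts
  Lj <- Dj <- numeric(nb)
  for (i in seq_len(nrow(light))) {
    ls <- light$start_hr[i]
    ds <- light$end_hr[i]            # dark phase follows the light phase
    for (j in seq_len(nb)) {
      off <- (j - 1) * bin_hr
      Lj[j] <- Lj[j] + sum(cpb[mid >= ls + off & mid < ls + off + bin_hr])
      Dj[j] <- Dj[j] + sum(cpb[mid >= ds + off & mid < ds + off + bin_hr])
    }
  }
  score <- ifelse(Lj + Dj > 0, 100 * Lj / (Lj + Dj), NA_real_)
  structure(data.frame(bin = seq_len(nb), offset_hr = (seq_len(nb) - 1) * bin_hr,
                       light_counts = Lj, dark_counts = Dj, score = score),
            class = c("masking_course", "data.frame"),
            n_light_phases = nrow(light))
}

#' Food-anticipatory activity metrics
#'
#' Quantifies FAA from a record under a feeding schedule: per-day counts in
#' the pre-meal window, the lead time at which the averaged, smoothed
#' activity profile first sustains half of its pre-meal maximum (scanning
#' backwards from mealtime to the last sub-half-maximum crossing), and the
#' fold change of mean counts-per-minute in the FAA window relative to a
#' baseline window.
#'
#' @param record an \code{activity_record} starting at ZT0 of feeding day 1.
#' @param feeding a \code{feeding_schedule}.
#' @param faa_window ZT window of anticipation, default \code{c(0, 6)}.
#' @param baseline_window ZT baseline window, default \code{c(10, 24)}.
#' @param day_range feeding days used for the averaged profile (default the
#'   last 7 scheduled days).
#' @param smooth_min centered moving-average width (minutes) applied to the
#'   6-min profile before the half-maximum scan.
#' @return A \code{faa_summary} list: \code{window_counts} (per-day counts in
#'   \code{faa_window}), \code{onset_lead_hr}, \code{fold_change} (NA and
#'   flagged when the baseline has no activity), \code{meal_start_zt}.
#' @export
faa_metrics <- function(record, feeding, faa_window = c(0, 6),
                        baseline_window = c(10, 24), day_range = NULL,
                        smooth_min = 30) {
  stopifnot(inherits(feeding, "feeding_schedule"))
  n_days <- min(nrow(feeding), floor(record_span_hr(record) / 24))
  if (is.null(day_range)) day_range <- c(max(1, n_days - 6), n_days)
  meal_start <- feeding$start_hr[nrow(feeding)]
  zt <- bin_mid_hr(record) %% 24
  day <- floor(bin_mid_hr(record) / 24) + 1
  in_faa <- zt >= faa_window[1] & zt < faa_window[2]
  window_counts <- vapply(seq_len(n_days), function(d)
    sum(record$counts[in_faa & day == d]), numeric(1))

  prof_bin <- if (6 %% record$bin_min == 0) 6 else record$bin_min
  prof <- fold_profile(record, fold_period_hr = 24, bin_min = prof_bin,
                       day_range = day_range)
  sm <- moving_average(prof$mean_cpm, round(smooth_min / prof_bin),
                       circular = TRUE)
  tt <- prof$time_hr + attr(prof, "bin_min") / 120  # bin midpoints
  pre_span <- faa_window[2] - faa_window[1]
  lead_rel <- (meal_start - tt) %% 24               # hours before mealtime
  pre <- lead_rel > 0 & lead_rel <= pre_span
  peak <- max(sm[pre])
  onset_lead <- NA_real_
  if (peak > 0) {
    half <- peak / 2
    ord <- order(lead_rel[pre])                     # nearest meal first
    lead_sorted <- lead_rel[pre][ord]
    v <- sm[pre][ord]
    below <- which(v < half)
    onset_lead <- if (!length(below)) pre_span else lead_sorted[below[1]]
  }
  in_base <- zt >= baseline_window[1] & zt < baseline_window[2]
  used <- day >= day_range[1] & day <= day_range[2]
  cpm_faa <- sum(record$counts[in_faa & used]) /
    (sum(in_faa & used) * record$bin_min)
  base_total <- sum(record$counts[in_base & used])
  fold_change <- if (base_total > 0)
    cpm_faa / (base_total / (sum(in_base & used) * record$bin_min)) else NA_real_
  structure(list(window_counts = window_counts, onset_lead_hr = onset_lead,
                 fold_change = fold_change, meal_start_zt = meal_start,
                 day_range = day_range,
                 flagged = is.na(fold_change)),
            class = "faa_summary")
}

## centered moving average; odd window enforced. circular = TRUE wraps the
## ends (for folded daily profiles); otherwise the edges where the full
## window does not fit are NA.
moving_average <- function(x, k, circular = FALSE) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2, circular = circular))
}
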
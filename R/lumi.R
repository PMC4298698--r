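#' Construct a bioluminescence trace
#'
#' Photomultiplier count series for one tissue explant. Corrected counts are
#' \code{(raw - background) / gain}.
#'
#' @param counts raw PMT counts at fixed intervals.
#' @param interval_min sampling interval (minutes), default 10.
#' @param t0 absolute hour of culture start (time axis origin).
#' @param background,gain PMT correction metadata.
#' @param medium_change_hr hour of medium change, or \code{NULL}.
#' @param animal_id,tissue,condition identifying labels.
#' @return An object of class \code{lumi_trace}.
#' @export
lumi_trace <- function(counts, interval_min = 10, t0 = 0, background = 0,
                       gain = 1, medium_change_hr = NULL,
                       animal_id = "animal", tissue = "tissue",
                       condition = "LD") {
  stopifnot(gain > 0, interval_min > 0)
  structure(list(counts = as.numeric(counts), interval_min = interval_min,
                 t0 = t0, background = background, gain = gain,
                 medium_change_hr = medium_change_hr, animal_id = animal_id,
                 tissue = tissue, condition = condition),
            class = "lumi_trace")
}

#' @export
print.lumi_trace <- function(x, ...) {
  cat(sprintf("<lumi_trace> %s %s (%s): %d samples at %g min (%.1f hr)\n",
              x$animal_id, x$tissue, x$condition, length(x$counts),
              x$interval_min, length(x$counts) * x$interval_min / 60))
  invisible(x)
}

#' Hours since culture start for each sample of a trace
#' @param trace a \code{lumi_trace}.
#' @export
trace_time_hr <- function(trace) {
  (seq_along(trace$counts) - 1) * trace$interval_min / 60
}

#' Background/gain correction of a trace
#'
#' @param trace a \code{lumi_trace}.
#' @return Data frame \code{time_hr} (hours since culture start),
#'   \code{value} (corrected counts); flagged via attribute
#'   \code{all_zero} when correction leaves no signal.
#' @export
correct_trace <- function(trace) {
  v <- (trace$counts - trace$background) / trace$gain
  out <- data.frame(time_hr = trace_time_hr(trace), value = v)
  attr(out, "all_zero") <- all(v == 0)
  out
}

#' Correct and trim a bioluminescence trace
#'
#' Applies background/gain correction, removes the initial
#' \code{trim_start_hr} hours (acute effects of explant preparation) and all
#' samples beyond \code{min(trim_end_hr, medium_change_hr)}.
#'
#' @param trace a \code{lumi_trace}.
#' @param trim_start_hr initial hours discarded (default 20).
#' @param trim_end_hr latest retained hour (default 192).
#' @return Data frame \code{time_hr}, \code{value} on the original absolute
#'   (culture-start) time axis; attribute \code{trim_start_hr}.
#' @export
preprocess_trace <- function(trace, trim_start_hr = 20, trim_end_hr = 192) {
  span <- length(trace$counts) * trace$interval_min / 60
  if (span <= trim_start_hr) stop("trace shorter than the start trim")
  s <- correct_trace(trace)
  keep <- s$time_hr >= trim_start_hr & s$time_hr <= trim_end_hr
  if (!is.null(trace$medium_change_hr))
    keep <- keep & s$time_hr < trace$medium_change_hr
  out <- s[keep, , drop = FALSE]
  if (diff(range(out$time_hr)) < 72)
    stop("fewer than 72 hr retained after trimming: too short for the ",
         "36-60 hr amplitude window and rhythm fitting")
  rownames(out) <- NULL
  attr(out, "trim_start_hr") <- trim_start_hr
  attr(out, "all_zero") <- all(out$value == 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full trace preparation for rhythm fitting
#'
#' Applies the fitting-side preprocessing chain in order: background/gain
#' correction, truncation at the medium change, running-average detrending
#' of the full corrected series, and only then the start/end trims. Doing
#' the detrend before the trims keeps the trimmed window fully covered by
#' the moving average (whose edges are dropped), so no fitted support is
#' lost -- which matters most for damped, low signal-to-noise traces whose
#' information is concentrated early.
#'
#' @param trace a \code{lumi_trace}.
#' @param trim_start_hr,trim_end_hr retained window (hr since culture
#'   start), defaults 20 and 192.
#' @param window_hr detrend window (default 24).
#' @return Detrended series (\code{time_hr}, \code{value}) over the trimmed
#'   support, with attribute \code{trim_start_hr} (used by
#'   \code{\link{fft_nlls}} to anchor the reported peak).
#' @export
prepare_trace <- function(trace, trim_start_hr = 20, trim_end_hr = 192,
                          window_hr = 24) {
  s <- correct_trace(trace)
  if (!is.null(trace$medium_change_hr))
    s <- s[s$time_hr < trace$medium_change_hr, , drop = FALSE]
  d <- detrend_running_average(s, window_hr)
  d <- d[d$time_hr >= trim_start_hr & d$time_hr <= trim_end_hr, , drop = FALSE]
  if (nrow(d) == 0 || diff(range(d$time_hr)) < 72)
    stop("fewer than 72 hr retained after detrending and trimming")
  rownames(d) <- NULL
  attr(d, "trim_start_hr") <- trim_start_hr
  d
}

#' Detrend a series by a centered running average
#'
#' Subtracts a centered moving average of width \code{window_hr} (rounded to
#' the nearest odd number of samples). Edges where the full window does not
#' fit are dropped, shortening the series by one window in total. A linear
#' trend is removed exactly; a sinusoid at the window period is removed
#' almost entirely (boxcar transfer function), so the detrend window must
#' differ from the signal period when absolute amplitudes matter.
#'
#' @param series data frame with \code{time_hr}, \code{value} at a uniform
#'   sampling step; span must be at least twice the window.
#' @param window_hr running-average width (hr), default 24.
#' @return The detrended, edge-trimmed series.
#' @export
detrend_running_average <- function(series, window_hr = 24) {
  t <- series$time_hr
  dt <- stats::median(diff(t))
  if (diff(range(t)) < 2 * window_hr)
    stop("series span must be at least twice the detrend window")
  k <- round(window_hr / dt)
  if (k %% 2 == 0) k <- k + 1L
  ma <- as.numeric(stats::filter(series$value, rep(1 / k, k), sides = 2))
  out <- data.frame(time_hr = t, value = series$value - ma)
  out <- out[!is.na(out$value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_hr") <- window_hr
  attr(out, "trim_start_hr") <- attr(series, "trim_start_hr")
  out
}

#' FFT-NLLS rhythm fit (damped cosine with linear trend)
#'
#' Fits \deqn{y(t) = c + b t + A e^{-t/T} \cos(2\pi (t - p)/\tau)} by
#' Levenberg-Marquardt least squares, seeded from the dominant discrete
#' Fourier component with period in \code{period_range}: initial tau and
#' phase from that component, initial amplitude from its spectral amplitude,
#' and no initial damping. The relative amplitude error (RAE) is the
#' halfwidth of the linearized 95\% confidence interval of A divided by the
#' fitted A, capped at 1 (0 = perfect rhythm, 1 = no significant rhythm).
#'
#' @param series detrended data frame \code{time_hr}, \code{value} spanning
#'   at least 72 hr.
#' @param damped fit an exponential damping term (rate bounded so the
#'   damping time constant stays >= \code{min_damping_hr}); if \code{FALSE}
#'   the cosine is undamped.
#' @param period_range allowed period range (hr) for the seeding Fourier
#'   component and the fitted tau.
#' @param min_damping_hr lower bound on the damping time constant.
#' @param noise_floor_mult a trace is flagged non-rhythmic (RAE = 1) when no
#'   spectral peak in \code{period_range} exceeds this multiple of the
#'   median spectral power.
#' @param conf_level confidence level for the amplitude interval.
#' @param peak_after_hr reference time for the reported phase: the first
#'   model peak at or after this hour. Defaults to the series'
#'   \code{trim_start_hr} attribute (set by \code{\link{preprocess_trace}}
#'   and propagated through detrending) or, failing that, the series start.
#' @return A \code{rhythm_fit} list: \code{period_hr}, \code{phase_hr}
#'   (time of the first model peak at or after \code{peak_after_hr}),
#'   \code{amplitude}, \code{damping_hr} (\code{Inf} when undamped),
#'   \code{rae}, \code{rss}, \code{trend = c(intercept, slope)},
#'   \code{converged}, \code{flagged}, \code{reason}.
#' @export
fft_nlls <- function(series, damped = TRUE, period_range = c(10, 40),
                     min_damping_hr = 12, noise_floor_mult = 3,
                     conf_level = 0.95, peak_after_hr = NULL) {
  t <- series$time_hr
  y <- series$value
  peak_after_hr <- peak_after_hr %||% attr(series, "trim_start_hr") %||% t[1]
  if (diff(range(t)) < 72) stop("series must span at least 72 hr for fitting")
  dt <- stats::median(diff(t))
  n <- length(y)
  yc <- y - mean(y)
  X <- stats::fft(yc)
  k <- seq_len(floor(n / 2))
  periods <- n * dt / k
  power <- Mod(X[k + 1])^2
  in_band <- periods >= period_range[1] & periods <= period_range[2]
  bad_fit <- function(reason) {
    structure(list(period_hr = NA_real_, phase_hr = NA_real_,
                   amplitude = NA_real_, damping_hr = NA_real_, rae = 1,
                   rss = NA_real_, trend = c(NA_real_, NA_real_),
                   converged = FALSE, flagged = TRUE, reason = reason),
              class = "rhythm_fit")
  }
  if (!any(in_band) || all(power[in_band] == 0)) return(bad_fit("non_rhythmic"))
  if (max(power[in_band]) <= noise_floor_mult * stats::median(power))
    return(bad_fit("non_rhythmic"))
  k_star <- k[in_band][which.max(power[in_band])]
  tau0 <- n * dt / k_star
  A0 <- 2 * Mod(X[k_star + 1]) / n
  ## X_k phase: component is A0 cos(2*pi*f*(t - t[1]) + phi)
  phi <- Arg(X[k_star + 1])
  p0 <- t[1] + (-phi * tau0 / (2 * pi)) %% tau0

  model <- function(par, t) {
    r <- if (damped) par["r"] else 0
    par["c"] + par["b"] * t +
      par["A"] * exp(-r * t) * cos(2 * pi * (t - par["p"]) / par["tau"])
  }
  par0 <- c(c = mean(y), b = 0, A = A0, tau = tau0, p = p0)
  lower <- c(c = -Inf, b = -Inf, A = 0, tau = period_range[1],
             p = p0 - tau0)
  upper <- c(c = Inf, b = Inf, A = Inf, tau = period_range[2], p = p0 + tau0)
  if (damped) {
    par0 <- c(par0, r = 0)
    lower <- c(lower, r = 0)
    upper <- c(upper, r = 1 / min_damping_hr)
  }
  fit <- try(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(par, t, y) y - model(par, t), t = t, y = y,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500)),
    silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4))
    return(bad_fit("non_converged"))
  par <- fit$par
  A <- unname(par["A"])
  tau <- unname(par["tau"])
  r <- if (damped) unname(par["r"]) else 0
  npar <- length(par)
  dof <- n - npar
  rss <- sum(fit$fvec^2)
  se_A <- tryCatch({
    cov <- solve(fit$hessian) * rss / dof
    sqrt(cov["A", "A"])
  }, error = function(e) NA_real_)
  rae <- if (is.na(se_A) || A <= 0) 1 else
    min(stats::qt(1 - (1 - conf_level) / 2, dof) * se_A / A, 1)
  ## first model peak at or after the series start: damped-cosine maxima sit
  ## at p + atan2(-r, omega)/omega + k tau
  omega <- 2 * pi / tau
  delta <- atan2(-r, omega) / omega
  kk <- ceiling((peak_after_hr - (par["p"] + delta)) / tau - 1e-9)
  phase_hr <- unname(par["p"] + delta + kk * tau)
  structure(list(period_hr = tau, phase_hr = phase_hr, amplitude = A,
                 damping_hr = if (r > 1e-6) 1 / r else Inf, rae = rae,
                 rss = rss, trend = unname(par[c("c", "b")]),
                 converged = TRUE, flagged = rae >= 1,
                 reason = if (rae >= 1) "non_rhythmic" else NA_character_),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (x$flagged && !x$converged) {
    cat("<rhythm_fit> flagged:", x$reason, "\n")
  } else {
    cat(sprintf("<rhythm_fit> tau = %.3f hr, first peak = %.2f hr, A = %.3g, RAE = %.3f%s\n",
                x$period_hr, x$phase_hr, x$amplitude, x$rae,
                if (is.finite(x$damping_hr)) sprintf(", damping T = %.1f hr", x$damping_hr) else ""))
  }
  invisible(x)
}

#' Evaluate the oscillatory component of a rhythm fit
#'
#' @param fit a \code{rhythm_fit}.
#' @param t hours.
#' @return \code{A exp(-t/T) cos(2 pi (t - p)/tau)} at \code{t}.
#' @export
fit_oscillation <- function(fit, t) {
  r <- if (is.finite(fit$damping_hr)) 1 / fit$damping_hr else 0
  fit$amplitude * exp(-r * t) * cos(2 * pi * (t - fit$phase_hr) / fit$period_hr)
}

#' Normalized relative amplitude of a fitted rhythm
#'
#' Half the peak-to-trough range of the fitted oscillation over the
#' amplitude window, divided by the mean of the corrected (undetrended)
#' signal over the same window. Invariant to PMT gain and background
#' settings after correction.
#'
#' @param fit a \code{rhythm_fit}.
#' @param corrected_series corrected series (\code{time_hr}, \code{value})
#'   before detrending.
#' @param window_hr amplitude window (hr since culture start), default
#'   \code{c(36, 60)}.
#' @return Relative amplitude (>= 0), or \code{NA} (flagged via attribute)
#'   when the mean corrected signal over the window is not positive.
#' @export
relative_amplitude <- function(fit, corrected_series, window_hr = c(36, 60)) {
  if (fit$flagged && !fit$converged) return(structure(NA_real_, flagged = TRUE))
  in_w <- corrected_series$time_hr >= window_hr[1] &
    corrected_series$time_hr <= window_hr[2]
  if (!any(in_w)) stop("amplitude window outside the retained support")
  denom <- mean(corrected_series$value[in_w])
  if (!(denom > 0)) return(structure(NA_real_, flagged = TRUE))
  tt <- seq(window_hr[1], window_hr[2], length.out = 481)
  osc <- fit_oscillation(fit, tt)
  (max(osc) - min(osc)) / 2 / denom
}

#' Quality-control filter for rhythm fits
#'
#' A fit is excluded when its relative amplitude error is at or above
#' \code{rae_max} (indistinguishable from background counts) or its period
#' lies outside the circadian range \code{period_range}.
#'
#' @param fit a \code{rhythm_fit}.
#' @param rae_max RAE exclusion threshold (default 0.84).
#' @param period_range retained period range (hr), default \code{c(17, 31)}
#'   (24 hr +/- 30\%).
#' @return List with \code{retained} (logical) and \code{reason}
#'   (\code{NA}, \code{"rae"} or \code{"period"}).
#' @export
qc_filter <- function(fit, rae_max = 0.84, period_range = c(17, 31)) {
  if (is.na(fit$period_hr) || fit$rae >= rae_max)
    return(list(retained = FALSE, reason = "rae"))
  if (fit$period_hr < period_range[1] || fit$period_hr > period_range[2])
    return(list(retained = FALSE, reason = "period"))
  list(retained = TRUE, reason = NA_character_)
}

#' Peak time of the second cycle of a trace
#'
#' Local maxima of the 3-hr-smoothed corrected series are indexed from
#' culture start -- including any peak inside the trimmed first 20 hr that
#' is visible in the raw series -- and the second maximum is returned.
#'
#' @param trace a \code{lumi_trace}, or a corrected series data frame.
#' @param smooth_hr centered moving-average width (hr) before peak picking.
#' @param min_peak_sep_hr a local maximum only counts as a cycle peak when
#'   it is the largest smoothed value within this window around it,
#'   suppressing noise bumps near troughs.
#' @return Peak time (hours since culture start); \code{NA} flagged when
#'   fewer than two maxima exist.
#' @export
second_cycle_peak <- function(trace, smooth_hr = 3, min_peak_sep_hr = 16) {
  s <- if (inherits(trace, "lumi_trace")) correct_trace(trace) else trace
  dt <- stats::median(diff(s$time_hr))
  sm <- moving_average(s$value, round(smooth_hr / dt))
  ok <- !is.na(sm)
  v <- sm[ok]
  tt <- s$time_hr[ok]
  d <- diff(v)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  half <- round(min_peak_sep_hr / 2 / dt)
  peaks <- peaks[vapply(peaks, function(i) {
    w <- max(1L, i - half):min(length(v), i + half)
    v[i] >= max(v[w])
  }, logical(1))]
  if (length(peaks) < 2) return(structure(NA_real_, flagged = TRUE))
  tt[peaks[2]]
}

#' Average duplicate tissue preparations within an animal
#'
#' Collapses multiple explants of the same tissue from the same animal to
#' one value: peak phases are averaged on the 24-hr circle (circular mean),
#' scalar quantities (period, relative amplitude) arithmetically. Duplicates
#' more than 6 hr apart on the circle are still averaged but flagged
#' discordant.
#'
#' @param entries data frame with columns \code{animal_id}, \code{tissue}
#'   and any of \code{phase_hr} (hours on a 24-hr circle), \code{period_hr},
#'   \code{rel_amplitude}.
#' @return One row per animal x tissue, with a \code{discordant} column.
#' @export
average_duplicates <- function(entries) {
  key <- interaction(entries$animal_id, entries$tissue, drop = TRUE)
  rows <- lapply(split(entries, key), function(g) {
    out <- g[1, , drop = FALSE]
    if ("phase_hr" %in% names(g)) {
      ang <- hours_to_angle(g$phase_hr)
      cs <- circ_summary(ang)
      out$phase_hr <- angle_to_hours(cs$mean_angle)
      sep <- max(outer(g$phase_hr, g$phase_hr, circ_dist_hr))
      out$discordant <- sep > 6
    } else out$discordant <- FALSE
    for (col in intersect(c("period_hr", "rel_amplitude"), names(g)))
      out[[col]] <- mean(g[[col]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

circ_dist_hr <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

#' Assemble a phase map from per-tissue peak times
#'
#' Converts absolute peak times (hours since culture start) to a common
#' reference frame per animal: \code{"ZT"} (hours after lights-on),
#' \code{"CT"} (circadian time anchored at the predicted activity onset =
#' CT12), or \code{"feeding"} (hours after daily food availability onset).
#'
#' @param peaks data frame with \code{animal_id}, \code{tissue},
#'   \code{peak_hr} (hours since culture start).
#' @param anchors named list (by animal id). Each element is a list with
#'   \code{frame} in \code{c("ZT","CT","feeding")}, \code{culture_start_zt}
#'   (ZT of culture start) and, for CT, \code{anchor} (a CT
#'   \code{time_anchor}) plus \code{culture_start_abs} (absolute hour of
#'   culture start on the anchor's axis); for feeding, \code{food_start_zt}.
#' @return Data frame of phase entries: \code{animal_id}, \code{tissue},
#'   \code{peak_hr}, \code{frame}, \code{phase_value} (hours in frame),
#'   \code{angle} (radians, \code{2 pi phase / 24}). Animals without an
#'   anchor are skipped and listed in attribute \code{skipped}.
#' @export
build_phase_map <- function(peaks, anchors) {
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(peaks))) {
    id <- as.character(peaks$animal_id[i])
    a <- anchors[[id]]
    if (is.null(a)) { skipped <- union(skipped, id); next }
    pv <- switch(a$frame,
      ZT = (a$culture_start_zt + peaks$peak_hr[i]) %% 24,
      CT = to_ct(a$culture_start_abs + peaks$peak_hr[i], a$anchor),
      feeding = (a$culture_start_zt + peaks$peak_hr[i] - a$food_start_zt) %% 24,
      stop("unknown frame '", a$frame, "'"))
    rows[[length(rows) + 1]] <- data.frame(
      animal_id = id, tissue = peaks$tissue[i], peak_hr = peaks$peak_hr[i],
      frame = a$frame, phase_value = pv, angle = hours_to_angle(pv))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(0), tissue = character(0),
               peak_hr = numeric(0), frame = character(0),
               phase_value = numeric(0), angle = numeric(0))
  attr(out, "skipped") <- skipped
  out
}

#' Read a luminometry trace (CSV + JSON sidecar)
#'
#' The CSV holds \code{time_hr}, \code{counts}; the sidecar (same path with
#' extension \code{.json}) holds the metadata fields of
#' \code{\link{lumi_trace}}.
#'
#' @param path CSV path.
#' @param sidecar optional explicit sidecar path.
#' @return A \code{lumi_trace}.
#' @export
read_lumi <- function(path, sidecar = NULL) {
  df <- utils::read.csv(path)
  sidecar <- sidecar %||% sub("\\.[^.]*$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list()
  dt <- stats::median(diff(df$time_hr)) * 60
  lumi_trace(df$counts, interval_min = dt,
             t0 = meta$t0 %||% 0, background = meta$background %||% 0,
             gain = meta$gain %||% 1,
             medium_change_hr = meta$medium_change_hr,
             animal_id = meta$animal_id %||% "animal",
             tissue = meta$tissue %||% "tissue",
             condition = meta$condition %||% "LD")
}

#' Write a luminometry trace (CSV + JSON sidecar)
#' @param trace a \code{lumi_trace}.
#' @param path CSV path; the sidecar is written next to it.
#' @export
write_lumi <- function(trace, path) {
  utils::write.csv(data.frame(time_hr = trace_time_hr(trace),
                              counts = trace$counts),
                   path, row.names = FALSE, quote = FALSE)
  meta <- trace[c("interval_min", "t0", "background", "gain",
                  "medium_change_hr", "animal_id", "tissue", "condition")]
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
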
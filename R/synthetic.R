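## Synthetic generators emulating the statistical structure of each assay:
## Poisson wheel-running counts gated by an entrainable oscillator with light
## masking and food anticipation; damped-cosine bioluminescence with drift;
## multi-tissue phase panels with wrapped-normal scatter; image stacks of
## blurred cellular oscillators with shot noise.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Parameters for the activity simulator
#'
#' @param genotype_mode \code{"control"} (functional circadian gate) or
#'   \code{"knockout"} (no gate: arrhythmic in constant conditions).
#' @param tau_hr free-running period of the gate.
#' @param gate_strength extra activity rate (counts/min) during subjective
#'   night.
#' @param base_rate ungated activity rate (counts/min). The default (0.5
#'   against a gate of 15) keeps daytime activity a few percent of the
#'   total, as in rhythmic controls; arrhythmic simulations typically raise
#'   it to reflect elevated ungated activity.
#' @param masking_suppression fraction of activity suppressed by light, in
#'   [0, 1].
#' @param masking_delay_min delay after lights-on before suppression engages
#'   (release at lights-off is immediate).
#' @param faa_amplitude peak food-anticipation rate (counts/min) once FAA is
#'   fully developed.
#' @param faa_span_hr hours before mealtime over which anticipation rises.
#' @param faa_growth_days time scale (days of restriction) over which the
#'   FAA component saturates.
#' @param seed optional integer seed.
#' @export
activity_sim_params <- function(genotype_mode = c("control", "knockout"),
                                tau_hr = 23.7, gate_strength = 15,
                                base_rate = 0.5, masking_suppression = 0.8,
                                masking_delay_min = 0, faa_amplitude = 0,
                                faa_span_hr = 3, faa_growth_days = 4,
                                seed = NULL) {
  genotype_mode <- match.arg(genotype_mode)
  stopifnot(gate_strength >= 0, base_rate >= 0,
            masking_suppression >= 0, masking_suppression <= 1)
  list(genotype_mode = genotype_mode, tau_hr = tau_hr,
       gate_strength = if (genotype_mode == "knockout") 0 else gate_strength,
       base_rate = base_rate, masking_suppression = masking_suppression,
       masking_delay_min = masking_delay_min, faa_amplitude = faa_amplitude,
       faa_span_hr = faa_span_hr, faa_growth_days = faa_growth_days,
       seed = seed)
}

## subjective-night onset times over the schedule: hard phase-locking to the
## start of the main dark period during entrainable 24-hr LD/LDLD phases,
## free-running at tau from the last locked onset otherwise
gate_onsets <- function(params, schedule) {
  tau <- params$tau_hr
  onsets <- numeric(0)
  night_dur <- numeric(0)
  last_onset <- 12            # lights-off of the reference LD 12:12 history
  for (i in seq_len(nrow(schedule$phases))) {
    ph <- schedule$phases[i, ]
    pat <- toupper(sub("[[:space:]].*$", "", ph$pattern))
    if (pat %in% c("LD", "LDLD")) {
      blocks <- schedule$blocks
      dk <- blocks[blocks$state == "dark" & blocks$start_hr >= ph$start_hr &
                     blocks$end_hr <= ph$end_hr, , drop = FALSE]
      if (nrow(dk)) {
        dur <- dk$end_hr - dk$start_hr
        main <- dk[dur >= max(dur) - 1e-9, , drop = FALSE]
        onsets <- c(onsets, main$start_hr)
        night_dur <- c(night_dur, pmin(main$end_hr - main$start_hr, 12))
        last_onset <- max(main$start_hr)
      }
    } else {
      o <- last_onset + tau * seq_len(ceiling((ph$end_hr - last_onset) / tau))
      o <- o[o >= ph$start_hr & o < ph$end_hr]
      onsets <- c(onsets, o)
      night_dur <- c(night_dur, rep(tau / 2, length(o)))
      if (length(o)) last_onset <- max(o)
    }
  }
  ord <- order(onsets)
  list(onset_hr = onsets[ord], night_dur_hr = night_dur[ord])
}

#' Simulate a wheel-running activity record
#'
#' Per-minute counts are Poisson with rate
#' \code{(base + gate * night(t) + faa(t)) * m(t)}: the circadian gate adds
#' activity during subjective night (phase-locked to lights-off under
#' entrainable LD/LDLD, free-running at tau otherwise; absent in
#' \code{"knockout"} mode); light masking multiplies the rate by
#' \code{1 - s} once \code{masking_delay_min} minutes of the light phase
#' have elapsed; the food-anticipation component rises exponentially over
#' \code{faa_span_hr} before each food window and saturates across
#' restriction days.
#'
#' @param params an \code{\link{activity_sim_params}} list.
#' @param schedule a \code{light_schedule} covering the simulated span.
#' @param feeding optional \code{feeding_schedule}.
#' @param days days to simulate (default: full schedule span).
#' @param bin_min output bin width (minutes).
#' @param animal_id label for the record.
#' @return List with \code{record} (an \code{activity_record}) and
#'   \code{truth} (tau, gate onsets, masking and FAA parameters).
#' @export
simulate_activity <- function(params, schedule, feeding = NULL, days = NULL,
                              bin_min = 6, animal_id = "sim") {
  days <- days %||% (schedule$span_hr / 24)
  span_hr <- days * 24
  if (span_hr > schedule$span_hr + 1e-9)
    stop("schedule does not cover the simulated span")
  n_min <- round(span_hr * 60)
  t <- (seq_len(n_min) - 0.5) / 60            # minute midpoints, hours
  rate <- rep(params$base_rate, n_min)

  gate <- gate_onsets(params, schedule)
  if (params$gate_strength > 0 && length(gate$onset_hr)) {
    night <- logical(n_min)
    for (i in seq_along(gate$onset_hr)) {
      o <- gate$onset_hr[i]
      night <- night | (t >= o & t < o + gate$night_dur_hr[i])
    }
    rate <- rate + params$gate_strength * night
  }

  faa_truth <- NULL
  if (!is.null(feeding) && params$faa_amplitude > 0 &&
      !isTRUE(attr(feeding, "ad_lib"))) {
    k <- params$faa_span_hr / 3
    faa <- numeric(n_min)
    for (d in feeding$day) {
      F_d <- (d - 1) * 24 + feeding$start_hr[feeding$day == d]
      w_d <- 1 - exp(-2 * (d - 1) / params$faa_growth_days)
      pre <- t >= F_d - params$faa_span_hr & t < F_d
      faa[pre] <- faa[pre] +
        params$faa_amplitude * w_d * exp(-(F_d - t[pre]) / k)
    }
    rate <- rate + faa
    faa_truth <- list(amplitude = params$faa_amplitude,
                      span_hr = params$faa_span_hr,
                      growth_days = params$faa_growth_days)
  }

  if (params$masking_suppression > 0) {
    blocks <- schedule$blocks
    lt <- blocks[blocks$state == "light", , drop = FALSE]
    if (nrow(lt)) {
      supp <- logical(n_min)
      for (i in seq_len(nrow(lt))) {
        s0 <- lt$start_hr[i] + params$masking_delay_min / 60
        supp <- supp | (t >= s0 & t < lt$end_hr[i])
      }
      rate[supp] <- rate[supp] * (1 - params$masking_suppression)
    }
  }

  counts <- with_seed(params$seed, stats::rpois(n_min, rate))
  rec <- activity_record(counts, bin_min = 1, start_hr = 0,
                         animal_id = animal_id,
                         genotype = params$genotype_mode)
  if (bin_min > 1) rec <- rebin_activity(rec, bin_min)
  list(record = rec,
       truth = list(tau_hr = params$tau_hr,
                    gate_onset_hr = gate$onset_hr,
                    gate_strength = params$gate_strength,
                    masking_suppression = params$masking_suppression,
                    masking_delay_min = params$masking_delay_min,
                    faa = faa_truth, seed = params$seed))
}

#' Parameters for the bioluminescence trace simulator
#'
#' @param tau_hr period of the planted rhythm.
#' @param phase0_hr time (hr since culture start) of an undamped cosine peak.
#' @param amplitude0 initial oscillation amplitude (counts).
#' @param damping_hr exponential damping time constant (hr).
#' @param baseline0 baseline counts at time 0.
#' @param drift_per_hr linear baseline drift (counts/hr).
#' @param noise \code{"gaussian"} or \code{"poisson"}.
#' @param noise_sd Gaussian noise SD (ignored for Poisson).
#' @param background,gain PMT metadata baked into the raw counts so that
#'   correction is exercised.
#' @param seed optional integer seed.
#' @export
lumi_sim_params <- function(tau_hr = 24, phase0_hr = 30, amplitude0 = 300,
                            damping_hr = 72, baseline0 = 500,
                            drift_per_hr = -0.5,
                            noise = c("gaussian", "poisson"), noise_sd = 10,
                            background = 100, gain = 2, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(amplitude0 >= 0, baseline0 >= 0, damping_hr > 0)
  list(tau_hr = tau_hr, phase0_hr = phase0_hr, amplitude0 = amplitude0,
       damping_hr = damping_hr, baseline0 = baseline0,
       drift_per_hr = drift_per_hr, noise = noise, noise_sd = noise_sd,
       background = background, gain = gain, seed = seed)
}

#' Simulate a bioluminescence trace
#'
#' Corrected-scale signal
#' \code{baseline0 + drift t + A0 exp(-t/T) cos(2 pi (t - phase0)/tau)} plus
#' noise, sampled at 10-min intervals, floored at zero, then re-expressed as
#' raw PMT counts via the gain and background metadata.
#'
#' @param params a \code{\link{lumi_sim_params}} list.
#' @param duration_hr recording length (>= 96 hr).
#' @param interval_min sampling interval.
#' @param ... labels passed to \code{\link{lumi_trace}} (animal_id, tissue,
#'   condition, medium_change_hr).
#' @return List with \code{trace} (a \code{lumi_trace}) and \code{truth}.
#' @export
simulate_trace <- function(params, duration_hr = 240, interval_min = 10,
                           ...) {
  if (duration_hr < 96) stop("duration must be at least 96 hr")
  t <- seq(0, duration_hr, by = interval_min / 60)
  signal <- params$baseline0 + params$drift_per_hr * t +
    params$amplitude0 * exp(-t / params$damping_hr) *
    cos(2 * pi * (t - params$phase0_hr) / params$tau_hr)
  value <- with_seed(params$seed, {
    if (params$noise == "gaussian")
      signal + stats::rnorm(length(t), 0, params$noise_sd)
    else stats::rpois(length(t), pmax(signal, 0))
  })
  value <- pmax(value, 0)
  raw <- value * params$gain + params$background
  trace <- lumi_trace(raw, interval_min = interval_min,
                      background = params$background, gain = params$gain, ...)
  list(trace = trace,
       truth = list(tau_hr = params$tau_hr, phase0_hr = params$phase0_hr,
                    amplitude0 = params$amplitude0,
                    damping_hr = params$damping_hr, seed = params$seed))
}

## mean tissue peak phases (ZT hours) used by the panel simulator
default_tissue_offsets <- c(SCN = 11, pituitary = 12, liver = 14.5,
                            kidney = 13.5, heart = 12.5, lung = 13.5,
                            spleen = 13)

#' Parameters for the multi-tissue phase panel simulator
#'
#' Condition presets reproduce the qualitative structure of the study
#' designs: tightly phased tissues in LD for both genotypes, dispersed and
#' damped knockout rhythms in DD, and feeding-locked liver/kidney (but not
#' heart/lung/spleen) under restricted feeding without a functional central
#' clock.
#'
#' @param n_animals animals per panel.
#' @param condition \code{"LD"}, \code{"DD"} or \code{"DD+FR"}.
#' @param genotype \code{"control"} or \code{"knockout"}.
#' @param tissues tissue names.
#' @param animal_phase_sd_hr SD of the animal-level phase (wrapped normal).
#' @param tissue_jitter_sd_hr SD of the per-tissue phase scatter within an
#'   animal; the per-animal circular variance is driven by this.
#' @param tissue_offsets named mean phase (ZT hr) per tissue.
#' @param amplitude_multiplier scales oscillation amplitude (damped rhythms
#'   in knockouts).
#' @param feeding_locked tissues entrained by the feeding schedule under
#'   \code{"DD+FR"}.
#' @param food_start_zt daily food-availability onset (ZT hr).
#' @param seed optional integer seed.
#' @export
panel_sim_params <- function(n_animals = 15,
                             condition = c("DD", "LD", "DD+FR"),
                             genotype = c("control", "knockout"),
                             tissues = c("pituitary", "liver", "kidney",
                                         "heart", "lung", "spleen"),
                             animal_phase_sd_hr = NULL,
                             tissue_jitter_sd_hr = NULL,
                             tissue_offsets = default_tissue_offsets,
                             amplitude_multiplier = NULL,
                             feeding_locked = c("liver", "kidney"),
                             food_start_zt = 6, seed = NULL) {
  condition <- match.arg(condition)
  genotype <- match.arg(genotype)
  knockout <- genotype == "knockout"
  if (is.null(animal_phase_sd_hr))
    animal_phase_sd_hr <- switch(condition,
      LD = if (knockout) 1.2 else 0.7,
      DD = if (knockout) 3 else 1,
      `DD+FR` = if (knockout) 3 else 1)
  if (is.null(tissue_jitter_sd_hr))
    tissue_jitter_sd_hr <- switch(condition,
      LD = if (knockout) 1.2 else 0.8,
      DD = if (knockout) 4 else 1,
      `DD+FR` = if (knockout) 4 else 1.2)
  if (is.null(amplitude_multiplier))
    amplitude_multiplier <- if (knockout && condition != "LD") 0.3 else 1
  stopifnot(length(tissues) > 0, animal_phase_sd_hr >= 0,
            tissue_jitter_sd_hr >= 0)
  list(n_animals = n_animals, condition = condition, genotype = genotype,
       tissues = tissues, animal_phase_sd_hr = animal_phase_sd_hr,
       tissue_jitter_sd_hr = tissue_jitter_sd_hr,
       tissue_offsets = tissue_offsets,
       amplitude_multiplier = amplitude_multiplier,
       feeding_locked = feeding_locked, food_start_zt = food_start_zt,
       seed = seed)
}

rwrapped_hr <- function(n, sd_hr) stats::rnorm(n, 0, sd_hr) %% 24

#' Simulate a multi-tissue phase panel
#'
#' Each animal draws a wrapped-normal phase; each tissue adds its mean
#' offset plus wrapped-normal scatter. Under the \code{"DD+FR"} knockout
#' preset, feeding-locked tissues (liver, kidney) cluster around a
#' feeding-determined phase with small scatter while the remaining tissues
#' stay dispersed.
#'
#' @param params a \code{\link{panel_sim_params}} list.
#' @param generate \code{"phases"} returns the truth phase table only;
#'   \code{"traces"} also simulates one bioluminescence trace per
#'   animal x tissue with matching peak phase and scaled amplitude.
#' @param duration_hr trace length when \code{generate = "traces"}.
#' @return List with \code{phases} (data frame \code{animal_id},
#'   \code{tissue}, \code{phase_hr}, \code{angle}), \code{params}, and
#'   (for traces) \code{traces}, a list of \code{lumi_trace}.
#' @export
simulate_panel <- function(params, generate = c("phases", "traces"),
                           duration_hr = 168) {
  generate <- match.arg(generate)
  with_seed(params$seed, {
    rows <- list()
    traces <- list()
    feeding_peak <- (params$food_start_zt + 8) %% 24  # post-meal peak phase
    for (i in seq_len(params$n_animals)) {
      id <- sprintf("%s_%s_%02d", params$genotype, params$condition, i)
      a_phase <- stats::rnorm(1, 0, params$animal_phase_sd_hr)
      for (tis in params$tissues) {
        off <- params$tissue_offsets[[tis]] %||% 13
        locked <- params$condition == "DD+FR" &&
          params$genotype == "knockout" && tis %in% params$feeding_locked
        phase <- if (locked)
          (feeding_peak + stats::rnorm(1, 0, 0.8)) %% 24
        else
          (off + a_phase + stats::rnorm(1, 0, params$tissue_jitter_sd_hr)) %% 24
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = id, tissue = tis, phase_hr = phase,
          angle = hours_to_angle(phase))
        if (generate == "traces") {
          tp <- lumi_sim_params(
            tau_hr = stats::rnorm(1, 24, 0.3), phase0_hr = 24 + phase,
            amplitude0 = 300 * params$amplitude_multiplier,
            damping_hr = if (params$amplitude_multiplier < 1) 48 else 96,
            baseline0 = 500, noise_sd = 10)
          traces[[paste(id, tis, sep = ".")]] <- simulate_trace(
            tp, duration_hr = duration_hr, animal_id = id, tissue = tis,
            condition = params$condition)$trace
        }
      }
    }
    phases <- do.call(rbind, rows)
    rownames(phases) <- NULL
    out <- list(phases = phases, params = params)
    if (generate == "traces") out$traces <- traces
    out
  })
}

#' Simulate a bioluminescence image stack
#'
#' Cells are placed uniformly at random in the field; each is a Gaussian
#' footprint whose intensity follows
#' \code{amp (1 + exp(-t/T) cos(2 pi (t - phase)/tau))} with wrapped-normal
#' phase scatter. Pixel values are the summed footprints plus a uniform
#' baseline, with Poisson shot noise; frames are sampled at 25-min
#' intervals.
#'
#' @param n_cells number of cells.
#' @param field_um field edge (micrometres); must tile into 40-um grids.
#' @param pixel_size_um pixel size.
#' @param cell_sigma_um Gaussian footprint SD.
#' @param phase_sd_hr wrapped-normal SD of cellular peak phases.
#' @param mean_phase_hr mean peak phase (hr).
#' @param amplitude per-cell amplitude scale (counts/pixel at the center).
#' @param amplitude_multiplier multiplies \code{amplitude} (knockout preset
#'   uses 0.3).
#' @param baseline background counts per pixel per frame.
#' @param tau_hr,damping_hr rhythm parameters.
#' @param days recording length (default 7).
#' @param shot_noise add Poisson noise (default \code{TRUE}).
#' @param seed optional integer seed.
#' @return List with \code{stack} (an \code{image_stack}) and \code{truth}
#'   (cell positions, phases, tau).
#' @export
simulate_stack <- function(n_cells = 40, field_um = 320, pixel_size_um = 4,
                           cell_sigma_um = 12, phase_sd_hr = 1,
                           mean_phase_hr = 12, amplitude = 60,
                           amplitude_multiplier = 1, baseline = 5,
                           tau_hr = 24, damping_hr = 96, days = 7,
                           shot_noise = TRUE, seed = NULL) {
  if ((field_um %% 40) != 0) stop("field must tile into 40-um grids")
  npx <- field_um / pixel_size_um
  if (abs(npx - round(npx)) > 1e-9) stop("field must be a whole number of pixels")
  npx <- round(npx)
  with_seed(seed, {
    t <- seq(0, days * 24, by = 25 / 60)
    pos <- cbind(x = stats::runif(n_cells, 0, field_um),
                 y = stats::runif(n_cells, 0, field_um))
    phases <- (mean_phase_hr + stats::rnorm(n_cells, 0, phase_sd_hr)) %% tau_hr
    px <- (seq_len(npx) - 0.5) * pixel_size_um
    ## footprints: pixels x cells
    Fmat <- matrix(0, npx * npx, n_cells)
    xs <- rep(px, times = npx)   # row coordinate varies fastest
    ys <- rep(px, each = npx)
    for (c in seq_len(n_cells))
      Fmat[, c] <- exp(-((xs - pos[c, 1])^2 + (ys - pos[c, 2])^2) /
                         (2 * cell_sigma_um^2))
    amp <- amplitude * amplitude_multiplier
    temporal <- amp * (1 + exp(-t / damping_hr) %o% rep(1, n_cells) *
                         cos(outer(t, phases, function(tt, p)
                           2 * pi * (tt - p) / tau_hr)))
    img <- Fmat %*% t(temporal) + baseline      # pixels x frames
    if (shot_noise)
      img <- matrix(stats::rpois(length(img), img), nrow = nrow(img))
    frames <- array(img, dim = c(npx, npx, length(t)))
    list(stack = image_stack(frames, pixel_size_um = pixel_size_um),
         truth = list(positions = pos, phases = phases, tau_hr = tau_hr,
                      phase_sd_hr = phase_sd_hr, amplitude = amp,
                      seed = seed))
  })
}
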
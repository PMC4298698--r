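#' Build a light schedule from a protocol description
#'
#' Constructs a contiguous timeline of light/dark blocks from a sequence of
#' protocol phases, each a standard photoperiod pattern held for a number of
#' days. Supported patterns:
#' \itemize{
#'   \item \code{"LD h:h"} ordinary light:dark cycle (e.g. \code{"LD 12:12"});
#'   \item \code{"DD"} constant darkness, \code{"LL"} constant light;
#'   \item \code{"LDLD a:b:c:d"} skeleton photoperiod, two light pulses per
#'     24-hr day (e.g. \code{"LDLD 1:10:1:12"});
#'   \item \code{"ULTRA h:h"} ultradian light:dark cycle whose cycle length
#'     (2h) need not divide 24 (e.g. \code{"ULTRA 3.5:3.5"}).
#' }
#' Time is continuous hours from the start of the protocol; hour 0 is ZT0
#' (lights-on) of the reference 12:12 LD day, so each light block is the
#' half-open interval \code{[start, end)}.
#'
#' @param protocol data frame with columns \code{pattern} (character) and
#'   \code{days} (number of days each pattern is held, >= 1).
#' @return An object of class \code{light_schedule}: a list with
#'   \code{blocks} (data frame \code{start_hr}, \code{end_hr}, \code{state}),
#'   \code{span_hr}, and the parsed \code{phases}.
#' @examples
#' sched <- build_light_schedule(data.frame(pattern = "LD 12:12", days = 2))
#' schedule_state(sched, c(0, 11.9, 12, 23.9))
#' @export
build_light_schedule <- function(protocol) {
  if (is.list(protocol) && !is.data.frame(protocol))
    protocol <- do.call(rbind, lapply(protocol, as.data.frame))
  if (!is.data.frame(protocol) || nrow(protocol) == 0L)
    stop("empty protocol: at least one (pattern, days) phase is required")
  stopifnot(all(c("pattern", "days") %in% names(protocol)))
  if (any(protocol$days < 1)) stop("each phase must last at least 1 day")

  blocks <- list()
  t <- 0
  phases <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    p <- parse_light_pattern(protocol$pattern[i])
    span <- protocol$days[i] * 24
    phases[[i]] <- list(pattern = protocol$pattern[i], days = protocol$days[i],
                        cycle_hr = p$cycle_hr, start_hr = t, end_hr = t + span)
    blocks[[i]] <- tile_pattern(p, t, t + span)
    t <- t + span
  }
  blocks <- do.call(rbind, blocks)
  ## merge adjacent blocks of equal state so the list is minimal
  keep <- c(TRUE, blocks$state[-1] != blocks$state[-nrow(blocks)])
  idx <- cumsum(keep)
  blocks <- data.frame(
    start_hr = tapply(blocks$start_hr, idx, min),
    end_hr   = tapply(blocks$end_hr, idx, max),
    state    = blocks$state[keep],
    row.names = NULL
  )
  structure(list(blocks = blocks, span_hr = t,
                 phases = do.call(rbind, lapply(phases, as.data.frame))),
            class = "light_schedule")
}

parse_light_pattern <- function(pattern) {
  pattern <- trimws(pattern)
  name <- toupper(sub("[[:space:]].*$", "", pattern))
  rest <- trimws(sub("^[^[:space:]]+", "", pattern))
  nums <- if (nzchar(rest)) as.numeric(strsplit(rest, ":")[[1]]) else numeric(0)
  if (anyNA(nums)) stop("cannot parse pattern components in '", pattern, "'")
  if (length(nums) && any(nums <= 0))
    stop("pattern components must be > 0 in '", pattern, "'")
  switch(name,
    DD = list(states = "dark", durs = 24, cycle_hr = 24),
    LL = list(states = "light", durs = 24, cycle_hr = 24),
    LD = {
      if (length(nums) != 2) stop("LD pattern needs two components")
      if (sum(nums) != 24) stop("LD cycle must sum to 24 hr, got ", sum(nums))
      list(states = c("light", "dark"), durs = nums, cycle_hr = 24)
    },
    LDLD = {
      if (length(nums) != 4) stop("LDLD pattern needs four components")
      if (sum(nums) != 24) stop("LDLD cycle must sum to 24 hr, got ", sum(nums))
      list(states = c("light", "dark", "light", "dark"), durs = nums,
           cycle_hr = 24)
    },
    ULTRA = {
      if (length(nums) != 2) stop("ULTRA pattern needs two components")
      list(states = c("light", "dark"), durs = nums, cycle_hr = sum(nums))
    },
    stop("unknown light pattern '", name, "'")
  )
}

## tile one pattern over [from, to), truncating the final partial cycle
tile_pattern <- function(p, from, to) {
  n_cycles <- ceiling((to - from) / p$cycle_hr)
  starts <- from + rep(seq_len(n_cycles) - 1, each = length(p$durs)) * p$cycle_hr +
    rep(cumsum(c(0, p$durs[-length(p$durs)])), n_cycles)
  ends <- starts + rep(p$durs, n_cycles)
  states <- rep(p$states, n_cycles)
  keep <- starts < to
  data.frame(start_hr = starts[keep], end_hr = pmin(ends[keep], to),
             state = states[keep])
}

#' Query the light state at given times
#'
#' @param schedule a \code{light_schedule}.
#' @param t numeric vector of absolute hours within the schedule span.
#' @return character vector, \code{"light"} or \code{"dark"}, one per time.
#' @export
schedule_state <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (any(t < 0 | t >= schedule$span_hr))
    stop("time outside schedule span [0, ", schedule$span_hr, ")")
  i <- findInterval(t, schedule$blocks$start_hr)
  schedule$blocks$state[i]
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule> span", x$span_hr, "hr,", nrow(x$blocks), "blocks\n")
  for (i in seq_len(nrow(x$phases)))
    cat(sprintf("  %-16s %g days (cycle %g hr)\n", x$phases$pattern[i],
                x$phases$days[i], x$phases$cycle_hr[i]))
  invisible(x)
}

#' Export a schedule as a two-column CSV (start_hr, state)
#'
#' @param schedule a \code{light_schedule}.
#' @param path output file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$blocks[, c("start_hr", "state")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a gradual food-restriction ramp schedule
#'
#' Daily food-availability windows that start at a fixed clock time and end
#' progressively earlier: on day 1 food is available for
#' \code{first_window_hr} ending at \code{first_removal_zt}; on each
#' successive day the removal time moves \code{step_hr} earlier until the
#' window has shrunk to \code{final_window_hr}, which is then held for
#' \code{n_fr_days} further days of stable restriction.
#'
#' @param first_removal_zt ZT/CT hour at which food is removed on ramp day 1.
#' @param first_window_hr duration (hr) of the day-1 window.
#' @param step_hr daily decrease of the removal time (hr, >= 0; 0 only for a
#'   degenerate no-ramp schedule with \code{final_window_hr == first_window_hr}).
#' @param final_window_hr duration (hr) of the final stable window.
#' @param n_fr_days number of stable restriction days appended after the ramp.
#' @return A \code{feeding_schedule}: data frame with columns \code{day},
#'   \code{start_hr}, \code{end_hr} (ZT hours of food availability), with
#'   attribute \code{ramp_days}.
#' @examples
#' fr <- build_fr_ramp(18, 12, 2, 4)        # 5 ramp days, final window ZT6-10
#' attr(fr, "ramp_days")
#' @export
build_fr_ramp <- function(first_removal_zt, first_window_hr, step_hr,
                          final_window_hr, n_fr_days = 0) {
  if (final_window_hr > first_window_hr)
    stop("final window must not exceed the first window")
  if (step_hr < 0) stop("step_hr must be >= 0")
  if (step_hr == 0 && final_window_hr != first_window_hr)
    stop("step_hr = 0 only valid when final and first windows are equal")
  widths <- if (step_hr == 0) first_window_hr else
    seq(first_window_hr, final_window_hr, by = -step_hr)
  if (utils::tail(widths, 1) != final_window_hr)
    stop("step_hr does not reach the final window exactly")
  if (any(widths < 0)) stop("schedule would produce a negative-length window")
  start <- first_removal_zt - first_window_hr
  ends <- start + widths
  ramp_days <- length(widths)
  day <- seq_len(ramp_days + n_fr_days)
  end_hr <- c(ends, rep(start + final_window_hr, n_fr_days))
  out <- data.frame(day = day, start_hr = start, end_hr = end_hr)
  structure(out, class = c("feeding_schedule", "data.frame"),
            ramp_days = ramp_days, ad_lib = FALSE)
}

#' Ad libitum feeding schedule over a number of days
#'
#' @param days number of days.
#' @return A \code{feeding_schedule} whose daily window spans the whole day.
#' @export
ad_lib_feeding <- function(days) {
  out <- data.frame(day = seq_len(days), start_hr = 0, end_hr = 24)
  structure(out, class = c("feeding_schedule", "data.frame"),
            ramp_days = 0L, ad_lib = TRUE)
}

#' Circadian-time anchor from detected activity onsets
#'
#' Fits a straight line through the last \code{n_last} detected activity
#' onsets (onset index vs absolute hour); the slope estimates the
#' free-running period tau and the line is extrapolated to the cycle nearest
#' \code{harvest_hr} (or to the next cycle when no harvest time is given) to
#' obtain the predicted onset, which is defined as CT12.
#'
#' For arrhythmic animals the onset series of a paired rhythmic control can
#' be supplied.
#'
#' @param onsets absolute hours of detected activity onsets (>= 2).
#' @param harvest_hr optional absolute hour of tissue harvest; the predicted
#'   onset is extrapolated to the cycle containing it.
#' @param n_last number of most recent onsets used in the regression.
#' @return An object of class \code{time_anchor} with \code{mode = "CT"},
#'   \code{tau_hr} and \code{predicted_onset_hr}.
#' @export
ct_anchor <- function(onsets, harvest_hr = NULL, n_last = 10) {
  if (length(onsets) < 2)
    stop("need at least 2 onsets to anchor circadian time")
  o <- utils::tail(sort(onsets), n_last)
  k <- seq_along(o)
  fit <- stats::lm(o ~ k)
  tau <- unname(stats::coef(fit)[2])
  if (!(tau > 0 && tau < 48)) stop("estimated tau outside (0, 48) hr")
  k_star <- if (is.null(harvest_hr)) length(o) + 1 else
    round((harvest_hr - stats::coef(fit)[1]) / tau)
  predicted <- unname(stats::coef(fit)[1] + tau * k_star)
  structure(list(mode = "CT", tau_hr = tau, predicted_onset_hr = predicted,
                 onset_hr = onsets),
            class = "time_anchor")
}

#' Zeitgeber-time anchor
#'
#' @param lights_on_hr absolute hour corresponding to ZT0 (lights-on) of the
#'   reference 12:12 LD cycle.
#' @return An object of class \code{time_anchor} with \code{mode = "ZT"}.
#' @export
zt_anchor <- function(lights_on_hr = 0) {
  structure(list(mode = "ZT", lights_on_hr = lights_on_hr),
            class = "time_anchor")
}

#' Convert absolute hours to circadian time
#'
#' CT is anchored so that the predicted activity onset maps to CT12 and one
#' free-running period tau spans 24 circadian hours:
#' \code{CT(t) = (12 + 24 (t - onset) / tau) mod 24}.
#'
#' @param t absolute hours.
#' @param anchor a \code{time_anchor} with \code{mode = "CT"}.
#' @return CT hours in [0, 24).
#' @export
to_ct <- function(t, anchor) {
  stopifnot(inherits(anchor, "time_anchor"))
  if (anchor$mode != "CT") stop("anchor is not a CT anchor")
  (12 + 24 * (t - anchor$predicted_onset_hr) / anchor$tau_hr) %% 24
}

#' Convert absolute hours to Zeitgeber time
#'
#' @param t absolute hours.
#' @param anchor a \code{time_anchor} with \code{mode = "ZT"}.
#' @return ZT hours in [0, 24).
#' @export
to_zt <- function(t, anchor) {
  stopifnot(inherits(anchor, "time_anchor"))
  if (anchor$mode != "ZT") stop("anchor is not a ZT anchor")
  (t - anchor$lights_on_hr) %% 24
}
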
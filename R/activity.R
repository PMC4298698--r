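#' Construct a wheel-running activity record
#'
#' @param counts non-negative integer wheel-revolution counts, one per bin.
#' @param bin_min minutes per bin; must divide 60.
#' @param start_hr absolute hour of the first bin's start.
#' @param animal_id,genotype identifying labels.
#' @return An object of class \code{activity_record}.
#' @export
activity_record <- function(counts, bin_min = 6, start_hr = 0,
                            animal_id = "animal", genotype = "control") {
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and complete")
  if (60 %% bin_min != 0) stop("bin_min must divide 60")
  structure(list(counts = as.numeric(counts), bin_min = bin_min,
                 start_hr = start_hr, animal_id = animal_id,
                 genotype = genotype),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("<activity_record> %s (%s): %d bins of %g min (%.1f days), %g total counts\n",
              x$animal_id, x$genotype, length(x$counts), x$bin_min,
              record_span_hr(x) / 24, sum(x$counts)))
  invisible(x)
}

#' Record span in hours
#' @param record an \code{activity_record}.
#' @export
record_span_hr <- function(record) length(record$counts) * record$bin_min / 60

## bin midpoints in absolute hours
bin_mid_hr <- function(record) {
  record$start_hr + (seq_along(record$counts) - 0.5) * record$bin_min / 60
}

#' Read an activity record from disk
#'
#' Two dialects are supported: \code{"csv"} (two columns \code{time_hr},
#' \code{counts}, header required; \code{time_hr} is the bin start) and
#' \code{"awd"} (Actimetrics-style text: a 7-line header with animal id,
#' start date, start time, bin length in minutes, age, sex and genotype,
#' followed by one count per line). The CSV dialect round-trips losslessly
#' through \code{\link{write_activity}}.
#'
#' @param path input file.
#' @param dialect \code{"csv"} or \code{"awd"}.
#' @return An \code{activity_record}.
#' @export
read_activity <- function(path, dialect = c("csv", "awd")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path)
    if (!all(c("time_hr", "counts") %in% names(df)))
      stop("activity CSV must have columns time_hr, counts")
    bad <- which(is.na(df$counts) | df$counts < 0)
    if (length(bad))
      stop("negative or missing counts at row ", bad[1])
    dt <- diff(df$time_hr)
    if (nrow(df) > 1 && any(abs(dt - dt[1]) > 1e-9))
      stop("non-uniform bin spacing at row ",
           which(abs(dt - dt[1]) > 1e-9)[1] + 1)
    bin_min <- if (nrow(df) > 1) dt[1] * 60 else 6
    activity_record(df$counts, bin_min = bin_min, start_hr = df$time_hr[1],
                    animal_id = sub("\\.[^.]*$", "", basename(path)))
  } else {
    lines <- readLines(path)
    if (length(lines) < 8) stop("AWD file too short for header + data")
    header <- lines[1:7]
    counts <- suppressWarnings(as.numeric(lines[-(1:7)]))
    bad <- which(is.na(counts) | counts < 0)
    if (length(bad))
      stop("negative or unparseable counts at data row ", bad[1])
    bin_min <- as.numeric(header[4])
    if (is.na(bin_min)) stop("AWD header line 4 must give bin minutes")
    activity_record(counts, bin_min = bin_min, start_hr = 0,
                    animal_id = trimws(header[1]),
                    genotype = trimws(header[7]))
  }
}

#' Write an activity record (CSV dialect)
#'
#' @param record an \code{activity_record}.
#' @param path output file.
#' @export
write_activity <- function(record, path) {
  df <- data.frame(time_hr = record$start_hr +
                     (seq_along(record$counts) - 1) * record$bin_min / 60,
                   counts = record$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an activity record in the AWD text dialect
#' @param record an \code{activity_record}.
#' @param path output file.
#' @export
write_activity_awd <- function(record, path) {
  header <- c(record$animal_id, "01-jan-00", "00:00",
              format(record$bin_min), "10", "M", record$genotype)
  writeLines(c(header, format(record$counts, trim = TRUE)), path)
  invisible(path)
}

#' Rebin an activity record to a coarser bin width
#'
#' Total counts are conserved exactly over complete coarse bins; a partial
#' trailing bin is dropped, never padded.
#'
#' @param record an \code{activity_record}.
#' @param bin_min new bin width (minutes); must be a multiple of the current
#'   width and divide 60.
#' @export
rebin_activity <- function(record, bin_min) {
  if (bin_min %% record$bin_min != 0)
    stop("new bin width must be a multiple of the current width")
  k <- bin_min / record$bin_min
  n <- floor(length(record$counts) / k)
  if (n == 0) stop("record shorter than one new bin")
  x <- record$counts[seq_len(n * k)]
  counts <- colSums(matrix(x, nrow = k))
  activity_record(counts, bin_min = bin_min, start_hr = record$start_hr,
                  animal_id = record$animal_id, genotype = record$genotype)
}

#' Average activity profile folded on a period
#'
#' Folds one or more records on \code{fold_period_hr} and averages
#' counts-per-minute across all folded cycles and animals, reporting the
#' per-bin mean and SEM (denominator: number of contributing cycles).
#'
#' @param records an \code{activity_record} or list of them.
#' @param fold_period_hr folding period (hr).
#' @param bin_min profile resolution (minutes; multiple of each record's bin).
#' @param day_range optional \code{c(first, last)} cycle (1-based, in units of
#'   the fold period from each record's start) restricting the data used.
#' @return An \code{activity_profile}: data frame with \code{bin},
#'   \code{time_hr} (bin start within the fold period), \code{mean_cpm},
#'   \code{sem_cpm}; attributes \code{fold_period_hr}, \code{n_cycles}.
#' @export
fold_profile <- function(records, fold_period_hr = 24, bin_min = 6,
                         day_range = NULL) {
  if (inherits(records, "activity_record")) records <- list(records)
  stopifnot(fold_period_hr > 0)
  bins_per_cycle <- fold_period_hr * 60 / bin_min
  if (abs(bins_per_cycle - round(bins_per_cycle)) > 1e-9)
    stop("bin_min must divide the fold period")
  bins_per_cycle <- round(bins_per_cycle)
  cycles <- list()
  for (rec in records) {
    r <- rebin_activity(rec, bin_min)
    n_cyc <- floor(length(r$counts) / bins_per_cycle)
    if (!is.null(day_range)) {
      if (day_range[2] > n_cyc)
        stop("day_range outside record span for animal ", r$animal_id)
      use <- seq(day_range[1], day_range[2])
    } else use <- seq_len(n_cyc)
    if (length(use) == 0) stop("no complete cycles in record")
    m <- matrix(r$counts[seq_len(n_cyc * bins_per_cycle)],
                nrow = bins_per_cycle)[, use, drop = FALSE]
    cycles[[length(cycles) + 1]] <- m / bin_min  # counts per minute
  }
  all_cycles <- do.call(cbind, cycles)
  mean_cpm <- rowMeans(all_cycles)
  n <- ncol(all_cycles)
  sem_cpm <- if (n > 1) apply(all_cycles, 1, stats::sd) / sqrt(n) else
    rep(0, bins_per_cycle)
  out <- data.frame(bin = seq_len(bins_per_cycle),
                    time_hr = (seq_len(bins_per_cycle) - 1) * bin_min / 60,
                    mean_cpm = mean_cpm, sem_cpm = sem_cpm)
  structure(out, class = c("activity_profile", "data.frame"),
            fold_period_hr = fold_period_hr, bin_min = bin_min, n_cycles = n)
}

#' Detect daily activity onsets
#'
#' An onset is the first bin of a run of bins whose counts-per-minute exceed
#' \code{threshold_frac} of the record's maximum rate, where the run is
#' sustained for at least \code{min_run_min} minutes and is preceded by at
#' least \code{quiet_hr} hours below threshold. At most one onset is
#' reported per circadian cycle (successive onsets are at least
#' \code{min_separation_hr} apart).
#'
#' @param record an \code{activity_record} spanning at least 2 days.
#' @param threshold_frac activity threshold as a fraction of the maximum
#'   bin rate.
#' @param min_run_min minimum sustained run (minutes) above threshold.
#' @param quiet_hr required preceding quiescence (hours).
#' @param min_separation_hr minimum spacing between reported onsets.
#' @return Numeric vector of onset times (absolute hours); empty with
#'   attribute \code{arrhythmic = TRUE} when no bin passes the criterion.
#' @export
detect_onsets <- function(record, threshold_frac = 0.1, min_run_min = 30,
                          quiet_hr = 4, min_separation_hr = 18) {
  if (record_span_hr(record) < 48) stop("record must span at least 2 days")
  x <- record$counts / record$bin_min
  thr <- threshold_frac * max(x)
  if (thr <= 0) {
    out <- numeric(0)
    attr(out, "arrhythmic") <- TRUE
    return(out)
  }
  above <- x >= thr
  run_bins <- ceiling(min_run_min / record$bin_min)
  quiet_bins <- ceiling(quiet_hr * 60 / record$bin_min)
  n <- length(x)
  candidate <- logical(n)
  for (i in seq_len(n)) {
    if (!above[i]) next
    if (i + run_bins - 1 > n) next
    if (!all(above[i:(i + run_bins - 1)])) next
    lo <- max(1L, i - quiet_bins)
    if (i == 1L || all(!above[lo:(i - 1L)])) candidate[i] <- TRUE
  }
  idx <- which(candidate)
  if (!length(idx)) {
    out <- numeric(0)
    attr(out, "arrhythmic") <- TRUE
    return(out)
  }
  sep_bins <- min_separation_hr * 60 / record$bin_min
  keep <- idx[1]
  for (i in idx[-1]) if (i - keep[length(keep)] >= sep_bins) keep <- c(keep, i)
  record$start_hr + (keep - 1) * record$bin_min / 60
}

#' Export a record as an actogram matrix (days x bins)
#'
#' Each row is one period of \code{period_hr} (default a calendar day; pass a
#' fitted free-running period to plot modulo tau). A trailing partial row is
#' padded with \code{NA}.
#'
#' @param record an \code{activity_record}.
#' @param period_hr row length in hours; must be a whole number of bins.
#' @return Numeric matrix with one row per period and one column per bin.
#' @export
actogram_matrix <- function(record, period_hr = 24) {
  bins <- period_hr * 60 / record$bin_min
  if (abs(bins - round(bins)) > 1e-9)
    stop("period_hr must be a whole number of bins")
  bins <- round(bins)
  n_rows <- ceiling(length(record$counts) / bins)
  x <- c(record$counts, rep(NA_real_, n_rows * bins - length(record$counts)))
  m <- matrix(x, ncol = bins, byrow = TRUE)
  colnames(m) <- sprintf("h%.2f", (seq_len(bins) - 1) * record$bin_min / 60)
  m
}
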
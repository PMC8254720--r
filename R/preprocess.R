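#' Preprocessing parameters for trace cleaning
#'
#' Thresholds for the four-step cleaning chain applied to every trial:
#' drop the first trial of each block, remove gross artifacts (pupil more
#' than `median_dev_max_mm` from the trial median or below `pupil_min_mm`),
#' excise `speed_excision_ms` epochs around samples whose pupil changes
#' faster than `speed_max_mm_per_s`, then average retained samples into
#' non-overlapping `bin_ms` windows (empty window = missing). Pupil traces
#' are expressed as change from the mean over the first `baseline_ms`, and
#' trials with `missing_frac_max` or more of their bins missing are
#' excluded.
#'
#' @param median_dev_max_mm Maximum absolute deviation from the trial
#'   median (mm); the documented robustness check reruns with 2.0.
#' @param pupil_min_mm Minimum plausible pupil diameter (mm).
#' @param speed_max_mm_per_s Maximum physiological pupil speed (mm/s).
#' @param speed_excision_ms Width of the excised epoch around a
#'   too-fast sample (centred: half on each side).
#' @param bin_ms Down-sampling window (100 ms = 10 Hz).
#' @param baseline_ms Baseline window from stimulus onset (within the
#'   light-response latency).
#' @param missing_frac_max Exclude a trial when the fraction of missing
#'   10 Hz bins reaches this value (ties excluded: ">= 40%").
#' @param exclude_first_trial_per_block Drop trial 1 of each block (its
#'   response is contaminated by the corridor onset).
#' @param trial_dur_ms Trial analysis window length (stimulus duration).
#' @return An object of class `pp_params`.
#' @export
pp_params <- function(median_dev_max_mm = 1.0,
                      pupil_min_mm = 0.1,
                      speed_max_mm_per_s = 2.5,
                      speed_excision_ms = 20,
                      bin_ms = 100,
                      baseline_ms = 200,
                      missing_frac_max = 0.40,
                      exclude_first_trial_per_block = TRUE,
                      trial_dur_ms = 4000) {
  p <- as.list(environment())
  num <- setdiff(names(p), "exclude_first_trial_per_block")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      stop("pp_params field `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (p$missing_frac_max > 1) stop("missing_frac_max must be in (0, 1]",
                                   call. = FALSE)
  structure(p, class = "pp_params")
}

#' Gross artifact rejection
#'
#' Removes samples with pupil below `pupil_min_mm` (blinks and signal
#' losses) or deviating more than `median_dev_max_mm` from the trial
#' median. The median is computed once over all raw samples of the trial,
#' before any removal; surviving samples are unmodified. Samples that are
#' already missing (NA pupil) count as removed.
#'
#' @param trace A `RawTrace` data.frame (`t_ms`, `pupil_mm`, optionally
#'   gaze columns).
#' @param params A [pp_params()].
#' @return List: `trace` (retained rows), `removed` (integer indices into
#'   the input rows), `median_mm` (the trial median used).
#' @export
filter_gross <- function(trace, params = pp_params()) {
  stopifnot(nrow(trace) > 0)
  med <- stats::median(trace$pupil_mm, na.rm = TRUE)
  bad <- is.na(trace$pupil_mm) |
    trace$pupil_mm < params$pupil_min_mm |
    abs(trace$pupil_mm - med) > params$median_dev_max_mm
  list(trace = trace[!bad, , drop = FALSE],
       removed = which(bad),
       median_mm = med)
}

#' Velocity-based artifact excision
#'
#' On the retained samples, the speed at each sample is the absolute pupil
#' change from its retained predecessor divided by the elapsed time. Any
#' sample faster than `speed_max_mm_per_s` marks every sample within half
#' of `speed_excision_ms` of its timestamp (inclusive) for removal; the
#' excised windows are unioned before removal. Applied after
#' [filter_gross()] so blink edges do not create spurious speeds.
#'
#' @param trace The gross-filtered `RawTrace`.
#' @param params A [pp_params()].
#' @return List: `trace` (retained rows), `removed` (indices into the
#'   *input* rows of this step).
#' @export
filter_speed <- function(trace, params = pp_params()) {
  n <- nrow(trace)
  if (n < 2L) return(list(trace = trace, removed = integer(0)))
  dp <- abs(diff(trace$pupil_mm))
  dt_s <- diff(trace$t_ms) / 1000
  speed <- dp / dt_s
  offenders <- which(speed > params$speed_max_mm_per_s) + 1L
  if (length(offenders) == 0L) {
    return(list(trace = trace, removed = integer(0)))
  }
  half <- params$speed_excision_ms / 2
  bad <- rep(FALSE, n)
  for (o in offenders) {
    bad <- bad | abs(trace$t_ms - trace$t_ms[o]) <= half
  }
  list(trace = trace[!bad, , drop = FALSE], removed = which(bad))
}

#' Down-sample retained samples to 10 Hz bins
#'
#' Bins are half-open windows `[k * bin_ms, (k+1) * bin_ms)` left-aligned at
#' stimulus onset, covering `[0, trial_dur_ms)`. Each channel's bin value is
#' the arithmetic mean of the retained samples falling in the window; a
#' window with no retained sample is missing (NA).
#'
#' @param trace The filtered `RawTrace`.
#' @param params A [pp_params()].
#' @return data.frame: `bin_start_ms`, `pupil_mm`, and `gaze_x_px` /
#'   `gaze_y_px` means when present in the input.
#' @export
downsample_trace <- function(trace, params = pp_params()) {
  n_bins <- ceiling(params$trial_dur_ms / params$bin_ms)
  starts <- (seq_len(n_bins) - 1L) * params$bin_ms
  bin_of <- floor(trace$t_ms / params$bin_ms) + 1L
  in_range <- bin_of >= 1L & bin_of <= n_bins
  chans <- intersect(c("pupil_mm", "gaze_x_px", "gaze_y_px"), names(trace))
  out <- data.frame(bin_start_ms = starts)
  for (ch in chans) {
    v <- rep(NA_real_, n_bins)
    if (any(in_range)) {
      m <- tapply(trace[[ch]][in_range], bin_of[in_range], mean)
      v[as.integer(names(m))] <- as.numeric(m)
    }
    out[[ch]] <- v
  }
  out
}

#' Baseline-correct a binned pupil trace
#'
#' The baseline is the mean of the non-missing bins starting before
#' `baseline_ms` (the pupillary light-response latency); every pupil bin
#' becomes change-from-baseline. If the whole baseline window is missing
#' the trial is marked invalid with reason `"no_baseline"`.
#'
#' @param binned Output of [downsample_trace()].
#' @param params A [pp_params()].
#' @return List of class `clean_trace`: `bins` (with `pupil_change_mm`,
#'   gaze in degrees if present), `baseline_mm`, `missing_fraction`,
#'   `valid`, `reason`.
#' @export
baseline_correct <- function(binned, params = pp_params()) {
  base_bins <- binned$bin_start_ms < params$baseline_ms
  base_vals <- binned$pupil_mm[base_bins]
  missing_fraction <- mean(is.na(binned$pupil_mm))
  if (all(is.na(base_vals))) {
    return(structure(list(bins = binned, baseline_mm = NA_real_,
                          missing_fraction = missing_fraction,
                          valid = FALSE, reason = "no_baseline"),
                     class = "clean_trace"))
  }
  baseline <- mean(base_vals, na.rm = TRUE)
  binned$pupil_change_mm <- binned$pupil_mm - baseline
  structure(list(bins = binned, baseline_mm = baseline,
                 missing_fraction = missing_fraction,
                 valid = TRUE, reason = NA_character_),
            class = "clean_trace")
}

#' Summarize a clean trace into one trial row
#'
#' The pupil response is the mean baseline-corrected change over the
#' response window (bins starting at or after `baseline_ms`); mean gaze is
#' computed over the same window. Trials with `missing_frac_max` or more of
#' their bins missing are invalid (reason `"too_missing"`).
#'
#' @param clean A `clean_trace` from [baseline_correct()].
#' @param params A [pp_params()].
#' @param screen A [screen_geometry()] for the gaze px-to-degrees map.
#' @return One-row data.frame: `pupil_response_mm`, `baseline_pupil_mm`,
#'   `gaze_x_deg`, `gaze_y_deg`, `missing_fraction`, `valid`, `reason`.
#' @export
summarize_trial <- function(clean, params = pp_params(),
                            screen = screen_geometry()) {
  stopifnot(inherits(clean, "clean_trace"))
  bins <- clean$bins
  resp_win <- bins$bin_start_ms >= params$baseline_ms
  valid <- clean$valid
  reason <- clean$reason
  if (valid && clean$missing_fraction >= params$missing_frac_max) {
    valid <- FALSE
    reason <- "too_missing"
  }
  resp <- NA_real_
  gx <- gy <- NA_real_
  if (valid) {
    resp <- mean(bins$pupil_change_mm[resp_win], na.rm = TRUE)
  }
  if (!is.null(bins$gaze_x_px)) {
    g <- gaze_to_degrees(mean(bins$gaze_x_px[resp_win], na.rm = TRUE),
                         mean(bins$gaze_y_px[resp_win], na.rm = TRUE),
                         screen)
    gx <- g[["x_deg"]]
    gy <- g[["y_deg"]]
  }
  data.frame(pupil_response_mm = resp,
             baseline_pupil_mm = clean$baseline_mm,
             gaze_x_deg = gx, gaze_y_deg = gy,
             missing_fraction = clean$missing_fraction,
             valid = valid,
             reason = reason %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Screen geometry for gaze linearization
#'
#' @param width_px,height_px Display resolution (1024 x 768).
#' @param width_deg,height_deg Display extent in degrees (40 x 30 at 57 cm).
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            width_deg = 40, height_deg = 30) {
  structure(list(width_px = width_px, height_px = height_px,
                 width_deg = width_deg, height_deg = height_deg),
            class = "screen_geometry")
}

#' Convert gaze pixels to degrees from screen centre
#'
#' Linear map; y increases upward. Sample files store y already in this
#' math-style convention (the converter from screen-native row coordinates,
#' which increase downward, flips the sign when writing).
#'
#' @param x_px,y_px Gaze coordinates in pixels.
#' @param screen A [screen_geometry()].
#' @return Named numeric vector / data.frame columns `x_deg`, `y_deg`.
#' @export
gaze_to_degrees <- function(x_px, y_px, screen = screen_geometry()) {
  c(x_deg = unname((x_px - screen$width_px / 2) *
                     screen$width_deg / screen$width_px),
    y_deg = unname((y_px - screen$height_px / 2) *
                     screen$height_deg / screen$height_px))
}

#' Preprocess one trial trace end to end
#'
#' Applies gross filtering, velocity excision, 10 Hz down-sampling,
#' baseline correction and summarisation.
#'
#' @param trace A `RawTrace` data.frame.
#' @param params A [pp_params()].
#' @param screen A [screen_geometry()].
#' @return One-row data.frame as [summarize_trial()], plus
#'   `n_removed_gross` and `n_removed_speed`.
#' @export
preprocess_trial <- function(trace, params = pp_params(),
                             screen = screen_geometry()) {
  g <- filter_gross(trace, params)
  s <- filter_speed(g$trace, params)
  binned <- downsample_trace(s$trace, params)
  clean <- baseline_correct(binned, params)
  out <- summarize_trial(clean, params, screen)
  out$n_removed_gross <- length(g$removed)
  out$n_removed_speed <- length(s$removed)
  out
}

#' Preprocess a whole session
#'
#' Drops the first trial of each block, then runs the full cleaning chain
#' on every remaining trial, producing per-trial summaries and an
#' exclusion log.
#'
#' @param trials Trial metadata data.frame (columns `participant_id`,
#'   `block`, `trial`, `size_level`, `location`, `report_mm`).
#' @param traces List of `RawTrace` data.frames, parallel to `trials` rows.
#' @param params A [pp_params()].
#' @param screen A [screen_geometry()].
#' @return List: `summaries` (metadata + summary columns, one row per
#'   non-dropped trial) and `log` (participant, block, trial,
#'   n_removed_gross, n_removed_speed, missing_fraction, valid, reason —
#'   including the dropped first trials with reason `"first_in_block"`).
#' @export
preprocess_session <- function(trials, traces, params = pp_params(),
                               screen = screen_geometry()) {
  stopifnot(nrow(trials) == length(traces))
  first <- params$exclude_first_trial_per_block & trials$trial == 1L
  rows <- vector("list", nrow(trials))
  logs <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    meta <- trials[i, c("participant_id", "block", "trial",
                        "size_level", "location", "report_mm")]
    if (first[i]) {
      logs[[i]] <- cbind(meta[c("participant_id", "block", "trial")],
                         n_removed_gross = NA_integer_,
                         n_removed_speed = NA_integer_,
                         missing_fraction = NA_real_,
                         valid = FALSE, reason = "first_in_block")
      next
    }
    s <- preprocess_trial(traces[[i]], params, screen)
    rows[[i]] <- cbind(meta, s)
    logs[[i]] <- cbind(meta[c("participant_id", "block", "trial")],
                       s[c("n_removed_gross", "n_removed_speed",
                           "missing_fraction", "valid", "reason")])
  }
  summaries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(summaries) <- NULL
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  list(summaries = summaries, log = log)
}
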
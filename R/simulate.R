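#' Simulation configuration ("paper-like" preset by default)
#'
#' Defines a complete generative model for synthetic sessions: 500 Hz pupil
#' traces whose light-response amplitude follows *perceived* (not physical)
#' figurine size, magnitude-estimation reports, gaze offsets tied to
#' figurine location and size, blink/spike artifacts, and an AQ-dependent
#' contextual (far vs near) perceived-size inflation.
#'
#' The perceived size of a far figurine is inflated by a contextual gain
#' `context_gain(aq) = context_gain_c0 * max(0, 1 - aq_coupling_beta *
#' (aq - aq_min)/(aq_max - aq_min))`, so the illusion weakens with
#' increasing autistic traits. Verbal size reports use a *separate,
#' AQ-independent* contextual gain (`report_context_gain`), reproducing the
#' behavioural/pupillometric dissociation the analysis is designed to
#' detect.
#'
#' The pupil constriction amplitude saturates with perceived light flux
#' (proportional to height squared):
#' `A(p) = saturation_a_max * (1 - exp(-gain_g * p^2 / saturation_a_max))`,
#' convolved in time with a unit-peak gamma kernel of shape `kernel_shape`
#' and time constant `kernel_tau_s`, delayed by `response_latency_s`.
#'
#' @param n_participants Number of simulated participants (default 50).
#' @param aq_min,aq_max Range of the discrete-uniform AQ sampler (2..31,
#'   matching a neurotypical adult sample below the clinical cut-off).
#' @param sampling_rate_hz Nominal eye-tracker rate (500).
#' @param fixation_s,stimulus_s Trial timeline: 1 s fixation, 4 s stimulus.
#' @param baseline_pupil_mm Mean pupil diameter at stimulus onset.
#' @param baseline_between_sd_mm Between-participant SD of baseline pupil.
#' @param baseline_trial_sd_mm Trial-to-trial SD of baseline pupil.
#' @param response_latency_s Latency of the pupillary light response.
#' @param kernel_shape,kernel_tau_s Gamma impulse-response parameters.
#' @param gain_g Constriction per unit perceived area (mm per deg^2) in the
#'   linear regime.
#' @param saturation_a_max Maximum attainable constriction (mm); produces
#'   the size-by-location interaction through saturation.
#' @param trial_amp_sd_mm Trial-to-trial SD of the constriction amplitude
#'   (physiological response variability).
#' @param reactivity_sd Between-participant SD of a multiplicative pupil
#'   reactivity factor (mean 1, truncated at 0.2).
#' @param context_gain_c0 Fractional perceived-size inflation for far
#'   stimuli at the minimum AQ.
#' @param aq_coupling_beta Fractional reduction of the pupil-channel context
#'   gain per unit of normalized AQ; values > 1 zero the gain below aq_max.
#' @param report_context_gain AQ-independent contextual gain used for
#'   verbal reports.
#' @param report_scale_mm_per_deg Millimetres reported per degree of
#'   perceived size (10 at 57 cm viewing distance, where 1 deg ~ 1 cm).
#' @param report_weber Multiplicative (Weber) report-noise coefficient.
#' @param pixels_per_degree Screen scale (1024 px / 40 deg = 25.6).
#' @param gaze_near_deg,gaze_far_deg Mean gaze offset (x, y) in degrees for
#'   the two locations (far figurines are higher and more to the right).
#' @param gaze_size_slope_deg_per_deg Vertical gaze shift per degree of
#'   figurine height above the base height (centre of mass rises with
#'   size).
#' @param gaze_noise_sd_deg Per-sample gaze jitter SD.
#' @param blink_rate_hz,blink_dur_ms Poisson blink process: onset rate and
#'   fixed duration; blink samples drop below 0.1 mm.
#' @param blink_rate_participant_sd Log-normal sigma of the per-participant
#'   blink-rate multiplier.
#' @param blink_as_gap If `TRUE`, blinks are emitted as missing samples
#'   (empty fields) instead of sub-0.1 mm values.
#' @param spike_rate_hz,spike_amp_mm Isolated spike artifacts: rate and
#'   displacement magnitude (sign random).
#' @param noise_sd_mm White measurement noise SD (per 500 Hz sample).
#' @param p_female Probability a participant is recorded as female (the
#'   generator gives gender no effect on any response).
#' @param seed Integer master seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 50,
                       aq_min = 2, aq_max = 31,
                       sampling_rate_hz = 500,
                       fixation_s = 1.0,
                       stimulus_s = 4.0,
                       baseline_pupil_mm = 4.26,
                       baseline_between_sd_mm = 0.7,
                       baseline_trial_sd_mm = 0.05,
                       response_latency_s = 0.2,
                       kernel_shape = 3,
                       kernel_tau_s = 0.55,
                       gain_g = 0.02,
                       saturation_a_max = 1.2,
                       trial_amp_sd_mm = 0.35,
                       reactivity_sd = 0.25,
                       context_gain_c0 = 0.20,
                       aq_coupling_beta = 1.5,
                       report_context_gain = 0.15,
                       report_scale_mm_per_deg = 10,
                       report_weber = 0.15,
                       pixels_per_degree = 25.6,
                       gaze_near_deg = c(-2, -2),
                       gaze_far_deg = c(2, 2),
                       gaze_size_slope_deg_per_deg = 0.3,
                       gaze_noise_sd_deg = 0.5,
                       blink_rate_hz = 0.5,
                       blink_dur_ms = 500,
                       blink_rate_participant_sd = 0.5,
                       blink_as_gap = FALSE,
                       spike_rate_hz = 0.5,
                       spike_amp_mm = 2,
                       noise_sd_mm = 0.001,
                       p_female = 0.66,
                       seed = 1L) {
  cfg <- as.list(environment())
  nonneg <- c("sampling_rate_hz", "fixation_s", "stimulus_s",
              "baseline_pupil_mm", "baseline_between_sd_mm",
              "baseline_trial_sd_mm", "response_latency_s", "kernel_shape",
              "kernel_tau_s", "gain_g", "saturation_a_max",
              "trial_amp_sd_mm", "reactivity_sd", "context_gain_c0",
              "aq_coupling_beta", "report_context_gain",
              "report_scale_mm_per_deg", "report_weber",
              "pixels_per_degree", "gaze_size_slope_deg_per_deg",
              "gaze_noise_sd_deg", "blink_rate_hz", "blink_dur_ms",
              "blink_rate_participant_sd", "spike_rate_hz", "spike_amp_mm",
              "noise_sd_mm")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("sim_config field `", f, "` must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (cfg$n_participants < 1) stop("need at least 1 participant", call. = FALSE)
  if (cfg$aq_min < 0 || cfg$aq_max > 50 || cfg$aq_min > cfg$aq_max) {
    stop("AQ sampler range must lie within 0..50", call. = FALSE)
  }
  if (length(cfg$gaze_near_deg) != 2L || length(cfg$gaze_far_deg) != 2L) {
    stop("gaze offsets must be (x, y) pairs in degrees", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Contextual perceived-size gain as a function of AQ
#'
#' @param aq Integer AQ score(s) or an [aq_score()] object.
#' @param cfg A [sim_config()].
#' @param channel `"pupil"` (AQ-coupled) or `"report"` (AQ-independent).
#' @return Non-negative fractional gain(s), vectorized over `aq`.
#' @export
context_gain <- function(aq, cfg, channel = c("pupil", "report")) {
  channel <- match.arg(channel)
  if (inherits(aq, "aq_score")) aq <- aq$score
  if (channel == "report") {
    return(rep(cfg$report_context_gain, length(aq)))
  }
  z <- (aq - cfg$aq_min) / (cfg$aq_max - cfg$aq_min)
  cfg$context_gain_c0 * pmax(0, 1 - cfg$aq_coupling_beta * z)
}

#' Perceived figurine height under the corridor illusion
#'
#' Near-end figurines are the reference (perceived = physical); far-end
#' figurines are perceived inflated by the contextual gain, which for the
#' pupil channel decreases with AQ (and is zero once the coupling saturates).
#'
#' @param physical_deg Physical height(s), degrees (> 0).
#' @inheritParams context_gain
#' @param location `"near"` or `"far"` (vectorized, recycled).
#' @return Perceived height(s) in degrees.
#' @export
perceived_height <- function(physical_deg, location, aq, cfg,
                             channel = c("pupil", "report")) {
  channel <- match.arg(channel)
  if (any(physical_deg <= 0)) stop("physical height must be > 0", call. = FALSE)
  if (!all(location %in% c("near", "far"))) {
    stop("location must be 'near' or 'far'", call. = FALSE)
  }
  g <- context_gain(aq, cfg, channel)
  physical_deg * ifelse(location == "far", 1 + g, 1)
}

#' Saturating constriction amplitude for a perceived size
#'
#' `A(p) = a_max * (1 - exp(-g * p^2 / a_max))`: strictly increasing and
#' concave in `p`, approaching `g * p^2` for small `g` and saturating at
#' `a_max`. Driving on area (height squared) reflects the dependence of the
#' light response on stimulus light flux.
#'
#' @param perceived_deg Perceived height(s), degrees.
#' @param cfg A [sim_config()].
#' @return Amplitude(s) in mm of constriction.
#' @export
response_amplitude <- function(perceived_deg, cfg) {
  a <- cfg$saturation_a_max
  g <- cfg$gain_g
  if (a == 0 || g == 0) return(g * perceived_deg^2)
  a * (1 - exp(-g * perceived_deg^2 / a))
}

#' Unit-peak gamma impulse response of the pupillary light response
#'
#' @param t_s Time(s) from response onset in seconds (values <= 0 give 0).
#' @param cfg A [sim_config()].
#' @return Kernel values, peaking at 1 at `(shape - 1) * tau` seconds.
#' @export
pupil_kernel <- function(t_s, cfg) {
  s <- cfg$kernel_shape
  tau <- cfg$kernel_tau_s
  tpk <- (s - 1) * tau
  k <- numeric(length(t_s))
  pos <- t_s > 0
  k[pos] <- (t_s[pos] / tpk)^(s - 1) * exp((s - 1) * (1 - t_s[pos] / tpk))
  k
}

# Mean of the (latency-shifted) kernel over the response window
# [baseline_ms, stimulus end), as used when predicting the expected
# baseline-corrected pupil response from an amplitude.
kernel_window_mean <- function(cfg, baseline_ms = 200) {
  tt <- seq(baseline_ms / 1000, cfg$stimulus_s, by = 1e-3)
  mean(pupil_kernel(tt - cfg$response_latency_s, cfg))
}

#' Simulate one artifact-free 500 Hz trial trace
#'
#' The expected trace is `baseline - A(perceived) * K(t - latency)`; before
#' the response latency it equals the baseline, so the first 200 ms are an
#' uncontaminated baseline window. Gaussian measurement noise is added per
#' sample. Gaze is the location/size-dependent mean offset plus jitter.
#'
#' @param trial One-row data.frame with `size_level` and `location` (as from
#'   [build_trial_list()]).
#' @param perceived_deg Perceived height driving the pupil response.
#' @param cfg A [sim_config()].
#' @param baseline_mm Trial baseline pupil diameter (mm).
#' @param amplitude_mm Constriction amplitude; defaults to
#'   `response_amplitude(perceived_deg, cfg)`.
#' @param set The [stimulus_set()] (for size-dependent gaze height).
#' @return A data.frame (`RawTrace`): `t_ms`, `pupil_mm`, `gaze_x_px`,
#'   `gaze_y_px`, with `t_ms` = 0, 2, ..., covering `[0, stimulus_s)`.
#' @export
simulate_trial_trace <- function(trial, perceived_deg, cfg,
                                 baseline_mm = cfg$baseline_pupil_mm,
                                 amplitude_mm = response_amplitude(perceived_deg, cfg),
                                 set = stimulus_set()) {
  dt <- 1000 / cfg$sampling_rate_hz
  t_ms <- seq(0, cfg$stimulus_s * 1000 - dt, by = dt)
  k <- pupil_kernel(t_ms / 1000 - cfg$response_latency_s, cfg)
  pupil <- baseline_mm - amplitude_mm * k
  if (cfg$noise_sd_mm > 0) {
    pupil <- pupil + stats::rnorm(length(t_ms), 0, cfg$noise_sd_mm)
  }
  mu <- if (trial$location == "far") cfg$gaze_far_deg else cfg$gaze_near_deg
  h <- stimulus_heights(set)[trial$size_level]
  mu_y <- mu[2] + cfg$gaze_size_slope_deg_per_deg * (h - set$base_height_deg)
  gx <- mu[1] + stats::rnorm(length(t_ms), 0, cfg$gaze_noise_sd_deg)
  gy <- mu_y + stats::rnorm(length(t_ms), 0, cfg$gaze_noise_sd_deg)
  data.frame(t_ms = t_ms,
             pupil_mm = pupil,
             gaze_x_px = 512 + gx * cfg$pixels_per_degree,
             gaze_y_px = 384 + gy * cfg$pixels_per_degree)
}

#' Inject blink and spike artifacts into a trace
#'
#' Blinks are contiguous runs (Poisson onsets at `blink_rate_hz`, duration
#' `blink_dur_ms`) whose pupil samples are forced below 0.1 mm (or to
#' missing when `blink_as_gap`); spikes are isolated samples displaced by
#' `spike_amp_mm` with random sign. The exact corrupted indices are
#' returned so tests can verify the cleaning chain against ground truth.
#'
#' @param trace A `RawTrace` data.frame.
#' @param cfg A [sim_config()].
#' @param blink_rate_hz Blink onset rate for this trial (defaults to the
#'   config value; per-participant multipliers are applied upstream).
#' @return List: `trace` (corrupted copy), `blink_idx`, `spike_idx`
#'   (integer sample indices; empty when rates are 0).
#' @export
inject_artifacts <- function(trace, cfg, blink_rate_hz = cfg$blink_rate_hz) {
  n <- nrow(trace)
  stopifnot(n > 0, all(is.finite(trace$t_ms)))
  dur_s <- cfg$stimulus_s
  blink_idx <- integer(0)
  if (blink_rate_hz > 0) {
    n_blinks <- stats::rpois(1, blink_rate_hz * dur_s)
    if (n_blinks > 0) {
      onsets <- stats::runif(n_blinks, 0, dur_s * 1000)
      for (o in onsets) {
        idx <- which(trace$t_ms >= o & trace$t_ms < o + cfg$blink_dur_ms)
        blink_idx <- union(blink_idx, idx)
      }
      blink_idx <- sort(blink_idx)
      if (cfg$blink_as_gap) {
        trace$pupil_mm[blink_idx] <- NA_real_
      } else {
        trace$pupil_mm[blink_idx] <- 0.01
      }
    }
  }
  spike_idx <- integer(0)
  if (cfg$spike_rate_hz > 0) {
    n_spikes <- stats::rpois(1, cfg$spike_rate_hz * dur_s)
    if (n_spikes > 0) {
      cand <- setdiff(seq_len(n), blink_idx)
      n_spikes <- min(n_spikes, length(cand))
      spike_idx <- sort(sample(cand, n_spikes))
      signs <- sample(c(-1, 1), n_spikes, replace = TRUE)
      trace$pupil_mm[spike_idx] <- trace$pupil_mm[spike_idx] +
        signs * cfg$spike_amp_mm
    }
  }
  list(trace = trace, blink_idx = blink_idx, spike_idx = spike_idx)
}

#' Simulate a verbal magnitude-estimation report
#'
#' `report = scale * perceived * (1 + N(0, weber))` millimetres: expectation
#' proportional to perceived size, with multiplicative (Weber-like) noise.
#'
#' @param perceived_deg Perceived height (degrees) for the report channel.
#' @param cfg A [sim_config()].
#' @return Report in millimetres.
#' @export
simulate_report <- function(perceived_deg, cfg) {
  perceived_deg * cfg$report_scale_mm_per_deg *
    (1 + stats::rnorm(length(perceived_deg), 0, cfg$report_weber))
}

#' Simulate a complete session for one participant
#'
#' Draws AQ, gender, baseline pupil, reactivity and blink-rate multipliers,
#' builds the balanced 100-trial list, and simulates every trial's 500 Hz
#' trace (with artifacts), gaze and verbal report. Fully reproducible from
#' `(cfg$seed, participant_id)`.
#'
#' @param cfg A [sim_config()].
#' @param participant_id Positive integer id.
#' @param aq Optional fixed AQ score (otherwise drawn discrete-uniform over
#'   `aq_min..aq_max`).
#' @return A `sim_session` object: list with `participant_id`, `aq`
#'   ([aq_score()]), `gender`, `trials` (metadata + `report_mm`), `traces`
#'   (list of `RawTrace`), and `ground_truth` (per-trial perceived heights,
#'   amplitudes, context gains and corrupted sample indices).
#' @export
simulate_session <- function(cfg, participant_id, aq = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  local_rng(derive_seed(cfg$seed, participant_id))
  if (is.null(aq)) {
    aq <- sample(cfg$aq_min:cfg$aq_max, 1)
  }
  aq <- if (inherits(aq, "aq_score")) aq else aq_score(aq)
  gender <- if (stats::runif(1) < cfg$p_female) "F" else "M"
  baseline_p <- stats::rnorm(1, cfg$baseline_pupil_mm, cfg$baseline_between_sd_mm)
  baseline_p <- max(baseline_p, 2)
  reactivity <- max(0.2, stats::rnorm(1, 1, cfg$reactivity_sd))
  blink_mult <- stats::rlnorm(1, -cfg$blink_rate_participant_sd^2 / 2,
                              cfg$blink_rate_participant_sd)
  trials <- build_trial_list(derive_seed(cfg$seed, participant_id * 101 + 1))
  trials$participant_id <- participant_id
  set <- stimulus_set()
  heights <- stimulus_heights(set)

  n <- nrow(trials)
  traces <- vector("list", n)
  gt <- vector("list", n)
  reports <- numeric(n)
  for (i in seq_len(n)) {
    tr <- trials[i, ]
    h <- heights[tr$size_level]
    p_pupil <- perceived_height(h, tr$location, aq, cfg, "pupil")
    p_report <- perceived_height(h, tr$location, aq, cfg, "report")
    amp <- reactivity * max(0, response_amplitude(p_pupil, cfg) +
                              stats::rnorm(1, 0, cfg$trial_amp_sd_mm))
    base_t <- baseline_p + stats::rnorm(1, 0, cfg$baseline_trial_sd_mm)
    clean <- simulate_trial_trace(tr, p_pupil, cfg, baseline_mm = base_t,
                                  amplitude_mm = amp, set = set)
    art <- inject_artifacts(clean, cfg, blink_rate_hz = cfg$blink_rate_hz * blink_mult)
    reports[i] <- simulate_report(p_report, cfg)
    traces[[i]] <- art$trace
    gt[[i]] <- data.frame(
      block = tr$block, trial = tr$trial,
      perceived_height_deg = p_pupil,
      perceived_height_report_deg = p_report,
      amplitude_mm = amp,
      baseline_mm = base_t,
      context_gain = context_gain(aq, cfg, "pupil"),
      n_corrupted = length(art$blink_idx) + length(art$spike_idx),
      corrupted_sample_indices = paste(sort(c(art$blink_idx, art$spike_idx)),
                                       collapse = ";")
    )
  }
  trials$report_mm <- reports
  structure(
    list(participant_id = participant_id,
         aq = aq,
         gender = gender,
         baseline_pupil_mm = baseline_p,
         trials = trials,
         traces = traces,
         ground_truth = do.call(rbind, gt)),
    class = "sim_session"
  )
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("Simulated session: participant %s, AQ %d, %d trials\n",
              x$participant_id, x$aq$score, nrow(x$trials)))
  invisible(x)
}

#' Simulate a full multi-participant dataset
#'
#' @param cfg A [sim_config()].
#' @return List of `sim_session` objects, length `cfg$n_participants`.
#' @export
simulate_dataset <- function(cfg) {
  lapply(seq_len(cfg$n_participants), function(i) simulate_session(cfg, i))
}

#' Fast summary-level simulation (no 500 Hz traces)
#'
#' Generates per-trial summaries directly from the same generative model as
#' [simulate_session()]: the expected baseline-corrected pupil response is
#' `-A * mean(K)` over the response window, with the identical AQ-coupled
#' perceived-size model, trial amplitude jitter, participant reactivity and
#' report noise. Used for simulation studies (parameter recovery, type-I
#' calibration) where simulating and re-cleaning millions of samples would
#' add nothing but runtime: artifact-free traces pass the cleaning chain
#' unchanged, so the trace route and this route share their distribution of
#' valid-trial summaries (verified by a dedicated equivalence test).
#'
#' @param cfg A [sim_config()].
#' @return List: `trials` (data.frame with participant_id, block, trial,
#'   size_level, location, pupil_response_mm, report_mm, valid) and
#'   `participants` (participant_id, aq, gender).
#' @export
simulate_summaries <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  kbar <- kernel_window_mean(cfg)
  set <- stimulus_set()
  heights <- stimulus_heights(set)
  per_part <- vector("list", cfg$n_participants)
  meta <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    local_rng(derive_seed(cfg$seed, i))
    aq <- sample(cfg$aq_min:cfg$aq_max, 1)
    gender <- if (stats::runif(1) < cfg$p_female) "F" else "M"
    stats::rnorm(1)                       # baseline draw (parity with trace path)
    reactivity <- max(0.2, stats::rnorm(1, 1, cfg$reactivity_sd))
    trials <- build_trial_list(derive_seed(cfg$seed, i * 101 + 1))
    trials$participant_id <- i
    h <- heights[trials$size_level]
    p_pupil <- perceived_height(h, trials$location, aq, cfg, "pupil")
    p_report <- perceived_height(h, trials$location, aq, cfg, "report")
    amp <- reactivity * pmax(0, response_amplitude(p_pupil, cfg) +
                               stats::rnorm(nrow(trials), 0, cfg$trial_amp_sd_mm))
    trials$pupil_response_mm <- -amp * kbar
    trials$report_mm <- simulate_report(p_report, cfg)
    trials$valid <- !(trials$trial == 1L)   # first trial per block excluded
    per_part[[i]] <- trials
    meta[[i]] <- data.frame(participant_id = i, aq = aq, gender = gender)
  }
  list(trials = do.call(rbind, per_part),
       participants = do.call(rbind, meta))
}
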
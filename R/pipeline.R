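#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of a run — simulation preset, preprocessing
#' thresholds, statistics options, seed and output directory — so that a
#' complete analysis (including the documented robustness rerun with a 2 mm
#' gross threshold) is a single-knob change. Round-trips losslessly through
#' JSON via [write_run_config()] / [read_run_config()].
#'
#' @param sim A [sim_config()].
#' @param pp A [pp_params()].
#' @param jzs_rscale_t Prior scale for t-test Bayes factors.
#' @param conf_level Confidence level for intervals.
#' @param out_dir Output directory.
#' @param seed Master seed (also forwarded into `sim`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), pp = pp_params(),
                       jzs_rscale_t = sqrt(2) / 2, conf_level = 0.95,
                       out_dir = ".", seed = sim$seed) {
  sim$seed <- seed
  structure(list(sim = sim, pp = pp, jzs_rscale_t = jzs_rscale_t,
                 conf_level = conf_level, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  payload <- unclass(cfg)
  payload$sim <- unclass(payload$sim)
  payload$pp <- unclass(payload$pp)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_config, x$sim)
  pp <- do.call(pp_params, x$pp)
  run_config(sim = sim, pp = pp, jzs_rscale_t = x$jzs_rscale_t,
             conf_level = x$conf_level, out_dir = x$out_dir, seed = x$seed)
}

# ---- dataset writers -------------------------------------------------------

#' Write a simulated dataset to disk in the pipeline's exchange formats
#'
#' Emits `samples.tsv` (one row per 500 Hz sample: participant_id, block,
#' trial, t_ms, pupil, gaze_x_px, gaze_y_px; missing pupil as empty field),
#' `trials.csv` (design metadata plus report_mm), `aq_scores.csv`
#' (participant_id, aq, gender) and `ground_truth.csv` (per-trial perceived
#' heights, amplitudes, context gains and corrupted sample indices).
#'
#' @param sessions List of `sim_session` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             trials = file.path(dir, "trials.csv"),
             aq = file.path(dir, "aq_scores.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  samp <- do.call(rbind, lapply(sessions, function(s) {
    meta <- s$trials
    do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
      tr <- s$traces[[i]]
      data.frame(participant_id = meta$participant_id[i],
                 block = meta$block[i], trial = meta$trial[i],
                 t_ms = tr$t_ms, pupil = tr$pupil_mm,
                 gaze_x_px = tr$gaze_x_px, gaze_y_px = tr$gaze_y_px)
    }))
  }))
  utils::write.table(samp, paths["samples"], sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  utils::write.csv(
    trials[, c("participant_id", "block", "trial", "size_level",
               "location", "report_mm")],
    paths["trials"], row.names = FALSE, quote = FALSE)
  aq <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(participant_id = s$participant_id, aq = s$aq$score,
               gender = s$gender)
  }))
  utils::write.csv(aq, paths["aq"], row.names = FALSE, quote = FALSE)
  gt <- do.call(rbind, lapply(sessions, function(s) {
    cbind(participant_id = s$participant_id, s$ground_truth)
  }))
  utils::write.csv(gt, paths["ground_truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a sample TSV back into per-trial traces
#'
#' @param path `samples.tsv` path (see [write_dataset()] for the dialect).
#' @param mm_per_unit Optional calibration factor (mm per recorded pupil
#'   unit) standing in for the artificial-pupil calibration; default 1
#'   (input already in mm).
#' @return List: `trials` (participant_id, block, trial index table) and
#'   `traces` (parallel list of `RawTrace` data.frames).
#' @export
read_samples_tsv <- function(path, mm_per_unit = 1) {
  d <- utils::read.delim(path, na.strings = c("", "NA"))
  need <- c("participant_id", "block", "trial", "t_ms", "pupil",
            "gaze_x_px", "gaze_y_px")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(d$participant_id, d$block, d$trial, drop = TRUE)
  idx <- split(seq_len(nrow(d)), key)
  # preserve file order of first appearance
  idx <- idx[order(vapply(idx, min, integer(1)))]
  trials <- do.call(rbind, lapply(idx, function(i) {
    d[i[1], c("participant_id", "block", "trial")]
  }))
  rownames(trials) <- NULL
  traces <- lapply(idx, function(i) {
    data.frame(t_ms = d$t_ms[i],
               pupil_mm = d$pupil[i] * mm_per_unit,
               gaze_x_px = d$gaze_x_px[i],
               gaze_y_px = d$gaze_y_px[i])
  })
  names(traces) <- NULL
  list(trials = trials, traces = traces)
}

# ---- validation ------------------------------------------------------------

#' Validate a dataset on disk without mutating it
#'
#' Checks, per trial, monotone timestamps and nominal 500 Hz spacing (2 ms
#' within 10% tolerance); pupil range plausibility (0-10 mm); design
#' balance of the trial list (10 size-by-location cells, 10 repetitions,
#' two blocks of 50); and AQ scores within 0-50. Findings are reported,
#' never thrown.
#'
#' @param samples_path,trials_path,aq_path Paths to the three input files
#'   (any may be `NULL` to skip its checks).
#' @return data.frame of findings: `file`, `check`, `where`, `message`;
#'   zero rows when everything is pristine.
#' @export
validate_inputs <- function(samples_path = NULL, trials_path = NULL,
                            aq_path = NULL) {
  findings <- list()
  note <- function(file, check, where, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(file = file, check = check, where = where, message = message)
  }
  if (!is.null(samples_path)) {
    d <- utils::read.delim(samples_path, na.strings = c("", "NA"))
    key <- paste(d$participant_id, d$block, d$trial)
    for (k in unique(key)) {
      i <- which(key == k)
      tt <- d$t_ms[i]
      if (is.unsorted(tt, strictly = TRUE)) {
        bad <- i[which(diff(tt) <= 0)[1] + 1L]
        note(samples_path, "monotone_timestamps", paste0("line ", bad + 1L),
             paste0("trial ", k, ": timestamps not strictly increasing"))
      } else if (length(tt) > 1L) {
        dt <- diff(tt)
        if (any(abs(dt - 2) > 0.2)) {
          note(samples_path, "nominal_rate", paste0("trial ", k),
               sprintf("sample spacing deviates from 2 ms (range %.3g-%.3g)",
                       min(dt), max(dt)))
        }
      }
    }
    bad_p <- which(!is.na(d$pupil) & (d$pupil < 0 | d$pupil > 10))
    for (b in utils::head(bad_p, 20L)) {
      note(samples_path, "pupil_range", paste0("line ", b + 1L),
           sprintf("pupil %.3g mm outside plausible 0-10 mm", d$pupil[b]))
    }
  }
  if (!is.null(trials_path)) {
    tr <- utils::read.csv(trials_path)
    for (pid in unique(tr$participant_id)) {
      s <- tr[tr$participant_id == pid, ]
      tab <- table(s$size_level, s$location)
      if (nrow(s) != 100L || !all(tab == 10L)) {
        note(trials_path, "design_balance", paste0("participant ", pid),
             "trial list is not 5 sizes x 2 locations x 10 repetitions")
      }
      if (!all(table(s$block) == 50L)) {
        note(trials_path, "block_structure", paste0("participant ", pid),
             "blocks are not two sets of 50 trials")
      }
    }
  }
  if (!is.null(aq_path)) {
    aq <- utils::read.csv(aq_path)
    bad <- which(!is.finite(aq$aq) | aq$aq < 0 | aq$aq > 50)
    for (b in bad) {
      note(aq_path, "aq_range", paste0("line ", b + 1L),
           sprintf("AQ score %s outside the 0-50 range of the 50-item scale",
                   aq$aq[b]))
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(file = character(), check = character(),
                      where = character(), message = character()))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

# ---- orchestration ---------------------------------------------------------

#' Simulate a dataset and write it to disk
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the file paths; prints a dataset digest.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  sessions <- simulate_dataset(cfg$sim)
  paths <- write_dataset(sessions, cfg$out_dir)
  n_art <- sum(vapply(sessions, function(s) sum(s$ground_truth$n_corrupted),
                      numeric(1)))
  message(sprintf("simulated %d participants x %d trials (%d corrupted samples)",
                  length(sessions), nrow(sessions[[1]]$trials), n_art))
  invisible(paths)
}

#' Preprocess a dataset on disk
#'
#' @param cfg A [run_config()].
#' @param dir Directory holding `samples.tsv` and `trials.csv` (default
#'   `cfg$out_dir`).
#' @return List: `summaries` (per-trial, merged with design metadata) and
#'   `log`; also written as `trial_summaries.csv` / `exclusion_log.csv`.
#' @export
run_preprocess <- function(cfg, dir = cfg$out_dir) {
  ds <- read_samples_tsv(file.path(dir, "samples.tsv"))
  meta <- utils::read.csv(file.path(dir, "trials.csv"))
  all_sum <- list(); all_log <- list()
  for (pid in unique(ds$trials$participant_id)) {
    sel <- ds$trials$participant_id == pid
    tr_meta <- merge(ds$trials[sel, ], meta,
                     by = c("participant_id", "block", "trial"), sort = FALSE)
    out <- preprocess_session(tr_meta, ds$traces[sel], cfg$pp)
    all_sum[[as.character(pid)]] <- out$summaries
    all_log[[as.character(pid)]] <- out$log
  }
  summaries <- do.call(rbind, all_sum)
  log <- do.call(rbind, all_log)
  rownames(summaries) <- rownames(log) <- NULL
  utils::write.csv(summaries, file.path(dir, "trial_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(log, file.path(dir, "exclusion_log.csv"), row.names = FALSE)
  list(summaries = summaries, log = log)
}

#' Analyze a dataset end to end and write the report bundle
#'
#' Runs [run_preprocess()] (unless given precomputed summaries), joins AQ
#' scores (participants without an AQ score are dropped with a warning),
#' runs [run_full_inference()] and writes `report.json` plus the cell-mean
#' and per-participant effect tables as CSV.
#'
#' @param cfg A [run_config()].
#' @param dir Dataset directory.
#' @param summaries Optional precomputed trial summaries.
#' @return The `inference_report`, invisibly.
#' @export
run_analyze <- function(cfg, dir = cfg$out_dir, summaries = NULL) {
  if (is.null(summaries)) summaries <- run_preprocess(cfg, dir)$summaries
  participants <- utils::read.csv(file.path(dir, "aq_scores.csv"))
  no_aq <- setdiff(unique(summaries$participant_id),
                   participants$participant_id)
  if (length(no_aq)) {
    warning("dropping participant(s) without AQ score: ",
            paste(no_aq, collapse = ", "), call. = FALSE)
    summaries <- summaries[!summaries$participant_id %in% no_aq, ]
  }
  rep <- run_full_inference(summaries, participants)
  write_report(rep, dir)
  invisible(rep)
}

#' Serialize an inference report bundle
#'
#' Writes `report.json` (schema-versioned, every statistic with its name,
#' value, df, p and lgBF) plus `cell_means.csv` (participant-by-cell means)
#' and `participant_effects.csv` (per-participant contextual effects and
#' AQ, the tables behind the effect-versus-AQ scatter plots).
#'
#' @param rep An `inference_report` from [run_full_inference()].
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(rep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$cell_means, file.path(dir, "cell_means.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$effects, file.path(dir, "participant_effects.csv"),
                   row.names = FALSE)
  slim <- rep
  slim$cell_means <- NULL
  slim$effects <- NULL
  payload <- c(list(schema = "pupilcontext-report/1"),
               rapply(unclass(slim), unclass, how = "replace"))
  path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `validate`, `preprocess`,
#' `analyze` and `report` (analyze is simulate-agnostic: it consumes the
#' exchange files wherever they came from). Installed at
#' `inst/cli/pupilcontext.R`; run as
#' `Rscript -e 'pupilcontext::cli_main()' <command> [options]` or via the
#' installed script.
#'
#' @param args Command-line arguments (default `commandArgs(trailingOnly =
#'   TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pupilcontext <command> [--config FILE] [--dir DIR] [--seed N]",
    "                    [--participants N] [--median-dev-max MM]",
    "commands: simulate | validate | preprocess | analyze | report",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(config = NULL, dir = NULL, seed = NULL,
               participants = NULL, median_dev_max = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts) || i == length(args)) {
      message("unknown or incomplete option: ", args[i], "\n", usage)
      return(invisible(1L))
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else run_config()
  if (!is.null(opts$seed)) {
    cfg$seed <- as.integer(opts$seed)
    cfg$sim$seed <- cfg$seed
  }
  if (!is.null(opts$participants)) {
    cfg$sim$n_participants <- as.integer(opts$participants)
  }
  if (!is.null(opts$median_dev_max)) {
    cfg$pp$median_dev_max_mm <- as.numeric(opts$median_dev_max)
  }
  if (!is.null(opts$dir)) cfg$out_dir <- opts$dir
  status <- 0L
  switch(cmd,
    simulate = run_simulate(cfg),
    validate = {
      v <- validate_inputs(file.path(cfg$out_dir, "samples.tsv"),
                           file.path(cfg$out_dir, "trials.csv"),
                           file.path(cfg$out_dir, "aq_scores.csv"))
      if (nrow(v) == 0L) message("validation: no findings") else {
        utils::write.csv(v, file.path(cfg$out_dir, "validation.csv"),
                         row.names = FALSE)
        message("validation: ", nrow(v), " finding(s), see validation.csv")
      }
    },
    preprocess = invisible(run_preprocess(cfg)),
    analyze = invisible(run_analyze(cfg)),
    report = {
      s <- utils::read.csv(file.path(cfg$out_dir, "trial_summaries.csv"))
      invisible(run_analyze(cfg, summaries = s))
    },
    {
      message("unknown command: ", cmd, "\n", usage)
      status <- 1L
    })
  invisible(status)
}
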
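#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Unknown keys
#' are rejected; the full configuration is embedded in every report so any
#' report can be regenerated from it.
#'
#' @param sim named list of overrides for [sim_config()].
#' @param channel EEG channel analysed (default `"eeg_v1"`, the
#'   visual-cortex derivation).
#' @param artifact_threshold amplitude threshold for excision (`NULL` =
#'   robust default).
#' @param classifier classifier spec for [repeated_evaluation()].
#' @param n_shuffles,train_fraction evaluation protocol parameters.
#' @param use_reference_scoring score epochs with the EMG/delta/theta
#'   threshold rules (plus micro-state smoothing) instead of using the
#'   simulator's ground-truth labels.
#' @param do_ablation run the per-band FNR ablation.
#' @param ablation_shuffles shuffles per band in the ablation.
#' @param do_hourly compute the hourly power/state correlations.
#' @param stage `"full"`, `"simulate"` or `"features"`: where to stop.
#' @param seed master seed; overrides `sim$seed`.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), channel = "eeg_v1",
                            artifact_threshold = NULL,
                            classifier = "kernel_nbc",
                            n_shuffles = 50L, train_fraction = 0.75,
                            use_reference_scoring = FALSE,
                            do_ablation = FALSE, ablation_shuffles = 20L,
                            do_hourly = TRUE,
                            stage = c("full", "simulate", "features"),
                            seed = 1L) {
  stage <- match.arg(stage)
  allowed_sim <- names(formals(sim_config))
  unknown <- setdiff(names(sim), allowed_sim)
  if (length(unknown) > 0L) {
    stop("unknown sim config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- list(sim = sim, channel = channel,
              artifact_threshold = artifact_threshold,
              classifier = classifier, n_shuffles = as.integer(n_shuffles),
              train_fraction = train_fraction,
              use_reference_scoring = isTRUE(use_reference_scoring),
              do_ablation = isTRUE(do_ablation),
              ablation_shuffles = as.integer(ablation_shuffles),
              do_hourly = isTRUE(do_hourly),
              stage = stage, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Simulate (or load) a recording and hypnogram, optionally re-score it with
#' the threshold rules, extract the nine-band feature matrix, train and
#' evaluate the classifier under the repeated-split protocol, and assemble a
#' report. Fully deterministic in the embedded configuration and seed.
#'
#' @param config a [pipeline_config()] (or plain list of its arguments).
#' @param recording,hypnogram optional pre-loaded inputs; when omitted the
#'   simulator produces them.
#' @return List of class `pipeline_report` with elements `config`,
#'   `state_fractions`, `features_summary`, and (per stage/flags)
#'   `evaluation`, `auc`, `ablation`, `hourly_correlation`, `scoring`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         recording = NULL, hypnogram = NULL) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  sim_args <- config$sim
  sim_args$seed <- config$seed
  scfg <- do.call(sim_config, sim_args)

  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(hypnogram)) {
    hypnogram <- stage_wrap("simulate", simulate_hypnogram(scfg))
  }
  truth <- hypnogram
  if (is.null(recording)) {
    chans <- unique(c(config$channel,
                      if (config$use_reference_scoring) "emg"))
    recording <- stage_wrap("simulate", {
      rec <- simulate_signals(hypnogram, scfg, channels = chans)
      inject_artifacts(rec, hypnogram, scfg)$recording
    })
  }
  report <- list(config = unclass(config),
                 state_fractions = as.list(state_fractions(truth)))
  if (config$stage == "simulate") {
    report$recording_channels <- names(recording$channels)
    class(report) <- "pipeline_report"
    return(report)
  }

  scoring <- NULL
  labels_hyp <- truth
  if (config$use_reference_scoring) {
    scoring <- stage_wrap("score", {
      met <- compute_epoch_metrics(recording, scfg$epoch_seconds,
                                   eeg_channel = config$channel)
      thr <- calibrate_thresholds(met, truth$labels)
      scored <- smooth_microstates(threshold_score(met, thr,
                                                   scfg$epoch_seconds,
                                                   truth$start_hour_of_day))
      list(thresholds = unclass(thr),
           accuracy = mean(scored$labels == truth$labels),
           kappa = cohens_kappa(scored, truth),
           hypnogram = scored)
    })
    labels_hyp <- scoring$hypnogram
    report$scoring <- scoring[c("thresholds", "accuracy", "kappa")]
  }

  feats <- stage_wrap("features", extract_features(
    recording, labels_hyp, channel = config$channel,
    artifact_threshold = config$artifact_threshold
  ))
  report$features_summary <- list(
    n_epochs = nrow(feats$values),
    n_dropped = length(feats$dropped_epochs),
    n_outliers_replaced = sum(lengths(feats$outliers)),
    bands = colnames(feats$values)
  )
  if (config$stage == "features") {
    report$features <- feats
    class(report) <- "pipeline_report"
    return(report)
  }

  ev <- stage_wrap("evaluate", repeated_evaluation(
    feats, classifier = config$classifier, n_shuffles = config$n_shuffles,
    train_fraction = config$train_fraction, seed = config$seed + 10L
  ))
  report$evaluation <- list(mean = as.list(ev$mean), sd = as.list(ev$sd),
                            pooled_confusion = as.list(ev$pooled_confusion),
                            redraws = ev$redraws)

  # single deterministic split for the ROC (redrawn, like the shuffles,
  # until both classes appear on each side)
  report$auc <- stage_wrap("evaluate", {
    sel <- feats$labels %in% c("WAKE", "REM")
    xx <- feats$values[sel, , drop = FALSE]; yy <- feats$labels[sel]
    set.seed(config$seed + 11L)
    tr <- NULL
    for (try in 1:100) {
      cand <- sample.int(nrow(xx), floor(nrow(xx) * config$train_fraction))
      if (length(unique(yy[cand])) == 2L && min(table(yy[cand])) >= 2L &&
          length(unique(yy[-cand])) == 2L) { tr <- cand; break }
    }
    if (is.null(tr)) NA_real_ else {
      m <- fit_kernel_nbc(xx[tr, , drop = FALSE], yy[tr])
      p <- predict_proba(m, xx[-tr, , drop = FALSE])
      roc_and_auc(p[, "REM"], yy[-tr])$auc
    }
  })

  if (config$do_ablation) {
    report$ablation <- stage_wrap("ablate", band_ablation_fnr(
      feats, classifier = config$classifier,
      n_shuffles = config$ablation_shuffles, seed = config$seed + 12L
    ))
  }
  if (config$do_hourly && truth$epoch_seconds * length(truth$labels) >= 3 * 3600) {
    report$hourly_correlation <- stage_wrap("evaluate", {
      hs <- hourly_summary(feats, labels_hyp)
      suppressWarnings(hourly_correlation(hs))
    })
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  state fractions:",
      paste(sprintf("%s %.3f", names(x$state_fractions),
                    unlist(x$state_fractions)), collapse = ", "), "\n")
  if (!is.null(x$evaluation)) {
    m <- x$evaluation$mean; s <- x$evaluation$sd
    for (k in names(m)) {
      cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", k, m[[k]], s[[k]]))
    }
    cat(sprintf("  AUC (single split): %.4f\n", x$auc))
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report a `pipeline_report`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  out <- report
  out$features <- NULL  # the matrix goes to CSV, not into the report
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}

# --- command-line surface ---------------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("expected a --flag, got '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flag_or <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) default else flags[[key]]
}

read_config_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `score`, `features`, `train`, `evaluate`,
#' `ablate`, `run`. Shared flags: `--seed N`, `--config cfg.json`,
#' `--out-dir D`. See the package README for examples. An executable
#' wrapper is installed under `inst/cli/remhf.R`.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the main result object of the subcommand.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: remhf <simulate|score|features|train|evaluate|ablate|run> [--flags]\n")
    return(invisible(NULL))
  }
  cmd <- args[1L]
  flags <- parse_cli_flags(args[-1L])
  out_dir <- flag_or(flags, "out-dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(flag_or(flags, "seed", 1L))
  cfg_overrides <- if (!is.null(flags$config)) read_config_json(flags$config) else list()

  result <- switch(cmd,
    simulate = {
      sim_args <- utils::modifyList(cfg_overrides, list(seed = seed))
      if (!is.null(flags$`duration-hours`)) {
        sim_args$duration_hours <- as.numeric(flags$`duration-hours`)
      }
      scfg <- do.call(sim_config, sim_args)
      hyp <- simulate_hypnogram(scfg)
      rec <- inject_artifacts(simulate_signals(hyp, scfg), hyp, scfg)$recording
      write_hypnogram(hyp, file.path(out_dir, "hypnogram.csv"))
      write_edf(rec, file.path(out_dir, "recording.edf"))
      message("wrote ", file.path(out_dir, "recording.edf"), " and hypnogram.csv")
      list(hypnogram = hyp, recording = rec)
    },
    score = {
      rec <- read_edf(flags$edf)
      met <- compute_epoch_metrics(rec, as.numeric(flag_or(flags, "epoch-seconds", 4)))
      thr <- if (!is.null(flags$thresholds)) {
        tj <- read_config_json(flags$thresholds)
        scoring_thresholds(tj$emg_rms, tj$delta_power, tj$theta_power)
      } else stop("score requires --thresholds thresholds.json (keys emg_rms, delta_power, theta_power)")
      hyp <- smooth_microstates(threshold_score(met, thr,
                                                start_hour_of_day = rec$start_hour_of_day))
      write_hypnogram(hyp, flag_or(flags, "out", file.path(out_dir, "hypno.csv")))
      hyp
    },
    features = {
      rec <- read_edf(flags$edf)
      hyp <- read_hypnogram(flags$hypno)
      fm <- extract_features(rec, hyp,
                             artifact_threshold = if (!is.null(flags$threshold)) as.numeric(flags$threshold) else NULL)
      write_features(fm, flag_or(flags, "out", file.path(out_dir, "features.csv")))
      fm
    },
    train = {
      ft <- read_features(flags$features)
      m <- fit_kernel_nbc(ft$values[ft$labels %in% c("WAKE", "REM"), , drop = FALSE],
                          ft$labels[ft$labels %in% c("WAKE", "REM")])
      write_nbc_json(m, flag_or(flags, "out", file.path(out_dir, "model.json")))
      m
    },
    evaluate = {
      ft <- read_features(flags$features)
      ev <- repeated_evaluation(ft$values, ft$labels,
                                classifier = flag_or(flags, "method", "kernel_nbc"),
                                n_shuffles = as.integer(flag_or(flags, "shuffles", 50L)),
                                seed = seed)
      jsonlite::write_json(
        list(mean = as.list(ev$mean), sd = as.list(ev$sd), meta = ev$meta),
        flag_or(flags, "report", file.path(out_dir, "report.json")),
        auto_unbox = TRUE, digits = NA)
      ev
    },
    ablate = {
      ft <- read_features(flags$features)
      ab <- band_ablation_fnr(ft$values, ft$labels,
                              classifier = flag_or(flags, "method", "kernel_nbc"),
                              n_shuffles = as.integer(flag_or(flags, "shuffles", 20L)),
                              seed = seed)
      jsonlite::write_json(ab, flag_or(flags, "report", file.path(out_dir, "fnr.json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      ab
    },
    run = {
      pc_args <- cfg_overrides
      pc_args$seed <- seed
      report <- run_pipeline(do.call(pipeline_config, pc_args))
      write_report_json(report, flag_or(flags, "report",
                                        file.path(out_dir, "pipeline_report.json")))
      report
    },
    stop("unknown subcommand '", cmd, "'")
  )
  invisible(result)
}
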
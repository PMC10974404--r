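# Experiment configuration and end-to-end orchestration:
# synth -> preprocess -> features -> select -> eelm -> evaluate.

#' Default experiment configuration
#'
#' All defaults follow the reference acquisition and modelling protocol:
#' 100 Hz sampling, 2-minute records at the eight LED wavelengths, 5 s
#' feature windows, linear SVR-RFE with 5-fold CV, a 200-member EELM with
#' 20 sigmoid hidden neurons, and 200 random 8:2 splits.
#'
#' @return nested list of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    acquisition = list(fs = 100, duration = 120,
                       wavelengths = HEMOPPG_WAVELENGTHS),
    cohort = list(n = 249, seed = 1),
    noise = list(white_sd = 0.003, drift_amp = 0.05, drift_freq = 0.25,
                 powerline_amp = 0.01, powerline_freq = 50,
                 motion_prob = 0.03, motion_amp = 0.05),
    preprocess = list(lowpass_cutoff = 10, fir_taps = 101,
                      wavelet_name = "coif5", wavelet_levels = 7,
                      comb_enabled = TRUE, comb_periods = 4,
                      period_band = c(0.7, 3.0)),
    features = list(win_len = 5),
    selection = list(use_rfe = TRUE, rfe_per_repeat = FALSE,
                     cost = 1, epsilon = 0.1, n_folds = 5),
    model = list(K = 20, P = 200, activation = "sigmoid"),
    evaluation = list(train_ratio = 0.8, n_repeats = 200, seed = 1)
  ), class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path file path.
#' @param cfg an `experiment_config`.
#' @return `read_config` returns a validated `experiment_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a configuration list
#'
#' Unknown keys raise an error naming the offending key; missing keys are
#' filled from [default_config()].
#'
#' @param raw a (possibly partial) nested configuration list.
#' @return a complete `experiment_config`.
#' @export
validate_config <- function(raw) {
  def <- default_config()
  bad <- setdiff(names(raw), names(def))
  if (length(bad) > 0)
    stop("unknown config section: ", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    bad_key <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad_key) > 0)
      stop("unknown config key: ", sec, ".", paste(bad_key, collapse = ", "))
    def[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  stopifnot(def$acquisition$fs > 0, def$acquisition$duration >= 10,
            def$evaluation$train_ratio > 0, def$evaluation$train_ratio < 1)
  def
}

.noise_from_config <- function(cfg) {
  do.call(noise_config, cfg$noise)
}

.preprocess_from_config <- function(cfg) {
  do.call(preprocess_config, cfg$preprocess)
}

#' Run a full experiment from a configuration
#'
#' Generates (or accepts) a cohort, extracts features, runs the repeated
#' split/select/train/evaluate protocol, and optionally writes the feature
#' matrix, the evaluation report, and the configuration into an artifact
#' directory. All randomness derives from the seeds in the configuration,
#' so a rerun with the same config reproduces the report exactly.
#'
#' @param cfg an `experiment_config` (see [default_config()]).
#' @param cohort optional pre-built cohort (list of subject records); when
#'   `NULL` a synthetic cohort is generated per `cfg$cohort` and
#'   `cfg$noise`.
#' @param out_dir optional artifact directory.
#' @param verbose log stage progress to stderr.
#' @return the `eval_report`, with the feature data and config attached as
#'   attributes `features` and `config`.
#' @export
run_experiment <- function(cfg = default_config(), cohort = NULL,
                           out_dir = NULL, verbose = TRUE) {
  cfg <- validate_config(unclass(cfg))
  log_msg <- function(...) if (verbose) message("[hemoppg] ", sprintf(...))

  if (is.null(cohort)) {
    log_msg("generating cohort: n=%d, seed=%d", cfg$cohort$n, cfg$cohort$seed)
    cohort <- generate_cohort(cfg$cohort$n, optics = optical_config(),
                              noise = .noise_from_config(cfg),
                              duration = cfg$acquisition$duration,
                              fs = cfg$acquisition$fs, seed = cfg$cohort$seed)
  }
  log_msg("extracting features from %d records", length(cohort))
  fz <- featurize_cohort(cohort, .preprocess_from_config(cfg),
                         win_len = cfg$features$win_len)

  log_msg("repeated evaluation: %d repeats, train ratio %.2f",
          cfg$evaluation$n_repeats, cfg$evaluation$train_ratio)
  report <- repeated_evaluation(
    fz$X, fz$y,
    n_repeats = cfg$evaluation$n_repeats,
    train_ratio = cfg$evaluation$train_ratio,
    K = cfg$model$K, P = cfg$model$P, activation = cfg$model$activation,
    use_rfe = cfg$selection$use_rfe,
    rfe_per_repeat = cfg$selection$rfe_per_repeat,
    seed = cfg$evaluation$seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      data.frame(subject_id = fz$ids, hb_ref = fz$y, fz$X,
                 check.names = FALSE),
      file.path(out_dir, "features.csv"), row.names = FALSE)
    write_config(cfg, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(report_to_list(report, cfg),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("artifacts written to %s", out_dir)
  }
  attr(report, "features") <- fz
  attr(report, "config") <- cfg
  report
}

# Serializable view of an eval_report (with provenance fields).
report_to_list <- function(report, cfg = NULL) {
  out <- list(
    rmse = report$rmse, pcc = report$pcc, pcc_p = report$pcc_p,
    bland_altman = report$bland_altman,
    grid_pct = as.list(report$grid_pct),
    n_repeats = report$n_repeats, n_skipped = report$n_skipped,
    k_selected = report$k_selected,
    mask = report$mask,
    package_version = tryCatch(
      as.character(utils::packageVersion("hemoppg")),
      error = function(e) NA_character_)
  )
  if (!is.null(cfg)) {
    out$config_hash <- sum(utf8ToInt(paste(deparse(unclass(cfg)),
                                           collapse = ""))) %% 1e9
    out$seeds <- list(cohort = cfg$cohort$seed,
                      evaluation = cfg$evaluation$seed)
  }
  out
}
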
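# End-to-end orchestration: corpus synthesis -> model training ->
# evaluation -> window labelling -> SAM aggregation -> statistics, driven
# by a single configuration list (YAML-serializable) so that any two runs
# with the same config and seeds produce identical outputs.

#' Default pipeline configuration
#'
#' @param out_dir Root output directory.
#' @param seed Master seed; per-stage seeds derive from it.
#' @return Nested configuration list with per-stage sections.
#' @export
default_pipeline_config <- function(out_dir = "sam_run", seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    window_s = 5,
    corpus = list(n_examples = 60, dur_s = 5,
                  split_fracs = c(train = 0.7, val = 0.15, test = 0.15),
                  count_distribution = c(0.25, 0.25, 0.25, 0.25),
                  snr_range = c(15, 30), rt60_range = c(0, 0.3)),
    model = counter_config(),
    sessions = list(n_participants = 4, days = 3, session_s = 30),
    stats = list(fdr_family = "grid", q = 0.05),
    flags = list(oracle_counter = FALSE, mask_phone_windows = FALSE,
                 entropy_base = "e", weight_by_time = FALSE)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_pipeline_config(), config)
}

snapshot_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- rapply(config, function(x) if (is.function(x)) NULL else x,
                how = "replace")
  yaml::write_yaml(cfg, file.path(dir, "config_snapshot.yaml"))
}

#' Stage 1: synthesize the labelled mixture corpus
#'
#' @param config Pipeline configuration list or YAML path.
#' @return The corpus manifest tibble (also written to disk).
#' @export
cmd_synth <- function(config = default_pipeline_config()) {
  config <- read_pipeline_config(config)
  dir <- file.path(config$out_dir, "corpus")
  snapshot_config(config, dir)
  cc <- config$corpus
  build_corpus(n_examples = cc$n_examples, dir = dir,
               split_fracs = cc$split_fracs,
               count_distribution = cc$count_distribution,
               seed = child_seed(config$seed, "corpus"), dur_s = cc$dur_s,
               snr_range = cc$snr_range, rt60_range = cc$rt60_range)
}

#' Stage 2: train the counting model on the corpus
#'
#' @param config Pipeline configuration list or YAML path.
#' @return The trained `counter_model` (also saved under the run
#'   directory).
#' @export
cmd_train <- function(config = default_pipeline_config()) {
  config <- read_pipeline_config(config)
  manifest_path <- file.path(config$out_dir, "corpus", "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("corpus manifest not found; run cmd_synth() first", call. = FALSE)
  }
  model <- train_counter(manifest_path,
                         config = utils::modifyList(counter_config(),
                                                    config$model),
                         seed = child_seed(config$seed, "train"))
  dir <- file.path(config$out_dir, "model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "counter_model.rds"))
  utils::write.csv(model$curves, file.path(dir, "training_curves.csv"),
                   row.names = FALSE)
  model
}

#' Stage 3: evaluate the counting model on the held-out test split
#'
#' @param config Pipeline configuration list or YAML path.
#' @param model Optional in-memory model (read from the run directory
#'   otherwise).
#' @return The evaluation report list; per-class CSV and JSON are written.
#' @export
cmd_eval <- function(config = default_pipeline_config(), model = NULL) {
  config <- read_pipeline_config(config)
  if (is.null(model)) {
    path <- file.path(config$out_dir, "model", "counter_model.rds")
    if (!file.exists(path)) {
      stop("no trained model found; run cmd_train() first", call. = FALSE)
    }
    model <- readRDS(path)
  }
  report <- evaluate_counter(model,
                             file.path(config$out_dir, "corpus",
                                       "manifest.csv"))
  dir <- file.path(config$out_dir, "eval")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_class, file.path(dir, "per_class.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(macro_sensitivity = report$macro_sensitivity,
                            macro_specificity = report$macro_specificity,
                            confusion = report$confusion),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  report
}

#' Synthesize a set of participant-day recording sessions
#'
#' Longer mixtures standing in for wristband sessions, with known
#' per-window truth so oracle-mode runs can be checked end to end.
#' Ambient richness differs across participants to give the statistics
#' stage something to find.
#'
#' @param config Pipeline configuration list or YAML path.
#' @return Session manifest tibble with `path`, `participant`, `day`,
#'   `t0_s`, `counts`.
#' @export
cmd_sessions <- function(config = default_pipeline_config()) {
  config <- read_pipeline_config(config)
  sc <- config$sessions
  dir <- file.path(config$out_dir, "sessions")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pi in seq_len(sc$n_participants)) {
    for (d in seq_len(sc$days)) {
      sseed <- child_seed(config$seed, sprintf("session-%d-%d", pi, d))
      k <- with_seed(sseed, sample(0:6, 1, prob = c(3, 3, 2, 2, 1, 1, 1)))
      sp <- synthesis_spec(n_speakers = k, snr_db = 20, rt60 = 0.2,
                           dur_s = sc$session_s, seed = sseed)
      ex <- synthesize_mixture(sp)
      path <- file.path(dir, sprintf("p%02d_d%02d.wav", pi, d))
      write_wav(ex$audio, path)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = path, participant = sprintf("P%02d", pi),
        day = as.character(as.Date("2018-03-05") + d - 1L), t0_s = 0,
        counts = paste(ex$true_counts, collapse = ";"))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  manifest
}

#' Label the 5-s windows of one recorded session
#'
#' @param audio An [audio_segment()] (or a WAV path).
#' @param model A trained `counter_model`, or `NULL` with `oracle_counts`
#'   supplied to bypass the model with ground truth.
#' @param oracle_counts Optional integer per-window truth.
#' @param window_s Window length in seconds.
#' @return Tibble with `window_start_s`, `count_class`, `level`.
#' @export
label_session <- function(audio, model = NULL, oracle_counts = NULL,
                          window_s = 5) {
  if (is.null(model) && is.null(oracle_counts)) {
    stop("either a model or oracle counts must be given", call. = FALSE)
  }
  if (is.null(oracle_counts)) {
    if (is.character(audio)) audio <- read_wav(audio)
    feats <- frame_features(audio, n_mels = model$config$n_mels)
    wins <- feature_windows(feats, window_s = window_s,
                            frame_subsample = model$config$frame_subsample)
    cls <- vapply(wins, function(wmat) {
      as.integer(predict_window_class(wmat, model))
    }, integer(1))
    classes <- factor(COUNT_CLASSES[cls], levels = COUNT_CLASSES,
                      ordered = TRUE)
  } else {
    classes <- count_to_class(oracle_counts)
  }
  tibble::tibble(window_start_s = (seq_along(classes) - 1) * window_s,
                 count_class = classes, level = count_to_level(classes))
}

#' Stage 4: score sessions and aggregate the SAM tables
#'
#' Labels every session's windows (with the trained model, or with the
#' generator's ground truth when `oracle_counter` is set), then aggregates
#' window labels into daily profiles and weekly per-participant SAM
#' vectors. Writes `windows.csv`, `daily.csv` and `weekly.csv`.
#'
#' @param config Pipeline configuration list or YAML path.
#' @param model Optional in-memory model.
#' @return List of tibbles `windows`, `daily`, `weekly`.
#' @export
cmd_sam <- function(config = default_pipeline_config(), model = NULL) {
  config <- read_pipeline_config(config)
  spath <- file.path(config$out_dir, "sessions", "sessions.csv")
  if (!file.exists(spath)) {
    stop("no session manifest found; run cmd_sessions() first", call. = FALSE)
  }
  sessions <- utils::read.csv(spath, stringsAsFactors = FALSE)
  oracle <- isTRUE(config$flags$oracle_counter)
  if (!oracle && is.null(model)) {
    mpath <- file.path(config$out_dir, "model", "counter_model.rds")
    if (!file.exists(mpath)) {
      stop("no trained model found; run cmd_train() first", call. = FALSE)
    }
    model <- readRDS(mpath)
  }
  win_rows <- list()
  for (i in seq_len(nrow(sessions))) {
    labels <- if (oracle) {
      label_session(NULL, oracle_counts = parse_counts(sessions$counts[i])[[1]],
                    window_s = config$window_s)
    } else {
      label_session(sessions$path[i], model = model,
                    window_s = config$window_s)
    }
    labels$participant <- sessions$participant[i]
    labels$day <- sessions$day[i]
    labels$window_start_s <- labels$window_start_s + sessions$t0_s[i]
    win_rows[[i]] <- labels
  }
  windows <- dplyr::bind_rows(win_rows)
  tables <- sam_tables(windows, window_s = config$window_s,
                       weight_by_time = isTRUE(config$flags$weight_by_time))
  dir <- file.path(config$out_dir, "sam")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(windows, file.path(dir, "windows.csv"), row.names = FALSE)
  utils::write.csv(tables$daily, file.path(dir, "daily.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$weekly, file.path(dir, "weekly.csv"),
                   row.names = FALSE)
  c(list(windows = windows), tables)
}

#' Stage 5: group and association statistics
#'
#' Runs the ANOVA table and the FDR-controlled association grid, either on
#' a supplied cohort (weekly SAM joined with participant metadata) or on a
#' synthetic cohort generated on the fly.
#'
#' @param config Pipeline configuration list or YAML path.
#' @param cohort Optional cohort tibble; generated with
#'   [generate_cohort()] when absent.
#' @return List with `anova`, `grid`, and the cohort used; CSV/JSON
#'   written under the run directory.
#' @export
cmd_stats <- function(config = default_pipeline_config(), cohort = NULL) {
  config <- read_pipeline_config(config)
  if (is.null(cohort)) {
    cohort <- generate_cohort(seed = child_seed(config$seed, "cohort"))
  }
  anova <- anova_table(cohort)
  grid <- association_grid(cohort, fdr_family = config$stats$fdr_family,
                           q = config$stats$q)
  dir <- file.path(config$out_dir, "stats")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(anova, file.path(dir, "anova.csv"), row.names = FALSE)
  utils::write.csv(grid, file.path(dir, "association_grid.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(n_tests = nrow(grid),
                            n_rejected = sum(grid$reject),
                            fdr_family = config$stats$fdr_family,
                            q = config$stats$q),
                       file.path(dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(anova = anova, grid = grid, cohort = cohort)
}

#' Run the whole pipeline on generated data
#'
#' Corpus synthesis, model training, evaluation, session scoring, SAM
#' aggregation and statistics in one call — a demonstration that runs
#' entirely on synthetic material.
#'
#' @param config Pipeline configuration list or YAML path.
#' @return List with the per-stage results.
#' @export
cmd_demo <- function(config = default_pipeline_config()) {
  config <- read_pipeline_config(config)
  manifest <- cmd_synth(config)
  model <- cmd_train(config)
  eval <- cmd_eval(config, model = model)
  cmd_sessions(config)
  sam <- cmd_sam(config, model = model)
  stats <- cmd_stats(config)
  list(manifest = manifest, model = model, eval = eval, sam = sam,
       stats = stats)
}
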
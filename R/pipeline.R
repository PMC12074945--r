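# End-to-end orchestration: simulate -> train -> cross-validate ->
# evaluate -> prescribe, driven by a single run configuration. Every
# stochastic artifact carries a JSON sidecar with the seed and a hash of
# the configuration that produced it, so reruns are verifiable.

#' Default run configuration
#'
#' One human-editable list controlling every pipeline stage. Training
#' defaults are the tuned operating point ([train_config()]); the grid is
#' the full 3x3x3 candidate set ([grid_spec()]). Corpus defaults emulate
#' the modelled literature: 68 studies totalling 1,594 subjects.
#'
#' @param seed root integer seed; every stochastic stage draws from a named
#'   child stream of it.
#' @param out_dir directory for all artifacts.
#' @param ... overrides for any top-level field.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1, out_dir = ".", ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    n_studies = 68,
    n_subjects_total = 1594,
    sizes = c(5, 12, 10, 8, 4),
    train = unclass(train_config()),
    grid = list(eta = c(0.001, 0.01, 0.1), beta = c(0.5, 0.7, 0.9),
                alpha = c(0, 0.001, 0.01)),
    k_outer = 10, k_inner = 10, n_inner_rounds = 2,
    input_scaling = "none",
    error_tolerance = 20,
    intensity_band = 5,
    target_improvement = 0.10,
    paths = list(study_table = "study_table.csv", corpus = "corpus.csv",
                 checkpoint = "model.json", history = "history.csv",
                 cv_report = "cv_report.csv", evaluation = "evaluation.json",
                 prescriptions = "rx.csv")
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default. The file extension selects the parser.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg
}

config_train <- function(cfg) {
  do.call(train_config, cfg$train)
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

artifact_path <- function(cfg, key) {
  file.path(cfg$out_dir, cfg$paths[[key]])
}

write_sidecar <- function(path, cfg, extra = list()) {
  jsonlite::write_json(
    c(list(seed = cfg$seed, config_hash = config_hash(cfg)), extra),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
}

#' Pipeline stage: simulate the study table and corpus
#'
#' Writes the seeded synthetic study-summary table and the Gaussian-
#' augmented encoded corpus (with its sidecar) under the configured paths.
#'
#' @param cfg a [default_run_config()] or [read_run_config()] result.
#' @return invisibly, a list with the `table` and `corpus` objects.
#' @export
run_simulate <- function(cfg = default_run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- synth_study_table(cfg$n_studies, cfg$seed,
                             n_total = cfg$n_subjects_total)
  corpus <- build_corpus(table, cfg$seed)
  write_study_table(table, artifact_path(cfg, "study_table"))
  write_corpus(corpus, artifact_path(cfg, "corpus"))
  write_sidecar(artifact_path(cfg, "corpus"), cfg,
                list(n_samples = nrow(corpus$x)))
  invisible(list(table = table, corpus = corpus))
}

#' Pipeline stage: train the prescription model
#'
#' Loads the simulated corpus, makes the 10-segment split (8 train, 1
#' validation, 1 test), trains with the configured settings and writes the
#' model checkpoint and the epoch history (epoch, train MSE, validation
#' MSE, damping).
#'
#' @param cfg a run configuration.
#' @param verbose print the display-interval training trace.
#' @return invisibly, the `fitt_fit`.
#' @export
run_train <- function(cfg = default_run_config(), verbose = FALSE) {
  corpus_path <- artifact_path(cfg, "corpus")
  if (!file.exists(corpus_path)) {
    stop("missing corpus at ", corpus_path, "; run the simulate stage first")
  }
  corpus <- read_corpus(corpus_path)
  plan <- make_splits(corpus, cfg$seed)
  roles <- split_roles(plan)
  net <- init_network(cfg$sizes, seed = child_seed(cfg$seed, "init"))
  if (identical(cfg$input_scaling, "minmax")) {
    net <- attach_input_scaling(net, corpus$x[roles$train, , drop = FALSE])
  }
  fit <- train_network(net,
                       corpus$x[roles$train, , drop = FALSE],
                       corpus$y[roles$train, , drop = FALSE],
                       corpus$x[roles$validation, , drop = FALSE],
                       corpus$y[roles$validation, , drop = FALSE],
                       config = config_train(cfg), verbose = verbose)
  ckpt <- artifact_path(cfg, "checkpoint")
  save_checkpoint(fit, ckpt,
                  extra = list(config_hash = config_hash(cfg),
                               stopped = fit$stopped, epochs = fit$epochs))
  utils::write.csv(fit$history, artifact_path(cfg, "history"),
                   row.names = FALSE)
  write_sidecar(ckpt, cfg, list(stopped = fit$stopped))
  invisible(fit)
}

#' Pipeline stage: nested cross-validation report
#'
#' Runs [nested_cv()] on the simulated corpus and writes the per-round
#' report (round, RMSE, MAE, R2 plus Mean and Best rows) as CSV with a
#' JSON summary sidecar.
#'
#' @param cfg a run configuration.
#' @param rounds optional reduced outer-fold count; the report is labelled
#'   with the count actually run.
#' @return invisibly, the `cv_result`.
#' @export
run_cv <- function(cfg = default_run_config(), rounds = NULL) {
  corpus_path <- artifact_path(cfg, "corpus")
  if (!file.exists(corpus_path)) {
    stop("missing corpus at ", corpus_path, "; run the simulate stage first")
  }
  corpus <- read_corpus(corpus_path)
  k_outer <- if (is.null(rounds)) cfg$k_outer else rounds
  cv <- nested_cv(corpus$x, corpus$y,
                  grid = do.call(grid_spec, cfg$grid),
                  seed = cfg$seed, k_outer = k_outer, k_inner = cfg$k_inner,
                  base_config = config_train(cfg), sizes = cfg$sizes,
                  n_inner_rounds = cfg$n_inner_rounds,
                  input_scaling = cfg$input_scaling)
  report <- rbind(
    data.frame(round = as.character(cv$rounds$round), rmse = cv$rounds$rmse,
               mae = cv$rounds$mae, r2 = cv$rounds$r2),
    data.frame(round = "Mean", rmse = cv$mean["rmse"], mae = cv$mean["mae"],
               r2 = cv$mean["r2"]),
    data.frame(round = "Best", rmse = cv$best["rmse"], mae = cv$best["mae"],
               r2 = cv$best["r2"])
  )
  path <- artifact_path(cfg, "cv_report")
  utils::write.csv(report, path, row.names = FALSE)
  write_sidecar(path, cfg, list(k_outer = k_outer, k_inner = cfg$k_inner))
  invisible(cv)
}

#' Pipeline stage: evaluate the trained model on the held-out test segment
#'
#' Recreates the split used in training, predicts the test segment, and
#' writes pooled metrics plus decoded-unit error ratios (intensity, time,
#' volume with the tolerance band) as JSON.
#'
#' @param cfg a run configuration.
#' @return invisibly, list with `metrics` and `error_ratios`.
#' @export
run_evaluate <- function(cfg = default_run_config()) {
  corpus_path <- artifact_path(cfg, "corpus")
  ckpt <- artifact_path(cfg, "checkpoint")
  if (!file.exists(corpus_path)) {
    stop("missing corpus at ", corpus_path, "; run the simulate stage first")
  }
  if (!file.exists(ckpt)) {
    stop("missing checkpoint at ", ckpt, "; run the train stage first")
  }
  corpus <- read_corpus(corpus_path)
  net <- load_checkpoint(ckpt)
  plan <- make_splits(corpus, cfg$seed)
  roles <- split_roles(plan)
  pred <- forward(net, corpus$x[roles$test, , drop = FALSE])
  target <- corpus$y[roles$test, , drop = FALSE]
  metrics <- metric_set(pred, target)
  # error ratios in physical units: intensity decoded to %HRR, time/volume
  # already physical
  dec <- function(m) cbind(intensity = m[, 2] * 100 + 50,
                           time = m[, 3], volume = m[, 4])
  ratios <- error_ratios(dec(pred), dec(target),
                         tolerance = cfg$error_tolerance)
  out <- list(
    n_test = length(roles$test),
    metrics = metrics[c("rmse", "mae", "r2", "mse", "pearson_r")],
    error_ratios = lapply(ratios[c("intensity", "time", "volume")],
                          function(e) e[c("mean", "sd", "within_band")]),
    tolerance = cfg$error_tolerance
  )
  path <- artifact_path(cfg, "evaluation")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  write_sidecar(path, cfg)
  invisible(list(metrics = metrics, error_ratios = ratios))
}

#' Pipeline stage: prescribe for a roster
#'
#' Loads the checkpoint and a subject roster CSV, generates per-subject
#' prescriptions at the configured target improvement, and writes the
#' per-subject FITT table with a flags column.
#'
#' @param cfg a run configuration.
#' @param roster_path CSV with columns `age,sex,bmi,vo2_pre,improvement`.
#' @return invisibly, the `batch_prescription`.
#' @export
run_prescribe <- function(cfg = default_run_config(), roster_path) {
  ckpt <- artifact_path(cfg, "checkpoint")
  if (!file.exists(ckpt)) {
    stop("missing checkpoint at ", ckpt, "; run the train stage first")
  }
  if (!file.exists(roster_path)) stop("missing roster at ", roster_path)
  net <- load_checkpoint(ckpt)
  roster <- read_roster(roster_path)
  batch <- batch_prescribe(net, roster,
                           target_improvement = cfg$target_improvement,
                           band = cfg$intensity_band)
  path <- artifact_path(cfg, "prescriptions")
  utils::write.csv(batch$table, path, row.names = FALSE)
  write_sidecar(path, cfg, list(n_subjects = nrow(batch$table)))
  invisible(batch)
}
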
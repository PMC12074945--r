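# Training-corpus construction: per-study Gaussian augmentation of published
# summary statistics into subject-level samples, plus fully synthetic study
# tables and ground-truth response surfaces for testing.

#' Derive a child RNG seed from a root seed and a key
#'
#' Stages and per-study streams draw from named child seeds so that rerunning
#' one stage, or permuting study rows, never changes another stream's draws.
#' Character keys are hashed (FNV-1a), so a study keeps its stream wherever
#' it sits in the table. Result always fits in a 32-bit integer seed.
#'
#' @param seed root integer seed.
#' @param key integer or character stream key.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, key) {
  h <- if (is.character(key)) fnv1a(key) else as.numeric(key)
  as.integer((as.numeric(seed) * 69069 + h * 12345 + 1) %% 2147483647)
}

# 32-bit FNV-1a string hash, kept in double arithmetic (exact below 2^53)
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  h %% 2147483647
}

#' Construct a study summary record
#'
#' One row of the literature table feeding augmentation: group size, the
#' three augmented characteristics as mean +/- SD, sex composition, the
#' observed relative VO2max improvement, and the study's prescription.
#'
#' @param study_id label.
#' @param n_subjects number of subjects contributed by the study.
#' @param age_mean,age_sd age in years.
#' @param bmi_mean,bmi_sd body-mass index in kg/m^2.
#' @param vo2_mean,vo2_sd baseline VO2max in mL kg^-1 min^-1.
#' @param prop_male proportion of male subjects in `[0, 1]` (0 or 1 for
#'   single-sex studies).
#' @param improvement relative VO2max improvement as a fraction.
#' @param prescription the study's [prescription()].
#' @return a `study_record` list.
#' @export
study_record <- function(study_id, n_subjects, age_mean, age_sd,
                         bmi_mean, bmi_sd, vo2_mean, vo2_sd,
                         prop_male, improvement, prescription) {
  stopifnot(n_subjects >= 1, age_sd >= 0, bmi_sd >= 0, vo2_sd >= 0,
            age_mean > 0, bmi_mean > 0, vo2_mean > 0,
            prop_male >= 0, prop_male <= 1, improvement > 0,
            inherits(prescription, "prescription"))
  structure(list(
    study_id = as.character(study_id), n_subjects = as.integer(n_subjects),
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    vo2_mean = vo2_mean, vo2_sd = vo2_sd,
    prop_male = prop_male, improvement = improvement,
    prescription = prescription
  ), class = "study_record")
}

# positive-only Gaussian draw: rejection of non-positive values; at the
# physiological scales of the study tables rejection is astronomically rare,
# so moments are effectively unbiased
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Augment one study into subject-level encoded samples
#'
#' Draws `n_subjects` simulated subjects: age, BMI and baseline VO2max are
#' drawn independently from Normal(mean, sd) (each subject's three continuous
#' draws form one 1x3 record); sex is assigned by a Bernoulli draw with the
#' study's male proportion; improvement and the prescription target are held
#' fixed at the study's values. Draws that violate positivity are redrawn.
#'
#' @param rec a [study_record()].
#' @param seed integer seed for this study's stream.
#' @return list with encoded input matrix `x` (`n_subjects` x 5) and target
#'   matrix `y` (`n_subjects` x 4).
#' @export
augment_study <- function(rec, seed) {
  stopifnot(inherits(rec, "study_record"))
  n <- rec$n_subjects
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sex <- stats::rbinom(n, 1, rec$prop_male)
  draws <- matrix(0, n, 3)  # one 1x3 record per subject: age, bmi, vo2
  for (i in seq_len(n)) {
    draws[i, ] <- c(rnorm_pos(1, rec$age_mean, rec$age_sd),
                    rnorm_pos(1, rec$bmi_mean, rec$bmi_sd),
                    rnorm_pos(1, rec$vo2_mean, rec$vo2_sd))
  }
  x <- t(vapply(seq_len(n), function(i) {
    encode_subject(subject_profile(draws[i, 1], sex[i], draws[i, 2],
                                   draws[i, 3], rec$improvement))
  }, numeric(5)))
  ycode <- encode_prescription(rec$prescription)
  y <- matrix(ycode, n, 4, byrow = TRUE,
              dimnames = list(NULL, names(ycode)))
  list(x = x, y = y)
}

#' Build an encoded corpus from a study table
#'
#' Concatenates [augment_study()] over every record; the corpus size equals
#' the sum of the studies' subject counts exactly. Each study draws from its
#' own child stream keyed by study id, so reordering the table permutes
#' provenance blocks without changing any study's draws.
#'
#' @param table list of [study_record()] objects.
#' @param seed root integer seed.
#' @return a `fitt_corpus`: list with `x` (n x 5), `y` (n x 4), `provenance`
#'   (study id per row) and `seed`.
#' @export
build_corpus <- function(table, seed) {
  if (length(table) == 0) stop("study table is empty")
  parts <- lapply(table, function(rec) {
    augment_study(rec, child_seed(seed, rec$study_id))
  })
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  y <- do.call(rbind, lapply(parts, `[[`, "y"))
  prov <- rep(vapply(table, `[[`, character(1), "study_id"),
              vapply(table, `[[`, integer(1), "n_subjects"))
  structure(list(x = x, y = y, provenance = prov, seed = seed),
            class = "fitt_corpus")
}

#' @export
print.fitt_corpus <- function(x, ...) {
  cat(sprintf("Encoded corpus: %d samples from %d studies (seed %d)\n",
              nrow(x$x), length(unique(x$provenance)), x$seed))
  invisible(x)
}

#' Generate a synthetic study-summary table
#'
#' Draws plausible aerobic-training study summaries for older adults:
#' age means 60-80 y (SD 2-7), BMI means 21-30 (SD 1-4), baseline VO2max
#' means 10-35 mL kg^-1 min^-1 (SD 1-5), improvements 5-20 percent, and
#' prescriptions with frequency 2-5 d/wk, intensity 50-80 %HRR, 20-60 min
#' sessions over 8-24 weeks; 10-40 subjects per study. `n_total` forces the
#' subject counts to sum to a given corpus size.
#'
#' @param k_studies number of studies.
#' @param seed integer seed.
#' @param n_total optional total subject count to hit exactly.
#' @return list of [study_record()] objects.
#' @export
synth_study_table <- function(k_studies, seed, n_total = NULL) {
  stopifnot(k_studies >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, "study-table"))
  sizes <- sample(10:40, k_studies, replace = TRUE)
  if (!is.null(n_total)) {
    stopifnot(n_total >= k_studies)
    sizes <- force_total(sizes, n_total)
  }
  lapply(seq_len(k_studies), function(i) {
    intensity <- stats::runif(1, 50, 80)
    study_record(
      study_id = sprintf("S%03d", i),
      n_subjects = sizes[i],
      age_mean = stats::runif(1, 60, 80), age_sd = stats::runif(1, 2, 7),
      bmi_mean = stats::runif(1, 21, 30), bmi_sd = stats::runif(1, 1, 4),
      vo2_mean = stats::runif(1, 10, 35), vo2_sd = stats::runif(1, 1, 5),
      prop_male = stats::runif(1),
      improvement = round_half_up(stats::runif(1, 0.05, 0.20), 2),
      prescription = prescription(
        frequency = sample(2:5, 1),
        intensity = round_half_up(intensity),
        time_min = round_half_up(stats::runif(1, 20, 60), 2),
        volume_wk = round_half_up(stats::runif(1, 8, 24), 2)
      )
    )
  })
}

# adjust integer sizes (each >= 1) to sum exactly to target
force_total <- function(sizes, target) {
  diff <- target - sum(sizes)
  k <- length(sizes)
  i <- 1
  while (diff != 0) {
    step <- sign(diff)
    if (sizes[i] + step >= 1) {
      sizes[i] <- sizes[i] + step
      diff <- diff - step
    }
    i <- if (i == k) 1 else i + 1
  }
  sizes
}

#' Generate a labelled synthetic response surface
#'
#' Ground truth for recovery tests. Two modes:
#' * `"smooth"`: targets are a fixed smooth nonlinear function of the
#'   subject vector, built so coded intensity decreases in BMI and age and
#'   session time increases in the improvement target;
#' * `"teacher"`: targets come from a randomly initialized network of the
#'   requested architecture (a realizable target for the trainer).
#'
#' Gaussian noise of standard deviation `noise_sd` is added to every target
#' dimension. The generating function is returned alongside the data so
#' tests can measure recovery against it.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param noise_sd target noise SD (0 for a noise-free surface).
#' @param mode `"smooth"` or `"teacher"`.
#' @param sizes teacher architecture (teacher mode), input first.
#' @return list with `x` (n x 5), `y` (n x 4), `f` (the noise-free
#'   generating function of an input matrix), `noise_sd`, and in teacher
#'   mode the `teacher` network.
#' @export
synth_response_surface <- function(n, seed, noise_sd = 0,
                                   mode = c("smooth", "teacher"),
                                   sizes = c(5, 12, 10, 8, 4)) {
  mode <- match.arg(mode)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(seed, paste0("surface-", mode)))
  x <- cbind(
    age = stats::runif(n, 60, 80),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = stats::runif(n, 21, 30),
    vo2_pre = stats::runif(n, 10, 35),
    improvement = stats::runif(n, 0.05, 0.20)
  )
  teacher <- NULL
  if (mode == "smooth") {
    f <- smooth_surface_fn
  } else {
    teacher <- init_network(sizes, seed = child_seed(seed, "teacher"),
                            init_scale = 0.8)
    teacher <- attach_input_scaling(teacher, x)
    f <- function(x) forward(teacher, x)
  }
  y <- f(x)
  if (noise_sd > 0) {
    y <- y + matrix(stats::rnorm(length(y), 0, noise_sd), nrow(y), ncol(y))
  }
  list(x = x, y = y, f = f, noise_sd = noise_sd, teacher = teacher)
}

# fixed smooth ground-truth map: coded intensity falls with BMI and age,
# session time rises with the improvement target
smooth_surface_fn <- function(x) {
  age <- x[, 1]; sex <- x[, 2]; bmi <- x[, 3]
  vo2 <- x[, 4]; imp <- x[, 5]
  cbind(
    frequency = 2 + 10 * imp + 0.3 * tanh((vo2 - 20) / 8),
    intensity = 0.15 - 0.012 * (bmi - 25) - 0.006 * (age - 70) -
      0.02 * sex + 0.1 * imp,
    time_min = 30 + 120 * imp + 5 * tanh((vo2 - 20) / 10) + 0.3 * (bmi - 25),
    volume_wk = 10 + 20 * imp + 0.08 * (75 - age)
  )
}

#' Write / read a study table as CSV
#'
#' Column layout: `study_id,n_subjects,age_mean,age_sd,bmi_mean,bmi_sd,`
#' `vo2_mean,vo2_sd,prop_male,improvement,frequency,intensity_pct_hrr,`
#' `time_min,volume_wk`.
#'
#' @param table list of [study_record()] objects.
#' @param path CSV file path.
#' @return `write_study_table` the path invisibly; `read_study_table` the
#'   record list.
#' @export
write_study_table <- function(table, path) {
  df <- do.call(rbind, lapply(table, function(r) {
    data.frame(study_id = r$study_id, n_subjects = r$n_subjects,
               age_mean = r$age_mean, age_sd = r$age_sd,
               bmi_mean = r$bmi_mean, bmi_sd = r$bmi_sd,
               vo2_mean = r$vo2_mean, vo2_sd = r$vo2_sd,
               prop_male = r$prop_male, improvement = r$improvement,
               frequency = r$prescription$frequency,
               intensity_pct_hrr = r$prescription$intensity,
               time_min = r$prescription$time_min,
               volume_wk = r$prescription$volume_wk)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    study_record(df$study_id[i], df$n_subjects[i],
                 df$age_mean[i], df$age_sd[i],
                 df$bmi_mean[i], df$bmi_sd[i],
                 df$vo2_mean[i], df$vo2_sd[i],
                 df$prop_male[i], df$improvement[i],
                 prescription(df$frequency[i], df$intensity_pct_hrr[i],
                              df$time_min[i], df$volume_wk[i]))
  })
}

#' Write / read an encoded corpus as CSV with a JSON sidecar
#'
#' The CSV holds the encoded 5+4 columns plus provenance; the sidecar
#' records the seed so reruns can be verified.
#'
#' @param corpus a `fitt_corpus`.
#' @param path CSV file path (`<path>.json` sidecar written next to it).
#' @return `write_corpus` the path invisibly; `read_corpus` the corpus.
#' @export
write_corpus <- function(corpus, path) {
  df <- data.frame(corpus$x, corpus$y, provenance = corpus$provenance,
                   check.names = FALSE)
  names(df) <- c("age", "sex", "bmi", "vo2_pre", "improvement",
                 "frequency", "intensity_code", "time_min", "volume_wk",
                 "provenance")
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = corpus$seed, n_samples = nrow(corpus$x),
         n_studies = length(unique(corpus$provenance))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  seed <- if (file.exists(side)) jsonlite::read_json(side)$seed else NA_integer_
  structure(list(
    x = as.matrix(df[, c("age", "sex", "bmi", "vo2_pre", "improvement")]),
    y = as.matrix(df[, c("frequency", "intensity_code", "time_min",
                         "volume_wk")]),
    provenance = df$provenance, seed = seed
  ), class = "fitt_corpus")
}
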
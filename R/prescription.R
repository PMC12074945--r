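# Inference-time use of a trained model: subject profile plus a target
# improvement in, decoded FITT prescription with an intensity range and
# plausibility screening out.

#' Generate an individualized prescription
#'
#' Encodes the subject profile (with the requested target improvement),
#' forward-passes the trained network, and decodes the 4-vector output:
#' frequency rounded to the nearest positive integer, intensity reported as
#' the %HRR midpoint with a symmetric band, time and volume to 2 decimals.
#' Decoded elements are screened for plausibility — intensity outside
#' 40-90 %HRR, time outside 10-90 min, volume outside 4-52 weeks — and
#' violations are flagged, never clipped or blocked. A non-positive time or
#' volume output yields no prescription and a flag.
#'
#' @param model a trained `fitt_network` or a `fitt_fit`.
#' @param profile a [subject_profile()].
#' @param target_improvement target relative VO2max improvement as a
#'   fraction (default 0.10, i.e. 10 percent).
#' @param band intensity-range half-width in %HRR (default 5; 10 for the
#'   wider band).
#' @return a `prescription_result`: `prescription` (NULL if undecodable),
#'   `flags` (character vector, empty when all elements are in bounds),
#'   `raw` (the network's 4-vector output).
#' @export
prescribe <- function(model, profile, target_improvement = 0.10, band = 5) {
  if (inherits(model, "fitt_fit")) model <- model$network
  stopifnot(inherits(model, "fitt_network"),
            inherits(profile, "subject_profile"), target_improvement > 0)
  if (any(!is.finite(flatten_params(model)))) {
    stop("model has non-finite parameters; train before prescribing")
  }
  profile$improvement <- round_half_up(target_improvement, 2)
  y <- forward(model, encode_subject(profile))
  flags <- character(0)
  rx <- NULL
  if (y[3] <= 0 || y[4] <= 0) {
    flags <- c(flags, "non-positive time or volume output; no prescription")
  } else if (y[2] <= -0.5 || y[2] >= 0.5) {
    flags <- c(flags, "intensity code outside (-0.5, 0.5); no prescription")
  } else {
    rx <- decode_prescription(y, band = band)
    if (rx$intensity < 40 || rx$intensity > 90) {
      flags <- c(flags, sprintf("intensity %.1f %%HRR outside 40-90",
                                rx$intensity))
    }
    if (rx$time_min < 10 || rx$time_min > 90) {
      flags <- c(flags, sprintf("time %.1f min outside 10-90", rx$time_min))
    }
    if (rx$volume_wk < 4 || rx$volume_wk > 52) {
      flags <- c(flags, sprintf("volume %.1f wk outside 4-52", rx$volume_wk))
    }
  }
  structure(list(prescription = rx, flags = flags, raw = y),
            class = "prescription_result")
}

#' @export
print.prescription_result <- function(x, ...) {
  if (is.null(x$prescription)) {
    cat("No prescription decodable from model output\n")
  } else {
    print(x$prescription)
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Prescribe for a roster of subjects
#'
#' Runs [prescribe()] per subject and summarizes each FITT element as
#' mean +/- SD with the min-max range, in the layout of a group
#' characteristics table. Per-subject failures are reported in the flags
#' column, never fatal.
#'
#' @param model a trained `fitt_network` or `fitt_fit`.
#' @param roster list of [subject_profile()] objects (e.g. from
#'   [read_roster()]).
#' @param target_improvement target improvement fraction for all subjects.
#' @param band intensity-range half-width in %HRR.
#' @return a `batch_prescription`: `results` (per-subject
#'   `prescription_result`s), `table` (per-subject FITT data frame with a
#'   `flags` column), `summary` (element, mean, sd, min, max).
#' @export
batch_prescribe <- function(model, roster, target_improvement = 0.10,
                            band = 5) {
  stopifnot(length(roster) >= 1)
  results <- lapply(roster, function(p) {
    tryCatch(prescribe(model, p, target_improvement, band),
             error = function(e) {
               structure(list(prescription = NULL,
                              flags = paste("error:", conditionMessage(e)),
                              raw = rep(NA_real_, 4)),
                         class = "prescription_result")
             })
  })
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]$prescription
    data.frame(
      subject = i,
      frequency = if (is.null(r)) NA_real_ else r$frequency,
      intensity = if (is.null(r)) NA_real_ else r$intensity,
      intensity_low = if (is.null(r)) NA_real_ else r$intensity_range[1],
      intensity_high = if (is.null(r)) NA_real_ else r$intensity_range[2],
      time_min = if (is.null(r)) NA_real_ else r$time_min,
      volume_wk = if (is.null(r)) NA_real_ else r$volume_wk,
      flags = paste(results[[i]]$flags, collapse = "; ")
    )
  })
  tab <- do.call(rbind, rows)
  summarize <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(c(mean = NA_real_, sd = NA_real_, min = NA_real_,
               max = NA_real_))
    }
    c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
  }
  elements <- c("frequency", "intensity", "time_min", "volume_wk")
  summ <- do.call(rbind, lapply(elements, function(el) {
    s <- summarize(tab[[el]])
    data.frame(element = el, mean = s["mean"], sd = s["sd"],
               min = s["min"], max = s["max"], row.names = NULL)
  }))
  structure(list(results = results, table = tab, summary = summ,
                 target_improvement = target_improvement),
            class = "batch_prescription")
}

#' @export
print.batch_prescription <- function(x, ...) {
  n_ok <- sum(!is.na(x$table$frequency))
  cat(sprintf("Prescriptions for %d subjects (%d decoded), target +%.0f%% VO2max\n",
              nrow(x$table), n_ok, 100 * x$target_improvement))
  labels <- c(frequency = "Frequency (d/w)", intensity = "Intensity (%HRR)",
              time_min = "Time (min)", volume_wk = "Volume (w)")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-17s %.1f +/- %.1f (%g-%g)\n",
                labels[[s$element]], s$mean, s$sd,
                round_half_up(s$min, 1), round_half_up(s$max, 1)))
  }
  invisible(x)
}
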
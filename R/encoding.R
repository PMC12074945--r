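# Deterministic coding between physiological / prescription quantities and the
# numeric vectors the network consumes and emits.
#
# Coding dialect:
#   * intensity (%HRR) -> decimal minus 0.5, so 50 %HRR codes to 0
#   * age / BMI / baseline VO2max carry 1 decimal; improvement, session time
#     and programme volume carry 2 decimals
#   * sex is 0 = female, 1 = male; frequency is carried as its raw value in
#     days/week and rounded to the nearest positive integer only at decode
#   * all rounding is round-half-up, applied once at encoding

#' Round half away from zero
#'
#' Classical round-half-up (ties away from zero), the canonical rounding
#' dialect used throughout the coding layer. Base [round()] rounds ties to
#' even, which would make printed 1- and 2-decimal conventions irreproducible.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(13.06, 1)   # 13.1
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Encode exercise intensity (%HRR)
#'
#' Converts a percent heart-rate-reserve intensity to the network code:
#' the decimal value minus 0.5, so that 50 %HRR is the coding origin.
#' For example 60 %HRR encodes to 0.1.
#'
#' @param pct_hrr intensity as percent of heart-rate reserve, in (0, 100).
#' @return intensity code in (-0.5, 0.5).
#' @seealso [decode_intensity()], [encode_intensity_range()]
#' @export
#' @examples
#' encode_intensity(60)  # 0.1
#' encode_intensity(50)  # 0
encode_intensity <- function(pct_hrr) {
  stopifnot(is.numeric(pct_hrr))
  if (any(!is.finite(pct_hrr)) || any(pct_hrr <= 0) || any(pct_hrr >= 100)) {
    stop("intensity must lie strictly between 0 and 100 %HRR")
  }
  (pct_hrr - 50) / 100  # algebraically pct/100 - 0.5, exact for integers
}

#' Decode an intensity code back to %HRR
#'
#' Inverse of [encode_intensity()].
#'
#' @param code intensity code in (-0.5, 0.5).
#' @return intensity as percent of heart-rate reserve.
#' @export
decode_intensity <- function(code) {
  stopifnot(is.numeric(code))
  if (any(!is.finite(code)) || any(code <= -0.5) || any(code >= 0.5)) {
    stop("intensity code must lie strictly between -0.5 and 0.5")
  }
  code * 100 + 50
}

#' Encode an intensity range by its midpoint
#'
#' Studies report intensity as a %HRR range; the coded value is the encoding
#' of the range midpoint.
#'
#' @param low,high range endpoints in %HRR, `low <= high`.
#' @return intensity code of the midpoint.
#' @export
#' @examples
#' encode_intensity_range(55, 65)  # 0.1
encode_intensity_range <- function(low, high) {
  if (any(low > high)) stop("intensity range must have low <= high")
  encode_intensity((low + high) / 2)
}

#' Construct a subject profile
#'
#' @param age age in years (stored to 1 decimal).
#' @param sex `0`/`"F"` = female, `1`/`"M"` = male.
#' @param bmi body-mass index in kg/m^2 (1 decimal).
#' @param vo2_pre baseline VO2max in mL kg^-1 min^-1 (1 decimal).
#' @param improvement target relative improvement in VO2max as a fraction
#'   (2 decimals; `0.10` = 10 percent).
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(age, sex, bmi, vo2_pre, improvement = 0.10) {
  sex <- code_sex(sex)
  stopifnot(is.numeric(age), is.numeric(bmi), is.numeric(vo2_pre),
            is.numeric(improvement))
  if (age <= 0 || bmi <= 0 || vo2_pre <= 0 || improvement <= 0) {
    stop("age, bmi, vo2_pre and improvement must be positive")
  }
  structure(list(
    age = round_half_up(age, 1),
    sex = sex,
    bmi = round_half_up(bmi, 1),
    vo2_pre = round_half_up(vo2_pre, 1),
    improvement = round_half_up(improvement, 2)
  ), class = "subject_profile")
}

code_sex <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- toupper(as.character(sex))
    sex <- ifelse(sex %in% c("M", "MALE", "1"), 1,
                  ifelse(sex %in% c("F", "FEMALE", "0"), 0, NA_real_))
  }
  sex <- as.numeric(sex)
  if (any(is.na(sex)) || !all(sex %in% c(0, 1))) {
    stop("sex must be one of 0/1/F/M")
  }
  sex
}

#' Encode a subject profile as the 5-dimensional network input
#'
#' Component order is fixed: age, sex, BMI, baseline VO2max, improvement.
#'
#' @param p a [subject_profile()].
#' @return numeric vector of length 5.
#' @export
encode_subject <- function(p) {
  if (!inherits(p, "subject_profile")) {
    p <- do.call(subject_profile, as.list(p))
  }
  c(age = p$age, sex = p$sex, bmi = p$bmi,
    vo2_pre = p$vo2_pre, improvement = p$improvement)
}

#' Construct an exercise prescription
#'
#' The four FITT elements the model prescribes: frequency in sessions per
#' week, intensity as a %HRR midpoint with its range, session time in
#' minutes and programme volume in weeks.
#'
#' @param frequency sessions per week (positive integer-valued).
#' @param intensity %HRR midpoint, in (0, 100).
#' @param time_min minutes per session (2 decimals).
#' @param volume_wk programme length in weeks (2 decimals).
#' @param intensity_range optional `c(low, high)` %HRR range bracketing
#'   `intensity`; defaults to `intensity +/- band`.
#' @param band half-width of the default intensity range, percentage points
#'   of HRR (default 5, i.e. midpoint plus or minus 5 %HRR).
#' @return a `prescription` list.
#' @export
prescription <- function(frequency, intensity, time_min, volume_wk,
                         intensity_range = NULL, band = 5) {
  stopifnot(is.numeric(frequency), is.numeric(intensity),
            is.numeric(time_min), is.numeric(volume_wk))
  if (frequency < 1) stop("frequency must be at least 1 session/week")
  if (intensity <= 0 || intensity >= 100) {
    stop("intensity must lie strictly between 0 and 100 %HRR")
  }
  if (time_min <= 0 || volume_wk <= 0) {
    stop("time and volume must be positive")
  }
  if (is.null(intensity_range)) {
    intensity_range <- c(intensity - band, intensity + band)
  }
  if (intensity_range[1] > intensity || intensity_range[2] < intensity) {
    stop("intensity_range must bracket the intensity midpoint")
  }
  structure(list(
    frequency = frequency,
    intensity = intensity,
    intensity_range = intensity_range,
    time_min = round_half_up(time_min, 2),
    volume_wk = round_half_up(volume_wk, 2)
  ), class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf(
    "FITT prescription: %g d/wk, %.1f %%HRR (%.1f-%.1f), %.2f min, %.2f wk\n",
    x$frequency, x$intensity, x$intensity_range[1], x$intensity_range[2],
    x$time_min, x$volume_wk))
  invisible(x)
}

#' Encode a prescription as the 4-dimensional network target
#'
#' Order is fixed: frequency (raw days/week), intensity code, time in
#' minutes (2 decimals), volume in weeks (2 decimals). The output coding
#' mirrors the input coding; only intensity is transformed.
#'
#' @param r a [prescription()].
#' @return numeric vector of length 4.
#' @export
encode_prescription <- function(r) {
  stopifnot(inherits(r, "prescription"))
  c(frequency = r$frequency,
    intensity = encode_intensity(r$intensity),
    time_min = round_half_up(r$time_min, 2),
    volume_wk = round_half_up(r$volume_wk, 2))
}

#' Decode a 4-vector of network output into a prescription
#'
#' Frequency is rounded to the nearest positive integer (never below 1);
#' intensity is decoded from its code and given a symmetric %HRR range.
#' Negative time or volume raises an error rather than being clipped.
#'
#' @param y numeric 4-vector (frequency, intensity code, time, volume).
#' @param band half-width of the attached intensity range in %HRR
#'   (default 5; set 10 for the wider band).
#' @return a [prescription()].
#' @export
decode_prescription <- function(y, band = 5) {
  y <- as.numeric(y)
  stopifnot(length(y) == 4)
  if (any(!is.finite(y))) stop("prescription vector must be finite")
  if (y[3] <= 0 || y[4] <= 0) {
    stop("decoded time/volume must be positive; got time = ",
         signif(y[3], 4), ", volume = ", signif(y[4], 4))
  }
  freq <- max(1, round_half_up(y[1]))
  prescription(
    frequency = freq,
    intensity = decode_intensity(y[2]),
    time_min = round_half_up(y[3], 2),
    volume_wk = round_half_up(y[4], 2),
    band = band
  )
}

#' Read a subject roster from CSV
#'
#' Expects columns `age,sex,bmi,vo2_pre,improvement`; `sex` accepted as
#' `F/M/0/1`, `improvement` as a fraction (values above 1 are treated as
#' percent and divided by 100).
#'
#' @param path CSV file path.
#' @return a list of [subject_profile()] objects.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "bmi", "vo2_pre", "improvement")
  if (!all(need %in% names(df))) {
    stop("roster must have columns: ", paste(need, collapse = ","))
  }
  lapply(seq_len(nrow(df)), function(i) {
    imp <- df$improvement[i]
    if (imp > 1) imp <- imp / 100
    subject_profile(df$age[i], df$sex[i], df$bmi[i], df$vo2_pre[i], imp)
  })
}
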
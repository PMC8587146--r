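# Crossing count with the fixed sign convention: a zero sample adopts the
# previous nonzero sign; leading zeros carry no sign and cannot cross.
count_crossings <- function(x) {
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0L)
  # forward-fill nonzero signs, then drop the (sign-less) leading zeros
  filled <- s
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) filled[i] <- last else last <- filled[i]
  }
  filled <- filled[filled != 0]
  if (length(filled) < 2) return(0L)
  sum(filled[-1] != filled[-length(filled)])
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Time-domain features of one window
#'
#' The seven classical per-window statistics: mean, min, max, median,
#' population standard deviation, zero-crossing count and mean-crossing
#' count.  Crossings count strict sign changes between consecutive samples
#' (of the raw samples about 0, and of the centred samples about the
#' window mean); a zero-valued sample adopts the previous nonzero sign.
#'
#' @param samples numeric vector (>= 2 samples).
#' @return named numeric vector with elements `mean`, `min`, `max`,
#'   `median`, `std`, `zero_crossings`, `mean_crossings`.
#' @export
time_domain_features <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 samples")
  m <- mean(samples)
  c(mean = m, min = min(samples), max = max(samples),
    median = median(samples), std = pop_sd(samples),
    zero_crossings = count_crossings(samples),
    mean_crossings = count_crossings(samples - m))
}

#' One-sided amplitude spectrum of a window
#'
#' Discrete Fourier transform of the raw (un-detrended, un-tapered) window
#' samples, normalised so amplitudes are physical: the DC bin is
#' `|X_0| / N` (hence exactly the window's time-domain mean for a real
#' signal), every other bin is `2 |X_k| / N`, except the Nyquist bin for
#' even `N`, which is not doubled.
#'
#' @param samples numeric vector (>= 2 samples).
#' @param rate_hz sampling rate in Hz.
#' @return list of class `spectrum_1s` with `frequencies_hz` (ascending,
#'   starting at 0) and `amplitudes` (non-negative), both of length
#'   `floor(N / 2) + 1`.
#' @export
amplitude_spectrum <- function(samples, rate_hz) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples")
  stopifnot(rate_hz > 0)
  half <- floor(n / 2) + 1
  amp <- Mod(fft(samples))[seq_len(half)] / n
  dbl <- rep(2, half)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[half] <- 1  # Nyquist bin not doubled
  structure(list(frequencies_hz = (seq_len(half) - 1) * rate_hz / n,
                 amplitudes = amp * dbl),
            class = "spectrum_1s")
}

#' Frequency-domain features of one spectrum
#'
#' Eight features per spectrum.  Six are common to all signals and
#' computed over all bins including DC: `mean`, `min`, `median`, `std`
#' (population), `mean_crossings` (of the amplitude sequence about its
#' mean, same crossing rule as the time domain) and `dc_component` (the
#' 0 Hz amplitude, equal to the window's time-domain mean under this
#' normalisation).  The peak features depend on the signal kind:
#' \describe{
#'   \item{`ACC`}{gravity makes the DC bin dominate accelerometer spectra,
#'     so the peak feature is `second_max` -- the largest non-DC amplitude
#'     when DC is the global maximum, otherwise the second-largest
#'     amplitude overall -- and `dominant_frequency` is its frequency.}
#'   \item{`BIO`}{for the dynamic cardiac signals (ECG, PPG) the peak
#'     feature is `max`, the global maximum amplitude (DC included), and
#'     `dominant_frequency` is its frequency.}
#' }
#' Ties are broken toward the lowest frequency.
#'
#' @param spectrum a `spectrum_1s` (>= 3 bins).
#' @param kind `"ACC"` or `"BIO"`.
#' @return named numeric vector of 8 features.
#' @export
frequency_domain_features <- function(spectrum, kind = c("ACC", "BIO")) {
  kind <- match.arg(kind)
  amp <- spectrum$amplitudes
  freq <- spectrum$frequencies_hz
  if (length(amp) < 3) stop("need at least 3 spectral bins")
  common <- c(mean = mean(amp), min = min(amp), median = median(amp),
              std = pop_sd(amp),
              mean_crossings = count_crossings(amp - mean(amp)),
              dc_component = amp[1])
  ranking <- order(-amp, seq_along(amp))  # lowest frequency wins ties
  if (kind == "ACC") {
    # ranking[2] is the largest non-DC bin when DC is the global max, and
    # the second-largest bin overall otherwise
    idx <- ranking[2]
    c(common, second_max = amp[idx], dominant_frequency = freq[idx])
  } else {
    idx <- ranking[1]
    c(common, max = amp[idx], dominant_frequency = freq[idx])
  }
}

# signal -> spectral kind
signal_kind <- function(signal) {
  if (grepl("^ACC", signal)) "ACC" else "BIO"
}

feature_column_names <- function() {
  unlist(lapply(CHANNEL_NAMES, function(nm) {
    tf <- c("mean", "min", "max", "median", "std",
            "zero_crossings", "mean_crossings")
    peak <- if (signal_kind(nm) == "ACC") "second_max" else "max"
    ff <- c("mean", "min", "median", "std", "mean_crossings",
            "dc_component", peak, "dominant_frequency")
    c(paste(nm, "time", tf, sep = "."), paste(nm, "freq", ff, sep = "."))
  }), use.names = FALSE)
}

#' Build the window-by-feature matrix
#'
#' For each window, computes the 7 time-domain and 8 frequency-domain
#' features on each of the five channels (accelerometer channels use the
#' `ACC` spectral-peak convention, ECG and PPG the `BIO` one), yielding 75
#' named columns with the grammar `{signal}.{time|freq}.{feature}`.
#'
#' @param windows a `window_set` with the five expected channels.
#' @return data frame of class `feature_matrix`: columns `window_id`,
#'   `activity`, then 75 numeric feature columns; one row per window in
#'   window order.
#' @export
build_feature_matrix <- function(windows) {
  missing <- setdiff(CHANNEL_NAMES, names(windows$rates))
  if (length(missing) > 0) {
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  }
  cols <- feature_column_names()
  n <- length(windows$windows)
  mat <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    w <- windows$windows[[i]]
    row <- numeric(0)
    for (nm in CHANNEL_NAMES) {
      x <- w$blocks[[nm]]
      tf <- time_domain_features(x)
      sp <- amplitude_spectrum(x, windows$rates[[nm]])
      ff <- frequency_domain_features(sp, signal_kind(nm))
      row <- c(row, tf, ff)
    }
    mat[i, ] <- row
  }
  out <- data.frame(
    window_id = vapply(windows$windows, `[[`, 0L, "window_id"),
    activity = vapply(windows$windows, `[[`, "", "activity"),
    check.names = FALSE
  )
  out <- cbind(out, as.data.frame(mat, check.names = FALSE))
  class(out) <- c("feature_matrix", "data.frame")
  out
}

# Names of the numeric feature columns of a feature matrix (everything
# except the window_id / activity / subject_id bookkeeping columns).
feature_cols <- function(fm) {
  setdiff(colnames(fm), c("window_id", "activity", "subject_id"))
}

#' Windowed features for a whole cohort
#'
#' Convenience wrapper: up-samples each record's accelerometer, cuts
#' windows and stacks the per-subject feature matrices with a
#' `subject_id` column.
#'
#' @param records list of `subject_record`s.
#' @param window_seconds window duration (default 7 s).
#' @param allowed_activities labels to keep.
#' @return `feature_matrix` data frame with a leading `subject_id` column.
#' @export
cohort_features <- function(records, window_seconds = 7,
                            allowed_activities = ACTIVITIES) {
  parts <- lapply(records, function(r) {
    ws <- extract_windows(upsample_record(r), window_seconds,
                          allowed_activities)
    fm <- build_feature_matrix(ws)
    cbind(subject_id = r$subject_id, fm)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("feature_matrix", "data.frame")
  out
}
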
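#' Up-sample a signal to twice its rate by pairwise averaging
#'
#' Doubles the sampling rate by interleaving each pair of consecutive
#' samples with their average: even output positions (0-based) carry the
#' original samples, odd position `2i + 1` carries
#' `mean(samples[i], samples[i + 1])`.  The final odd slot, which has no
#' successor, repeats the last sample.
#'
#' @param samples numeric vector (length >= 1).
#' @return numeric vector of length `2 * length(samples)`.
#' @export
#' @examples
#' upsample_by_pairwise_average(c(0, 2, 4))  # 0 1 2 3 4 4
upsample_by_pairwise_average <- function(samples) {
  n <- length(samples)
  if (n < 1) stop("cannot up-sample an empty sequence")
  out <- numeric(2 * n)
  out[seq(1, 2 * n, by = 2)] <- samples
  mids <- if (n > 1) (samples[-n] + samples[-1]) / 2 else numeric(0)
  out[seq(2, 2 * n, by = 2)] <- c(mids, samples[n])
  out
}

#' Up-sample the accelerometer channels of a record to 64 Hz
#'
#' Applies [upsample_by_pairwise_average()] to each 32 Hz ACC channel;
#' PPG (64 Hz) and ECG (700 Hz) are left untouched.
#'
#' @param record a `subject_record`.
#' @return the record with all ACC channels at 64 Hz.
#' @export
upsample_record <- function(record) {
  for (nm in c("ACC-X", "ACC-Y", "ACC-Z")) {
    ch <- record$channels[[nm]]
    if (ch$rate_hz == 32) {
      ch$samples <- upsample_by_pairwise_average(ch$samples)
      ch$rate_hz <- 64
      record$channels[[nm]] <- ch
    }
  }
  record
}

#' Cut label-pure non-overlapping windows across all channels
#'
#' Tiles each labeled activity interval from its start in steps of
#' `window_seconds`; a window that would extend past the interval end is
#' discarded, so every window carries exactly one activity label.  Windows
#' never span label boundaries.  Per channel, a window holds
#' `round(window_seconds * rate_hz)` samples (448 at 64 Hz and 4900 at
#' 700 Hz for the default 7 s windows).
#'
#' @param record a `subject_record` whose ACC channels are already at
#'   64 Hz (see [upsample_record()]).
#' @param window_seconds window duration in seconds (> 0).
#' @param allowed_activities labels to keep; windows with other labels are
#'   dropped.
#' @return an object of class `window_set`: list with `window_seconds`,
#'   `rates` (named channel rates) and `windows`, a list of windows each
#'   holding `window_id`, `activity`, `start_s` and `blocks` (named list of
#'   per-channel sample vectors).  An empty window list is returned (not an
#'   error) when no interval fits a whole window.
#' @export
extract_windows <- function(record, window_seconds = 7,
                            allowed_activities = ACTIVITIES) {
  if (window_seconds <= 0) stop("window_seconds must be > 0")
  rates <- vapply(record$channels, `[[`, 0, "rate_hz")
  lens <- round(window_seconds * rates)
  if (any(lens < 2)) stop("window too short for channel rates")
  windows <- list()
  wid <- 0L
  for (i in seq_len(nrow(record$labels))) {
    act <- record$labels$activity[i]
    if (!(act %in% allowed_activities)) next
    s <- record$labels$start_s[i]
    e <- record$labels$end_s[i]
    k <- floor((e - s) / window_seconds + 1e-9)
    if (k < 1) next
    for (j in seq_len(k) - 1) {
      t0 <- s + j * window_seconds
      blocks <- vector("list", length(record$channels))
      names(blocks) <- names(record$channels)
      ok <- TRUE
      for (nm in names(record$channels)) {
        r <- rates[[nm]]
        i0 <- ceiling(t0 * r - 1e-9)  # first sample index (0-based) at or after t0
        idx <- (i0 + 1):(i0 + lens[[nm]])
        if (idx[length(idx)] > length(record$channels[[nm]]$samples)) {
          ok <- FALSE
          break
        }
        blocks[[nm]] <- record$channels[[nm]]$samples[idx]
      }
      if (!ok) next
      wid <- wid + 1L
      windows[[wid]] <- list(window_id = wid, activity = act,
                             start_s = t0, blocks = blocks)
    }
  }
  structure(list(window_seconds = window_seconds, rates = rates,
                 windows = windows),
            class = "window_set")
}
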
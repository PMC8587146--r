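# Independent brute-force oracles used to validate the fast paths.
# These are deliberately naive re-implementations that share no code with
# the package internals.

# Time-domain statistics coded independently of the package: base
# summary functions for the plain moments, explicit loops for the
# crossing logic (the contested part).
oracle_time_features <- function(x) {
  m <- mean(x)
  crossings <- function(z) {
    signs <- integer(0)
    last <- 0
    for (v in z) {
      sg <- if (v > 0) 1L else if (v < 0) -1L else last
      if (sg != 0) signs <- c(signs, sg)
      last <- sg
    }
    cnt <- 0L
    if (length(signs) >= 2) {
      for (i in 2:length(signs)) if (signs[i] != signs[i - 1]) cnt <- cnt + 1L
    }
    cnt
  }
  c(mean = m, min = min(x), max = max(x), median = median(x),
    std = sqrt(mean((x - m)^2)),
    zero_crossings = crossings(x), mean_crossings = crossings(x - m))
}

# Direct O(N^2) discrete Fourier transform, one-sided amplitudes.
oracle_amplitude_spectrum <- function(x, rate_hz) {
  n <- length(x)
  half <- floor(n / 2) + 1
  idx <- 0:(n - 1)
  amp <- numeric(half)
  for (k in 0:(half - 1)) {
    re <- sum(x * cos(2 * pi * k * idx / n))
    im <- -sum(x * sin(2 * pi * k * idx / n))
    a <- sqrt(re^2 + im^2) / n
    if (k > 0 && !(n %% 2 == 0 && k == n / 2)) a <- 2 * a
    amp[k + 1] <- a
  }
  list(frequencies_hz = (0:(half - 1)) * rate_hz / n, amplitudes = amp)
}

# Full-scan frequency features with the explicit tie rule (lowest
# frequency wins) and the ACC second-max convention.
oracle_freq_features <- function(freq, amp, kind) {
  n <- length(amp)
  m <- mean(amp)
  med <- median(amp)
  sdv <- sqrt(mean((amp - m)^2))
  crossings <- function(z) {
    signs <- integer(0)
    last <- 0
    for (v in z) {
      sg <- if (v > 0) 1L else if (v < 0) -1L else last
      if (sg != 0) signs <- c(signs, sg)
      last <- sg
    }
    cnt <- 0L
    if (length(signs) >= 2) {
      for (i in 2:length(signs)) if (signs[i] != signs[i - 1]) cnt <- cnt + 1L
    }
    cnt
  }
  # global max, lowest frequency on ties
  imax <- 1
  for (i in seq_len(n)) if (amp[i] > amp[imax]) imax <- i
  # second-largest overall, lowest frequency on ties
  i2 <- NA
  for (i in seq_len(n)) {
    if (i == imax) next
    if (is.na(i2) || amp[i] > amp[i2]) i2 <- i
  }
  common <- c(mean = m, min = min(amp), median = med, std = sdv,
              mean_crossings = crossings(amp - m), dc_component = amp[1])
  if (kind == "ACC") {
    if (imax == 1) {
      # DC is the global max: largest amplitude among non-DC bins
      pick <- 2
      for (i in 2:n) if (amp[i] > amp[pick]) pick <- i
    } else {
      # otherwise: second-largest amplitude overall
      pick <- i2
    }
    c(common, second_max = amp[pick], dominant_frequency = freq[pick])
  } else {
    c(common, max = amp[imax], dominant_frequency = freq[imax])
  }
}

# Spearman rho with average ranks, from first principles.
oracle_spearman <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  if (den == 0) 0 else num / den
}

# Exhaustive iterative oracle for the correlation-drop rule: at every step
# recompute all surviving pairs, take the one with the largest |rho|
# (ties: lexicographic names), drop its lower-relevance member, repeat.
oracle_correlation_select <- function(X, labels, threshold = 0.85) {
  cols <- colnames(X)
  y <- match(labels, sort(unique(labels)))
  rel <- vapply(cols, function(cc) abs(oracle_spearman(X[, cc], y)), 0)
  alive <- cols
  repeat {
    best <- NULL
    for (i in seq_along(alive)) {
      for (j in seq_along(alive)) {
        if (j <= i) next
        a <- alive[i]; b <- alive[j]
        r <- abs(oracle_spearman(X[, a], X[, b]))
        if (r > threshold) {
          key <- list(r = r, lo = min(a, b), hi = max(a, b))
          if (is.null(best) || r > best$r ||
              (r == best$r && (key$lo < best$lo ||
                               (key$lo == best$lo && key$hi < best$hi)))) {
            best <- key
          }
        }
      }
    }
    if (is.null(best)) break
    drop <- if (rel[[best$lo]] < rel[[best$hi]]) best$lo
            else if (rel[[best$hi]] < rel[[best$lo]]) best$hi
            else best$hi
    alive <- setdiff(alive, drop)
  }
  alive
}

# Rank-based (Mann-Whitney) AUC, independent of pROC.
oracle_auc <- function(truth01, score) {
  pos <- score[truth01 == 1]
  neg <- score[truth01 == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Small hand-rolled subject record for windowing tests: deterministic
# ramps on every channel, arbitrary label track.
make_test_record <- function(labels, total_s = max(labels$end_s),
                             acc_rate = 64) {
  rates <- c("ACC-X" = acc_rate, "ACC-Y" = acc_rate, "ACC-Z" = acc_rate,
             "PPG" = 64, "ECG" = 700)
  channels <- lapply(names(rates), function(nm) {
    n <- round(total_s * rates[[nm]])
    list(name = nm, rate_hz = unname(rates[[nm]]), samples = seq_len(n) / n)
  })
  names(channels) <- names(rates)
  structure(list(subject_id = "T01", channels = channels, labels = labels),
            class = "subject_record")
}
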
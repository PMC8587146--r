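test_that("time-domain features match hand arithmetic", {
  f <- time_domain_features(c(1, -1, 1, -1))
  expect_equal(unname(f[c("mean", "min", "max", "median", "std")]),
               c(0, -1, 1, 0, 1))
  expect_equal(unname(f["zero_crossings"]), 3)
  expect_equal(unname(f["mean_crossings"]), 3)

  g <- time_domain_features(c(2, 2, 2))
  expect_equal(unname(g[c("std", "zero_crossings", "mean_crossings")]),
               c(0, 0, 0))
  expect_error(time_domain_features(1), "2 samples")
})

test_that("zero samples adopt the previous nonzero sign when crossing", {
  # 1, 0, -1: the zero keeps sign +1, so exactly one crossing
  expect_equal(unname(time_domain_features(c(1, 0, -1))["zero_crossings"]), 1)
  # 1, 0, 1: no crossing
  expect_equal(unname(time_domain_features(c(1, 0, 1))["zero_crossings"]), 0)
})

test_that("amplitude spectrum is physically normalised", {
  for (n in c(17, 448)) {
    sp <- amplitude_spectrum(rep(3.5, n), 64)
    expect_equal(sp$amplitudes[1], 3.5, tolerance = 1e-9)
    expect_lt(max(abs(sp$amplitudes[-1])), 1e-9)
    expect_equal(sp$frequencies_hz[1], 0)
    expect_length(sp$amplitudes, floor(n / 2) + 1)
  }
  t <- (0:447) / 64
  sp <- amplitude_spectrum(2 * cos(2 * pi * 4 * t), 64)
  bin <- which(sp$frequencies_hz == 4)
  expect_equal(sp$amplitudes[bin], 2, tolerance = 1e-9)
  expect_lt(max(sp$amplitudes[-bin]), 1e-9)
})

test_that("frequency features follow the per-kind peak conventions", {
  amp <- c(3, 0.01, 2, 0.02, 0.01)
  sp <- structure(list(frequencies_hz = c(0, 2, 4, 6, 8), amplitudes = amp),
                  class = "spectrum_1s")
  f <- frequency_domain_features(sp, "ACC")
  expect_equal(unname(f["dc_component"]), 3)
  expect_equal(unname(f["second_max"]), 2)
  expect_equal(unname(f["dominant_frequency"]), 4)

  sp2 <- structure(list(frequencies_hz = c(0, 1.2, 2.4),
                        amplitudes = c(0.5, 5, 0.1)),
                   class = "spectrum_1s")
  g <- frequency_domain_features(sp2, "BIO")
  expect_equal(unname(g["max"]), 5)
  expect_equal(unname(g["dominant_frequency"]), 1.2)

  # ACC fallback: DC not the global max -> second-largest overall
  sp3 <- structure(list(frequencies_hz = c(0, 2, 4, 6),
                        amplitudes = c(1, 5, 3, 0.1)),
                   class = "spectrum_1s")
  h <- frequency_domain_features(sp3, "ACC")
  expect_equal(unname(h["second_max"]), 3)
  expect_equal(unname(h["dominant_frequency"]), 4)

  expect_error(frequency_domain_features(
    structure(list(frequencies_hz = c(0, 1), amplitudes = c(1, 1)),
              class = "spectrum_1s"), "ACC"), "3 spectral bins")
})

test_that("ties in spectral peaks resolve to the lowest frequency", {
  sp <- structure(list(frequencies_hz = c(0, 1, 2, 3),
                       amplitudes = c(0.1, 2, 2, 1)),
                  class = "spectrum_1s")
  expect_equal(unname(frequency_domain_features(sp, "BIO")["dominant_frequency"]), 1)
  expect_equal(unname(frequency_domain_features(sp, "ACC")["dominant_frequency"]), 2)
})

test_that("feature matrix has 75 named columns in window order", {
  rec <- make_test_record(
    data.frame(start_s = 0, end_s = 28, activity = "walking"))
  # make channels non-trivial
  set.seed(5)
  for (nm in names(rec$channels)) {
    n <- length(rec$channels[[nm]]$samples)
    rec$channels[[nm]]$samples <- rnorm(n)
  }
  ws <- extract_windows(rec, 7)
  fm <- build_feature_matrix(ws)
  fcols <- setdiff(colnames(fm), c("window_id", "activity"))
  expect_length(fcols, 75)
  expect_false(any(duplicated(fcols)))
  expect_equal(nrow(fm), 4)
  expect_equal(fm$window_id, 1:4)
  # grammar holds for every column
  for (cc in fcols) expect_silent(parse_feature_column(cc))
  # composition spot-check
  w2 <- ws$windows[[2]]
  expect_identical(fm[2, "ECG.time.std"],
                   unname(time_domain_features(w2$blocks$ECG)["std"]))
  expect_identical(
    fm[3, "ACC-Y.freq.dc_component"],
    unname(frequency_domain_features(
      amplitude_spectrum(ws$windows[[3]]$blocks$`ACC-Y`, 64),
      "ACC")["dc_component"]))
  # spectral peak conventions per signal: ACC columns carry second_max,
  # bio columns carry max
  expect_true("ACC-X.freq.second_max" %in% fcols)
  expect_true("ECG.freq.max" %in% fcols)
  expect_false("ECG.freq.second_max" %in% fcols)
})

test_that("window order statistics and spectra satisfy basic invariants", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(16:300, 1))
    tf <- time_domain_features(x)
    expect_gte(tf[["max"]], tf[["median"]])
    expect_gte(tf[["median"]], tf[["min"]])
    expect_gte(tf[["std"]], 0)
    sp <- amplitude_spectrum(x, 64)
    expect_true(all(sp$amplitudes >= 0))
    expect_true(all(diff(sp$frequencies_hz) > 0))
  }
})

test_that("gravity makes the ACC DC bin dominate simulated windows", {
  rec <- upsample_record(simulate_subject(
    subject_params("S1"), default_protocol(14), seed = 3))
  ws <- extract_windows(rec, 7)
  for (w in ws$windows) {
    # the axis carrying most of the 1 g gravity must be DC-dominant
    mags <- vapply(c("ACC-X", "ACC-Y", "ACC-Z"), function(nm) {
      sp <- amplitude_spectrum(w$blocks[[nm]], 64)
      sp$amplitudes[1] - max(sp$amplitudes[-1])
    }, 0)
    expect_gt(max(mags), 0)
  }
})

test_that("feature extraction is independent of window order", {
  rec <- make_test_record(
    data.frame(start_s = 0, end_s = 21, activity = "walking"))
  set.seed(11)
  for (nm in names(rec$channels)) {
    rec$channels[[nm]]$samples <-
      rnorm(length(rec$channels[[nm]]$samples))
  }
  ws <- extract_windows(rec, 7)
  fm <- build_feature_matrix(ws)
  perm <- c(3, 1, 2)
  ws2 <- ws
  ws2$windows <- ws$windows[perm]
  fm2 <- build_feature_matrix(ws2)
  fcols <- setdiff(colnames(fm), c("window_id", "activity"))
  expect_equal(unname(as.matrix(fm2[, fcols])),
               unname(as.matrix(fm[perm, fcols, drop = FALSE])))
})
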
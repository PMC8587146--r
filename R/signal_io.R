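# Lossless serialisation of doubles: 17 significant digits round-trip
# IEEE-754 binary64 exactly through decimal text.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a subject recording as a directory of delimited text files
#'
#' One CSV per channel (`ACC-X.csv`, ..., `ECG.csv`; columns `name`,
#' `rate_hz` on the first data row, then one sample value per row under a
#' `sample` header in a second file section would be ambiguous, so the
#' layout is: a one-row header table `name,rate_hz` followed by the sample
#' values, one per line) and a `labels.csv` with rows
#' `start_s,end_s,activity`.  Values are serialised losslessly, so
#' `read_subject(write_subject(r))` reproduces `r` exactly.
#'
#' @param record a `subject_record`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_subject <- function(record, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(record$channels)) {
    ch <- record$channels[[nm]]
    f <- file.path(path, paste0(nm, ".csv"))
    con <- file(f, "w")
    writeLines(c("name,rate_hz", paste(ch$name, fmt_num(ch$rate_hz), sep = ","),
                 "sample", fmt_num(ch$samples)), con)
    close(con)
  }
  lab <- record$labels
  lines <- c("start_s,end_s,activity",
             paste(fmt_num(lab$start_s), fmt_num(lab$end_s), lab$activity,
                   sep = ","))
  writeLines(lines, file.path(path, "labels.csv"))
  writeLines(record$subject_id, file.path(path, "subject_id.txt"))
  invisible(path)
}

read_channel_file <- function(f) {
  lines <- readLines(f)
  if (length(lines) < 4 || lines[1] != "name,rate_hz" || lines[3] != "sample") {
    stop("malformed channel file: ", f)
  }
  hdr <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  samples <- as.numeric(lines[-(1:3)])
  if (anyNA(samples)) stop("non-numeric sample value in ", f)
  list(name = hdr[1], rate_hz = as.numeric(hdr[2]), samples = samples)
}

#' @rdname write_subject
#' @return `read_subject` returns the reconstructed `subject_record`;
#'   it validates the channel inventory (the five expected names with
#'   their admissible rates) and the label track (numeric, ordered,
#'   non-overlapping intervals) and fails loudly otherwise.
#' @export
read_subject <- function(path) {
  channels <- list()
  for (nm in CHANNEL_NAMES) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing channel file: ", nm)
    ch <- read_channel_file(f)
    if (ch$name != nm) stop("channel file ", f, " declares name ", ch$name)
    if (!(ch$rate_hz %in% CHANNEL_RATES_OK[[nm]])) {
      stop("channel ", nm, " has unexpected rate ", ch$rate_hz, " Hz")
    }
    channels[[nm]] <- ch
  }
  lf <- file.path(path, "labels.csv")
  if (!file.exists(lf)) stop("missing labels file: labels.csv")
  lines <- readLines(lf)
  if (length(lines) < 1 || lines[1] != "start_s,end_s,activity") {
    stop("malformed labels file: bad header")
  }
  n <- length(lines) - 1
  labels <- data.frame(start_s = numeric(n), end_s = numeric(n),
                       activity = character(n))
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1], ",", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("malformed labels row ", i + 1)
    s <- suppressWarnings(as.numeric(parts[1]))
    e <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(s) || is.na(e) || s >= e) {
      stop("malformed labels row ", i + 1, ": bad interval")
    }
    labels[i, ] <- list(s, e, parts[3])
  }
  if (n > 1) {
    bad <- which(labels$start_s[-1] < labels$end_s[-n])
    if (length(bad) > 0) {
      stop("overlapping label intervals at rows ",
           paste(bad + 1, bad + 2, sep = "-", collapse = ", "))
    }
  }
  sid_f <- file.path(path, "subject_id.txt")
  sid <- if (file.exists(sid_f)) readLines(sid_f)[1] else basename(path)
  structure(list(subject_id = sid, channels = channels, labels = labels),
            class = "subject_record")
}

#' Parse a feature column name
#'
#' Validates the `{signal}.{time|freq}.{feature}` grammar.
#'
#' @param name column name, e.g. `"ACC-Y.freq.median"`.
#' @return list with `signal`, `domain` (`"time"` or `"freq"`) and
#'   `feature`; errors on any name outside the grammar.
#' @export
parse_feature_column <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3 || !(parts[1] %in% CHANNEL_NAMES) ||
      !(parts[2] %in% c("time", "freq")) || !grepl("^[a-z_]+$", parts[3])) {
    stop("invalid feature column name: ", name)
  }
  list(signal = parts[1], domain = parts[2], feature = parts[3])
}

#' Write / read a feature matrix as CSV
#'
#' First column `window_id`, second `activity` (preceded by `subject_id`
#' when present), then the named feature columns.  Numeric values are
#' serialised losslessly; `read_feature_matrix` validates every feature
#' column name against the `{signal}.{time|freq}.{feature}` grammar.
#'
#' @param fm a `feature_matrix` data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  fcols <- feature_cols(fm)
  lapply(fcols, parse_feature_column)
  meta <- intersect(c("subject_id", "window_id", "activity"), colnames(fm))
  hdr <- paste(c(meta, fcols), collapse = ",")
  rows <- vapply(seq_len(nrow(fm)), function(i) {
    vals <- c(vapply(meta, function(m) as.character(fm[i, m]), ""),
              fmt_num(as.numeric(fm[i, fcols])))
    paste(vals, collapse = ",")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- intersect(c("subject_id", "window_id", "activity"), colnames(df))
  if (!all(c("window_id", "activity") %in% meta)) {
    stop("feature matrix must have window_id and activity columns")
  }
  fcols <- setdiff(colnames(df), meta)
  lapply(fcols, parse_feature_column)
  for (cc in fcols) df[[cc]] <- as.numeric(df[[cc]])
  class(df) <- c("feature_matrix", "data.frame")
  df
}

#' Serialise evaluation results to JSON
#'
#' Writes per-subject evaluation results (weighted F1/AUC, per-activity
#' F1, confusion matrices, CV fold scores) plus the cohort means as a
#' structured JSON document.
#'
#' @param results result list from [subject_specific_eval()] /
#'   [loso_eval()] (or a list of them).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_results <- function(results, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x$detail <- NULL
      lapply(x, strip)
    } else if (is.matrix(x)) {
      list(labels = rownames(x), counts = unname(apply(x, 1, as.list)))
    } else x
  }
  jsonlite::write_json(strip(results), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a labeled confusion matrix as CSV
#'
#' @param confusion square count matrix (true labels as rows).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(confusion, path) {
  write.csv(as.data.frame.matrix(confusion), path)
  invisible(path)
}
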
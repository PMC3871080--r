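#' @importFrom stats rnorm runif rpois quantile sd fft predict
#' @importFrom utils read.csv write.csv modifyList
NULL

# closed activity vocabularies: fine labels as annotated, coarse classes as
# classified (walking and running speeds merged)
.FINE_LABELS <- c("clean", "computer", "throw",
                  "walk_2.0", "walk_3.5", "run_5.5", "run_7.5", "vacuum")
.COARSE_LABELS <- c("clean", "computer", "throw", "walk", "run", "vacuum")

#' Activity label vocabularies
#'
#' @param type `"fine"` for the annotated labels (walk/run split by speed),
#'   `"coarse"` for the six classification classes.
#' @return Character vector of labels.
#' @export
activity_labels <- function(type = c("coarse", "fine")) {
  switch(match.arg(type), coarse = .COARSE_LABELS, fine = .FINE_LABELS)
}

#' Map a fine activity label to its coarse class
#'
#' Walking speeds map to `"walk"`, running speeds to `"run"`; other labels
#' (including shaker trial tags) pass through unchanged.
#'
#' @param label character vector of fine labels.
#' @return Character vector of coarse labels.
#' @export
coarse_label <- function(label) {
  out <- label
  out[label %in% c("walk_2.0", "walk_3.5")] <- "walk"
  out[label %in% c("run_5.5", "run_7.5")] <- "run"
  out
}

empty_annotations <- function() {
  data.frame(subject = character(0), label = character(0),
             start_s = numeric(0), end_s = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a triaxial acceleration recording
#'
#' A recording is a uniformly sampled triaxial acceleration series in g units,
#' stamped with the device that produced it and optionally annotated with
#' activity bouts (`subject`, `label`, `start_s`, `end_s`; times in seconds
#' relative to the start of the recording, half-open `[start_s, end_s)`).
#'
#' @param x,y,z numeric vectors of equal length, acceleration in g.
#' @param fs sampling rate in Hz (> 0).
#' @param device_id device label.
#' @param start_time time offset of the first sample, seconds.
#' @param annotations data frame with columns `subject`, `label`, `start_s`,
#'   `end_s`, or `NULL` for none.
#' @return An object of class `"acc_recording"`.
#' @export
recording <- function(x, y, z, fs, device_id = "device", start_time = 0,
                      annotations = NULL) {
  if (length(x) < 1 || length(x) != length(y) || length(x) != length(z))
    stop("x, y, z must have identical length >= 1")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("acceleration samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive sampling rate in Hz")
  if (is.null(annotations)) annotations <- empty_annotations()
  need <- c("subject", "label", "start_s", "end_s")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns subject, label, start_s, end_s")
  dur <- length(x) / fs
  if (nrow(annotations) > 0) {
    bad <- annotations$start_s < 0 | annotations$start_s >= annotations$end_s |
      annotations$end_s > dur + 1e-9
    if (any(bad))
      stop("bout annotations must satisfy 0 <= start_s < end_s <= duration")
  }
  structure(list(device_id = device_id, fs = fs, start_time = start_time,
                 x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 annotations = annotations),
            class = "acc_recording")
}

#' @export
print.acc_recording <- function(x, ...) {
  cat(sprintf("<acc_recording> device=%s  fs=%g Hz  n=%d (%.1f s)  bouts=%d\n",
              x$device_id, x$fs, length(x$x), length(x$x) / x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `acc_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$x) / rec$fs

annotation_path <- function(path) sub("\\.csv$", "_bouts.csv", path)

#' Read a recording from CSV
#'
#' The signal file is a CSV with header `x,y,z` (optionally `t,x,y,z`), one
#' sample per row, acceleration in g. If a sidecar annotation file exists at
#' the same path with `.csv` replaced by `_bouts.csv` (columns
#' `subject,label,start_s,end_s`), its bouts are merged into the recording.
#'
#' @param path signal CSV path.
#' @param fs sampling rate in Hz (not stored in the CSV).
#' @param device_id device label to stamp on the recording.
#' @return An `acc_recording`.
#' @export
read_recording <- function(path, fs, device_id = "device") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty signal file: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  nm <- names(raw)
  if (!identical(nm, c("x", "y", "z")) && !identical(nm, c("t", "x", "y", "z")))
    stop("signal CSV header must be x,y,z or t,x,y,z (got: ",
         paste(nm, collapse = ","), ")")
  if (nrow(raw) == 0) stop("empty signal file (no data rows): ", path)
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]))
    if (length(bad) > 0)
      stop(sprintf("malformed value '%s' in column '%s' at line %d of %s",
                   raw[[j]][bad[1]], nm[j], bad[1] + 1L, path))
  }
  if ("t" %in% nm && nrow(raw) > 1 && any(diff(num$t) <= 0))
    stop("t column must be strictly increasing in ", path)
  ann <- NULL
  apath <- annotation_path(path)
  if (!identical(apath, path) && file.exists(apath)) {
    ann <- read.csv(apath, stringsAsFactors = FALSE)
  }
  recording(num$x, num$y, num$z, fs = fs, device_id = device_id,
            annotations = ann)
}

#' Write a recording (and its annotations) to CSV
#'
#' Writes the `x,y,z` signal CSV; if the recording carries bout annotations
#' they are written to the `_bouts.csv` sidecar.
#'
#' @param rec an `acc_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(x = rec$x, y = rec$y, z = rec$z)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (nrow(rec$annotations) > 0)
    write.csv(rec$annotations, annotation_path(path),
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-sample triaxial vector magnitude
#'
#' Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three axes at every sample,
#' in g. For a stationary device this is 1 g (gravity); for an ideal orbital
#' shaker trial it is the constant `sqrt(A^2 + 1)` where `A` is the
#' centripetal acceleration.
#'
#' @param rec an `acc_recording`.
#' @return Numeric vector, same length as the recording.
#' @export
vector_magnitude <- function(rec) {
  sqrt(rec$x^2 + rec$y^2 + rec$z^2)
}

#' Cut annotated bouts into fixed, non-overlapping analysis windows
#'
#' Per bout, exactly `floor(use_last_s / window_s)` contiguous non-overlapping
#' windows are taken from the final `use_last_s` seconds of the bout (the
#' early part of each bout is treated as a settling period and discarded).
#' When `window_s` does not divide `use_last_s` the trailing remainder is
#' discarded. Windows inherit the subject, device and coarse activity class
#' (walking and running speeds merged).
#'
#' @param rec an annotated `acc_recording`.
#' @param window_s window length, seconds (default 20).
#' @param use_last_s portion at the end of each bout to window (default 60).
#' @return List of `"acc_window"` objects, each holding per-axis samples, the
#'   vector-magnitude channel, and subject/activity/device metadata.
#' @export
make_windows <- function(rec, window_s = 20, use_last_s = 60) {
  ann <- rec$annotations
  if (nrow(ann) == 0) stop("recording has no bout annotations")
  n_win <- floor(use_last_s / window_s)
  if (n_win < 1) stop("window_s exceeds use_last_s; no windows possible")
  wlen <- round(window_s * rec$fs)
  n <- length(rec$x)
  out <- vector("list", nrow(ann) * n_win)
  k <- 0
  for (i in seq_len(nrow(ann))) {
    b <- ann[i, ]
    if (b$end_s - b$start_s < use_last_s - 1e-9)
      stop(sprintf(
        "bout '%s' (subject %s) lasts %.1f s, shorter than use_last_s = %g s",
        b$label, b$subject, b$end_s - b$start_s, use_last_s))
    region0 <- b$end_s - use_last_s
    for (w in seq_len(n_win)) {
      t0 <- region0 + (w - 1) * window_s
      i0 <- round((t0 - rec$start_time) * rec$fs)
      idx <- seq.int(i0 + 1L, length.out = wlen)
      if (idx[wlen] > n)
        stop(sprintf("bout '%s' extends past the end of the recording",
                     b$label))
      k <- k + 1
      xs <- rec$x[idx]; ys <- rec$y[idx]; zs <- rec$z[idx]
      out[[k]] <- structure(
        list(x = xs, y = ys, z = zs, vm = sqrt(xs^2 + ys^2 + zs^2),
             subject_id = b$subject, activity = coarse_label(b$label),
             fine_label = b$label, device_id = rec$device_id,
             window_index = w, fs = rec$fs),
        class = "acc_window")
    }
  }
  out
}
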
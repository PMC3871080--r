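#' Time-domain features of a signal window
#'
#' The eight TD descriptors: mean, sample standard deviation (n-1
#' denominator), the 10th/25th/50th/75th/90th empirical percentiles (linear
#' interpolation) and the lag-1 autocorrelation
#' `r1 = sum((x_t - xbar)(x_{t+1} - xbar)) / sum((x_t - xbar)^2)`.
#' All of these except `lag1_autocorr` are expressed in g and therefore scale
#' one-for-one with a device gain; `lag1_autocorr` is scale-free. For a
#' constant window the autocorrelation is defined as 0 by convention.
#'
#' @param signal numeric window (length >= 2), g.
#' @return One-row data frame: `mean, sd, p10, p25, p50, p75, p90,
#'   lag1_autocorr`.
#' @export
td_features <- function(signal) {
  n <- length(signal)
  if (n < 2) stop("need at least 2 samples")
  if (!all(is.finite(signal))) stop("signal must be finite")
  q <- quantile(signal, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  xc <- signal - mean(signal)
  den <- sum(xc^2)
  lag1 <- if (den <= 0) 0 else sum(xc[-n] * xc[-1]) / den
  data.frame(mean = mean(signal), sd = sd(signal),
             p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
             lag1_autocorr = lag1)
}

#' One-sided periodogram with a variance (Parseval) normalization
#'
#' Plain periodogram of the demeaned signal, no taper, normalized so that the
#' sum of the spectral power equals the biased sample variance
#' `mean((x - xbar)^2)` exactly. Frequency resolution is `fs / n` (0.05 Hz
#' for a 20-s window at 80 Hz).
#'
#' @param signal numeric window (length >= 16).
#' @param fs sampling rate, Hz.
#' @return Data frame with `freq` (Hz, from 0 to fs/2) and `power` (g²).
#' @export
power_spectrum <- function(signal, fs) {
  n <- length(signal)
  if (n < 16) stop("need at least 16 samples")
  if (!all(is.finite(signal))) stop("signal must be finite")
  xd <- signal - mean(signal)
  pw <- Mod(fft(xd))^2 / n^2
  half <- floor(n / 2)
  power <- pw[seq_len(half + 1)]
  if (n %% 2 == 0) {
    if (half > 1) power[2:half] <- 2 * power[2:half]  # Nyquist bin is unique
  } else {
    power[2:(half + 1)] <- 2 * power[2:(half + 1)]
  }
  data.frame(freq = (0:half) * fs / n, power = power)
}

#' Frequency-domain features of a signal window
#'
#' The seven FD descriptors: mean acceleration of the raw (not demeaned)
#' window; total spectral power; dominant frequency (maximum periodogram bin,
#' ties broken toward the lower frequency); power in the locomotor band
#' (default 0.6-2.5 Hz, both edges inclusive); that band power divided by
#' total power; and the cumulative-spectral-power percentiles `f10`/`f90`
#' (the lowest frequency at which cumulative power reaches 10% / 90% of the
#' total). Apart from `mean_acc` (scales with gain) and `total_power`/
#' `band_power` (scale with gain squared), these descriptors characterise the
#' shape of the spectrum and are invariant under a uniform device gain.
#'
#' For a constant window (zero total power) the frequency descriptors and
#' `band_ratio` are defined as 0.
#'
#' @param signal numeric window (length >= 16), g.
#' @param fs sampling rate, Hz.
#' @param band locomotor band `(low, high)` in Hz, inside `(0, fs/2)`.
#' @return One-row data frame: `mean_acc, total_power, dom_freq, band_power,
#'   band_ratio, f10, f90`.
#' @export
fd_features <- function(signal, fs, band = c(0.6, 2.5)) {
  if (length(band) != 2 || band[1] >= band[2])
    stop("band must be (low, high) with low < high")
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie inside (0, fs/2)")
  sp <- power_spectrum(signal, fs)
  total <- sum(sp$power)
  if (total <= 0) {
    return(data.frame(mean_acc = mean(signal), total_power = 0, dom_freq = 0,
                      band_power = 0, band_ratio = 0, f10 = 0, f90 = 0))
  }
  dom <- sp$freq[which.max(sp$power)]
  inband <- sp$freq >= band[1] & sp$freq <= band[2]
  bp <- sum(sp$power[inband])
  cum <- cumsum(sp$power)
  f10 <- sp$freq[which(cum >= 0.10 * total)[1]]
  f90 <- sp$freq[which(cum >= 0.90 * total)[1]]
  data.frame(mean_acc = mean(signal), total_power = total, dom_freq = dom,
             band_power = bp, band_ratio = bp / total, f10 = f10, f90 = f90)
}

.META_COLS <- c("subject_id", "device_id", "activity", "fine_label",
                "window_index")

#' Extract a feature table from a list of windows
#'
#' One row per window, computed on the requested channel (the vector
#' magnitude by default; per-axis extraction is available but not the
#' default). Rows are sorted deterministically by (subject, activity, window
#' index). The returned data frame carries a `feature_set` attribute
#' (`"TD"` or `"FD"`) consumed by the transfer-evaluation stage.
#'
#' @param windows list of `acc_window`s of a single homogeneous length.
#' @param feature_set `"TD"` or `"FD"`.
#' @param channel `"vm"` (default) or one of `"x"`, `"y"`, `"z"`.
#' @param band locomotor band for FD features.
#' @return Data frame with metadata columns (`subject_id`, `device_id`,
#'   `activity`, `fine_label`, `window_index`) followed by feature columns.
#' @export
extract_table <- function(windows, feature_set = c("TD", "FD"),
                          channel = "vm", band = c(0.6, 2.5)) {
  feature_set <- match.arg(feature_set)
  channel <- match.arg(channel, c("vm", "x", "y", "z"))
  if (length(windows) == 0) {
    out <- data.frame(subject_id = character(0), device_id = character(0),
                      activity = character(0), fine_label = character(0),
                      window_index = integer(0))
    attr(out, "feature_set") <- feature_set
    return(out)
  }
  lens <- vapply(windows, function(w) length(w[[channel]]), integer(1))
  if (length(unique(lens)) != 1)
    stop("windows have mixed lengths: ",
         paste(unique(lens), collapse = ", "))
  rows <- lapply(windows, function(w) {
    feats <- if (feature_set == "TD") td_features(w[[channel]])
             else fd_features(w[[channel]], w$fs, band = band)
    cbind(data.frame(subject_id = w$subject_id, device_id = w$device_id,
                     activity = w$activity, fine_label = w$fine_label,
                     window_index = w$window_index,
                     stringsAsFactors = FALSE),
          feats)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$activity, out$fine_label,
                   out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_set") <- feature_set
  out
}

feature_cols <- function(tbl) setdiff(names(tbl), .META_COLS)
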
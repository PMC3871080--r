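#' Centripetal acceleration of orbital motion, in g
#'
#' Closed form `a = omega^2 * r` for a point in uniform circular motion, with
#' `omega = 2*pi*rpm/60`, expressed in g units. The conversion constant is
#' fixed at 9.81 m/s² by default, which reproduces the published shaker
#' calibration column {0.091, 0.363, 1.113, 2.272, 3.271} g at
#' rpm {40, 80, 140, 200, 240} and r = 5.08 cm to three decimals.
#'
#' @param rpm platform revolutions per minute (vectorised; >= 0).
#' @param radius_m orbit radius in metres (> 0).
#' @param g_ms2 standard gravity used for the g conversion.
#' @return Centripetal acceleration in g.
#' @export
#' @examples
#' round(centripetal_acceleration(c(40, 80, 140, 200, 240)), 3)
centripetal_acceleration <- function(rpm, radius_m = 0.0508, g_ms2 = 9.81) {
  if (any(rpm < 0)) stop("rpm must be >= 0")
  if (any(radius_m <= 0)) stop("radius_m must be > 0")
  (2 * pi * rpm / 60)^2 * radius_m / g_ms2
}

#' Mean vector magnitude of one device over a trial's analysis window
#'
#' Arithmetic mean of the triaxial vector magnitude over the trial's analysis
#' window only (by default the second minute of a 2-min trial; the first
#' minute is treated as settling time).
#'
#' @param trial a `shaker_trial`.
#' @param device_id which device's recording to analyse.
#' @return Mean VM in g.
#' @export
trial_mean_vm <- function(trial, device_id) {
  rec <- trial$recordings[[device_id]]
  if (is.null(rec))
    stop("device '", device_id, "' absent from trial")
  idx <- window_index(rec, trial$analysis_window)
  mean(vector_magnitude(rec)[idx])
}

window_index <- function(rec, win) {
  fs <- rec$fs
  seq.int(floor(win[1] * fs) + 1L, floor(win[2] * fs))
}

#' Mean per-revolution peak acceleration of a single axis
#'
#' During orbital shaking each in-plane axis crosses 0 g twice per revolution,
#' giving two acceleration peaks (one each side of baseline) per revolution.
#' The window is partitioned into half-revolution segments of
#' `60 / (2 * rpm)` seconds; within each segment the peak is the sampled
#' maximum of `|series|`, refined by parabolic interpolation over the three
#' samples around it (the standard correction for the amplitude a uniform
#' sampling grid misses between samples); the mean over segments is returned
#' together with the segment (peak) count. Segment-max extraction is robust
#' to sensor noise, unlike zero-crossing detection.
#'
#' @param series one axis of acceleration over the analysis window, g.
#' @param rpm platform speed (> 0).
#' @param fs sampling rate, Hz.
#' @return List with `mean_peak` (g) and `n_peaks`.
#' @export
mean_peak_acceleration <- function(series, rpm, fs) {
  if (rpm <= 0) stop("rpm must be > 0 for peak extraction")
  half_T <- 60 / (2 * rpm)
  dur <- length(series) / fs
  n_seg <- floor(dur / half_T)
  if (n_seg < 4) stop("window covers fewer than 4 half-revolutions")
  t <- (seq_along(series) - 1) / fs
  seg <- floor(t / half_T)
  a <- abs(series)
  n <- length(a)
  peaks <- vapply(seq_len(n_seg) - 1, function(s) {
    idx <- which(seg == s)
    i <- idx[which.max(a[idx])]
    peak_refine(a, i, n)
  }, numeric(1))
  list(mean_peak = mean(peaks), n_peaks = n_seg)
}

# parabolic vertex through (a[i-1], a[i], a[i+1]); falls back to the sampled
# maximum at series edges or where the three points are not concave
peak_refine <- function(a, i, n) {
  if (i <= 1 || i >= n) return(a[i])
  y1 <- a[i - 1]; y2 <- a[i]; y3 <- a[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(y2)
  delta <- 0.5 * (y1 - y3) / den
  if (abs(delta) > 1) return(y2)
  y2 - 0.25 * (y1 - y3) * delta
}

#' Compare two devices over repeated shaker trials at one speed
#'
#' Computes trial-level mean vector magnitudes for each device, the percent
#' difference of device B relative to device A (the reference denominator),
#' mean per-revolution peak acceleration on the first in-plane axis, the
#' centripetal-acceleration oracle, and a two-sided trial-label permutation
#' test on the difference of trial means. The permutation test treats the
#' trial as the exchangeable unit.
#'
#' @param trials list of `shaker_trial`s, all at the same rpm.
#' @param device_a,device_b device ids; `device_a` is the reference.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `"shaker_comparison"`: rpm, per-device mean VM
#'   and mean peak, `oracle_g`, `pct_difference`, `p_value`, `n_trials`.
#' @export
compare_devices <- function(trials, device_a, device_b, n_perm = 2000,
                            seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  rpms <- unique(vapply(trials, function(tr) tr$rpm, numeric(1)))
  if (length(rpms) != 1) stop("trials must all be at the same rpm")
  ma_i <- vapply(trials, trial_mean_vm, numeric(1), device_id = device_a)
  mb_i <- vapply(trials, trial_mean_vm, numeric(1), device_id = device_b)
  if (length(ma_i) < 3) stop("need >= 3 trials per device")
  ma <- mean(ma_i); mb <- mean(mb_i)
  obs <- mb - ma
  pooled <- c(ma_i, mb_i)
  nA <- length(ma_i)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pick <- sample(length(pooled), nA)
    mean(pooled[-pick]) - mean(pooled[pick])
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  peak <- function(dev_id) {
    if (rpms == 0) return(NA_real_)
    mean(vapply(trials, function(tr) {
      rec <- tr$recordings[[dev_id]]
      idx <- window_index(rec, tr$analysis_window)
      mean_peak_acceleration(rec$x[idx], rpms, rec$fs)$mean_peak
    }, numeric(1)))
  }
  mean_vm <- c(ma, mb); mean_pk <- c(peak(device_a), peak(device_b))
  names(mean_vm) <- names(mean_pk) <- c(device_a, device_b)
  structure(list(rpm = rpms, mean_vm = mean_vm, mean_peak = mean_pk,
                 oracle_g = centripetal_acceleration(rpms,
                                                     trials[[1]]$radius_m),
                 pct_difference = 100 * (mb - ma) / ma,
                 p_value = p, n_trials = length(trials)),
            class = "shaker_comparison")
}

#' Shaker comparison table across platform speeds
#'
#' Runs [compare_devices()] at every rpm present in `trials` and assembles the
#' calibration report: oracle centripetal acceleration, per-device mean VM and
#' mean per-revolution peak, percent difference (denominator = device A) and
#' permutation p-value.
#'
#' @inheritParams compare_devices
#' @return Data frame with one row per rpm.
#' @export
shaker_comparison_table <- function(trials, device_a, device_b,
                                    n_perm = 2000, seed = 1) {
  rpms <- sort(unique(vapply(trials, function(tr) tr$rpm, numeric(1))))
  rows <- lapply(rpms, function(r) {
    sub <- Filter(function(tr) tr$rpm == r, trials)
    cmp <- compare_devices(sub, device_a, device_b, n_perm = n_perm,
                           seed = child_seed(seed, "perm", r))
    data.frame(rpm = r, nominal_hz = nominal_hz(r), oracle_g = cmp$oracle_g,
               mean_vm_a = cmp$mean_vm[[device_a]],
               mean_vm_b = cmp$mean_vm[[device_b]],
               mean_peak_a = cmp$mean_peak[[device_a]],
               mean_peak_b = cmp$mean_peak[[device_b]],
               pct_difference = cmp$pct_difference,
               p_value = cmp$p_value, n_trials = cmp$n_trials)
  })
  do.call(rbind, rows)
}
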
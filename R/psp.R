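#' Measure a biphasic postsynaptic potential
#'
#' Both amplitudes are measured from the basal resting potential (the mean
#' over the baseline window): the depolarization amplitude is the maximal
#' peak inside the search window minus the baseline, and the
#' hyperpolarization amplitude is the baseline minus the trough, i.e. the
#' minimum between the peak time and the end of the search window. Both
#' amplitudes are floored at zero, so a purely monophasic potential scores
#' zero on the opposite phase.
#'
#' @param trace Numeric voltage trace, mV, uniformly sampled.
#' @param dt Sample interval, ms.
#' @param baseline_window `c(start, end)` in seconds over which the resting
#'   potential is averaged.
#' @param search_window `c(start, end)` in seconds within which the peak and
#'   trough are sought.
#' @return An object of class `psp_measure`: list with `depolarization`,
#'   `hyperpolarization` (mV, >= 0), `baseline` (mV), `peak_time`,
#'   `trough_time` (s).
#' @export
measure_psp <- function(trace, dt, baseline_window, search_window) {
  stopifnot(is.numeric(trace), dt > 0,
            length(baseline_window) == 2L, length(search_window) == 2L)
  n <- length(trace)
  t_end <- (n - 1L) * dt / 1000
  win_idx <- function(w, what) {
    if (w[1L] < 0 || w[2L] > t_end || w[1L] >= w[2L])
      stop("measure_psp(): ", what, " window out of trace range")
    i0 <- as.integer(floor(w[1L] * 1000 / dt)) + 1L
    i1 <- as.integer(ceiling(w[2L] * 1000 / dt)) + 1L
    c(max(1L, i0), min(n, i1))
  }
  b <- win_idx(baseline_window, "baseline")
  s <- win_idx(search_window, "search")
  baseline <- mean(trace[b[1L]:b[2L]])
  seg <- trace[s[1L]:s[2L]]
  ipk <- which.max(seg)
  peak <- seg[ipk]
  depol <- max(0, peak - baseline)
  after <- seg[ipk:length(seg)]
  itr <- ipk - 1L + which.min(after)
  trough <- min(after)
  hyper <- max(0, baseline - trough)
  structure(list(depolarization = depol, hyperpolarization = hyper,
                 baseline = baseline,
                 peak_time = (s[1L] + ipk - 2L) * dt / 1000,
                 trough_time = (s[1L] + itr - 2L) * dt / 1000),
            class = "psp_measure")
}

#' @export
print.psp_measure <- function(x, ...) {
  cat(sprintf("PSP: depolarization %.2f mV, hyperpolarization %.2f mV (baseline %.1f mV)\n",
              x$depolarization, x$hyperpolarization, x$baseline))
  invisible(x)
}

#' Quantify a barrage of recruited EPSPs
#'
#' Detects EPSP-like deflections with a derivative-threshold picker
#' (default 0.05 mV/ms), measures each amplitude as local peak minus the
#' preceding trough, discards events smaller than the 0.1 mV floor, and
#' restricts the analysis to the 10 s following stimulus onset. The
#' instantaneous frequency series is the reciprocal of inter-event intervals.
#'
#' @param trace Numeric voltage trace, mV.
#' @param dt Sample interval, ms.
#' @param stim_onset Stimulus onset, s.
#' @param window Analysis window length after onset, s.
#' @param min_amplitude Amplitude floor, mV.
#' @param slope_threshold Rising-slope threshold, mV/ms.
#' @return List with `times` (s), `amplitudes` (mV), and `frequency`
#'   (data frame `time`, `hz` of instantaneous frequencies).
#' @export
measure_epsp_barrage <- function(trace, dt, stim_onset, window = 10,
                                 min_amplitude = 0.1, slope_threshold = 0.05) {
  stopifnot(is.numeric(trace), dt > 0, window > 0)
  n <- length(trace)
  t_end <- (n - 1L) * dt / 1000
  if (t_end < stim_onset + window)
    stop("measure_epsp_barrage(): trace must span ", window, " s after onset")
  slope <- c(0, diff(trace)) / dt              # mV/ms
  rising <- slope >= slope_threshold
  onsets <- which(!rising[-n] & rising[-1L]) + 1L
  times <- numeric(0); amps <- numeric(0)
  look_back <- max(1L, as.integer(round(10 / dt)))   # trough search, 10 ms
  look_fwd <- max(1L, as.integer(round(50 / dt)))    # peak search, 50 ms
  for (i in onsets) {
    trough <- min(trace[max(1L, i - look_back):i])
    j_end <- min(n, i + look_fwd)
    # peak: maximum until the slope first turns negative (or window end)
    fall <- which(slope[(i + 1L):j_end] < 0)
    j_pk <- if (length(fall)) i + fall[1L] - 1L else j_end
    seg <- trace[i:max(i, j_pk)]
    pk <- i - 1L + which.max(seg)
    amp <- trace[pk] - trough
    tt <- (pk - 1L) * dt / 1000
    if (amp >= min_amplitude && tt >= stim_onset && tt <= stim_onset + window) {
      # merge detections that resolve to the same peak
      if (length(times) == 0L || tt > times[length(times)]) {
        times <- c(times, tt); amps <- c(amps, amp)
      }
    }
  }
  freq <- if (length(times) >= 2L) {
    data.frame(time = times[-1L], hz = 1 / diff(times))
  } else data.frame(time = numeric(0), hz = numeric(0))
  list(times = times, amplitudes = amps, frequency = freq)
}
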
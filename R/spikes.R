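#' Detect spikes in a sampled voltage trace
#'
#' Upward threshold crossings, one event per refractory window, aligned to
#' the local voltage peak following the crossing.
#'
#' @param trace Numeric vector of membrane potential samples (mV), uniformly
#'   sampled.
#' @param dt Sample interval in ms.
#' @param threshold Detection threshold in mV.
#' @param refractory Minimum separation between events, ms.
#' @return Numeric vector of spike times in seconds (peak-aligned).
#' @export
detect_spikes <- function(trace, dt, threshold = -10, refractory = 5) {
  if (length(trace) == 0L) stop("detect_spikes(): empty trace")
  stopifnot(is.numeric(trace), dt > 0, refractory > 0)
  if (any(!is.finite(trace))) stop("detect_spikes(): non-finite trace sample")
  above <- trace > threshold
  crossings <- which(!above[-length(above)] & above[-1L]) + 1L
  if (length(crossings) == 0L) return(numeric(0))
  ref_samp <- max(1L, as.integer(round(refractory / dt)))
  times <- numeric(0)
  last <- -Inf
  for (i in crossings) {
    if ((i - last) * dt < refractory) next
    j_end <- min(length(trace), i + ref_samp)
    pk <- i - 1L + which.max(trace[i:j_end])
    times <- c(times, pk)
    last <- pk
  }
  (times - 1L) * dt / 1000
}

#' Group spikes into bursts
#'
#' A burst is a cluster of two or more spikes with consecutive inter-spike
#' intervals strictly less than `max_isi` seconds. Spikes falling inside the
#' stimulus window are excluded first (they are evoked directly by the nerve
#' shock, not by the pattern generator) and singleton groups are discarded.
#' An interval of exactly `max_isi` splits a cluster.
#'
#' @param spike_times Sorted numeric vector of spike times, seconds.
#' @param stim_window Optional `c(start, end)` in seconds; spikes in
#'   `[start, end]` are removed before grouping.
#' @param max_isi Maximum intra-burst inter-spike interval, s.
#' @param min_spikes Minimum spikes per burst.
#' @return An object of class `burst_set`: a list with `bursts` (data frame
#'   of `start`, `end`, `n_spikes`), `n` (burst count),
#'   `excluded_stim_spikes`, and `spikes` (the grouped spike times).
#' @export
detect_bursts <- function(spike_times, stim_window = NULL, max_isi = 1,
                          min_spikes = 2L) {
  stopifnot(is.numeric(spike_times), max_isi > 0)
  if (any(!is.finite(spike_times))) stop("detect_bursts(): non-finite spike time")
  if (is.unsorted(spike_times)) stop("detect_bursts(): spike times must be sorted")
  excluded <- 0L
  if (!is.null(stim_window)) {
    stopifnot(length(stim_window) == 2L, stim_window[1L] <= stim_window[2L])
    in_stim <- spike_times >= stim_window[1L] & spike_times <= stim_window[2L]
    excluded <- sum(in_stim)
    spike_times <- spike_times[!in_stim]
  }
  groups <- list()
  if (length(spike_times) > 0L) {
    brk <- c(0L, which(diff(spike_times) >= max_isi), length(spike_times))
    for (k in seq_len(length(brk) - 1L)) {
      g <- spike_times[(brk[k] + 1L):brk[k + 1L]]
      if (length(g) >= min_spikes) groups[[length(groups) + 1L]] <- g
    }
  }
  bursts <- if (length(groups)) {
    data.frame(start = vapply(groups, min, 0),
               end = vapply(groups, max, 0),
               n_spikes = vapply(groups, length, 0L))
  } else {
    data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0))
  }
  structure(list(bursts = bursts, n = nrow(bursts),
                 excluded_stim_spikes = excluded, spikes = groups),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat("Burst set:", x$n, "burst(s);",
      x$excluded_stim_spikes, "stimulus-window spike(s) excluded\n")
  if (x$n) print(x$bursts)
  invisible(x)
}

#' Classify spike propagation direction from paired soma/nerve recordings
#'
#' Each somatic spike is greedily paired one-to-one with the nearest nerve
#' impulse within `window` ms. The lag (nerve time minus soma time) decides
#' the direction: a nerve impulse leading the soma spike by more than the
#' ambiguity band means the spike originated at the distal initiation zone
#' and travelled antidromically toward the soma; a lagging impulse means
#' orthodromic propagation away from the soma. Burst-level labels and the
#' per-animal category aggregate the spike labels.
#'
#' @param soma_times Sorted somatic spike times, seconds.
#' @param nerve_times Sorted nerve impulse times, seconds.
#' @param window Pairing window, ms (one-sided).
#' @param ambiguity Half-width of the ambiguous lag band, ms.
#' @param bursts Optional `burst_set` for the soma spikes; computed with
#'   default settings when omitted.
#' @return An object of class `propagation_label`: list with `spikes`
#'   (data frame: `time`, `lag_ms`, `label`), `bursts` (data frame:
#'   `start`, `end`, `label`), and `animal` (one of `"antidromic-only"`,
#'   `"mixed"`, `"orthodromic-only"`, or `NA` if nothing was classifiable).
#' @export
match_and_classify <- function(soma_times, nerve_times, window = 50,
                               ambiguity = 0.5, bursts = NULL) {
  if (window <= 0) stop("match_and_classify(): window must be > 0")
  stopifnot(is.numeric(soma_times), is.numeric(nerve_times))
  if (is.unsorted(soma_times) || is.unsorted(nerve_times))
    stop("match_and_classify(): event lists must be sorted")
  ns <- length(soma_times); nn <- length(nerve_times)
  lag_ms <- rep(NA_real_, ns)
  if (ns > 0L && nn > 0L) {
    # enumerate candidate pairs within the window, assign greedily by |lag|
    cand <- NULL
    for (i in seq_len(ns)) {
      lags <- (nerve_times - soma_times[i]) * 1000
      ok <- which(abs(lags) <= window)
      if (length(ok))
        cand <- rbind(cand, cbind(i = i, j = ok, lag = lags[ok]))
    }
    if (!is.null(cand)) {
      cand <- cand[order(abs(cand[, "lag"])), , drop = FALSE]
      used_s <- logical(ns); used_n <- logical(nn)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, "i"]; j <- cand[r, "j"]
        if (!used_s[i] && !used_n[j]) {
          used_s[i] <- TRUE; used_n[j] <- TRUE
          lag_ms[i] <- cand[r, "lag"]
        }
      }
    }
  }
  label <- ifelse(is.na(lag_ms), "unmatched",
                  ifelse(lag_ms < -ambiguity, "antidromic",
                         ifelse(lag_ms > ambiguity, "orthodromic", "unmatched")))
  spikes <- data.frame(time = soma_times, lag_ms = lag_ms, label = label,
                       stringsAsFactors = FALSE)
  if (is.null(bursts)) bursts <- detect_bursts(soma_times)
  stopifnot(inherits(bursts, "burst_set"))
  blab <- character(0)
  if (bursts$n > 0L) {
    blab <- vapply(seq_len(bursts$n), function(k) {
      sel <- soma_times >= bursts$bursts$start[k] &
        soma_times <= bursts$bursts$end[k]
      lb <- label[sel]
      lb <- lb[lb != "unmatched"]   # ambiguous spikes excluded from burst labels
      if (length(lb) == 0L) return(NA_character_)
      if (all(lb == "antidromic")) "antidromic"
      else if (all(lb == "orthodromic")) "orthodromic"
      else "mixed"
    }, "")
  }
  bl <- blab[!is.na(blab)]
  animal <- if (length(bl) == 0L) NA_character_
  else if (all(bl == "antidromic")) "antidromic-only"
  else if (all(bl == "orthodromic")) "orthodromic-only"
  else "mixed"
  structure(list(
    spikes = spikes,
    bursts = cbind(bursts$bursts, label = c(blab, character(0))),
    animal = animal), class = "propagation_label")
}

#' @export
print.propagation_label <- function(x, ...) {
  cat("Propagation:", x$animal, "—",
      sum(x$spikes$label == "antidromic"), "antidromic,",
      sum(x$spikes$label == "orthodromic"), "orthodromic,",
      sum(x$spikes$label == "unmatched"), "unmatched spike(s)\n")
  invisible(x)
}

#' Classify an extracellular nerve impulse waveform
#'
#' A propagating axonal impulse recorded en passant is triphasic (two
#' downward phases flanking a positive deflection); an impulse that enters
#' the recording pipette but is blocked inside it is biphasic (a downward
#' deflection followed by an upward one). The classifier extracts the sign
#' sequence of prominent extrema and maps (-,+,-) to triphasic and (-,+) to
#' biphasic; anything else is unknown.
#'
#' @param snippet Numeric vector centred on the impulse (>= 5 ms of context).
#' @param dt Sample interval, ms.
#' @param prominence Minimum extremum magnitude as a fraction of the largest
#'   absolute deflection.
#' @return One of `"triphasic"`, `"biphasic"`, `"unknown"`.
#' @export
classify_impulse_waveform <- function(snippet, dt, prominence = 0.3) {
  stopifnot(is.numeric(snippet), dt > 0)
  if (length(snippet) * dt < 5) stop("classify_impulse_waveform(): need >= 5 ms context")
  z <- snippet - stats::median(snippet)
  amp <- max(abs(z))
  if (amp == 0) return("unknown")
  d <- diff(z)
  # local extrema: sign changes of the first difference
  s <- sign(d)
  s[s == 0] <- 1
  idx <- which(diff(s) != 0) + 1L
  if (length(idx) == 0L) return("unknown")
  keep <- idx[abs(z[idx]) >= prominence * amp]
  if (length(keep) == 0L) return("unknown")
  signs <- sign(z[keep])
  # collapse runs of the same sign
  pat <- signs[c(TRUE, diff(signs) != 0)]
  if (identical(pat, c(-1, 1, -1))) "triphasic"
  else if (identical(pat, c(-1, 1))) "biphasic"
  else "unknown"
}
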
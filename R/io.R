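#' Extracellular nerve impulse templates
#'
#' A propagating axonal impulse recorded en passant is triphasic: two
#' downward phases with a positive deflection between them. An impulse that
#' enters the suction pipette but is blocked inside it is biphasic: a
#' downward deflection followed by an upward one.
#'
#' @param kind `"triphasic"` or `"biphasic"`.
#' @param dt Sample interval, ms.
#' @param amp Peak magnitude, arbitrary units (uV-scale).
#' @param width Half-width of the template support, ms.
#' @return Numeric vector of template samples (odd length, centred).
#' @export
nerve_impulse_template <- function(kind = c("triphasic", "biphasic"),
                                   dt = 0.25, amp = 20, width = 3) {
  kind <- match.arg(kind)
  tt <- seq(-width, width, by = dt)
  g <- function(mu, sd) exp(-((tt - mu) / sd)^2)
  w <- if (kind == "triphasic") {
    -g(-0.8, 0.4) + 1.2 * g(0, 0.4) - g(0.8, 0.4)
  } else {
    -g(-0.5, 0.45) + 0.8 * g(0.6, 0.7)
  }
  amp * w / max(abs(w))
}

#' Render an extracellular nerve trace from impulse times
#'
#' @param n Number of samples.
#' @param dt Sample interval, ms.
#' @param impulse_times Impulse times, s.
#' @param kind Waveform kind, see [nerve_impulse_template()].
#' @param amp Impulse amplitude.
#' @param noise_sd Additive white-noise SD.
#' @return Numeric vector of length `n`.
#' @export
render_nerve_trace <- function(n, dt, impulse_times,
                               kind = c("triphasic", "biphasic"),
                               amp = 20, noise_sd = 0) {
  kind <- match.arg(kind)
  tr <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  if (length(impulse_times) == 0L) return(tr)
  tpl <- nerve_impulse_template(kind, dt = dt, amp = amp)
  half <- (length(tpl) - 1L) %/% 2L
  for (ts in impulse_times) {
    ic <- as.integer(round(ts * 1000 / dt)) + 1L
    i0 <- ic - half; i1 <- ic + half
    j0 <- max(1L, i0); j1 <- min(n, i1)
    if (j0 > j1) next
    tr[j0:j1] <- tr[j0:j1] + tpl[(j0 - i0 + 1L):(j1 - i0 + 1L)]
  }
  tr
}

#' Write / read delimited-text trace files
#'
#' Traces are stored as tab-separated text: column 1 is time in seconds, the
#' remaining columns are named channels (header row). `write_episode()` also
#' writes a JSON sidecar with the event times and condition tags.
#'
#' @param channels Data frame whose first column is `time` (s).
#' @param file Path of the trace file.
#' @return `read_trace()` returns the data frame; writers return the path,
#'   invisibly.
#' @export
write_trace <- function(channels, file) {
  stopifnot(is.data.frame(channels), names(channels)[1L] == "time")
  utils::write.table(channels, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  if (names(df)[1L] != "time") stop("read_trace(): first column must be 'time'")
  df
}

#' @rdname write_trace
#' @param rec An `episode_recording` (traces must have been kept).
#' @param stem Output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @export
write_episode <- function(rec, stem) {
  stopifnot(inherits(rec, "episode_recording"))
  if (is.null(rec$channels))
    stop("write_episode(): episode was simulated without keep_traces")
  write_trace(rec$channels, paste0(stem, ".tsv"))
  meta <- list(dt_ms = rec$dt, duration_s = rec$duration,
               spike_times = rec$spike_times,
               soma_events = rec$soma_events,
               nerve_impulse_times = rec$nerve_impulse_times,
               stim_window = rec$stim_window,
               condition = rec$condition, seed = rec$seed)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Serialise circuit parameters as structured text
#'
#' @param config Parameter list (see [cpg_defaults()]).
#' @param file Output path (JSON).
#' @export
write_circuit_config <- function(config, file) {
  jsonlite::write_json(config, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_circuit_config
#' @export
read_circuit_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  p <- cpg_defaults()
  unknown <- setdiff(names(cfg), names(p))
  if (length(unknown))
    stop("read_circuit_config(): unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  p[names(cfg)] <- cfg
  p
}
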
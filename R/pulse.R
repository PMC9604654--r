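# Biphasic pulse-train protocol: gating schedule and waveform sampling.

#' Pulse-train protocol
#'
#' Defaults describe the reference protocol: five trains of eight biphasic
#' pulses, 100 us pulse width and 100 us intra-train interval, 198.4 ms
#' between trains, for a total delivery of exactly 1 s with 4 ms of on-time.
#'
#' @param amplitude pulse amplitude (V).
#' @param pulse_width,pulse_interval on/off durations within a train (s).
#' @param pulses_per_train,n_trains counts (>= 1).
#' @param train_interval pause following each train (s).
#' @param polarity `"BIPHASIC"` (alternating sign per pulse) or
#'   `"MONOPHASIC"`.
#' @return list of class `pulse_protocol`.
#' @export
pulse_protocol <- function(amplitude = 1000, pulse_width = 100e-6,
                           pulse_interval = 100e-6, pulses_per_train = 8L,
                           n_trains = 5L, train_interval = 198.4e-3,
                           polarity = c("BIPHASIC", "MONOPHASIC")) {
  polarity <- match.arg(polarity)
  if (any(c(pulse_width, pulse_interval, train_interval) <= 0))
    stop("all durations must be positive")
  if (pulses_per_train < 1 || n_trains < 1)
    stop("counts must be at least 1")
  if (amplitude <= 0) stop("amplitude must be positive")
  structure(list(amplitude = amplitude, pulse_width = pulse_width,
                 pulse_interval = pulse_interval,
                 pulses_per_train = as.integer(pulses_per_train),
                 n_trains = as.integer(n_trains),
                 train_interval = train_interval, polarity = polarity),
            class = "pulse_protocol")
}

#' Gating schedule of a protocol
#'
#' Expands the protocol into its ordered on-intervals: each train contributes
#' `pulses_per_train` pulses of `pulse_width`, each followed by
#' `pulse_interval`; each train is followed by `train_interval`.
#'
#' @param protocol a [pulse_protocol()].
#' @return list with `intervals` (matrix of `start`, `end` in s, one row per
#'   pulse), `total_duration` (s) and `total_on_time` (s).
#' @export
gating_schedule <- function(protocol) {
  p <- protocol
  train_len <- p$pulses_per_train * (p$pulse_width + p$pulse_interval)
  train_starts <- (seq_len(p$n_trains) - 1) * (train_len + p$train_interval)
  pulse_offsets <- (seq_len(p$pulses_per_train) - 1) *
    (p$pulse_width + p$pulse_interval)
  starts <- as.vector(outer(pulse_offsets, train_starts, "+"))
  intervals <- cbind(start = starts, end = starts + p$pulse_width)
  list(intervals = intervals,
       total_duration = p$n_trains * train_len + p$n_trains * p$train_interval,
       total_on_time = p$n_trains * p$pulses_per_train * p$pulse_width)
}

#' Sample the protocol waveform
#'
#' Voltage at time `t`: plus/minus the amplitude alternating per pulse
#' (biphasic) or the amplitude (monophasic) inside on-intervals, zero
#' elsewhere. The polarity pattern matters only for plotting the waveform;
#' field magnitude and Joule heating are quadratic in V and unaffected.
#'
#' @param protocol a [pulse_protocol()].
#' @param t time(s) in s, within `[0, total_duration]`.
#' @return voltage(s) in volts.
#' @export
sample_waveform <- function(protocol, t) {
  sched <- gating_schedule(protocol)
  if (any(t < 0 | t > sched$total_duration))
    stop("domain error: t must lie in [0, ", sched$total_duration, "] s")
  iv <- sched$intervals
  out <- numeric(length(t))
  idx <- findInterval(t, iv[, "start"])
  on <- idx >= 1 & t <= iv[pmax(idx, 1), "end"]
  sign_of <- if (protocol$polarity == "BIPHASIC")
    ifelse(idx %% 2 == 1, 1, -1) else rep(1, length(t))
  out[on] <- protocol$amplitude * sign_of[on]
  out
}

#' Write the waveform as a two-column CSV
#'
#' @param protocol a [pulse_protocol()].
#' @param file output path.
#' @param dt sampling step (s).
#' @return `file`, invisibly.
#' @export
write_waveform_csv <- function(protocol, file, dt = 10e-6) {
  total <- gating_schedule(protocol)$total_duration
  t <- seq(0, total, by = dt)
  utils::write.csv(data.frame(t = t, V = sample_waveform(protocol, t)),
                   file, row.names = FALSE)
  invisible(file)
}
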
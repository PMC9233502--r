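# Somatic whole-cell voltage analysis: spike detection, spike-removed
# subthreshold envelope, per-tone envelope integrals, tone-window firing
# rates.

#' Detect action potentials in a voltage sweep
#'
#' Spike times are upward crossings of -20 mV, with a 2-ms refractory
#' separation (crossings closer than 2 ms to the previous accepted spike are
#' discarded).
#'
#' @param sweep numeric vector, membrane potential in mV.
#' @param sample_rate sampling rate, Hz.
#' @param threshold detection threshold, mV.
#' @param refractory minimum separation between spikes, s.
#' @param t0 time of the first sample, s (so returned times share the
#'   protocol clock).
#' @return numeric vector of spike times, s.
#' @export
detect_spikes <- function(sweep, sample_rate, threshold = -20,
                          refractory = 0.002, t0 = 0) {
  up <- which(sweep[-1L] > threshold & sweep[-length(sweep)] <= threshold)
  if (length(up) == 0L) return(numeric(0))
  times <- t0 + up / sample_rate
  keep <- times[1L]
  if (length(times) > 1L) {
    for (tm in times[-1L]) {
      if (tm - keep[length(keep)] >= refractory) keep <- c(keep, tm)
    }
  }
  keep
}

#' Remove spikes from a sweep to obtain the subthreshold envelope
#'
#' Samples within +-`half_width` of each spike are replaced by linear
#' interpolation between the window edges; overlapping windows are merged.
#'
#' @param sweep numeric vector, mV.
#' @param spike_times spike times from [detect_spikes()], s.
#' @param sample_rate sampling rate, Hz.
#' @param half_width half-width of the excision window, s.
#' @param t0 time of the first sample, s.
#' @return the sweep with spikes excised.
#' @export
subthreshold_envelope <- function(sweep, spike_times, sample_rate,
                                  half_width = 0.002, t0 = 0) {
  if (length(spike_times) == 0L) return(sweep)
  n <- length(sweep)
  lo <- pmax(1L, as.integer(floor((spike_times - half_width - t0) *
                                    sample_rate)) + 1L)
  hi <- pmin(n, as.integer(ceiling((spike_times + half_width - t0) *
                                     sample_rate)) + 1L)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  # merge overlapping excision windows
  m_lo <- lo[1L]; m_hi <- hi[1L]
  wins <- list()
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= m_hi + 1L) m_hi <- max(m_hi, hi[i])
    else { wins[[length(wins) + 1L]] <- c(m_lo, m_hi); m_lo <- lo[i]; m_hi <- hi[i] }
  }
  wins[[length(wins) + 1L]] <- c(m_lo, m_hi)
  out <- sweep
  for (w in wins) {
    a <- max(1L, w[1L] - 1L); b <- min(n, w[2L] + 1L)
    out[w[1L]:w[2L]] <- seq(out[a], out[b],
                            length.out = w[2L] - w[1L] + 3L)[-c(1L, w[2L] - w[1L] + 3L)]
  }
  out
}

#' Per-tone integral of the evoked subthreshold envelope
#'
#' For each tone, the trapezoidal integral of (envelope - resting baseline)
#' over the 500-ms tone window, in mV.s. The resting baseline is the mean of
#' the envelope over 1 s before stimulus onset of the same sweep, which
#' cancels slow drift.
#'
#' @param envelope spike-removed sweep (mV).
#' @param protocol a [make_protocol()] object.
#' @param sample_rate sampling rate, Hz.
#' @return numeric vector, one integral per tone (mV.s).
#' @export
tone_envelope_integral <- function(envelope, protocol, sample_rate) {
  n <- length(envelope)
  t <- (seq_len(n) - 1L) / sample_rate - protocol$pre_stimulus_window
  last_off <- protocol$tone_onsets[protocol$n_tones] + protocol$tone_duration
  if (t[n] < last_off - 1e-9)
    stop("protocol extends beyond the recorded sweep")
  base_idx <- which(t >= -min(1, protocol$pre_stimulus_window) & t < 0)
  rest <- mean(envelope[base_idx])
  vapply(protocol$tone_onsets, function(on) {
    idx <- which(t >= on & t <= on + protocol$tone_duration)
    pracma::trapz(t[idx], envelope[idx] - rest)
  }, numeric(1))
}

#' Tone-window firing rate
#'
#' Total number of spikes falling in any `[onset, onset + 0.5 s)` tone
#' window across all trials, divided by the total tone-window time
#' (`n_trials * n_tones * tone_duration`), in Hz. Set `per_trial_count =
#' TRUE` for the raw per-trial count (total tone-window spikes / n_trials).
#'
#' @param spike_times list of per-trial spike-time vectors (s, stimulus
#'   clock).
#' @param protocol a [make_protocol()] object.
#' @param per_trial_count return spikes per trial instead of Hz.
#' @return firing rate in Hz (or spikes/trial).
#' @export
tone_firing_rate <- function(spike_times, protocol, per_trial_count = FALSE) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  n_trials <- length(spike_times)
  if (n_trials < 1L) stop("need at least one trial")
  count <- 0L
  for (spk in spike_times) {
    for (on in protocol$tone_onsets) {
      count <- count + sum(spk >= on & spk < on + protocol$tone_duration)
    }
  }
  if (per_trial_count) return(count / n_trials)
  count / (n_trials * protocol$n_tones * protocol$tone_duration)
}

#' Analyze a voltage sweep set
#'
#' Full somatic pipeline: spike detection per trial, spike removal,
#' per-tone envelope integrals, and the tone-window firing rate.
#'
#' @param vss a `voltage_sweeps` object ([simulate_voltage()] or built by
#'   hand with elements `sweeps`, `sample_rate`, `protocol`).
#' @return list with `spike_times` (per trial), `firing_rate` (Hz),
#'   `envelope_integrals` (`n_trials x n_tones` mV.s matrix), and
#'   `mean_integral`.
#' @export
analyze_sweeps <- function(vss) {
  stopifnot(!is.null(vss$sweeps), !is.null(vss$sample_rate),
            !is.null(vss$protocol))
  p <- vss$protocol
  t0 <- -p$pre_stimulus_window
  n_trials <- nrow(vss$sweeps)
  spikes <- vector("list", n_trials)
  ints <- matrix(NA_real_, n_trials, p$n_tones)
  for (i in seq_len(n_trials)) {
    sw <- vss$sweeps[i, ]
    spikes[[i]] <- detect_spikes(sw, vss$sample_rate, t0 = t0)
    env <- subthreshold_envelope(sw, spikes[[i]], vss$sample_rate, t0 = t0)
    ints[i, ] <- tone_envelope_integral(env, p, vss$sample_rate)
  }
  list(spike_times = spikes,
       firing_rate = tone_firing_rate(spikes, p),
       envelope_integrals = ints,
       mean_integral = mean(ints))
}
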
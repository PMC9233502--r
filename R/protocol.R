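#' Auditory stimulation protocol
#'
#' Describes the tone-train stimulus shared by all pipelines: trains of pure
#' tones presented repeatedly, with a silent pre-stimulus window before the
#' first tone of every trial. The default is the conditioning stimulus used
#' throughout: 5 tones of 500 ms separated by 500 ms, 20 trials.
#'
#' Time zero is the onset of the first tone; tone k (0-based) starts at
#' `k * (tone_duration + isi)` seconds.
#'
#' @param condition_label one of `"CS_PLUS"`, `"CS_MINUS"`, `"REFERENCE"`,
#'   `"NAIVE_5K"`, `"NAIVE_15K"`.
#' @param n_tones number of tones per train.
#' @param tone_duration tone duration in seconds.
#' @param isi inter-stimulus interval between tones, seconds.
#' @param n_trials number of stimulus repetitions.
#' @param pre_stimulus_window silent window before the first tone, seconds.
#' @return an object of class `stim_protocol`: a list with the arguments plus
#'   `tone_onsets` (seconds) and `span` (first onset to last offset, seconds).
#' @examples
#' p <- make_protocol("CS_PLUS")
#' p$tone_onsets  # 0 1 2 3 4
#' p$span         # 4.5
#' @export
make_protocol <- function(condition_label = c("CS_PLUS", "CS_MINUS",
                                              "REFERENCE", "NAIVE_5K",
                                              "NAIVE_15K"),
                          n_tones = 5L, tone_duration = 0.5, isi = 0.5,
                          n_trials = 20L, pre_stimulus_window = 5.0) {
  condition_label <- match.arg(condition_label)
  n_tones <- as.integer(n_tones)
  n_trials <- as.integer(n_trials)
  if (n_tones < 1L) stop("n_tones must be >= 1")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (tone_duration <= 0) stop("tone_duration must be positive")
  if (isi <= 0) stop("isi must be positive")
  if (pre_stimulus_window <= 0) stop("pre_stimulus_window must be positive")
  onsets <- (seq_len(n_tones) - 1L) * (tone_duration + isi)
  structure(list(
    condition_label = condition_label,
    n_tones = n_tones,
    tone_duration = tone_duration,
    isi = isi,
    n_trials = n_trials,
    pre_stimulus_window = pre_stimulus_window,
    tone_onsets = onsets,
    span = n_tones * tone_duration + (n_tones - 1L) * isi
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "Stimulus protocol [%s]: %d x %.0f-ms tones, %.0f-ms ISI, %d trials\n",
    x$condition_label, x$n_tones, 1000 * x$tone_duration, 1000 * x$isi,
    x$n_trials))
  cat(sprintf("  span %.2f s, pre-stimulus window %.1f s\n",
              x$span, x$pre_stimulus_window))
  invisible(x)
}

# Frame index (1-based, left-closed bins) of a time relative to first tone
# onset, for a trace whose first frame starts at -pre_stimulus_window.
time_to_frame <- function(t, frame_rate, pre_window) {
  as.integer(floor((t + pre_window) * frame_rate)) + 1L
}
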
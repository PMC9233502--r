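# Shared fixtures, built in code.

toy_protocol <- function(n_trials = 4L) {
  make_protocol("CS_PLUS", n_trials = n_trials)
}

# A dF/F block with a known deterministic signal per trial (no noise).
toy_block <- function(signal, n_trials = 4L, frame_rate = 30,
                      protocol = toy_protocol(n_trials), units = "dff") {
  tr <- matrix(rep(signal, each = n_trials), nrow = n_trials)
  roi_block(tr, frame_rate, protocol, "tuft", units = units)
}

# Time axis matching the generator layout (s, 0 = first tone onset).
toy_times <- function(protocol = toy_protocol(), frame_rate = 30,
                      post = 2.5) {
  n <- as.integer(round((protocol$pre_stimulus_window + protocol$span +
                           post) * frame_rate))
  (seq_len(n) - 1L) / frame_rate - protocol$pre_stimulus_window
}

# Triangular pulse: rises to `peak` at time t_peak, back to 0 at t_end.
triangle_signal <- function(tt, t_start, t_peak, t_end, peak) {
  ifelse(tt >= t_start & tt <= t_peak,
         peak * (tt - t_start) / (t_peak - t_start),
         ifelse(tt > t_peak & tt <= t_end,
                peak * (t_end - tt) / (t_end - t_peak), 0))
}

expect_within_sem <- function(est, target, sem, k = 2) {
  expect_lt(abs(est - target), k * sem + 1e-12)
}
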
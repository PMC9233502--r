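# Synthetic-data generator. Defaults are anchored to the condition means the
# study reports; the kernel amplitude and decay per condition are calibrated
# so the analysis pipeline recovers those means (see calibrate_kernel).

#' Default generator configuration
#'
#' Ground-truth parameters for the synthetic-data generator, anchored to the
#' reported condition means of the study being emulated: trial-averaged peak
#' dF/F and normalized response integrals per compartment and condition,
#' responder fractions, sister-branch recruitment probabilities, per-tone
#' subthreshold envelope areas and tone-window firing rates of the somatic
#' recordings (control and APV), and per-condition freezing percentages.
#' Parameters the source does not report (noise SDs, kinetics, jitter) are
#' fixed realistic choices documented in the methods vignette.
#'
#' @return a nested list of class `generator_config`.
#' @export
generator_defaults <- function() {
  cal <- list(
    frame_rate = 30,
    sigma_f = 0.1,          # dF/F white noise SD per frame
    tau_r = 0.05,           # transient rise time constant, s
    trial_response_p = 0.6, # per-trial response probability of a responder
    amp_jitter_sd = 0.2,    # lognormal sigma of per-trial amplitude jitter
    f0_mean = 100, f0_sd = 10,  # per-ROI raw baseline fluorescence (a.u.)
    post_window = 2.5,      # recording continues this long after last tone, s
    conditions = list(
      # peak/integral/sem are the emulated condition means and the printed
      # between-dendrite SEM of the peak at sample size n; the generator
      # converts sem into per-ROI amplitude heterogeneity (cond_sdlog)
      tuft = list(
        CS_PLUS   = list(peak = 0.74, integral = 1.48, sem = 0.05,
                         p_resp = 0.20, n = 52L),
        CS_MINUS  = list(peak = 0.58, integral = 1.12, sem = 0.05,
                         p_resp = 0.18, n = 46L),
        REFERENCE = list(peak = 0.70, integral = 1.33, sem = 0.08,
                         p_resp = 0.20, n = 37L),
        NAIVE_5K  = list(peak = 0.73, integral = 1.33, sem = 0.08,
                         p_resp = 0.20, n = 30L),
        NAIVE_15K = list(peak = 0.70, integral = 1.33, sem = 0.08,
                         p_resp = 0.20, n = 30L)),
      basal = list(
        CS_PLUS   = list(peak = 0.78, integral = 1.51, sem = 0.04,
                         p_resp = 0.20, n = 56L),
        CS_MINUS  = list(peak = 0.90, integral = 1.60, sem = 0.05,
                         p_resp = 0.18, n = 61L),
        REFERENCE = list(peak = 0.84, integral = 1.56, sem = 0.05,
                         p_resp = 0.20, n = 64L),
        NAIVE_5K  = list(peak = 0.84, integral = 1.56, sem = 0.05,
                         p_resp = 0.20, n = 30L),
        NAIVE_15K = list(peak = 0.84, integral = 1.56, sem = 0.05,
                         p_resp = 0.20, n = 30L))
    ))
  coact <- list(
    q = list(CS_PLUS = 0.69, CS_MINUS = 0.74),
    p_global = 1,        # probability of a neuron-wide event per trial
    local_rate = 0.01,   # rare branch-local events, events/s
    branch_range = c(2L, 4L))
  volt <- list(
    sample_rate = 10000,
    rest = -65,             # resting potential, mV
    sigma_v = 0.3,          # recording noise SD, mV
    envelope_area = list(control = list(CS_PLUS = 1.20, CS_MINUS = 1.18),
                         APV     = list(CS_PLUS = 0.60, CS_MINUS = 0.60)),
    rate = list(control = list(CS_PLUS = 0.53, CS_MINUS = 0.44),
                APV     = list(CS_PLUS = 0.06, CS_MINUS = 0.07)),
    spont_rate = 0.2,       # spikes/s outside tone windows
    area_jitter_sd = 0.10,  # lognormal sigma, per-trial envelope jitter
    cell_sd = 0.30,         # lognormal sigma, per-cell envelope scaling
    rate_cell_cv = 0.25,    # CV of the per-cell firing-rate scaling
    n_cells = 13L,
    spike_amp = 80,         # spike template height above rest, mV
    spike_dur = 0.002)      # template duration, s
  behav <- list(
    cs_plus_mean = 68.5, cs_minus_mean = 12.3,  # baseline-corrected %
    baseline_mean = 5, baseline_sd = 2,
    mouse_sd = 9.7, presentation_sd = 10,
    n_presentations = 8L, n_mice = 20L)
  structure(list(calcium = cal, co_activity = coact, voltage = volt,
                 behavior = behav),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic generator configuration\n")
  cat(sprintf("  calcium: %d tuft + %d basal conditions, sigma_F = %g\n",
              length(x$calcium$conditions$tuft),
              length(x$calcium$conditions$basal), x$calcium$sigma_f))
  cat(sprintf("  voltage: rates CS+ %.2f / CS- %.2f Hz (control)\n",
              x$voltage$rate$control$CS_PLUS, x$voltage$rate$control$CS_MINUS))
  cat(sprintf("  behavior: freezing CS+ %.1f%% / CS- %.1f%%\n",
              x$behavior$cs_plus_mean, x$behavior$cs_minus_mean))
  invisible(x)
}

# Peak-normalized difference-of-exponentials transient kernel evaluated at
# times t (s); zero for t < 0.
dexp_kernel <- function(t, tau_r, tau_d) {
  stopifnot(tau_d > tau_r, tau_r > 0)
  k <- ifelse(t < 0, 0, exp(-pmax(t, 0) / tau_d) - exp(-pmax(t, 0) / tau_r))
  tp <- log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r)
  k / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

# Time axis of a generated trace (s, 0 = first tone onset).
trace_times <- function(protocol, frame_rate, post_window) {
  n <- as.integer(round((protocol$pre_stimulus_window + protocol$span +
                           post_window) * frame_rate))
  (seq_len(n) - 1L) / frame_rate - protocol$pre_stimulus_window
}

# Unit-amplitude compound response: one kernel per tone onset.
compound_response <- function(tt, protocol, tau_r, tau_d) {
  out <- numeric(length(tt))
  for (on in protocol$tone_onsets) out <- out + dexp_kernel(tt - on, tau_r, tau_d)
  out
}

.calib_cache <- new.env(parent = emptyenv())

# Noise-free expected trial-averaged trace pushed through the actual
# pipeline (smoothing, detection, peak, integral) for given kernel params.
pipeline_on_expected <- function(amp, tau_d, protocol, cal, margin = 2) {
  tt <- trace_times(protocol, cal$frame_rate, cal$post_window)
  trace <- sg_smooth(amp * cal$trial_response_p *
                       compound_response(tt, protocol, cal$tau_r, tau_d))
  avg <- structure(list(trace = trace, baseline_sd = 0, threshold = 0,
                        frame_rate = cal$frame_rate, protocol = protocol),
                   class = "trial_avg")
  list(peak = peak_amplitude(avg, margin),
       integral = response_integral(avg, margin))
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

# Per-ROI amplitude heterogeneity (lognormal sdlog, mean 1) needed so the
# between-dendrite SD of the recovered peak matches the condition's printed
# SEM at its sample size. The within-ROI component (trial averaging of the
# Bernoulli(response) x lognormal(jitter) factor over n_trials) is removed
# in quadrature.
cond_sdlog <- function(cond, cal, n_trials) {
  if (is.null(cond$sem) || cond$sem <= 0) return(0)
  rel_total <- cond$sem * sqrt(cond$n) / cond$peak
  p <- cal$trial_response_p
  var_bj <- p * exp(cal$amp_jitter_sd^2) - p^2
  cv_within <- sqrt(var_bj / n_trials) / p
  cv_roi <- sqrt(max(rel_total^2 - cv_within^2, 0))
  sqrt(log1p(cv_roi^2))
}

# Monte Carlo expectation of the pipeline's (peak, integral) estimators for
# a given kernel. The trial average decomposes as G * amp * s + eta, where
# s is the smoothed compound shape, G the mean over trials of the
# Bernoulli(response) x lognormal(jitter) factor, and eta the smoothed
# averaged frame noise; the estimator expectations are computed over (G,
# eta) with a fixed internal RNG stream (common random numbers), so the
# calibration is deterministic and smooth in tau_d.
estimator_expectation <- function(amp, tau_d, protocol, cal, margin,
                                  roi_sdlog = 0, n_reps = 1000L,
                                  mc_seed = 760321L) {
  tt <- trace_times(protocol, cal$frame_rate, cal$post_window)
  s <- sg_smooth(compound_response(tt, protocol, cal$tau_r, tau_d))
  nf <- length(tt)
  nt <- protocol$n_trials
  mu_j <- -cal$amp_jitter_sd^2 / 2
  bsd <- cal$sigma_f  # pooled unsmoothed single-trial baseline SD
  sd_avg <- cal$sigma_f / sqrt(nt)
  with_preserved_rng({
    set.seed(mc_seed)
    pk <- numeric(n_reps); ig <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      g <- mean(stats::rbinom(nt, 1L, cal$trial_response_p) *
                  stats::rlnorm(nt, mu_j, cal$amp_jitter_sd))
      if (roi_sdlog > 0)
        g <- g * stats::rlnorm(1, -roi_sdlog^2 / 2, roi_sdlog)
      eta <- if (cal$sigma_f > 0) sg_smooth(stats::rnorm(nf, 0, sd_avg))
      else numeric(nf)
      avg <- structure(list(trace = g * amp * s + eta, baseline_sd = bsd,
                            threshold = 3 * bsd,
                            frame_rate = cal$frame_rate,
                            protocol = protocol), class = "trial_avg")
      if (detect_response(avg, margin)$responsive) {
        pk[r] <- peak_amplitude(avg, margin)
        ig[r] <- response_integral(avg, margin)
      } else {
        # a real ROI like this would be classified non-responsive and
        # excluded from the condition mean
        pk[r] <- NA_real_; ig[r] <- NA_real_
      }
    }
    list(peak = mean(pk, na.rm = TRUE), integral = mean(ig, na.rm = TRUE))
  })
}

#' Calibrate the transient kernel to a target peak and integral
#'
#' The generator's transient family is a peak-normalized difference of
#' exponentials with fixed rise time. For a given condition this routine
#' finds the decay time constant and kernel amplitude such that the
#' *expectation of the pipeline's estimators* — the peak and normalized
#' trapezoidal integral of the smoothed trial average, under the configured
#' noise, per-trial response probability and amplitude jitter — equals the
#' condition's target values. The expectation is evaluated by a
#' deterministic internal Monte Carlo (fixed seed, common random numbers),
#' which reduces to the noise-free forward calculation when `sigma_f = 0`
#' and jitter is off. Results are cached per parameter set.
#'
#' @param target_peak target trial-averaged peak, dF/F.
#' @param target_integral target normalized integral, s.
#' @param protocol a [make_protocol()] object.
#' @param cal the `calcium` element of a [generator_defaults()] config.
#' @param margin evoked-window decay margin, s.
#' @return list with `amp` (single-trial kernel amplitude, dF/F), `tau_d`
#'   (s), and `attenuation` (ratio of the expected recovered peak to
#'   `amp * trial_response_p`, i.e. the documented smoothing attenuation).
#' @export
calibrate_kernel <- function(target_peak, target_integral, protocol, cal,
                             margin = 2, roi_sdlog = 0) {
  key <- paste(target_peak, target_integral, protocol$n_tones,
               protocol$tone_duration, protocol$isi, protocol$n_trials,
               protocol$pre_stimulus_window, cal$frame_rate, cal$tau_r,
               cal$trial_response_p, cal$amp_jitter_sd, cal$sigma_f,
               cal$post_window, margin, roi_sdlog, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  # noise-free first pass
  f0 <- function(td) pipeline_on_expected(1, td, protocol, cal,
                                          margin)$integral - target_integral
  lo <- cal$tau_r * 1.5; hi <- 5
  if (f0(lo) > 0 || f0(hi) < 0)
    stop("target integral outside the attainable range of the kernel family")
  tau_d <- stats::uniroot(f0, c(lo, hi), tol = 1e-5)$root
  amp <- target_peak / pipeline_on_expected(1, tau_d, protocol, cal,
                                            margin)$peak
  # refine against the estimator expectation under the full noise model
  stochastic <- cal$sigma_f > 0 || cal$amp_jitter_sd > 0 ||
    cal$trial_response_p < 1 || roi_sdlog > 0
  if (stochastic) {
    for (it in 1:2) {
      fi <- function(td) estimator_expectation(amp, td, protocol, cal,
                                               margin, roi_sdlog)$integral -
        target_integral
      span <- c(max(lo, tau_d * 0.6), min(hi, tau_d * 1.7))
      if (fi(span[1L]) < 0 && fi(span[2L]) > 0)
        tau_d <- stats::uniroot(fi, span, tol = 1e-3)$root
      e <- estimator_expectation(amp, tau_d, protocol, cal, margin,
                                 roi_sdlog)
      amp <- amp * target_peak / e$peak
    }
  }
  e <- estimator_expectation(amp, tau_d, protocol, cal, margin, roi_sdlog)
  out <- list(amp = amp, tau_d = tau_d,
              attenuation = e$peak / (amp * cal$trial_response_p),
              expected = e)
  .calib_cache[[key]] <- out
  out
}

#' Simulate per-ROI trial blocks of dendritic calcium fluorescence
#'
#' Generates raw-fluorescence trial matrices at 30 Hz emulating GCaMP6f
#' recordings from single dendrites: per-ROI baseline F0, tone-locked
#' difference-of-exponentials transients in responder ROIs (per-trial
#' response probability and lognormal amplitude jitter), and Gaussian noise.
#' Exactly `ceiling(p_resp * n_rois)` ROIs are responders. The kernel
#' amplitude and decay are calibrated per condition so the pipeline recovers
#' the configured trial-averaged peak and normalized integral
#' ([calibrate_kernel()]).
#'
#' @param config a [generator_defaults()] configuration.
#' @param protocol a [make_protocol()] object; its `condition_label` selects
#'   the condition parameters.
#' @param n_rois number of candidate ROIs.
#' @param compartment `"tuft"` or `"basal"`.
#' @param seed integer seed (mandatory: generation is refused without one).
#' @param p_resp responder fraction override; default from the config. Use 1
#'   to simulate a purely responsive population.
#' @return list of [roi_block()]s (raw F units) with attribute
#'   `ground_truth`: the condition parameters, calibrated kernel, and the
#'   responder index set actually used.
#' @export
simulate_roi_trials <- function(config, protocol, n_rois,
                                compartment = c("tuft", "basal"), seed,
                                p_resp = NULL) {
  compartment <- match.arg(compartment)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation")
  if (n_rois < 1L) stop("n_rois must be >= 1")
  cal <- config$calcium
  cond <- cal$conditions[[compartment]][[protocol$condition_label]]
  if (is.null(cond)) stop("no condition parameters for this protocol label")
  if (is.null(p_resp)) p_resp <- cond$p_resp
  stopifnot(p_resp >= 0, p_resp <= 1)
  sdl <- cond_sdlog(cond, cal, protocol$n_trials)
  k <- calibrate_kernel(cond$peak, cond$integral, protocol, cal,
                        roi_sdlog = sdl)
  set.seed(seed)
  n_resp <- as.integer(ceiling(p_resp * n_rois))
  responders <- sort(sample.int(n_rois, n_resp))
  tt <- trace_times(protocol, cal$frame_rate, cal$post_window)
  shape <- compound_response(tt, protocol, cal$tau_r, k$tau_d)
  mu_j <- -cal$amp_jitter_sd^2 / 2  # lognormal jitter with mean 1
  blocks <- vector("list", n_rois)
  for (r in seq_len(n_rois)) {
    f0 <- max(20, stats::rnorm(1, cal$f0_mean, cal$f0_sd))
    is_resp <- r %in% responders
    roi_scale <- if (sdl > 0) stats::rlnorm(1, -sdl^2 / 2, sdl) else 1
    tr <- matrix(0, protocol$n_trials, length(tt))
    for (i in seq_len(protocol$n_trials)) {
      sig <- numeric(length(tt))
      if (is_resp && stats::runif(1) < cal$trial_response_p)
        sig <- roi_scale * k$amp *
          stats::rlnorm(1, mu_j, cal$amp_jitter_sd) * shape
      tr[i, ] <- f0 * (1 + sig + stats::rnorm(length(tt), 0, cal$sigma_f))
    }
    tr[tr < 0] <- 0
    blocks[[r]] <- roi_block(tr, cal$frame_rate, protocol, compartment,
                             roi_id = sprintf("%s_%s_roi%03d", compartment,
                                              protocol$condition_label, r),
                             units = "F")
  }
  attr(blocks, "ground_truth") <- list(condition = cond, kernel = k,
                                       p_resp = p_resp,
                                       responders = responders,
                                       sigma_f = cal$sigma_f, seed = seed)
  blocks
}

#' Simulate sister-branch calcium activity for branch co-activity analysis
#'
#' Each synthetic neuron owns 2-4 sister tuft branches. On every trial a
#' neuron-wide event recruits each sister branch independently with
#' probability `q` (the ground-truth co-activity); rare branch-local events
#' occur on top at a low Poisson rate. Recruited/local events produce the
#' condition's calibrated calcium transient in that branch's trace.
#'
#' @param config a [generator_defaults()] configuration.
#' @param protocol a [make_protocol()] object (condition selects `q`).
#' @param n_neurons number of neurons.
#' @param seed integer seed (mandatory).
#' @return list of neurons; each element is a list of sister [roi_block()]s
#'   (raw F units) sharing a `neuron_id`. Attribute `ground_truth` holds `q`
#'   and the recruitment matrices actually drawn.
#' @export
simulate_sister_branches <- function(config, protocol, n_neurons, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation")
  co <- config$co_activity
  cal <- config$calcium
  q <- co$q[[protocol$condition_label]]
  if (is.null(q)) stop("no co-activity parameter for this condition")
  cond <- cal$conditions$tuft[[protocol$condition_label]]
  k <- calibrate_kernel(cond$peak, cond$integral, protocol, cal)
  set.seed(seed)
  tt <- trace_times(protocol, cal$frame_rate, cal$post_window)
  shape <- compound_response(tt, protocol, cal$tau_r, k$tau_d)
  mu_j <- -cal$amp_jitter_sd^2 / 2
  total_t <- diff(range(tt)) + 1 / cal$frame_rate
  neurons <- vector("list", n_neurons)
  truth <- vector("list", n_neurons)
  for (n in seq_len(n_neurons)) {
    nb <- sample(seq(co$branch_range[1L], co$branch_range[2L]), 1L)
    recruit <- matrix(FALSE, nb, protocol$n_trials)
    blocks <- vector("list", nb)
    global_evt <- stats::runif(protocol$n_trials) < co$p_global
    branch_sig <- vector("list", nb)
    for (b in seq_len(nb)) branch_sig[[b]] <-
        matrix(0, protocol$n_trials, length(tt))
    for (i in seq_len(protocol$n_trials)) {
      for (b in seq_len(nb)) {
        sig <- numeric(length(tt))
        if (global_evt[i] && stats::runif(1) < q) {
          recruit[b, i] <- TRUE
          sig <- sig + k$amp * stats::rlnorm(1, mu_j, cal$amp_jitter_sd) * shape
        }
        n_loc <- stats::rpois(1, co$local_rate * total_t)
        if (n_loc > 0) {
          for (te in stats::runif(n_loc, tt[1L], tt[length(tt)])) {
            sig <- sig + k$amp * stats::rlnorm(1, mu_j, cal$amp_jitter_sd) *
              dexp_kernel(tt - te, cal$tau_r, k$tau_d)
          }
        }
        branch_sig[[b]][i, ] <- sig
      }
    }
    for (b in seq_len(nb)) {
      f0 <- max(20, stats::rnorm(1, cal$f0_mean, cal$f0_sd))
      tr <- f0 * (1 + branch_sig[[b]] +
                    matrix(stats::rnorm(length(branch_sig[[b]]), 0,
                                        cal$sigma_f),
                           nrow = protocol$n_trials))
      tr[tr < 0] <- 0
      blocks[[b]] <- roi_block(tr, cal$frame_rate, protocol, "tuft",
                               roi_id = sprintf("n%02d_b%d", n, b),
                               neuron_id = sprintf("n%02d", n), units = "F")
    }
    neurons[[n]] <- blocks
    truth[[n]] <- recruit
  }
  attr(neurons, "ground_truth") <- list(q = q, recruit = truth, seed = seed)
  neurons
}

#' Simulate a drifting two-photon movie with known shifts
#'
#' A fixed scene of bright dendrite-like blobs on a noisy background is
#' translated frame by frame by the supplied integer shifts (wrap-free
#' padding with the background level), giving a registration test case with
#' exact ground truth.
#'
#' @param true_shifts integer matrix `[n_frames x 2]` of (dy, dx) per frame;
#'   all `|shift| < frame_size/4`.
#' @param seed integer seed (mandatory).
#' @param dims frame dimensions (pixels).
#' @param n_blobs number of bright blobs in the scene.
#' @param noise_sd per-pixel Gaussian noise SD added to every frame.
#' @return list with `movie` (`ny x nx x n_frames` array), `scene`, and
#'   `true_shifts`.
#' @export
simulate_movie <- function(true_shifts, seed, dims = c(64L, 64L),
                           n_blobs = 12L, noise_sd = 0.05) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation")
  true_shifts <- matrix(as.integer(round(true_shifts)), ncol = 2L)
  if (any(abs(true_shifts) >= min(dims) / 4))
    stop("shifts must satisfy |shift| < frame_size/4")
  set.seed(seed)
  ny <- dims[1L]; nx <- dims[2L]
  scene <- matrix(0.1, ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny)
  xs <- matrix(rep(seq_len(nx), each = ny), ny)
  for (b in seq_len(n_blobs)) {
    cy <- stats::runif(1, ny * 0.3, ny * 0.7)
    cx <- stats::runif(1, nx * 0.3, nx * 0.7)
    s <- stats::runif(1, 1.2, 2.5)
    scene <- scene + exp(-((ys - cy)^2 + (xs - cx)^2) / (2 * s^2))
  }
  nf <- nrow(true_shifts)
  movie <- array(0, c(ny, nx, nf))
  for (i in seq_len(nf)) {
    fr <- translate_frame(scene, true_shifts[i, 1L], true_shifts[i, 2L],
                          fill = 0.1)
    movie[, , i] <- fr + stats::rnorm(ny * nx, 0, noise_sd)
  }
  list(movie = movie, scene = scene, true_shifts = true_shifts)
}

# 2-ms triangular-exponential spike template (linear rise, exponential
# decay), sampled at `sr` Hz, height `amp` mV.
spike_template <- function(amp, dur, sr) {
  n <- as.integer(round(dur * sr))
  t <- seq_len(n) / sr
  rise_n <- max(1L, as.integer(round(n / 4)))
  tpl <- numeric(n)
  tpl[seq_len(rise_n)] <- amp * seq_len(rise_n) / rise_n
  dec <- (rise_n + 1L):n
  tpl[dec] <- amp * exp(-(t[dec] - t[rise_n]) / (dur / 4))
  tpl
}

#' Simulate somatic voltage sweeps
#'
#' Each sweep is a resting potential plus a tone-locked smooth depolarizing
#' envelope (half-sine per tone, with per-tone area equal to the configured
#' mV.s value, per-cell and per-trial lognormal jitter), stereotyped spike
#' templates inserted at Poisson times within tone windows at the configured
#' per-condition rate (plus a low spontaneous rate outside), and Gaussian
#' recording noise, sampled at 10 kHz. The APV condition uses the suppressed
#' envelope and rate.
#'
#' @param config a [generator_defaults()] configuration.
#' @param protocol a [make_protocol()] object (CS_PLUS / CS_MINUS).
#' @param n_trials number of sweeps.
#' @param condition `"control"` or `"APV"`.
#' @param seed integer seed (mandatory).
#' @param cell_scale per-cell multiplicative envelope factor (drawn by
#'   [simulate_voltage_cells()]; default 1).
#' @param rate_scale per-cell multiplicative firing-rate factor (drawn by
#'   [simulate_voltage_cells()]; default 1).
#' @return an object of class `voltage_sweeps`: list with `sweeps`
#'   (`n_trials x n_samples` mV matrix), `sample_rate`, `protocol`,
#'   `condition`, and `ground_truth` (configured area, rate, spike times).
#' @export
simulate_voltage <- function(config, protocol, n_trials,
                             condition = c("control", "APV"), seed,
                             cell_scale = 1, rate_scale = 1) {
  condition <- match.arg(condition)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation")
  v <- config$voltage
  area <- v$envelope_area[[condition]][[protocol$condition_label]]
  rate <- v$rate[[condition]][[protocol$condition_label]]
  if (is.null(area) || is.null(rate))
    stop("no voltage parameters for this condition")
  rate <- rate * rate_scale
  if (rate < 0) stop("firing rate must be non-negative")
  set.seed(seed)
  sr <- v$sample_rate
  dur <- protocol$pre_stimulus_window + protocol$span + 0.5
  n_samp <- as.integer(round(dur * sr))
  t <- (seq_len(n_samp) - 1L) / sr - protocol$pre_stimulus_window
  tone_d <- protocol$tone_duration
  env_unit <- numeric(n_samp)  # unit-area-per-tone envelope
  for (on in protocol$tone_onsets) {
    idx <- which(t >= on & t < on + tone_d)
    env_unit[idx] <- env_unit[idx] +
      (pi / (2 * tone_d)) * sin(pi * (t[idx] - on) / tone_d)
  }
  tpl <- spike_template(v$spike_amp, v$spike_dur, sr)
  mu_j <- -v$area_jitter_sd^2 / 2
  sweeps <- matrix(0, n_trials, n_samp)
  spk_truth <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    jit <- stats::rlnorm(1, mu_j, v$area_jitter_sd)
    sweep <- v$rest + area * cell_scale * jit * env_unit
    # Poisson spikes in tone windows at `rate`, spontaneous outside
    spk <- numeric(0)
    for (on in protocol$tone_onsets) {
      n_s <- stats::rpois(1, rate * tone_d)
      if (n_s > 0) spk <- c(spk, stats::runif(n_s, on, on + tone_d))
    }
    out_t <- dur - protocol$n_tones * tone_d
    n_sp <- stats::rpois(1, v$spont_rate * out_t)
    if (n_sp > 0) {
      cand <- stats::runif(n_sp * 3, t[1L], t[n_samp])
      in_tone <- Reduce(`|`, lapply(protocol$tone_onsets, function(on)
        cand >= on & cand < on + tone_d))
      spk <- c(spk, utils::head(cand[!in_tone], n_sp))
    }
    spk <- sort(spk)
    for (ts in spk) {
      i0 <- as.integer(round((ts - t[1L]) * sr)) + 1L
      idx <- i0:min(n_samp, i0 + length(tpl) - 1L)
      sweeps_add <- tpl[seq_along(idx)]
      sweep[idx] <- sweep[idx] + sweeps_add
    }
    spk_truth[[i]] <- spk
    sweeps[i, ] <- sweep + stats::rnorm(n_samp, 0, v$sigma_v)
  }
  structure(list(sweeps = sweeps, sample_rate = sr, protocol = protocol,
                 condition = condition,
                 ground_truth = list(area = area * cell_scale, rate = rate,
                                     spikes = spk_truth, seed = seed)),
            class = "voltage_sweeps")
}

#' Simulate a population of recorded cells
#'
#' Draws per-cell lognormal envelope and firing-rate scalings (mean 1) and
#' generates one [simulate_voltage()] sweep set per cell. Cell identity is
#' determined by the seed: calling this with the *same* seed for the CS+
#' and CS- conditions yields the same per-cell scalings, emulating the
#' paired within-cell design of the recordings (the per-cell factors cancel
#' in paired comparisons).
#'
#' @inheritParams simulate_voltage
#' @param n_cells number of cells.
#' @return list of `voltage_sweeps`, one per cell.
#' @export
simulate_voltage_cells <- function(config, protocol, n_cells, n_trials,
                                   condition = c("control", "APV"), seed) {
  condition <- match.arg(condition)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation")
  set.seed(seed)
  mu_c <- -config$voltage$cell_sd^2 / 2
  scales <- stats::rlnorm(n_cells, mu_c, config$voltage$cell_sd)
  r_sdl <- sqrt(log1p(config$voltage$rate_cell_cv^2))
  rate_scales <- stats::rlnorm(n_cells, -r_sdl^2 / 2, r_sdl)
  seeds <- sample.int(.Machine$integer.max, 2L * n_cells)
  cond_off <- if (protocol$condition_label == "CS_PLUS") 0L else n_cells
  lapply(seq_len(n_cells), function(i)
    simulate_voltage(config, protocol, n_trials, condition,
                     seed = seeds[cond_off + i], cell_scale = scales[i],
                     rate_scale = rate_scales[i]))
}

#' Simulate per-mouse freezing records
#'
#' Per mouse: a 2-min habituation baseline freezing percentage and 8 CS+
#' plus 8 CS- presentation percentages drawn around the configured
#' condition means (plus the mouse's baseline, so the baseline-corrected
#' score recovers the configured mean), with mouse-level and
#' presentation-level Gaussian variability, truncated to [0, 100].
#'
#' @param config a [generator_defaults()] configuration.
#' @param n_mice number of mice.
#' @param seed integer seed (mandatory).
#' @return data.frame with columns `mouse_id`, `baseline`, `condition`
#'   (`CS_PLUS`/`CS_MINUS`), `presentation` (1-8), `freezing` (%).
#' @export
simulate_freezing <- function(config, n_mice, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation")
  if (n_mice < 1L) stop("n_mice must be >= 1")
  b <- config$behavior
  set.seed(seed)
  rows <- list()
  for (m in seq_len(n_mice)) {
    base <- min(100, max(0, stats::rnorm(1, b$baseline_mean, b$baseline_sd)))
    eff_p <- stats::rnorm(1, b$cs_plus_mean, b$mouse_sd)
    eff_m <- stats::rnorm(1, b$cs_minus_mean, b$mouse_sd)
    for (cond in c("CS_PLUS", "CS_MINUS")) {
      eff <- if (cond == "CS_PLUS") eff_p else eff_m
      fz <- stats::rnorm(b$n_presentations, base + eff, b$presentation_sd)
      fz <- pmin(100, pmax(0, fz))
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = sprintf("m%02d", m), baseline = base, condition = cond,
        presentation = seq_len(b$n_presentations), freezing = fz,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- list(cs_plus = b$cs_plus_mean,
                                    cs_minus = b$cs_minus_mean, seed = seed)
  out
}

#' Simulate a complete synthetic dataset
#'
#' Bundles ROI blocks (tuft and basal, CS+ and CS-), sister-branch
#' recordings, voltage sweep sets per condition, and freezing records, with
#' the generator configuration embedded as ground truth.
#'
#' @param config a [generator_defaults()] configuration.
#' @param seed integer seed (mandatory).
#' @param n_rois_override optional named list overriding per-condition ROI
#'   counts.
#' @return a list of class `synthetic_dataset`.
#' @export
simulate_dataset <- function(config = generator_defaults(), seed,
                             n_rois_override = NULL) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible generation")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 16L)
  roi_blocks <- list()
  i <- 0L
  for (comp in c("tuft", "basal")) {
    for (cond in c("CS_PLUS", "CS_MINUS")) {
      i <- i + 1L
      p <- make_protocol(cond)
      n <- config$calcium$conditions[[comp]][[cond]]$n
      if (!is.null(n_rois_override[[paste(comp, cond, sep = "_")]]))
        n <- n_rois_override[[paste(comp, cond, sep = "_")]]
      roi_blocks[[paste(comp, cond, sep = "_")]] <-
        simulate_roi_trials(config, p, n, comp, seed = seeds[i], p_resp = 1)
    }
  }
  volt <- list()
  for (cond in c("CS_PLUS", "CS_MINUS")) {
    for (drug in c("control", "APV")) {
      i <- i + 1L
      p <- make_protocol(cond, pre_stimulus_window = 1)
      volt[[paste(drug, cond, sep = "_")]] <-
        simulate_voltage_cells(config, p, config$voltage$n_cells, 20L, drug,
                               seed = seeds[i])
    }
  }
  i <- i + 1L
  sisters <- simulate_sister_branches(config, make_protocol("CS_PLUS"), 30L,
                                      seed = seeds[i])
  i <- i + 1L
  behavior <- simulate_freezing(config, config$behavior$n_mice,
                                seed = seeds[i])
  structure(list(roi_blocks = roi_blocks, voltage = volt, sisters = sisters,
                 behavior = behavior, ground_truth = config, seed = seed),
            class = "synthetic_dataset")
}
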
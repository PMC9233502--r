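# Composite-sigmoid reduced neuron model: two tuft sigmoids control the
# maximum and threshold of a basal sigmoid converting basal input into an
# output firing rate, simulated as per-bin Poisson spiking over the 500-ms
# stimulus divided into ten 50-ms bins.

#' Construct composite-sigmoid model parameters
#'
#' The nine parameters of the reduced model:
#' `M(t) = a1 + a2 / (1 + exp(-(t - a3)/a4))` (rate ceiling as a function of
#' tuft input), `T(t) = b1 + b2 / (1 + exp(-(t - b3)/b4))` (basal threshold
#' as a function of tuft input), and
#' `F(b, t) = c1 + M(t) / (1 + exp(-(b - T(t))))` (expected spikes per bin),
#' where `b` and `t` are per-bin basal and tuft synapse counts and `c1` is
#' the baseline firing rate in spikes per bin.
#'
#' @param a1,a2,a3,a4 max-sigmoid parameters (`a4 != 0`, `a1 + a2 >= 0`).
#' @param b1,b2,b3,b4 threshold-sigmoid parameters (`b4 != 0`).
#' @param c1 baseline rate, spikes per bin (`>= 0`).
#' @return an object of class `sigmoid_params` (named numeric vector).
#' @export
sigmoid_params <- function(a1, a2, a3, a4, b1, b2, b3, b4, c1) {
  if (a4 == 0 || b4 == 0) stop("a4 and b4 must be nonzero")
  if (c1 < 0) stop("c1 must be non-negative")
  if (a1 + a2 < 0) stop("a1 + a2 must be non-negative (rate ceiling)")
  structure(c(a1 = a1, a2 = a2, a3 = a3, a4 = a4,
              b1 = b1, b2 = b2, b3 = b3, b4 = b4, c1 = c1),
            class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat("Composite-sigmoid parameters:\n")
  print(unclass(x))
  invisible(x)
}

#' Rate-ceiling sigmoid M(t)
#' @param t tuft input count (per bin).
#' @param params a [sigmoid_params()] object.
#' @return `a1 + a2 / (1 + exp(-(t - a3)/a4))`.
#' @export
max_sigmoid <- function(t, params) {
  params[["a1"]] + params[["a2"]] /
    (1 + exp(-(t - params[["a3"]]) / params[["a4"]]))
}

#' Basal-threshold sigmoid T(t)
#' @inheritParams max_sigmoid
#' @return `b1 + b2 / (1 + exp(-(t - b3)/b4))`.
#' @export
threshold_sigmoid <- function(t, params) {
  params[["b1"]] + params[["b2"]] /
    (1 + exp(-(t - params[["b3"]]) / params[["b4"]]))
}

#' Composite input-output rate F(b, t)
#' @param b basal input count (per bin).
#' @inheritParams max_sigmoid
#' @return expected spikes per bin, `c1 + M(t)/(1 + exp(-(b - T(t))))`.
#' @export
io_rate <- function(b, t, params) {
  params[["c1"]] + max_sigmoid(t, params) /
    (1 + exp(-(b - threshold_sigmoid(t, params))))
}

#' Reduced-model simulation configuration
#'
#' @param n_basal,n_tuft numbers of stimulus-evoked synapses.
#' @param stimulus_duration auditory period, s.
#' @param n_bins number of time bins (`n_bins * bin_width` must equal
#'   `stimulus_duration`).
#' @param bin_width bin width, s.
#' @return a list of class `reduced_sim_config`.
#' @export
reduced_sim_config <- function(n_basal = 200L, n_tuft = 200L,
                               stimulus_duration = 0.5, n_bins = 10L,
                               bin_width = 0.05) {
  if (abs(n_bins * bin_width - stimulus_duration) > 1e-12)
    stop("n_bins * bin_width must equal stimulus_duration")
  structure(list(n_basal = as.integer(n_basal), n_tuft = as.integer(n_tuft),
                 stimulus_duration = stimulus_duration,
                 n_bins = as.integer(n_bins), bin_width = bin_width),
            class = "reduced_sim_config")
}

# Bin synapse counts: each synapse gets a uniform time on [0, duration) and
# is assigned to a half-open 50-ms bin.
bin_synapses <- function(n, config) {
  tabulate(findInterval(stats::runif(n, 0, config$stimulus_duration),
                        seq(0, config$stimulus_duration,
                            by = config$bin_width),
                        rightmost.closed = FALSE),
           nbins = config$n_bins)
}

#' Simulate one trial of the reduced model
#'
#' Assigns each basal and tuft synapse a uniform time in the stimulus
#' window, bins the counts into the ten 50-ms bins, evaluates the composite
#' sigmoid per bin to obtain the Poisson mean, samples per-bin spike counts,
#' and converts the total count to an output frequency.
#'
#' @param params a [sigmoid_params()] object.
#' @param config a [reduced_sim_config()].
#' @param seed integer seed; if `NULL` the current RNG stream is used (so
#'   callers looping over repeats seed once).
#' @return list with `counts` (per bin), `total`, and `frequency` (Hz).
#' @export
simulate_sigmoid_trial <- function(params, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bb <- bin_synapses(config$n_basal, config)
  tt <- bin_synapses(config$n_tuft, config)
  lam <- io_rate(bb, tt, params)
  if (any(lam < 0))
    stop("negative Poisson rate: invalid parameter combination")
  counts <- stats::rpois(config$n_bins, lam)
  list(counts = counts, total = sum(counts),
       frequency = sum(counts) / config$stimulus_duration)
}

#' Deterministic expected input-output curve
#'
#' Expected output frequency with per-bin synapse counts replaced by their
#' means (`n/10` per bin): `(n_bins * F(b/10, t/10)) / duration`. This is the
#' smooth curve used as the genetic-algorithm objective.
#'
#' @param params a [sigmoid_params()] object.
#' @param n_basal,n_tuft synapse counts (vectors are swept elementwise with
#'   recycling).
#' @param config a [reduced_sim_config()] (bin structure only).
#' @return expected frequency, Hz.
#' @export
expected_frequency <- function(params, n_basal, n_tuft,
                               config = reduced_sim_config()) {
  lam <- io_rate(n_basal / config$n_bins, n_tuft / config$n_bins, params)
  config$n_bins * lam / config$stimulus_duration
}

#' Monte Carlo input-output curve
#'
#' Sweeps one input count while holding the other fixed, running
#' `n_repeats` Poisson trials per sweep point.
#'
#' @param params a [sigmoid_params()] object.
#' @param sweep which input to sweep: `"tuft"` or `"basal"`.
#' @param sweep_counts synapse counts swept (default 200 to 300 by 5).
#' @param fixed_count the non-swept input count (default 200).
#' @param n_repeats trials per sweep point.
#' @param seed integer seed (mandatory).
#' @return data.frame: `count`, `mean_freq`, `sem_freq` (Hz).
#' @export
io_curve <- function(params, sweep = c("tuft", "basal"),
                     sweep_counts = seq(200L, 300L, by = 5L),
                     fixed_count = 200L, n_repeats = 100L, seed) {
  sweep <- match.arg(sweep)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible simulation")
  if (length(sweep_counts) == 0L) stop("sweep range is empty")
  set.seed(seed)
  rows <- lapply(sweep_counts, function(k) {
    cfg <- if (sweep == "tuft")
      reduced_sim_config(n_basal = fixed_count, n_tuft = k)
    else reduced_sim_config(n_basal = k, n_tuft = fixed_count)
    f <- vapply(seq_len(n_repeats), function(i)
      simulate_sigmoid_trial(params, cfg)$frequency, numeric(1))
    data.frame(count = k, mean_freq = mean(f),
               sem_freq = stats::sd(f) / sqrt(n_repeats))
  })
  do.call(rbind, rows)
}

ga_defaults <- function() {
  list(pop_size = 120L, generations = 300L, tournament_k = 3L,
       crossover_p = 0.5, mutation_p = 0.4, mutation_sd_frac = 0.10,
       mutation_sd_final = 0.005, elitism = 2L)
}

default_sigmoid_bounds <- function() {
  rbind(a1 = c(0, 0.05),  a2 = c(0, 0.2),   a3 = c(10, 40), a4 = c(0.5, 10),
        b1 = c(10, 40),   b2 = c(-30, 0),   b3 = c(10, 40), b4 = c(0.5, 10),
        c1 = c(0, 0.05))
}

#' Fit the composite-sigmoid model with a genetic algorithm
#'
#' Minimizes the summed absolute difference between the model's expected
#' input-output curves (tuft sweep at fixed basal, basal sweep at fixed
#' tuft) and the supplied target curves. Real-coded genetic algorithm:
#' tournament selection (k = 3), uniform crossover (p = 0.5), Gaussian
#' mutation with SD 10% of each parameter's search range, elitism of 2.
#' Candidates producing a negative Poisson rate anywhere on the target
#' inputs are rejected with infinite loss rather than clamped.
#'
#' @param target data.frame with columns `sweep` (`"tuft"`/`"basal"`),
#'   `count`, and `freq` (Hz) — the curves to fit.
#' @param fixed_count non-swept input count used for both sweeps.
#' @param bounds 9 x 2 matrix of parameter search ranges (rows named
#'   a1..a4, b1..b4, c1).
#' @param ga_config list overriding [ga_defaults()] entries.
#' @param seed integer seed (mandatory).
#' @param config a [reduced_sim_config()] (bin structure).
#' @return an object of class `sigmoid_fit`: the best [sigmoid_params()],
#'   the per-generation best loss (non-increasing), the final loss, and the
#'   target. Methods: `print`, `summary`, `coef`, `predict`, `simulate`,
#'   `plot`, `residuals`.
#' @export
fit_sigmoid <- function(target, fixed_count = 200L,
                        bounds = default_sigmoid_bounds(),
                        ga_config = list(), seed,
                        config = reduced_sim_config()) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible fitting")
  stopifnot(all(c("sweep", "count", "freq") %in% names(target)),
            nrow(bounds) == 9L)
  ga <- utils::modifyList(ga_defaults(), ga_config)
  set.seed(seed)
  lo <- bounds[, 1L]; hi <- bounds[, 2L]
  rng <- hi - lo
  tuft_tgt <- target[target$sweep == "tuft", ]
  basal_tgt <- target[target$sweep == "basal", ]
  loss_fn <- function(v) {
    p <- tryCatch(sigmoid_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7],
                                 v[8], v[9]), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    ft <- expected_frequency(p, fixed_count, tuft_tgt$count, config)
    fb <- expected_frequency(p, basal_tgt$count, fixed_count, config)
    lam_t <- io_rate(fixed_count / config$n_bins,
                     tuft_tgt$count / config$n_bins, p)
    lam_b <- io_rate(basal_tgt$count / config$n_bins,
                     fixed_count / config$n_bins, p)
    if (any(lam_t < 0) || any(lam_b < 0)) return(Inf)
    sum(abs(ft - tuft_tgt$freq)) + sum(abs(fb - basal_tgt$freq))
  }
  np <- ga$pop_size
  pop <- matrix(stats::runif(np * 9L, rep(lo, each = np),
                             rep(hi, each = np)), nrow = np)
  fit <- apply(pop, 1L, loss_fn)
  best_trace <- numeric(ga$generations)
  for (g in seq_len(ga$generations)) {
    ord <- order(fit)
    new_pop <- matrix(NA_real_, np, 9L)
    new_pop[seq_len(ga$elitism), ] <- pop[ord[seq_len(ga$elitism)], ]
    # mutation SD anneals geometrically from the initial to the final
    # fraction of each parameter's range
    sd_frac <- ga$mutation_sd_frac *
      (ga$mutation_sd_final / ga$mutation_sd_frac)^((g - 1) /
                                                      max(1, ga$generations - 1))
    for (i in (ga$elitism + 1L):np) {
      pick <- function() {
        cand <- sample.int(np, ga$tournament_k)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- ifelse(stats::runif(9L) < ga$crossover_p, p1, p2)
      do_mut <- stats::runif(9L) < ga$mutation_p
      mut <- stats::rnorm(9L, 0, sd_frac * rng) * do_mut
      child <- pmin(hi, pmax(lo, child + mut))
      new_pop[i, ] <- child
    }
    pop <- new_pop
    fit <- apply(pop, 1L, loss_fn)
    best_trace[g] <- min(fit)
  }
  best <- pop[which.min(fit), ]
  params <- sigmoid_params(best[1], best[2], best[3], best[4], best[5],
                           best[6], best[7], best[8], best[9])
  structure(list(params = params, loss = min(fit), loss_trace = cummin(best_trace),
                 target = target, fixed_count = fixed_count,
                 bounds = bounds, ga = ga, config = config, seed = seed),
            class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) unclass(object$params)

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Composite-sigmoid model fit (genetic algorithm)\n")
  cat(sprintf("  final loss: %.4g over %d target points\n", x$loss,
              nrow(x$target)))
  cat("  parameters:\n")
  print(round(unclass(x$params), 4))
  invisible(x)
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 rel_loss = object$loss / sum(abs(object$target$freq)),
                 resid_range = range(res)),
            class = "summary.sigmoid_fit")
}

#' @export
print.summary.sigmoid_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  relative loss: %.3f%% of target magnitude\n",
              100 * x$rel_loss))
  cat(sprintf("  residual range: [%.4g, %.4g] Hz\n", x$resid_range[1L],
              x$resid_range[2L]))
  invisible(x)
}

#' Predicted expected frequencies at the target inputs
#' @param object a `sigmoid_fit`.
#' @param newdata optional data.frame with `sweep` and `count`; defaults to
#'   the fitted target inputs.
#' @param ... unused.
#' @return numeric vector of expected frequencies, Hz.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$target
  vapply(seq_len(nrow(newdata)), function(i) {
    if (newdata$sweep[i] == "tuft")
      expected_frequency(object$params, object$fixed_count,
                         newdata$count[i], object$config)
    else expected_frequency(object$params, newdata$count[i],
                            object$fixed_count, object$config)
  }, numeric(1))
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  predict(object) - object$target$freq
}

#' Simulate Poisson spiking from a fitted composite-sigmoid model
#' @param object a `sigmoid_fit`.
#' @param nsim number of trials.
#' @param seed integer seed (mandatory).
#' @param n_basal,n_tuft synapse counts for the simulated condition.
#' @param ... unused.
#' @return data.frame with one row per trial: `total` spikes and
#'   `frequency` (Hz).
#' @export
simulate.sigmoid_fit <- function(object, nsim = 1, seed, n_basal = 200L,
                                 n_tuft = 200L, ...) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible simulation")
  set.seed(seed)
  cfg <- reduced_sim_config(n_basal = n_basal, n_tuft = n_tuft)
  rows <- lapply(seq_len(nsim), function(i) {
    tr <- simulate_sigmoid_trial(object$params, cfg)
    data.frame(trial = i, total = tr$total, frequency = tr$frequency)
  })
  do.call(rbind, rows)
}

#' Plot fitted and target input-output curves
#' @param x a `sigmoid_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sigmoid_fit <- function(x, ...) {
  tgt <- x$target
  pred <- predict(x)
  cols <- c(tuft = "firebrick", basal = "steelblue")
  graphics::plot(tgt$count, tgt$freq, col = cols[tgt$sweep], pch = 1,
                 xlab = "swept synapse count",
                 ylab = "output frequency (Hz)", ...)
  for (sw in unique(tgt$sweep)) {
    i <- tgt$sweep == sw
    graphics::lines(tgt$count[i], pred[i], col = cols[sw])
  }
  graphics::legend("topleft", legend = unique(tgt$sweep),
                   col = cols[unique(tgt$sweep)], lty = 1, bty = "n")
  invisible(x)
}

#' Benchmark composite-sigmoid parameters
#'
#' A fixed parameter set with the qualitative sweep geometry the reduced
#' model is meant to capture: over the 200-300 sweep the tuft curve is
#' steeper and more strongly curved than the nearly linear basal curve,
#' and the two diverge over the upper half of the sweep, spanning output
#' rates around the measured CS-/CS+ firing-rate range.
#'
#' @return a [sigmoid_params()] object.
#' @export
benchmark_sigmoid_params <- function() {
  sigmoid_params(a1 = 0.005, a2 = 0.08, a3 = 26, a4 = 2.5,
                 b1 = 26, b2 = -8, b3 = 26, b4 = 3, c1 = 0.004)
}
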
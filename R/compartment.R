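# Reduced biophysical compartment model: stylized L2/3 pyramidal morphology,
# NMDA/AMPA synapses, distance-graded Ih in the tuft, adaptive-exponential
# soma spiking, and the synapse-count firing-rate sweeps.

#' NMDA synaptic conductance
#'
#' Voltage-dependent NMDA conductance at time `t` after synapse onset:
#' `g_max * (exp(-t/70) - exp(-t/3)) / (1 + 0.3 * exp(-0.08 * v))`, zero for
#' `t < 0`. The denominator is the magnesium-block factor.
#'
#' @param t time since synapse activation, ms.
#' @param v local membrane potential, mV.
#' @param g_max maximal conductance, nS.
#' @return conductance in nS.
#' @export
nmda_conductance <- function(t, v, g_max = 1) {
  ifelse(t < 0, 0,
         g_max * (exp(-pmax(t, 0) / 70) - exp(-pmax(t, 0) / 3)) /
           (1 + 0.3 * exp(-0.08 * v)))
}

#' AMPA synaptic conductance
#'
#' Instantaneous rise, exponential decay with a 0.5-ms time constant:
#' `g_max * exp(-t/0.5)`, zero for `t < 0`.
#'
#' @param t time since synapse activation, ms.
#' @param g_max maximal conductance, nS.
#' @return conductance in nS.
#' @export
ampa_conductance <- function(t, g_max = 1) {
  ifelse(t < 0, 0, g_max * exp(-pmax(t, 0) / 0.5))
}

#' Relative Ih density as a function of distance from the soma
#'
#' `max(0, -0.8696 + 2.087 * exp(x / 323))`, with `x` in micrometres; the
#' hyperpolarization-activated conductance increases steeply toward the
#' distal apical tuft.
#'
#' @param x distance from the soma, micrometres (`x >= 0`).
#' @return relative density (dimensionless, floored at 0).
#' @export
ih_density <- function(x) {
  stopifnot(all(x >= 0))
  pmax(0, -0.8696 + 2.087 * exp(x / 323))
}

#' Reduced stylized morphology of an L2/3 pyramidal neuron
#'
#' A tree rooted at a spherical soma: `n_basal` basal branches emanating
#' from the soma, an apical trunk, and `n_tuft` tuft branches at the trunk's
#' distal end, each discretized into segments. Thin tuft branches give the
#' tuft a higher local input impedance than the basal dendrites, the
#' geometric substrate of its synaptic nonlinearity.
#'
#' @param seg_len segment length, micrometres.
#' @param soma_diam soma diameter, micrometres.
#' @param n_basal,basal_len,basal_diam basal branch count / length / diameter.
#' @param trunk_len,trunk_diam apical trunk length / diameter.
#' @param n_tuft,tuft_len,tuft_diam tuft branch count / length / diameter.
#' @param ra axial resistivity, ohm cm.
#' @param cm specific capacitance, uF/cm^2.
#' @param g_pas leak conductance density, S/cm^2.
#' @param e_pas leak reversal, mV.
#' @return an object of class `reduced_morphology`: a data.frame of
#'   compartments (`comp`, `parent`, `region`, `x` distance from soma,
#'   `length`, `diam`, `area`, `cap` pF, `g_leak` nS, `g_ax` nS) with the
#'   passive constants as attributes. Parents always precede children.
#' @export
reduced_morphology <- function(seg_len = 25, soma_diam = 20,
                               n_basal = 4L, basal_len = 150,
                               basal_diam = 1.2,
                               trunk_len = 300, trunk_diam = 2,
                               n_tuft = 4L, tuft_len = 150, tuft_diam = 0.8,
                               ra = 150, cm = 1, g_pas = 3e-4,
                               e_pas = -70) {
  stopifnot(seg_len > 0, soma_diam > 0, basal_len > 0, trunk_len > 0,
            tuft_len > 0)
  rows <- list(data.frame(region = "soma", parent = 0L, x = 0,
                          length = soma_diam, diam = soma_diam))
  add_branch <- function(rows, region, parent0, x0, len, diam) {
    nseg <- max(1L, as.integer(round(len / seg_len)))
    l <- len / nseg
    par <- parent0
    for (s in seq_len(nseg)) {
      rows[[length(rows) + 1L]] <-
        data.frame(region = region, parent = par,
                   x = x0 + (s - 0.5) * l, length = l, diam = diam)
      par <- length(rows)
    }
    rows
  }
  for (b in seq_len(n_basal))
    rows <- add_branch(rows, "basal", 1L, 0, basal_len, basal_diam)
  rows <- add_branch(rows, "trunk", 1L, 0, trunk_len, trunk_diam)
  trunk_end <- length(rows)
  for (b in seq_len(n_tuft))
    rows <- add_branch(rows, "tuft", trunk_end, trunk_len, tuft_len,
                       tuft_diam)
  m <- do.call(rbind, rows)
  m$comp <- seq_len(nrow(m))
  # lateral area (sphere for the soma)
  m$area <- ifelse(m$region == "soma", pi * m$diam^2, pi * m$diam * m$length)
  m$cap <- cm * m$area * 1e-2                # pF (uF/cm^2 * um^2)
  m$g_leak <- g_pas * m$area * 10            # nS (S/cm^2 * um^2)
  # axial conductance to parent: series half-cylinders, nS
  g_ax <- numeric(nrow(m))
  half_r <- function(i) {
    if (m$region[i] == "soma") return(0)     # soma treated as isopotential
    ra * (m$length[i] / 2) / (pi * (m$diam[i] / 2)^2) * 1e-2  # MOhm
  }
  for (i in 2:nrow(m)) {
    r <- half_r(i) + half_r(m$parent[i])
    g_ax[i] <- 1e3 / r                       # nS = 1/MOhm * 1e3
  }
  m$g_ax <- g_ax
  m <- m[, c("comp", "parent", "region", "x", "length", "diam", "area",
             "cap", "g_leak", "g_ax")]
  structure(m, class = c("reduced_morphology", "data.frame"),
            ra = ra, cm = cm, g_pas = g_pas, e_pas = e_pas)
}

#' Single-compartment point-neuron reduction
#'
#' One isopotential somatic compartment with leak only, for passive
#' benchmarks (RC charging, charge conservation) and f-I characterization
#' of the soma spike mechanism.
#'
#' @inheritParams reduced_morphology
#' @return a one-compartment `reduced_morphology`.
#' @export
point_neuron <- function(soma_diam = 20, cm = 1, g_pas = 5e-5,
                         e_pas = -70) {
  area <- pi * soma_diam^2
  m <- data.frame(comp = 1L, parent = 0L, region = "soma", x = 0,
                  length = soma_diam, diam = soma_diam, area = area,
                  cap = cm * area * 1e-2, g_leak = g_pas * area * 10,
                  g_ax = 0)
  structure(m, class = c("reduced_morphology", "data.frame"),
            ra = NA_real_, cm = cm, g_pas = g_pas, e_pas = e_pas)
}

#' Channel configuration for the reduced model
#'
#' Soma spiking is an adaptive exponential integrate-and-fire mechanism
#' (threshold slope `delta_t`, soft threshold `v_t`, reset, subthreshold
#' and spike-triggered adaptation); the tuft carries an Ih conductance
#' whose density follows [ih_density()] of distance from the soma, with a
#' first-order activation gate.
#'
#' @param adex_enabled enable the soma spike mechanism.
#' @param delta_t,v_t,v_reset AdEx threshold slope (mV), soft threshold
#'   (mV), reset (mV).
#' @param a_w,b_w,tau_w adaptation coupling (nS), spike increment (pA),
#'   time constant (ms).
#' @param t_ref absolute refractory period after a spike, ms.
#' @param gh_base tuft Ih base density, S/cm^2 (scaled by [ih_density()]).
#' @param ih_e,ih_v_half,ih_k,ih_tau Ih reversal (mV), activation midpoint
#'   (mV), slope (mV), gate time constant (ms).
#' @return a list of class `channel_config`.
#' @export
channel_config <- function(adex_enabled = TRUE, delta_t = 2, v_t = -49,
                           v_reset = -55, a_w = 2, b_w = 40, tau_w = 150,
                           t_ref = 2, gh_base = 1.5e-5, ih_e = -45,
                           ih_v_half = -82, ih_k = 7, ih_tau = 50) {
  structure(list(adex = list(enabled = adex_enabled, delta_t = delta_t,
                             v_t = v_t, v_reset = v_reset, a_w = a_w,
                             b_w = b_w, tau_w = tau_w, t_ref = t_ref),
                 gh_base = gh_base,
                 ih = list(e = ih_e, v_half = ih_v_half, k = ih_k,
                           tau = ih_tau)),
            class = "channel_config")
}

#' Place synapses on the morphology
#'
#' Positions are uniform over the total length of the chosen region's
#' segments (a segment is chosen with probability proportional to its
#' length). Stimulus synapses fire exactly once at a uniform time in
#' `[0, 500)` ms; background synapses fire homogeneous Poisson trains with
#' a per-synapse rate drawn once, uniform on 10-100 Hz.
#'
#' @param morph a [reduced_morphology()].
#' @param n number of synapses (> 0).
#' @param region `"tuft"`, `"basal"`, or `"anywhere"`.
#' @param kind `"stimulus"` or `"background"`.
#' @param seed integer seed (mandatory).
#' @param g_max maximal conductance, nS (applies to both the NMDA and AMPA
#'   components; their maxima have a 1:1 ratio by default).
#' @param duration_ms simulation span for background trains / stimulus
#'   window, ms.
#' @param bg_rate_range background per-synapse rate range, Hz.
#' @param nmda_ratio NMDA/AMPA maximal-conductance ratio (1 by default;
#'   0 emulates NMDA-receptor block).
#' @return an object of class `synapse_ensemble`: list with `comp`,
#'   `g_ampa`, `g_nmda` (per synapse), `events` (data.frame `time` ms,
#'   `syn` index), and `rates` (background only).
#' @export
place_synapses <- function(morph, n, region = c("tuft", "basal", "anywhere"),
                           kind = c("stimulus", "background"), seed,
                           g_max = 1, duration_ms = 500,
                           bg_rate_range = c(10, 100), nmda_ratio = 1) {
  region <- match.arg(region)
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible placement")
  if (n <= 0) stop("n must be positive")
  if (g_max <= 0) stop("g_max must be positive")
  set.seed(seed)
  cand <- if (region == "anywhere") which(morph$region != "soma")
  else which(morph$region == region)
  if (length(cand) == 0L) stop("region has no compartments")
  comp <- sample(cand, n, replace = TRUE, prob = morph$length[cand])
  rates <- NULL
  if (kind == "stimulus") {
    events <- data.frame(time = stats::runif(n, 0, 500), syn = seq_len(n))
  } else {
    rates <- stats::runif(n, bg_rate_range[1L], bg_rate_range[2L])
    evs <- lapply(seq_len(n), function(k) {
      ne <- stats::rpois(1, rates[k] * duration_ms / 1000)
      if (ne == 0) return(NULL)
      data.frame(time = stats::runif(ne, 0, duration_ms), syn = k)
    })
    events <- do.call(rbind, evs)
    if (is.null(events)) events <- data.frame(time = numeric(0),
                                              syn = integer(0))
  }
  events <- events[order(events$time), , drop = FALSE]
  structure(list(comp = comp, g_ampa = rep(g_max, n),
                 g_nmda = rep(g_max * nmda_ratio, n), events = events,
                 rates = rates, kind = kind, region = region),
            class = "synapse_ensemble")
}

combine_ensembles <- function(...) {
  es <- list(...)
  es <- es[!vapply(es, is.null, logical(1))]
  offset <- 0L
  comp <- integer(0); ga <- numeric(0); gn <- numeric(0)
  evs <- list()
  for (e in es) {
    comp <- c(comp, e$comp); ga <- c(ga, e$g_ampa); gn <- c(gn, e$g_nmda)
    ev <- e$events; ev$syn <- ev$syn + offset
    evs[[length(evs) + 1L]] <- ev
    offset <- offset + length(e$comp)
  }
  events <- do.call(rbind, evs)
  events <- events[order(events$time), , drop = FALSE]
  list(comp = comp, g_ampa = ga, g_nmda = gn, events = events)
}

#' Simulate the reduced compartment model
#'
#' Integrates the compartmental cable equations (leak + axial coupling
#' implicit, synaptic and Ih conductances semi-implicit with gating at the
#' previous step, AdEx soma terms explicit) with the NMDA/AMPA synaptic
#' currents at a 0 mV reversal.
#'
#' @param morph a [reduced_morphology()].
#' @param channels a [channel_config()].
#' @param synapses a `synapse_ensemble`, a list of them (combined), or
#'   `NULL`.
#' @param duration_ms simulated time, ms.
#' @param dt_ms time step, ms (must be <= 0.025).
#' @param i_inj optional somatic injected current: vector of pA per step, or
#'   a single value applied throughout.
#' @param v0 initial voltage, mV (default: leak reversal).
#' @param record which voltages to keep: `"soma"` or `"all"`.
#' @param record_dt_ms recording interval, ms.
#' @return list with `t` (ms), `v_soma` (mV), `spikes` (soma spike times,
#'   ms), and `v_all` (matrix, when `record = "all"`).
#' @export
simulate_compartments <- function(morph, channels = channel_config(),
                                  synapses = NULL, duration_ms = 500,
                                  dt_ms = 0.025, i_inj = NULL, v0 = NULL,
                                  record = c("soma", "all"),
                                  record_dt_ms = 0.1) {
  record <- match.arg(record)
  if (dt_ms > 0.025 + 1e-12) stop("dt_ms must be <= 0.025 ms")
  if (inherits(synapses, "synapse_ensemble")) synapses <- list(synapses)
  syn <- if (is.null(synapses) || length(synapses) == 0L)
    list(comp = integer(0), g_ampa = numeric(0), g_nmda = numeric(0),
         events = data.frame(time = numeric(0), syn = integer(0)))
  else do.call(combine_ensembles, synapses)
  e_pas <- attr(morph, "e_pas")
  if (is.null(v0)) v0 <- e_pas
  gh <- numeric(nrow(morph))
  tuft <- morph$region == "tuft"
  gh[tuft] <- channels$gh_base * ih_density(morph$x[tuft]) *
    morph$area[tuft] * 10  # nS
  n_steps <- as.integer(round(duration_ms / dt_ms))
  inj <- if (is.null(i_inj)) numeric(0)
  else if (length(i_inj) == 1L) rep(i_inj, n_steps)
  else i_inj
  simulate_cable_cpp(parent = as.integer(morph$parent) - 1L,
                     cap = morph$cap, g_leak = morph$g_leak,
                     e_leak = e_pas, g_ax = morph$g_ax, g_h = gh,
                     ih = channels$ih, adex = channels$adex,
                     syn_comp = as.integer(syn$comp) - 1L,
                     syn_g_ampa = syn$g_ampa, syn_g_nmda = syn$g_nmda,
                     ev_time = as.numeric(syn$events$time),
                     ev_syn = as.integer(syn$events$syn) - 1L,
                     i_inj = inj, duration = duration_ms, dt = dt_ms,
                     v0 = v0, record_all = record == "all",
                     record_every = max(1L,
                                        as.integer(round(record_dt_ms /
                                                           dt_ms))))
}

#' Stimulus-synapse firing-rate sweep
#'
#' Holds one region's stimulus-evoked synapse count fixed (default 200)
#' while sweeping the other region's count (default 200 to 300), with 75
#' background synapses (1 nS, 10-100 Hz Poisson) always active. Each sweep
#' point is simulated `n_repeats` times with fresh random placements and
#' activation times; the soma firing rate over the 500-ms stimulus window
#' is returned as mean and SEM.
#'
#' @param morph a [reduced_morphology()].
#' @param channels a [channel_config()].
#' @param sweep_region region whose count is swept (`"tuft"` or `"basal"`).
#' @param sweep_counts synapse counts swept.
#' @param fixed_n fixed synapse count in the other region.
#' @param n_repeats simulations per sweep point.
#' @param seed integer seed (mandatory).
#' @param g_max_stim stimulus synapse maximal conductance, nS.
#' @param n_background,g_max_bg background synapse count and conductance.
#' @param duration_ms stimulus window, ms.
#' @param dt_ms integration step, ms.
#' @return data.frame: `count`, `mean_rate` (Hz), `sem_rate`.
#' @export
synapse_sweep <- function(morph, channels = channel_config(),
                          sweep_region = c("tuft", "basal"),
                          sweep_counts = seq(200L, 300L, by = 5L),
                          fixed_n = 200L, n_repeats = 10L, seed,
                          g_max_stim = 0.5, n_background = 75L,
                          g_max_bg = 1, duration_ms = 500, dt_ms = 0.025) {
  sweep_region <- match.arg(sweep_region)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible simulation")
  fixed_region <- if (sweep_region == "tuft") "basal" else "tuft"
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             3L * length(sweep_counts) * n_repeats),
                  ncol = 3L)
  row <- 0L
  out <- lapply(seq_along(sweep_counts), function(i) {
    k <- sweep_counts[i]
    rates <- vapply(seq_len(n_repeats), function(r) {
      j <- (i - 1L) * n_repeats + r
      bg <- place_synapses(morph, n_background, "anywhere", "background",
                           seed = seeds[j, 1L], g_max = g_max_bg,
                           duration_ms = duration_ms)
      fx <- place_synapses(morph, fixed_n, fixed_region, "stimulus",
                           seed = seeds[j, 2L], g_max = g_max_stim)
      sw <- place_synapses(morph, k, sweep_region, "stimulus",
                           seed = seeds[j, 3L], g_max = g_max_stim)
      sim <- simulate_compartments(morph, channels, list(bg, fx, sw),
                                   duration_ms = duration_ms, dt_ms = dt_ms)
      length(sim$spikes) / (duration_ms / 1000)
    }, numeric(1))
    data.frame(count = k, mean_rate = mean(rates),
               sem_rate = stats::sd(rates) / sqrt(n_repeats))
  })
  do.call(rbind, out)
}

#' Synapse counts required to reach a target firing rate
#'
#' Linear interpolation of a [synapse_sweep()] curve at a target rate; the
#' smallest swept count whose interpolated mean rate reaches the target.
#'
#' @param curve data.frame from [synapse_sweep()].
#' @param target_rate firing rate, Hz.
#' @return interpolated synapse count (`NA` if the curve never reaches the
#'   target).
#' @export
synapses_for_rate <- function(curve, target_rate) {
  if (max(curve$mean_rate) < target_rate) return(NA_real_)
  if (curve$mean_rate[1L] >= target_rate) return(curve$count[1L])
  stats::approx(curve$mean_rate, curve$count, xout = target_rate,
                ties = "ordered")$y
}
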
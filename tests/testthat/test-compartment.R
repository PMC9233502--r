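test_that("NMDA conductance evaluates its closed form exactly", {
  expect_equal(nmda_conductance(0, -70), 0)
  expect_equal(nmda_conductance(0, 30), 0)
  expect_equal(nmda_conductance(-5, 0), 0)
  expect_equal(nmda_conductance(70, 0, g_max = 2),
               2 * (exp(-1) - exp(-70 / 3)) / 1.3, tolerance = 1e-12)
  # time of peak ~ 9.88 ms (numerical maximization oracle)
  t_peak <- optimize(function(t) exp(-t / 70) - exp(-t / 3),
                     c(0, 50), maximum = TRUE)$maximum
  expect_equal(t_peak, 9.88, tolerance = 0.01)
  g <- nmda_conductance(seq(0, 50, 0.01), -20)
  expect_equal(seq(0, 50, 0.01)[which.max(g)], t_peak, tolerance = 0.02)
  # magnesium block relieves with depolarization
  expect_gt(nmda_conductance(10, 0), nmda_conductance(10, -70))
})

test_that("AMPA conductance has instantaneous rise and 0.5-ms decay", {
  expect_equal(ampa_conductance(0, 3), 3)
  expect_equal(ampa_conductance(0.5, 3), 3 / exp(1))
  expect_equal(ampa_conductance(-1, 3), 0)
  tt <- seq(0, 30, by = 1e-4)
  expect_equal(pracma::trapz(tt, ampa_conductance(tt, 2)), 0.5 * 2,
               tolerance = 1e-3)
})

test_that("Ih density follows the printed distance law, floored at 0", {
  expect_equal(ih_density(0), -0.8696 + 2.087, tolerance = 1e-12)
  expect_equal(ih_density(0), 1.2174)
  expect_equal(ih_density(323), -0.8696 + 2.087 * exp(1), tolerance = 1e-12)
  expect_equal(ih_density(323), 4.8036, tolerance = 1e-4)
  x <- seq(0, 500, by = 10)
  expect_true(all(diff(ih_density(x)) > 0))
  expect_error(ih_density(-1))
})

test_that("synapse placement is uniform over the region length", {
  m <- reduced_morphology()
  s <- place_synapses(m, 200, "tuft", "stimulus", seed = 2)
  expect_true(all(m$region[s$comp] == "tuft"))
  expect_true(all(s$events$time >= 0 & s$events$time < 500))
  expect_equal(nrow(s$events), 200L)           # one activation each
  s2 <- place_synapses(m, 200, "tuft", "stimulus", seed = 2)
  expect_identical(s$comp, s2$comp)
  expect_identical(s$events, s2$events)
  # chi-square uniformity over segments at n = 10000
  big <- place_synapses(m, 10000, "basal", "stimulus", seed = 3)
  cand <- which(m$region == "basal")
  obs <- tabulate(factor(big$comp, levels = cand), nbins = length(cand))
  expect_gt(chisq.test(obs, p = m$length[cand] / sum(m$length[cand]))$p.value,
            0.01)
  # background trains carry per-synapse rates in [10, 100]
  bg <- place_synapses(m, 75, "anywhere", "background", seed = 4)
  expect_true(all(bg$rates >= 10 & bg$rates <= 100))
  expect_error(place_synapses(m, 0, "tuft", "stimulus", seed = 1))
})

test_that("quiescent model settles at rest with no spikes", {
  m <- reduced_morphology()
  sim <- simulate_compartments(m, channel_config(gh_base = 0), NULL,
                               duration_ms = 200)
  expect_length(sim$spikes, 0)
  # the AdEx exponential leaves a ~1e-5 mV equilibrium offset at rest
  expect_lt(max(abs(sim$v_soma + 70)), 1e-3)
})

test_that("passive point-neuron step response matches the RC charging
           curve within 1%", {
  m <- point_neuron()
  ch <- channel_config(adex_enabled = FALSE, gh_base = 0)
  i0 <- 50  # pA
  sim <- simulate_compartments(m, ch, NULL, duration_ms = 150,
                               i_inj = i0, record_dt_ms = 0.1)
  tau <- m$cap[1] / m$g_leak[1]
  analytic <- -70 + i0 / m$g_leak[1] * (1 - exp(-sim$t / tau))
  amplitude <- i0 / m$g_leak[1]
  expect_lt(max(abs(sim$v_soma - analytic)), 0.01 * amplitude)
})

test_that("charge balances in the passive limit", {
  m <- point_neuron()
  ch <- channel_config(adex_enabled = FALSE, gh_base = 0)
  i0 <- 40
  sim <- simulate_compartments(m, ch, NULL, duration_ms = 200,
                               i_inj = i0, record_dt_ms = 0.05)
  # injected charge = capacitive charge + leak charge
  injected <- i0 * 200                              # pA ms = fC
  cap_q <- m$cap[1] * (sim$v_soma[length(sim$v_soma)] - sim$v_soma[1])
  leak_q <- pracma::trapz(sim$t, m$g_leak[1] * (sim$v_soma + 70))
  expect_equal(cap_q + leak_q, injected, tolerance = 0.01 * injected)
})

test_that("halving dt changes the soma trace by less than 0.5 mV", {
  m <- reduced_morphology()
  ch <- channel_config(adex_enabled = FALSE)  # continuous dynamics
  bg <- place_synapses(m, 75, "anywhere", "background", seed = 6)
  st <- place_synapses(m, 100, "tuft", "stimulus", seed = 7, g_max = 0.5)
  s1 <- simulate_compartments(m, ch, list(bg, st), duration_ms = 500,
                              dt_ms = 0.025, record_dt_ms = 0.5)
  s2 <- simulate_compartments(m, ch, list(bg, st), duration_ms = 500,
                              dt_ms = 0.0125, record_dt_ms = 0.5)
  expect_lt(max(abs(s1$v_soma - s2$v_soma)), 0.5)
})

test_that("synaptic current vanishes at the 0 mV reversal", {
  # a cell initialized and resting at the reversal is not moved by synapses
  m <- point_neuron(e_pas = 0)
  ch <- channel_config(adex_enabled = FALSE, gh_base = 0)
  syn <- structure(list(comp = rep(1L, 5), g_ampa = rep(2, 5),
                        g_nmda = rep(2, 5),
                        events = data.frame(time = c(20, 80, 150, 260, 330),
                                            syn = 1:5)),
                   class = "synapse_ensemble")
  sim <- simulate_compartments(m, ch, syn, duration_ms = 400, v0 = 0)
  expect_lt(max(abs(sim$v_soma)), 1e-9)
})

test_that("blow-up aborts with a diagnostic", {
  m <- point_neuron()
  ch <- channel_config(adex_enabled = FALSE, gh_base = 0)
  expect_error(simulate_compartments(m, ch, NULL, duration_ms = 50,
                                     i_inj = 1e6), "blow-up")
  expect_error(simulate_compartments(m, ch, NULL, dt_ms = 0.05), "dt_ms")
})

test_that("synapse sweep is monotone and NMDA block suppresses firing", {
  m <- reduced_morphology()
  ch <- channel_config()
  counts <- c(200L, 300L)
  sw <- synapse_sweep(m, ch, "tuft", sweep_counts = counts,
                      n_repeats = 8L, seed = 11)
  expect_equal(nrow(sw), 2L)
  tol <- 3 * sqrt(sum(sw$sem_rate^2))
  expect_gt(sw$mean_rate[2] - sw$mean_rate[1], -tol)
  # single-point sweep
  sw1 <- synapse_sweep(m, ch, "basal", sweep_counts = 250L,
                       n_repeats = 3L, seed = 12)
  expect_equal(nrow(sw1), 1L)
  # NMDA block (APV analog): rates drop
  rate_with <- mean(vapply(1:6, function(s) {
    bg <- place_synapses(m, 75, "anywhere", "background", seed = s)
    fx <- place_synapses(m, 200, "basal", "stimulus", seed = s + 50,
                         g_max = 0.5)
    tu <- place_synapses(m, 250, "tuft", "stimulus", seed = s + 100,
                         g_max = 0.5)
    length(simulate_compartments(m, ch, list(bg, fx, tu))$spikes) / 0.5
  }, numeric(1)))
  rate_blocked <- mean(vapply(1:6, function(s) {
    bg <- place_synapses(m, 75, "anywhere", "background", seed = s,
                         nmda_ratio = 0)
    fx <- place_synapses(m, 200, "basal", "stimulus", seed = s + 50,
                         g_max = 0.5, nmda_ratio = 0)
    tu <- place_synapses(m, 250, "tuft", "stimulus", seed = s + 100,
                         g_max = 0.5, nmda_ratio = 0)
    length(simulate_compartments(m, ch, list(bg, fx, tu))$spikes) / 0.5
  }, numeric(1)))
  expect_lt(rate_blocked, rate_with)
})
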
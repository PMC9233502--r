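bench <- benchmark_sigmoid_params()

test_that("sigmoid components hit their analytic limits", {
  p <- sigmoid_params(a1 = 1, a2 = 10, a3 = 20, a4 = 5,
                      b1 = 30, b2 = -10, b3 = 25, b4 = 3, c1 = 0.2)
  expect_equal(max_sigmoid(-1e6, p), 1)             # t -> -Inf: a1
  expect_equal(max_sigmoid(20, p), 1 + 5)           # midpoint: a1 + a2/2
  expect_equal(threshold_sigmoid(1e6, p), 30 - 10)  # t -> +Inf: b1 + b2
  expect_equal(threshold_sigmoid(25, p), 30 - 5)
  # b2 = 0: threshold constant in t
  p0 <- sigmoid_params(1, 10, 20, 5, 30, 0, 25, 3, 0.2)
  expect_equal(threshold_sigmoid(-50, p0), threshold_sigmoid(500, p0))
  # printed-value check: a1=0, a2=10, a3=20, a4=5 at t=25
  p2 <- sigmoid_params(0, 10, 20, 5, 30, -10, 25, 3, 0)
  expect_equal(max_sigmoid(25, p2), 10 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(max_sigmoid(25, p2), 7.310586, tolerance = 1e-6)
})

test_that("composite io_rate obeys baseline, midpoint and ceiling", {
  p <- sigmoid_params(1, 10, 20, 5, 30, -10, 25, 3, 0.2)
  t0 <- 22
  expect_equal(io_rate(threshold_sigmoid(t0, p), t0, p),
               0.2 + max_sigmoid(t0, p) / 2)
  expect_equal(io_rate(1e6, t0, p), 0.2 + max_sigmoid(t0, p))
  expect_equal(io_rate(-1e6, t0, p), 0.2)
  # bounds: c1 <= F <= c1 + max(M) on a parameter grid
  for (b in seq(-50, 80, by = 10)) {
    for (t in seq(-20, 60, by = 10)) {
      f <- io_rate(b, t, p)
      expect_gte(f, 0.2)
      expect_lte(f, 0.2 + 1 + 10 + 1e-12)
    }
  }
  expect_error(sigmoid_params(1, 1, 1, 0, 1, 1, 1, 1, 0.1), "a4")
  expect_error(sigmoid_params(1, 1, 1, 1, 1, 1, 1, 1, -0.1), "c1")
})

test_that("synapse binning conserves counts in half-open 50-ms bins", {
  cfg <- reduced_sim_config(n_basal = 137L, n_tuft = 201L)
  set.seed(8)
  for (i in 1:20) {
    expect_equal(sum(dendplast:::bin_synapses(cfg$n_basal, cfg)), 137L)
    expect_equal(sum(dendplast:::bin_synapses(cfg$n_tuft, cfg)), 201L)
  }
  expect_error(reduced_sim_config(n_bins = 9), "stimulus_duration")
})

test_that("Poisson sampling matches the per-bin rate sum", {
  # degenerate parameters make F constant = lambda per bin
  lam <- 0.12
  p <- sigmoid_params(a1 = 0, a2 = 0, a3 = 0, a4 = 1,
                      b1 = 0, b2 = 0, b3 = 0, b4 = 1, c1 = lam)
  cfg <- reduced_sim_config()
  set.seed(10)
  f <- replicate(4000, simulate_sigmoid_trial(p, cfg)$frequency)
  expected <- 10 * lam / 0.5
  se <- sqrt(10 * lam) / 0.5 / sqrt(4000)
  expect_within_sem(mean(f), expected, se, k = 3)
  # mean frequency converges to the analytic per-bin sum for the benchmark
  set.seed(11)
  sums <- replicate(4000, {
    bb <- dendplast:::bin_synapses(200L, cfg)
    tt <- dendplast:::bin_synapses(200L, cfg)
    lam_k <- io_rate(bb, tt, bench)
    c(sum(rpois(10, lam_k)) / 0.5, sum(lam_k) / 0.5)
  })
  expect_within_sem(mean(sums[1, ]), mean(sums[2, ]),
                    sd(sums[1, ] - sums[2, ]) / sqrt(4000), k = 3)
  # identical seed gives identical counts
  t1 <- simulate_sigmoid_trial(bench, cfg, seed = 33)
  t2 <- simulate_sigmoid_trial(bench, cfg, seed = 33)
  expect_identical(t1$counts, t2$counts)
  # all-off parameters give zero output
  p0 <- sigmoid_params(0, 0, 0, 1, 0, 0, 0, 1, 0)
  expect_equal(simulate_sigmoid_trial(p0, cfg, seed = 1)$frequency, 0)
})

test_that("io_curve sweeps behave and expose tuft/basal asymmetry", {
  cv <- io_curve(bench, "tuft", sweep_counts = 260L, n_repeats = 50L,
                 seed = 3)
  expect_equal(nrow(cv), 1L)
  set.seed(4)
  f <- replicate(50, simulate_sigmoid_trial(
    bench, reduced_sim_config(n_basal = 200L, n_tuft = 260L))$frequency)
  expect_within_sem(cv$mean_freq, mean(f),
                    sqrt(cv$sem_freq^2 + var(f) / 50), k = 3)
  # monotone non-decreasing mean under a2>0, b2<0 (within 3 SEM)
  cv2 <- io_curve(bench, "tuft", sweep_counts = seq(200L, 300L, 25L),
                  n_repeats = 150L, seed = 5)
  d <- diff(cv2$mean_freq)
  tol <- 3 * sqrt(cv2$sem_freq[-1]^2 + cv2$sem_freq[-nrow(cv2)]^2)
  expect_true(all(d > -tol))
  # identical total input, different tuft/basal split differ when b2 != 0
  f1 <- expected_frequency(bench, 150, 250)
  f2 <- expected_frequency(bench, 250, 150)
  expect_gt(abs(f1 - f2), 1e-3)
})

test_that("genetic algorithm recovers curves from known parameters", {
  counts <- seq(200L, 300L, by = 10L)
  target <- rbind(
    data.frame(sweep = "tuft", count = counts,
               freq = expected_frequency(bench, 200L, counts)),
    data.frame(sweep = "basal", count = counts,
               freq = expected_frequency(bench, counts, 200L)))
  fit <- fit_sigmoid(target, seed = 17,
                     ga_config = list(generations = 200L))
  expect_lt(fit$loss / sum(abs(target$freq)), 0.05)
  expect_true(all(diff(fit$loss_trace) <= 0))
  expect_s3_class(fit, "sigmoid_fit")
  expect_length(coef(fit), 9L)
  expect_equal(length(predict(fit)), nrow(target))
  expect_equal(residuals(fit), predict(fit) - target$freq)
  sim <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(nrow(sim), 3L)
})

test_that("GA handles a degenerate all-zero target without crashing", {
  counts <- seq(200L, 300L, by = 20L)
  target <- rbind(data.frame(sweep = "tuft", count = counts, freq = 0),
                  data.frame(sweep = "basal", count = counts, freq = 0))
  fit <- fit_sigmoid(target, seed = 8, ga_config = list(generations = 60L))
  expect_lt(coef(fit)[["c1"]], 0.01)
  expect_lt(max(abs(predict(fit))), 0.5)
})

test_that("convergence is robust to the population size", {
  # both the default and a doubled population converge on the benchmark;
  # a larger population is never catastrophically worse
  counts <- seq(200L, 300L, by = 20L)
  target <- rbind(
    data.frame(sweep = "tuft", count = counts,
               freq = expected_frequency(bench, 200L, counts)),
    data.frame(sweep = "basal", count = counts,
               freq = expected_frequency(bench, counts, 200L)))
  mag <- sum(abs(target$freq))
  for (s in 1:3) {
    f1 <- fit_sigmoid(target, seed = s,
                      ga_config = list(generations = 120L, pop_size = 60L))
    f2 <- fit_sigmoid(target, seed = s,
                      ga_config = list(generations = 120L, pop_size = 120L))
    expect_lt(f1$loss / mag, 0.05)
    expect_lt(f2$loss / mag, 0.05)
  }
})

test_that("benchmark curves diverge with a more linear basal sweep", {
  counts <- seq(200L, 300L, by = 5L)
  ft <- expected_frequency(bench, 200L, counts)
  fb <- expected_frequency(bench, counts, 200L)
  gap <- abs(ft - fb)
  expect_gt(mean(gap[counts > 250]), mean(gap[counts <= 250]))
  expect_lt(max(abs(diff(diff(fb)))), max(abs(diff(diff(ft)))))
})
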
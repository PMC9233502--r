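test_that("dF/F uses a per-trial 5-s baseline", {
  p <- toy_protocol(n_trials = 2L)
  nf <- as.integer((p$pre_stimulus_window + p$span + 2.5) * 30)
  # trial 1: F0 = 10 with +5 transient; trial 2: F0 = 20, same transient
  tr <- rbind(rep(10, nf), rep(20, nf))
  tr[, 160:170] <- tr[, 160:170] + 5
  b <- roi_block(tr, 30, p, "tuft", units = "F")
  d <- compute_dff(b)
  expect_equal(d$units, "dff")
  expect_equal(max(d$trials[1, ]), 0.5)
  expect_equal(max(d$trials[2, ]), 0.25)
  expect_equal(d$trials[1, 1:150], rep(0, 150))
  # constant trace maps to all zeros
  bc <- roi_block(matrix(7, 2, nf), 30, p, "tuft", units = "F")
  expect_true(all(compute_dff(bc)$trials == 0))
})

test_that("dF/F errors name the offending trial and refuse bad inputs", {
  p <- toy_protocol(n_trials = 2L)
  nf <- as.integer((p$pre_stimulus_window + p$span + 2.5) * 30)
  tr <- rbind(rep(10, nf), rep(0, nf))
  b <- roi_block(tr, 30, p, "tuft", units = "F")
  expect_error(compute_dff(b), "trial 2")
  expect_error(compute_dff(compute_dff(roi_block(tr + 1, 30, p, "tuft",
                                                 units = "F"))),
               "raw fluorescence")
})

test_that("un-normalizing dF/F reproduces raw F to machine precision", {
  set.seed(3)
  p <- toy_protocol(n_trials = 3L)
  nf <- as.integer((p$pre_stimulus_window + p$span + 2.5) * 30)
  raw <- matrix(100 + rnorm(3 * nf, 0, 5), 3, nf)
  b <- roi_block(raw, 30, p, "tuft", units = "F")
  d <- compute_dff(b)
  f0 <- rowMeans(raw[, 1:150])
  back <- sweep(sweep(d$trials, 1, f0, "*"), 1, f0, "+")
  expect_equal(back, raw, tolerance = 1e-12)
})

test_that("Savitzky-Golay filter preserves quadratics and is linear", {
  x <- seq_len(60)
  quad <- 2 + 0.3 * x - 0.01 * x^2
  expect_equal(sg_smooth(quad)[4:57], quad[4:57], tolerance = 1e-10)
  expect_equal(sg_smooth(rep(5, 30)), rep(5, 30))
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(sg_smooth(2 * a + 3 * b), 2 * sg_smooth(a) + 3 * sg_smooth(b),
               tolerance = 1e-12)
})

test_that("impulse response equals the per-window least-squares fit", {
  # oracle: fit a quadratic to each 7-sample window of a unit impulse and
  # evaluate at the window centre
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- sg_smooth(imp)
  for (c0 in 8:14) {
    w <- (c0 - 3):(c0 + 3)
    fit <- lm(y ~ x + I(x^2), data = data.frame(x = w - c0, y = imp[w]))
    expect_equal(sm[c0], unname(coef(fit)[1]), tolerance = 1e-10)
  }
  expect_warning(sg_smooth(1:5), "unfiltered")
})

test_that("trial averaging, threshold and detection follow the 3xSD rule", {
  p <- toy_protocol(n_trials = 2L)
  tt <- toy_times(p)
  sig <- triangle_signal(tt, 0.2, 0.5, 1.5, 0.8)
  b <- toy_block(sig, n_trials = 2L)
  avg <- trial_average(b)
  expect_equal(avg$threshold, 3 * avg$baseline_sd)
  expect_equal(avg$baseline_sd, 0)           # noise-free baseline
  # single trial: identity up to smoothing
  b1 <- toy_block(sig, n_trials = 1L)
  expect_equal(trial_average(b1)$trace, sg_smooth(sig))
  # two opposite trials cancel
  tr <- rbind(sig, -sig)
  b2 <- roi_block(tr, 30, toy_protocol(2L), "tuft", units = "dff")
  expect_equal(max(abs(trial_average(b2)$trace)), 0)
})

test_that("pooled unsmoothed baseline SD tracks the noise SD", {
  # smoothing would shrink white noise SD by ~sqrt(3); the threshold is
  # anchored to the raw baseline variability instead
  set.seed(11)
  p <- toy_protocol(n_trials = 20L)
  nf <- length(toy_times(p))
  tr <- matrix(rnorm(20 * nf, 0, 0.1), 20, nf)
  b <- roi_block(tr, 30, p, "tuft", units = "dff")
  avg <- trial_average(b)
  expect_within_sem(avg$baseline_sd, 0.1, 0.1 * 0.2 / 2)  # within 20%
})

test_that("detection uses a strict threshold and reports first crossing", {
  p <- toy_protocol(1L)
  tt <- toy_times(p)
  flat <- toy_block(rep(0, length(tt)), 1L)
  expect_false(detect_response(trial_average(flat))$responsive)
  # evoked exactly equal to threshold everywhere: not responsive
  b <- toy_block(ifelse(tt >= 0 & tt <= 2, 0.3, 0), 1L)
  avg <- trial_average(b)
  avg$trace <- ifelse(tt >= 0 & tt <= 2, 0.3, 0)  # bypass smoothing ramp
  avg$baseline_sd <- 0.1; avg$threshold <- 0.3
  expect_false(detect_response(avg)$responsive)
  avg$trace[tt >= 0.5 & tt <= 1] <- 0.5
  det <- detect_response(avg)
  expect_true(det$responsive)
  expect_equal(det$onset_time, 0.5, tolerance = 2 / 30)
})

test_that("peak amplitude takes the maximum after the first crossing", {
  p <- toy_protocol(1L)
  tt <- toy_times(p)
  sig <- triangle_signal(tt, 0.2, 0.6, 1.2, 0.8)
  avg <- trial_average(toy_block(sig, 1L))
  avg$baseline_sd <- 0.1; avg$threshold <- 0.3
  expect_equal(peak_amplitude(avg), max(sg_smooth(sig)), tolerance = 1e-9)
  # two transients: the larger one wins
  sig2 <- triangle_signal(tt, 0.2, 0.5, 1.0, 0.5) +
    triangle_signal(tt, 2.0, 2.4, 2.9, 0.7)
  avg2 <- trial_average(toy_block(sig2, 1L))
  avg2$baseline_sd <- 0.1; avg2$threshold <- 0.3
  expect_equal(peak_amplitude(avg2), max(sg_smooth(sig2)), tolerance = 1e-9)
  # error on a non-responsive ROI
  avg$threshold <- 10; avg$baseline_sd <- 10 / 3
  expect_error(peak_amplitude(avg), "non-responsive")
})

test_that("normalized integral is amplitude-free and matches quadrature", {
  p <- toy_protocol(1L)
  tt <- toy_times(p)
  # rectangular pulse of duration 2 s: integral 2 regardless of height
  for (A in c(0.5, 3)) {
    avg <- structure(list(trace = ifelse(tt >= 0 & tt < 2, A, 0),
                          baseline_sd = 0, threshold = 0, frame_rate = 30,
                          protocol = p), class = "trial_avg")
    expect_equal(response_integral(avg), 2, tolerance = 0.05)
  }
  # triangular pulse, peak 1, base 1 s: area 0.5
  avg <- structure(list(trace = triangle_signal(tt, 0, 0.5, 1, 1),
                        baseline_sd = 0, threshold = 0, frame_rate = 30,
                        protocol = p), class = "trial_avg")
  expect_equal(response_integral(avg), 0.5, tolerance = 0.02)
  # peak-normalized kernel over the 6-s evoked window vs fine quadrature
  kern <- function(t) ifelse(t < 0, 0, exp(-t / 0.6) - exp(-t / 0.05))
  tp <- log(0.6 / 0.05) * 0.6 * 0.05 / (0.6 - 0.05)
  knorm <- function(t) kern(t) / kern(tp)
  fine <- seq(0, 6.5, by = 1e-4)
  oracle <- pracma::trapz(fine, knorm(fine) / max(knorm(fine)))
  avg <- structure(list(trace = knorm(tt), baseline_sd = 0, threshold = 0,
                        frame_rate = 30, protocol = p),
                   class = "trial_avg")
  expect_equal(response_integral(avg), oracle, tolerance = 0.01 * oracle)
  # invariance to positive scaling
  avg2 <- avg; avg2$trace <- 7.3 * avg$trace
  expect_equal(response_integral(avg2), response_integral(avg),
               tolerance = 1e-12)
})

test_that("peak amplitude is monotone under pointwise trace increase", {
  p <- toy_protocol(1L)
  tt <- toy_times(p)
  base <- triangle_signal(tt, 0.2, 0.8, 2, 0.6)
  avg <- structure(list(trace = base, baseline_sd = 0.05, threshold = 0.15,
                        frame_rate = 30, protocol = p), class = "trial_avg")
  bumped <- avg
  bumped$trace <- base + ifelse(tt >= 0 & tt <= 6.5, 0.1, 0)
  expect_gte(peak_amplitude(bumped), peak_amplitude(avg))
})

test_that("branch correlation is the mean recruited fraction over trials", {
  both <- matrix(TRUE, 2, 6)
  expect_equal(branch_correlation(both), 1)
  alternating <- rbind(c(TRUE, FALSE, TRUE, FALSE),
                       c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(branch_correlation(alternating), 0.5)
  expect_error(branch_correlation(matrix(TRUE, 1, 5)), "2 sister")
})
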
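# dendplast

Analysis pipelines and neuron models for studying how fear-learning
plasticity is compartmentalized between the apical **tuft** and **basal**
dendrites of cortical layer 2/3 pyramidal neurons.

After auditory fear conditioning, a conditioned tone train (CS+) evokes
larger Ca²⁺ responses than a neutral train (CS−) in tuft dendrites but not
in basal dendrites, and somatic firing increases without a change in the
subthreshold voltage — a pattern consistent with tuft input controlling
the neuron's input–output function. `dendplast` provides every
computational stage of such a study, plus a synthetic-data generator with
known ground truth so the whole chain is verifiable end to end:

- **Calcium pipeline** — frame registration by whole-frame
  cross-correlation, ROI extraction, per-trial ΔF/F = (F − F₀)/F₀,
  Savitzky–Golay smoothing (order 2, 7 samples), responder detection by a
  strict 3×SD-of-baseline rule, trial-averaged peak amplitude, the
  peak-normalized trapezoidal response integral, and sister-branch
  co-activity.
- **Ephys pipeline** — spike detection, spike-removed subthreshold
  envelopes, per-tone envelope integrals (mV·s), tone-window firing rates
  (Hz).
- **Behavior** — baseline-corrected freezing scores and the <30-point
  discrimination-exclusion filter.
- **Reduced neuron model** — the composite two-sigmoid model
  `M(t) = a₁ + a₂/(1 + e^{−(t−a₃)/a₄})`,
  `T(t) = b₁ + b₂/(1 + e^{−(t−b₃)/b₄})`,
  `F(b, t) = c₁ + M(t)/(1 + e^{−(b−T(t))})`,
  where tuft input t sets the maximum and threshold of the sigmoid
  converting basal input b into a firing rate; simulated as per-bin
  Poisson spiking over ten 50-ms bins and fitted with a genetic algorithm
  (`fit_sigmoid()`, a classed model with `coef`/`predict`/`simulate`/
  `plot` methods).
- **Biophysical model** — a reduced multicompartment pyramidal neuron
  (Rcpp cable integrator) with voltage-dependent NMDA
  (`g_max (e^{−t/70} − e^{−t/3})/(1 + 0.3 e^{−0.08v})`) and AMPA
  synapses, distance-graded tuft Ih, background drive, and the
  synapse-count → firing-rate sweeps that compare tuft and basal efficacy.
- **Exact tests** — Mann–Whitney and Wilcoxon signed-rank with full
  enumeration at small n, and the paired t test.

## Worked example

Simulate the responsive tuft population for both conditioned stimuli at
the study's sample sizes, run the calcium pipeline, and compare:

```r
library(dendplast)

cfg <- generator_defaults()
plus <- simulate_roi_trials(cfg, make_protocol("CS_PLUS"), 52, "tuft",
                            seed = 42, p_resp = 1)
minus <- simulate_roi_trials(cfg, make_protocol("CS_MINUS"), 46, "tuft",
                             seed = 43, p_resp = 1)
rp <- subset(analyze_roi_set(plus), responsive)
rm <- subset(analyze_roi_set(minus), responsive)
mean(rp$peak_amplitude)   # 0.79 (+- 0.05 SEM, n = 51)
mean(rm$peak_amplitude)   # 0.58 (+- 0.05 SEM, n = 37)
mann_whitney(rp$peak_amplitude, rm$peak_amplitude)
#> mann_whitney: statistic = 1335, p = 0.0009494 (normal approximation)
```

The CS+ population recovers the configured 0.74 ΔF/F ground truth within
sampling error, CS− recovers 0.58, and the rank test reports the CS+ >
CS− tuft contrast — the compartmentalization signature. Fitting the
composite sigmoid to curves generated from a known benchmark:

```r
counts <- seq(200, 300, 5)
truth <- benchmark_sigmoid_params()
target <- rbind(
  data.frame(sweep = "tuft", count = counts,
             freq = expected_frequency(truth, 200, counts)),
  data.frame(sweep = "basal", count = counts,
             freq = expected_frequency(truth, counts, 200)))
fit <- fit_sigmoid(target, seed = 99)
summary(fit)
#> Composite-sigmoid model fit (genetic algorithm)
#>   final loss: 0.06859 over 42 target points
#>   relative loss: 0.696% of target magnitude
```

A command-line interface exposes every stage
(`inst/exec/dendplast simulate|calcium|ephys|behavior|reduced-model|compartment-sweep|fit-ga|report`).

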
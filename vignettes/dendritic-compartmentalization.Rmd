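---
title: "Models and pipelines for compartmentalized dendritic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and pipelines for compartmentalized dendritic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendplast)
```

# Scope

`dendplast` implements the analysis and modelling toolchain for a class of
experiments on learning-related plasticity in the apical tuft versus basal
dendrites of cortical layer 2/3 pyramidal neurons: auditory fear
conditioning with a conditioned (CS+) and a neutral (CS−) tone train,
two-photon GCaMP6f imaging of single dendrites, in vivo whole-cell somatic
recordings (control and under NMDA-receptor block), and two neuron models —
a composite two-sigmoid abstraction and a reduced biophysical compartment
model — that connect tuft input changes to somatic firing. A synthetic-data
generator emulates the statistical structure of all of these recordings
with known ground truth, so every pipeline stage is testable end to end
without any experimental data.

# The calcium pipeline

Raw fluorescence is converted to relative change per trial,
$\Delta F/F = (F - F_0)/F_0$, with $F_0$ the mean over the 5 s (150 frames
at 30 Hz) before stimulus onset of that trial; a per-trial baseline cancels
slow drift and bleaching. Traces are smoothed with a second-order,
seven-sample Savitzky–Golay filter; edges are mirror-padded, which keeps
the filter linear and exactly preserves constants and (in the interior)
quadratics. The trial-averaged response is the pointwise mean over trials
(the filter is linear, so smoothing trials and smoothing the average are
identical).

**Detection threshold.** A dendrite is responsive when its trial-averaged
trace strictly exceeds three times the baseline SD inside the evoked
window. The baseline SD is defined as the SD of the *recorded* baseline
fluorescence: the unsmoothed single-trial $\Delta F/F$ samples over the 5-s
pre-stimulus window, pooled across trials (deviations from each trial's
baseline mean). This choice is deliberate and matters. If the SD is instead
taken on the trial-averaged, smoothed trace, the threshold shrinks with
$\sqrt{n_{\mathrm{trials}}}$ and with the filter's variance reduction until
it sits ~3 SD of the *same* process whose maximum is being tested; the
maximum of ~200 correlated samples then exceeds it in roughly a quarter of
pure-noise ROIs, and a ~20% responder fraction is unrecoverable. Anchored
to the recorded baseline variability, the rule is a meaningful classifier
at both granularities used here: the trial-average level for peak/integral
statistics, and the single-trial level (same rule, per-trial baseline SD)
for the event flags that enter the sister-branch co-activity statistic.

The evoked window runs from stimulus onset to the last tone offset plus a
2-s decay margin (GCaMP6f decay outlasts the final tone; the margin is
configurable). Crossings use a strict inequality, time zero is the first
tone onset, and frames are left-closed bins. The peak amplitude is the
maximum of the trial average between the first crossing and the end of the
window; the response integral is trapezoidal integration of the trial
average over the evoked window after division by the peak, so it is
amplitude-free (units of seconds, conventionally written ΔF/F·s); negative
excursions are included as-is. Whether the peak is taken on the smoothed or
raw average is not fully determined by the source methods; the smoothed
average is used throughout.

**Registration.** Frames are aligned by the integer shift maximizing
whole-frame cross-correlation with a reference image. The reference is the
mean of the contiguous 67-frame (~2.2 s) window with minimal mean
frame-to-frame displacement — a minimal-motion epoch — since a
threshold-based description of "minimal drift" is ambiguous. Registration
is integer-pixel only; shifts are defined relative to the chosen reference,
so a movie with no static epoch is recovered up to a constant offset
(relative shifts are exact). Sub-pixel refinement is out of scope.

**Sister branches.** Co-activity of a neuron's sister tuft branches is the
per-trial fraction of branches showing a transient, averaged over trials.
The generator gives every trial a neuron-wide event that recruits each
branch independently with probability $q$ (the ground-truth co-activity),
plus rare branch-local events (0.01 events/s); this makes the recovered
statistic equal $q$ up to the local-event and detection corrections.

# The synthetic calcium generator and its calibration

A responder dendrite's transient is a peak-normalized difference of
exponentials $e^{-t/\tau_d} - e^{-t/\tau_r}$ with $\tau_r$ = 50 ms, one
kernel per tone onset; this family is standard for GCaMP kinetics and
analytically convenient. On each trial a responder responds with
probability 0.6 with lognormal amplitude jitter (sdlog 0.2, mean 1) —
values chosen to give trial-to-trial variability resembling published
single-dendrite heatmaps while keeping trial-averaged statistics
controlled. Gaussian white frame noise has SD 0.1 ΔF/F, a typical
dendritic GCaMP6f noise level at 30 Hz. Exactly
$\lceil p_\mathrm{resp} \cdot n \rceil$ of the candidate ROIs are
responders; default responder fractions are 0.20 (CS+) and 0.18 (CS−).

Each condition (compartment × stimulus) is defined by three anchors: the
trial-averaged peak, the normalized integral, and the between-dendrite SEM
of the peak at the condition's sample size. `calibrate_kernel()` finds
$\tau_d$ and the kernel amplitude such that the *expectation of the
pipeline's estimators* — peak and normalized integral of the smoothed
trial average over responsive ROIs, under the full noise, response and
jitter model — equals the target pair. The expectation is computed by a
deterministic internal Monte Carlo (fixed seed, common random numbers),
which collapses to the noise-free forward calculation in the deterministic
limit; calibrating the estimator rather than the noise-free trace removes
the small positive bias of a max statistic over a noisy average (and the
corresponding negative bias of the peak-normalized integral), which would
otherwise exceed the ±2 SEM recovery band for the tightly concentrated
integral. The printed SEM is converted into per-ROI lognormal amplitude
heterogeneity by removing the within-ROI trial-averaging component in
quadrature. This dispersion is what makes the inferential pattern
reproducible: with it, the CS+/CS− contrast in tuft peaks is significant
under a Mann–Whitney test at the study's sample sizes while the basal
contrast is not, exactly as in the modelled experiments. Dispersion of the
normalized integral is *not* emulated — the kernel family concentrates it
far more tightly than real shape heterogeneity would — so integral SEMs
should not be compared against experimental ones.

What the generator does not emulate: slow baseline drift, bleaching,
spontaneous (non-evoked) transients, neuropil contamination, shape
heterogeneity across dendrites, or correlated noise. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated stochastic model, not robustness to every artefact of real imaging.

# Somatic voltage analysis and generator

Spikes are upward crossings of −20 mV with a 2-ms refractory separation
(the source reports spike counts without stating criteria). The
subthreshold envelope removes samples within ±2 ms of each spike by linear
interpolation between window edges, merging overlaps. The per-tone
subthreshold response is the trapezoidal integral of (envelope − rest)
over each 500-ms tone window, with rest the per-trial mean over 1 s before
stimulus onset (a per-trial baseline cancels drift). The quantity is an
integral of voltage over time and is implemented in mV·s, although the
field sometimes prints mV/s for it. The tone-window firing rate divides
the total spike count in all tone windows by total tone-window time
(`n_trials × n_tones × 0.5 s`), reconciling a per-trial count definition
with units of Hz; the raw per-trial count is available behind
`per_trial_count = TRUE`.

The voltage generator uses a half-sine depolarizing envelope per tone with
configured area (CS+ 1.20, CS− 1.18 mV·s), Poisson spikes inside tone
windows at the configured condition rates (control 0.53/0.44 Hz; NMDA
block 0.06/0.07 Hz with a suppressed envelope), a 2-ms
triangular-exponential spike template (+80 mV; shape only needs to be
detectable), 0.3 mV recording noise, and a 0.2 Hz spontaneous rate outside
tone windows (the depolarizing holding current used experimentally is
emulated only through this nonzero baseline rate). Per-cell lognormal
scalings of envelope (sdlog 0.30) and rate (CV 0.25) reproduce the
between-cell spread implied by the reported SEMs; scalings are derived
from the seed so that CS+ and CS− calls with the same seed describe the
same cells, emulating the paired within-cell design — the cell factors
then cancel in paired comparisons, which is why the Wilcoxon signed-rank
test on rates retains its sensitivity.

# Behavior

The freezing score per condition is the mean over eight presentations of
(presentation % − baseline %), floored at zero (freezing below the 2-min
habituation baseline is noise). Mice with a CS+ − CS− difference strictly
below 30 percentage points are excluded; exactly 30 is included. The
generator draws mouse-level effects (SD 9.7) and presentation noise (SD
10) around the configured corrected means (68.5% / 12.3%), truncated to
[0, 100]; the implied score SD (~10.4) matches the reported group SEM at
n = 20.

# The composite-sigmoid reduced model

Tuft input $t$ sets the maximum and threshold of a basal sigmoid through

$$M(t) = a_1 + \frac{a_2}{1 + e^{-(t - a_3)/a_4}}, \qquad
  T(t) = b_1 + \frac{b_2}{1 + e^{-(t - b_3)/b_4}},$$

$$F(b, t) = c_1 + \frac{M(t)}{1 + e^{-(b - T(t))}},$$

with $F$ the expected spike count per bin and $c_1$ the baseline rate. The
500-ms stimulus is split into ten 50-ms half-open bins; each synapse gets
a uniform time on [0, 500) ms and $b_k, t_k$ are per-bin counts. "Poisson
probability" is read as the Poisson *mean* per bin with unbounded counts —
a Bernoulli-per-bin reading would cap output at 20 Hz and make a baseline
rate parameter meaningless. Parameters yielding a negative rate anywhere
are rejected with infinite loss during fitting, never clamped.

`expected_frequency()` is the deterministic curve with per-bin counts
replaced by their means ($n/10$); because $F$ is nonlinear, the Monte
Carlo mean over random binnings differs from this plug-in value (a Jensen
gap that can be substantial near threshold), so the plug-in curve is used
consistently as the fitting objective on both sides, and the invariant
"mean simulated frequency equals the per-bin rate sum" is always stated
conditional on the drawn bins.

The genetic algorithm is real-coded: population 120, tournament selection
(k = 3), uniform crossover (p = 0.5), per-gene mutation probability 0.4
with Gaussian SD annealing geometrically from 10% to 0.5% of each
parameter's search range, elitism 2, 300 generations, explicit seed; bounds
ship with `default_sigmoid_bounds()`. Annealing is what brings
self-recovery of a known benchmark below 1% relative loss — a fixed 10%
mutation plateaus an order of magnitude higher. The per-generation best
loss is non-increasing by elitism. `benchmark_sigmoid_params()` is a fixed
parameter set whose tuft sweep is steeper and more strongly curved than
the nearly linear basal sweep, with the curves diverging over the upper
half of the 200–300 synapse range — the qualitative geometry the reduced
model is meant to capture.

# The reduced compartment model

The morphology is a stylized tree: a 20-µm soma, four 150-µm basal
branches (1.2 µm), a 300-µm apical trunk (2 µm), and four 150-µm tuft
branches (0.8 µm), in 25-µm segments; thin tuft branches give the tuft the
high local input impedance that underlies its synaptic nonlinearity. Axial
resistivity is 150 Ω·cm and capacitance 1 µF/cm². The leak density default
is 3·10⁻⁴ S/cm², an in-vivo high-conductance operating point: with the
prescribed 75 background synapses (1 nS, per-synapse Poisson rates drawn
once uniform on 10–100 Hz — the fixed-rate reading of "randomly activated
between 10 and 100 Hz"), a quiet-state leak lets the accumulating NMDA
conductance regeneratively pin the whole cell at the synaptic reversal,
because the reduced model deliberately omits the repolarizing potassium
and SK conductances of full biophysical models. Two further choices keep
the model in a fluctuation-driven regime: each synapse's conductance
saturates at its stated maximum under repeated activation, and the somatic
spike mechanism has a 2-ms absolute refractory period.

Synapses combine a voltage-dependent NMDA conductance
$g_{\mathrm{NMDA}} = g_{\max}\,(e^{-t/70} - e^{-t/3})/(1 + 0.3\,e^{-0.08 v})$
(t in ms, v in mV) and an AMPA conductance with instantaneous rise and
0.5-ms decay, at a 1:1 maximal-conductance ratio and 0 mV reversal.
Stimulus synapses are placed uniformly over the target region's length and
fire exactly once at a uniform time in the 500-ms window. The tuft carries
an Ih conductance whose relative density follows
$\max(0,\, -0.8696 + 2.087\,e^{x/323})$ of distance x (µm) from the soma,
with a first-order activation gate (midpoint −82 mV, slope 7 mV, τ 50 ms,
reversal −45 mV). Somatic spiking is adaptive exponential
integrate-and-fire (ΔT 2 mV, soft threshold −49 mV, reset −55 mV,
adaptation a = 2 nS, b = 40 pA, τ_w = 150 ms) — a deliberate simplification
in place of a ten-conductance channel set whose values are not available;
its f–I characteristics are an extension point, not a calibrated claim.

Integration is semi-implicit with a Hines-ordered O(n) tree solve per
step: leak and axial coupling are implicit, synaptic and Ih conductances
enter the diagonal with gating evaluated at the previous step, and the
AdEx terms are explicit; dt defaults to 0.025 ms, and |v| > 200 mV aborts
with a diagnostic. A passive single-compartment reduction reproduces the
analytic RC charging curve to 0.02%, and halving dt moves the somatic
trace by well under 0.5 mV on a fixed synaptic ensemble.

The stimulus conductance default (0.5 nS) places the 200–300-synapse
sweeps at output rates of roughly 1–6 Hz. This is above the ~0.5 Hz
evoked rates of the modelled recordings: with the reference morphology and
channel table unavailable, the model is property-level — it is asked to
reproduce orderings (firing rate monotone in synapse count; fewer tuft
than basal synapses needed to reach a common target rate; NMDA block
suppressing rates; a steeper, diverging tuft sweep), not absolute synapse
counts, which are explicitly out of scope.

# Exact nonparametric tests

`mann_whitney()` and `wilcoxon_signed_rank()` use midranks for ties and
full enumeration (all labelings, all sign patterns) for up to 12
observations, with tie-corrected normal approximations beyond; two-sided
p-values double the smaller tail, capped at 1. Zero differences are
dropped in the signed-rank test (the original convention). `paired_t()`
is the standard paired statistic against the t distribution. Exact
branches are verified against independently coded enumeration oracles and
the reference implementations where those are exact.

# Problem sizes

The validation suite runs the recovery harness at the modelled study's
sample sizes — 52/46 tuft and 56/61 basal dendrites × 20 trials, 13 cells
× 20 trials, 20 mice, 100 candidate ROIs, 30 neurons with 2–4 sister
branches — and the model checks at 10 000 Poisson repeats, 30 repeats per
sweep point over 200–300 synapses in steps of 25, and 5 000 null datasets
for test size. These sizes were chosen to make sampling tolerances
(±2 SEM, 3 Poisson SE, ±5 percentage points, ±0.05) meaningful while
keeping a full run in a few minutes on one core.

# Known limitations

The generator's fidelity is statistical, not biophysical: transients are
a fixed kernel family, noise is white, and non-evoked activity is absent.
The compartment model's absolute rates and synapse counts are not
calibrated to any reconstructed neuron. The registration module is
integer-pixel and assumes a low-motion epoch exists. The exact-test
cutoff (12) keeps enumeration cheap; beyond it the normal approximation
is used even when enumeration would still be feasible.
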
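---
title: "Methods: spike-train connectivity and motor-pattern analysis in gaspnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train connectivity and motor-pattern analysis in gaspnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

gaspnet analyzes simultaneously recorded brainstem neuron spike trains and
respiratory motor signals of the kind collected from the ventral
respiratory column (VRC), medullary raphe and pontine respiratory group in
vivo: firing-pattern classification against the respiratory cycle,
pairwise short-timescale functional-connectivity screening, motor-pattern
segmentation of the integrated phrenic signal under hypoxia, and assembly
of directed correlation feature maps. Because such recordings are rarely
public, the package ships a generator that produces whole sessions with
known ground truth, and every stage is validated by parameter and
structure recovery against it. This vignette explains the models, the
tunable parameters, the numerical choices, and what the validation does
and does not show.

## Respiratory cycle-triggered histograms and pattern classes

A cycle-triggered histogram (CTH) maps each spike to normalized
respiratory phase — inspiration (I) linearly onto [0, 0.5), expiration
(E) onto [0.5, 1) — and divides per-bin spike counts by the real time the
bin spans, summed over cycles. The phase map gives both phases equal
visual weight regardless of the actual I:E duration ratio, matching how
phase-normalized CTHs are conventionally drawn; the rate normalization
removes the resulting occupancy bias. CTHs are individually scaled to
their maximum rate for display. The default resolution is 25 bins per
phase (`cth_bins_per_phase`), enough to resolve in which half of a phase
the peak falls at the cycle counts the generator produces.

A neuron is *respiratory modulated* if either of two complementary tests
rejects at level `alpha_cth` (default 0.05):

* **Test A (parametric).** A Pearson chi-square test of rate homogeneity
  across phase bins, with counts pooled over cycles and the null
  expectation proportional to each bin's summed time span. The
  span-proportional expectation matters: with unequal I and E durations a
  time-homogeneous train is *not* phase-uniform, and a test against a
  uniform phase expectation would reject every unmodulated neuron.
* **Test B (randomization).** Each cycle's spikes are rotated by an
  independent uniform circular shift *in time within the cycle*, phases
  are recomputed, and the statistic is the variance of the pooled phase
  histogram; `p = (1 + #{surrogate >= observed})/(n_shuffles + 1)`.
  Rotating in time (rather than in mapped phase) is exactly
  distribution-preserving under the null even when the phase map is
  nonlinear in time, which keeps the test calibrated. Under a
  homogeneous Poisson null both tests hold their level (measured 3.5–5%
  at nominal 5% over hundreds of simulations).

Modulated neurons are classified I or E by the phase half containing the
maximum bin (ties toward the earlier bin, for determinism), and Aug/Dec by
whether the within-phase peak falls in the second or first half of that
phase — the augmenting/decrementing dichotomy used for respiratory
neurons. A neuron is *phasic* if any smoothed (5-bin cyclic moving average) bin
rate falls below `max(0.05 * peak rate, 0.5 spikes/s)` — "firing
probability essentially zero" somewhere in the cycle — and *tonic*
otherwise. Post-inspiratory profiles are treated as decrementing
expiratory (E-Dec); they are not given a separate label.

## Cross-correlogram screening with gamma-ISI surrogates

The cross-correlogram counts target spikes at signed lags relative to
every reference spike (positive lag = target after reference), in
half-open bins of `corr_bin_width` (0.5 ms) across `± corr_window`
(50 ms). These defaults resolve the 1–5 ms latencies typical of
paucisynaptic interactions while keeping the Monte Carlo affordable.

Significance uses surrogate spike trains with gamma-distributed
interspike intervals (ISIs). The shape parameter is estimated from the
data by the method of moments, `k = mean(ISI)^2/var(ISI)`, clipped to
[0.05, 100], **on pause-excluded ISIs** (those not exceeding 10× the
median ISI): for phasic respiratory or burst-firing cells, silent-phase
pauses otherwise dominate the variance and drive the fit to absurd
overdispersion that has nothing to do with the within-activity renewal
statistics the surrogate should reproduce. For a stationary train the
exclusion is negligible (0.1% of exponential ISIs), so the estimator
retains its stated behaviour (shape 1 for Poisson trains, consistent
recovery of simulated shapes). The scale uses the mean of *all* ISIs, so
surrogates match the recorded rate. Both trains of a pair are surrogated,
destroying all correlation under the null while preserving each train's
rate and ISI dispersion.

Two numerical choices keep the feature statistics honest:

* **Background subtraction.** Neurons sharing the respiratory rhythm
  co-modulate over hundreds of milliseconds, which lifts or tilts the
  whole ±50 ms correlogram relative to an ISI-surrogate null. Features of
  interest are millisecond-scale departures *from that background*, so a
  running-median background (window `corr_background`, default 25 ms) is
  subtracted from the observed and from every surrogate correlogram
  before any statistic is formed. The window must be much wider than
  genuine features (couplings span a few ms; a central common-drive peak
  spans up to ~±3 ms) and much narrower than rhythm-scale co-modulation;
  25 ms satisfies both with margin. The median (not a mean) is used so
  strong features do not bleed into their own background estimate.
* **Edge guard.** Within half a background window of the correlogram
  edge the running median is estimated from a truncated window;
  candidate features whose extremum falls there are discarded as
  unreliable.

A candidate feature is a maximal run of ≥2 consecutive bins outside the
pointwise 2.5/97.5 percentile surrogate band, same side. The
detectability index (DI) is the extremum departure divided by the
standard deviation of the observed residuals outside all candidate
extents ("correlogram noise"); DI ≥ 3 (`di_threshold`) marks a
significant feature. The feature's Monte Carlo p-value is the p-value of
its DI: it is compared with each surrogate's own maximum *studentized*
departure over all bins in that sign — a max-statistic correction for
scanning 201 bins. Studentizing both sides matters: cycle-locked
co-modulation overdisperses the observed correlogram bins relative to
renewal surrogates, and a raw-departure comparison is then
systematically anticonservative for sharply phase-locked pairs, whereas
the departure-to-noise ratio is close to pivotal. Feature extents containing
lag 0 are *central* (shared-input signature); others are *offset*
(excitation for peaks, inhibition for troughs, directed source→target)
and are reported with positive lag, swapping the reference/target roles
when needed.

Across all pairs, each pair's evidence is pooled as its minimum feature
p-value (1 if featureless) and Benjamini–Hochberg FDR control is applied
at `fdr_q` (0.05); an edge requires BH survival of its pair, a
feature p-value below the BH threshold, and DI ≥ 3. With
`n_surrogates` surrogate pairs the smallest attainable p-value is
`1/(n_surrogates + 1)`, which bounds how many pairs BH can ever reject —
screens of many pairs need enough surrogates (the connection-recovery
validation uses 400 for 190 pairs; the false-positive calibration uses
200, the floor for inference).

## Motor-pattern segmentation

Inspiratory onsets are upward crossings of `theta_on` on a 50 ms
moving-average copy of the integrated phrenic signal, expiratory onsets
the subsequent downward crossings of `theta_off < theta_on` (hysteresis);
thresholds derive from control-window baseline and peak percentiles via
`k_on` (0.2) and `k_off` (0.1). Per-cycle features are compared with
control statistics: augmentation = amplitude or frequency above the
control mean by `z_augment` (2) SDs for `n_consec` (3) consecutive
cycles; apneusis = inspiratory duration beyond `a_apneusis` (2)× the
control median; apnea = silence longer than max(2× control median cycle,
`t_apnea_floor` = 5 s); a gasp = a burst during/after apnea with
time-to-peak < `f_gasp` (0.25) of its duration (decrementing shape) and
duration below the control median inspiratory duration; a sigh
(augmented burst) = an isolated late-inspiratory peak beyond `s_sigh`
(1.5)× its *neighbours'* median peak. Judging sighs against neighbouring
cycles rather than the control median keeps epoch-wide amplitude gains
(augmentation) from flagging every cycle; an augmented breath during
depression, with its late peak and long rise, is never a gasp. Silences
between consecutive gasps of one quasiperiodic episode are part of the
gasping epoch, not separate apneas. Epochs tile the analyzed window, each
extending to the start of the next; normal cycles before the first
disturbance are control, after it recovery.

Blood-pressure steps are sustained rises of ≥ `bp_step_height` (5 mmHg)
achieved within `bp_step_window` (2 s) on a median-filtered trace; the
coincidence count is the number of gasps with a step within 2 s. A neuron
is gasp-synchronous if its rate within ±`sync_halfwidth` (0.5 s) of at
least half the gasp onsets exceeds `q_sync` (3)× its session-median rate;
the synchrony table carries each such neuron's control pattern class, so
recruitment of non-inspiratory cells into gasping is visible.

## Spike-triggered averages

The STA averages the full-wave-rectified signal (`|x − median|`; recorded
nerve signals carry DC offsets) around every trigger spike over
±`sta_window` (100 ms), excluding and counting triggers without full
coverage. Significance re-uses the correlogram machinery — gamma-ISI
surrogate triggers, running-median detrending, pointwise bands,
max-statistic p-values, DI — and flags a significant offset peak at
positive lag as premotor-consistent, an offset trough as
inhibition-consistent.

## The synthetic generator

The generator emulates the recorded preparation at the level the analysis
sees, not biophysically. Respiratory-phase-locked intensity profiles are
raised-cosine half-waves per phase (augmenting `sin^2(pi u/2)`,
decrementing its mirror), with modulation depth `depth`, a tonic floor
`base_rate (1 − depth)` outside the preferred phase (zero for phasic
cells), and time-average `base_rate` within it. The scripted hypoxia
sequence (control 300 s → augmentation 60 s → apneusis with three sighs
60 s → apnea 30 s → gasping 60 s → recovery 120 s, in the bundled
scenario) scales amplitude/frequency/inspiratory duration per epoch,
suppresses phase-locked firing during apnea and gasping, and adds
decrementing burst envelopes (instant rise, 100 ms decay, 400 ms
duration, peak 200 spikes/s) at quasiperiodic gasp times (5 ± 1 s) for
gasp-participating cells. Cat-like control timing is used (I = 1.0 s,
E = 1.5 s, ~2% jitter). A gasp-only class is silent during control and
recruited during gasping. Blood pressure is baseline plus slow drift and
noise, with an 8 mmHg step at each gasp relaxing with a 30 s time
constant — large enough to detect above the 5 mmHg criterion, slow enough
that successive steps remain distinct. Phrenic bursts rise abruptly to
30% of their peak then augment as `u^1.5`, decaying with a 10 ms constant
at expiratory onset; the abrupt onset and fast decay keep
threshold-crossing cycle boundaries within ~50 ms of truth, as sharp
inspiratory onsets do in real integrated phrenic records.

Pairwise coupling multiplies the target intensity by `strength` over
`[latency, latency + kernel_width]` after each realized source spike
(compounding multiplicatively when kernels overlap), so inhibition is
bounded at zero and the process remains a valid point process. Sampling
is by exact thinning of a dominating Poisson candidate stream, vectorized
in topological order over the coupling graph; cyclic graphs (reciprocal
excitation) fall back to a sequential event walk in global time order.
The thinning bound uses `strength^2` per incoming excitatory connection
(two overlapping kernels); with ≥3 overlapping source spikes in one
kernel window — probability ~1e-5 at the default rates — the acceptance
probability saturates at 1, a negligible bias. Each neuron draws from an
RNG stream keyed by its id, so adding a neuron never perturbs the others'
spikes and identical (configuration, seed) reproduce sessions exactly.
Common drives are latent Poisson sources (rate 25/s, kernel 3 ms, share
factor 6 by default) wired excitatorily to all members — strong enough
that member pairs show the central-peak signature the screening is meant
to find. The bundled default scenario carries connections only: the
drive-induced burst clustering in member trains departs from the renewal
statistics the gamma-ISI surrogate assumes and would confound the
connection-recovery benchmark, so the shared-drive signature is
validated with dedicated stationary pair fixtures instead.

What the generator does **not** emulate: biophysical dynamics, spike
sorting artefacts, electrode drift, bursting ISI structure beyond what
phase-locking induces, closed-loop chemoreflex feedback, and baroreflex
coupling between blood pressure and the network. Recovery results
therefore validate the *pipeline's statistics and logic*, not its
robustness to every failure mode of in vivo data.

## Validation scale and results computed

The shipped test-suite benchmarks use: 50 replicates × 100 independent
Poisson pairs (10 spikes/s, 300 s, 200 surrogates) for false-positive
calibration of the full screening procedure; the bundled 20-neuron
scenario with 12 injected connections over 10 seeds (400 surrogates, 190
pairs each) for connectivity recovery — requiring ≥80% of connections
recovered with correct sign and extremum lag inside the injected kernel
window, and no edges among pairs that share no injected source in ≥9/10
seeds. The recovery screen runs over the whole record; the studentized
max-statistic keeps the gasp-epoch burst firing (which a renewal
surrogate cannot represent in raw counts) from generating spurious
edges, and `spliceSession()` remains available for screening defined
record segments (e.g. only the quasi-eupneic epochs, or only the
hypoxic response). Pairs that jointly participate in the scripted gasp
drive are genuinely co-driven, so edges among them are assessed as
shared-input detections, not false positives. Class recovery uses 200
generated neurons (depth 0.8, 100 cycles) for ≥95%
CTH class recovery plus 500 null simulations per modulation test; exact
brute-force oracles for correlogram counts and CTH rates; and the
scripted hypoxia scenario plus 100 control-only records for segmentation,
gasp specificity, and blood-pressure-step/gasp coincidence. These sizes
make the whole suite run in tens of minutes on one core while leaving the
statistical assertions well-powered.

## Known limitations

* The gamma-ISI surrogate is a renewal null; for strongly nonstationary
  trains (gasp-only cells, deep phasic silence) it is only an
  approximation, mitigated — not eliminated — by the pause-excluded shape
  fit and background subtraction. Pairs of cells co-recruited by the
  same scripted drive are flagged by design; interpreting such central
  features as shared input rather than direct coupling is the analyst's
  task, as it is with real data.
* Epoch labels are rule-based operationalizations of patterns that
  experts label by inspection; the thresholds are config-exposed, and
  boundary placement is only as good as burst detection.
* BH is applied to per-pair minimum p-values; with a small surrogate
  count the attainable p-value floor limits how many pairs can be
  declared significant in large screens.
* Directedness of offset features is the conventional interpretation of
  correlogram asymmetry; it is not causal inference.
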
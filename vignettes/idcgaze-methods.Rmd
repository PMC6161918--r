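---
title: "Methods: eye-tracking markers of internally directed cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye-tracking markers of internally directed cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idcgaze)
```

# Scope and model

`idcgaze` analyses binocular 250 Hz eye-tracking recordings from paradigms
that contrast externally directed cognition (reading stimuli at fixation)
with internally directed cognition (mental arithmetic), optionally under
expected visual distraction. The pipeline has five stages — preprocessing,
ocular-event detection, parameter extraction, trial filtering, inference —
plus a synthetic-recording generator used to validate all of them.

This vignette documents the assumptions, the tunable parameters and the
numerical choices, in particular every place where the design was
genuinely open and the package had to commit to one convention.

# Preprocessing

Blinks are defined as maximal runs of at least `blink_min_run = 3`
consecutive samples (12 ms at 250 Hz) in which the pupil of *either* eye is
invalid. The 3-sample minimum rejects isolated dropped samples that
trackers occasionally emit; it is configurable. Each blink is masked with
`blink_pad_samples = 2` extra samples (8 ms) on both sides, because lid
closure distorts pupil and gaze estimates shortly before and after the
detectable blink.

Range exclusion flags pupil diameters outside [1.8, 15] mm in either eye
and absolute fixation disparities above 60 mm (the mean inter-pupil
distance): such values are physically impossible and indicate measurement
error. The per-participant rule then flags samples more than
`sd_multiplier = 3` SD from the participant's mean, computed separately
for pupil and disparity *after* blink masking and range exclusion, over
the participant's whole session. Computing the statistics after blink
masking is a commitment the package makes explicitly; computing them
before would let blink artifacts inflate the SD and hide true outliers.

Masked samples are dropped from all later computations, never
interpolated: interpolation would manufacture data inside the very
intervals known to be corrupted.

Discard rates are reported as two percentages on deliberately disjoint
denominators — blink discard as a share of all samples, range/SD discard
as a share of the samples that survived blink masking — so the two
artifact classes can be tracked independently.

# Event detection

Velocity is estimated with the 5-point moving-average differentiator
$v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6\,\Delta t)$, which is
exact on linear position signals and attenuates sample-to-sample noise.
Velocity is undefined on the two samples at each segment edge and wherever
the 5-sample window touches a masked sample, so detected events can never
span a blink.

The detection threshold is elliptic and median-based: per velocity
component, $\sigma^2 = \mathrm{median}(v^2) - \mathrm{median}(v)^2$ and
$\eta = \lambda\sigma$ with $\lambda = 6$; a sample is saccadic when
$(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$, strictly — samples exactly at
threshold are sub-threshold. The median-based estimator is robust to the
saccades themselves, which inflate a plain SD. Thresholds are estimated
**per trial and per eye**; whether a single recording session or each
trial should supply the estimation window is genuinely open, and per-trial
estimation is the convention of the established velocity-threshold
toolboxes, adapts to slow drifts in noise level, and keeps trials
statistically independent.

Supra-threshold runs of at least `min_duration_samples = 2` (8 ms) become
monocular events. Amplitude is the start-to-end displacement (not path
length), again the toolbox convention. Binocular events are left-eye
events overlapping a right-eye event by at least one sample; the merged
event spans the union of the two intervals (the package's choice; the
alternative, intersection, discards real event time) and takes the mean of
the two eyes' amplitudes. Events with amplitude ≤ 1.5° are classified as
microsaccades, the boundary being inclusive.

# Eye parameters and baselines

Six parameters are computed per trial in four contiguous 500 ms bins
relative to calculation onset, the first bin covering operand reading
(it starts 100 ms after first-operand onset so that all bins have equal
width). Bin membership is by event *onset* in half-open intervals
$[\mathrm{start}, \mathrm{end})$; onset-based counting with half-open
bins guarantees each event is counted exactly once.

* **Rates** (blink, saccade, microsaccade): onset count × 2 → Hz.
* **Fixation disparity**: median over eligible samples of right-minus-left
  horizontal gaze, in screen mm (531 mm / 1920 px pitch, configurable);
  negative = convergent.
* **Pupil diameter**: median of the binocular-mean pupil over eligible
  samples. The binocular mean is the package's combination rule for the
  two eyes' pupils; the single-valued convention is standard and the
  choice is inconsequential for baseline-corrected analyses.
* **Gaze at center**: % of samples whose *cyclopean* gaze (binocular mean)
  lies within 1° of screen center. The denominator is the full bin count
  (125 samples) including masked samples; masked samples can never enter
  the numerator. Cyclopean gaze is used wherever the two eyes must be
  reduced to one position.

"Eligible" for the continuous parameters means: valid under the mask and
outside every blink, saccade and microsaccade interval — pupil estimates
during saccades are distorted by the moving eye.

Baselines are trial-wise and subtractive. Pupil and disparity use the
median of the 500 ms window preceding first-operand onset. Because
blinks and saccades are rare (1–2 per second), a 500 ms window would give
unstable rate baselines, so the rates and gaze-at-center use the full 2 s
sign-presentation window (count/2 → Hz). Bins with no eligible samples,
and trials whose baseline window is empty, propagate as missing and are
handled listwise in the statistics, never zero-filled.

Distractor-locked epochs re-anchor the same six parameters to distractor
onset (window −500 to +1000 ms, 500 ms bins) with the 500 ms pre-distractor
window as baseline.

# Trial filtering

Analysis retains correct, non-catch multiplication trials whose response
time lies within 3 SD of the participant's mean RT, the mean and SD being
computed over correct non-catch multiplication trials pooled across both
blocks (a per-block rule would halve the estimation sample for no gain).
Catch trials — distractor onset at 1.0 s, included only to sustain
distractor expectation inside the analysis window — are excluded from eye
analyses but kept in the performance percentages, which are reported per
block over all multiplication trials. Passive-viewing trials are pooled
across the two blocks into a single condition cell; participants who
answered any passive trial with a number (i.e. calculated instead of
viewing) are excluded wholesale, since their passive cell no longer
reflects passive viewing.

# Inference

`paired_t` is the classical paired t test with
$d_z = t/\sqrt{n}$ and Bonferroni correction $p_{corr} = \min(1, k\,p)$.

`jzs_bf_ttest` computes the JZS default Bayes factor from $t$ and $n$: a
Cauchy prior with scale $r = 0.707$ ($\sqrt{2}/2$, the "medium" default)
on the standardized effect size, expressed as a normal scale mixture over
the relative prior variance $g$ and integrated numerically:
$$\mathrm{BF}_{10} = \frac{\int_0^\infty (1+Ngr^2)^{-1/2}
  \bigl(1+\tfrac{t^2}{(1+Ngr^2)\nu}\bigr)^{-(\nu+1)/2}
  (2\pi)^{-1/2} g^{-3/2} e^{-1/(2g)}\,dg}
 {\bigl(1+\tfrac{t^2}{\nu}\bigr)^{-(\nu+1)/2}}, \qquad \nu = N-1.$$
The integrand is evaluated on the log scale relative to the null
likelihood (numerically essential for large $|t|$, where both likelihoods
underflow) and integrated by adaptive quadrature to a relative tolerance
of $10^{-6}$; the test suite checks agreement with a 200 001-node
fine-grid quadrature to $10^{-4}$ relative error. The result is invariant
to the sign of $t$.

`rm_anova_2way` is a fully within-subject two-factor ANOVA by direct
sums-of-squares decomposition, each effect tested against its own
subject-by-effect stratum with uncorrected degrees of freedom (the
convention of the common within-subject ANOVA tools; a sphericity
correction is deliberately not applied by default). The reported effect
size is *generalized* eta squared,
$\eta^2_G = SS_{effect} / (SS_{effect} + SS_{subjects} + \sum SS_{error})$,
the variant appropriate for within-subject designs; plain $\eta^2$ would
not be comparable across designs. Participants with incomplete cells are
removed listwise. ANOVA-level Bayes factors are not provided: the
reference implementations are Monte-Carlo and not exactly reproducible,
and the package restricts itself to quantities it can compute
deterministically.

Power for the paired t test is exact under the noncentral t distribution:
$\mathrm{power} = P(|T'| > t_{crit})$ with $df = n-1$ and noncentrality
$d_z\sqrt{n}$; `sample_size_paired_t` scans $n$ upward and returns the
first $n$ reaching the target.

# The synthetic-data generator

`simulate_session` emulates the paradigm with the study's structure: two
blocks (without/with distractors) of 18 multiplication + 4 passive-viewing
trials; a 2 s multiplication sign, 300 + 300 ms operands, a calculation
period ending at the response; in the distractor block the five onset
delays (1.0, 1.5, 1.75, 2.0, 2.25 s after calculation onset) randomly
assigned to four or five trials each, the 1.0 s trials flagged as catch
trials; distractor positions drawn from 8 positions on a 150 px circle.

The signal model per trial:

* **Fixational gaze**: a 2-D Gaussian random walk (`drift_sd = 0.002`
  °/sample) plus white tremor (`tremor_sd = 0.005`°), the simplest pair
  that exercises a velocity threshold realistically (≈ 0.5 °/s combined
  velocity noise at 250 Hz).
* **Saccadic events**: microsaccades as a Poisson process
  (`microsaccade_rate = 1.2` Hz) over the whole trial with log-normal
  amplitudes truncated at 1.5°; larger saccades (`saccade_rate_idc = 0.8`
  Hz, log-normal around 3°) only during the calculation period of
  multiplication trials — emulating the decoupling-related rise in eye
  activity during internal focus. Displacements follow a raised-cosine
  position profile. Event counts are Poisson; onsets colliding with
  another event or a blink are *resampled*, not dropped, so configured
  rates are conserved exactly in expectation.
* **Main sequence**: with a raised-cosine profile of duration $D$, peak
  velocity is $\pi A/(2D)$. The generator ties duration to the main
  sequence, $D = \pi/(2\,\mathrm{slope})$ (24 ms at the default slope of
  65 (°/s)/°), so that $v_{peak} = \mathrm{slope} \times A$ holds exactly
  for every amplitude. A duration that grows linearly with amplitude and
  an exact linear main sequence cannot both hold under a fixed profile
  shape; the package commits to the exact main sequence because it is the
  property the detection tests verify, and for amplitudes up to ~2° the
  resulting duration differs from the common linear duration rule
  (≈ 2.2 ms/° + 21 ms) by only a few milliseconds.
* **Blinks**: Poisson (`blink_rate = 0.25` Hz), uniform 100–300 ms
  duration, rendered as invalid pupil *and* gaze over the interval.
* **Vergence**: white disparity noise (`vergence_sd = 0.3` mm on screen),
  applied antisymmetrically to the two eyes' horizontal positions; tremor
  is common-mode so that disparity is exactly the vergence process.
* **Pupil**: baseline 4 mm plus, in multiplication trials only, a linear
  task-evoked ramp from calculation onset saturating at
  `pupil_task_gain = 0.3` mm after 1 s, with white measurement noise
  (0.02 mm per eye).
* **Behavior**: correctness sampled at `accuracy = 0.85` /
  `forgot_rate = 0.07`; response times log-normal around 2.5 s, clamped to
  [1.6, 8] s so the analysis window always fits.

Where the paradigm fixes a value (display geometry, trial counts, event
timing, distractor delays) the defaults are that value; the oculomotor
process parameters are literature-plausible choices, not fitted to any
dataset, selected once at design time.

Seeding: a session-level seed deterministically derives per-trial
substreams (drawn up front), so the same trial gets the same draws
regardless of trial order, and identical configurations yield
byte-identical outputs.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: no post-saccadic oscillations, no smooth
pursuit, no pink/oscillatory tremor spectra, no pupil foreshortening or
gaze-dependent pupil artifacts, no return-to-center statistics (gaze is a
free random walk between events), no cognitive model of arithmetic, and
no stimulus-evoked responses to the distractor itself. Recovery and
calibration results on synthetic data bound the pipeline's correctness,
not its field performance on any particular tracker.

# Problem sizes and numerical tolerances

The test suite runs at sizes chosen to make sampling error negligible
relative to the asserted tolerances while keeping the default run fast:
detector/brute-force equivalence on 50 simulated traces (plus both eyes),
event recovery on one full default session (44 trials, ≈ 380 injected
events), t-test calibration and power recovery on 10⁴ Monte-Carlo
replicates (3-SE bands), Bayes-factor verification against a fine-grid
quadrature at 10⁻⁴ relative error, and pipeline determinism on a reduced
3-participant configuration compared byte-for-byte.

# Known limitations

* Fixation disparity noise is white; real vergence drifts are slow, so
  per-bin disparity medians on real data will be more autocorrelated than
  simulated ones.
* The per-trial velocity-threshold estimation window follows toolbox
  convention but cannot be verified against the original analyses, which
  do not state it.
* Generalized η² is reported where sources often print bare "η²"; values
  are comparable only within the same convention.
* The package analyses single sessions independently; no hierarchical
  modeling across participants beyond the repeated-measures ANOVA.
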
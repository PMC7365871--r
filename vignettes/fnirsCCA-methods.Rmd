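---
title: "Classifying second-language proficiency from fNIRS activation patterns"
author: "fnirsCCA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying second-language proficiency from fNIRS activation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsCCA)
```

# The problem

Functional near-infrared spectroscopy (fNIRS) measures task-evoked changes
in oxygenated (oxy-Hb) and deoxygenated (deoxy-Hb) hemoglobin over the
cortex. In a block-design listening paradigm, participants with high and
low second-language (L2) proficiency produce systematically different
activation patterns over frontal-temporal channels, and the question is
whether an individual's proficiency group can be predicted from the
activation pattern of *other* people's brains — cross-participant
classification. Two obstacles dominate: individual differences (large
between-subject variability within a group) and small samples relative to
the 44-channel feature dimension. The pipeline in this package addresses
both with a standardized per-channel activation statistic and
stability-based sparse feature selection.

The full chain is: simulate (or ingest) recordings → band-pass filter →
epoch into 33-s language blocks → linear baseline correction → 5–18 s
window averages → per-channel activation indicators → sparse CCA
stability selection on the L2 features → leave-one-out classification.

# The measurement model

The montage is two 3×5 optode grids (one per hemisphere), eight emitters
and seven detectors per grid in a checkerboard, every grid-adjacent
emitter–detector pair forming a measurement channel: 22 per set, 44 total
(`buildProbeLayout()`). Recordings are sampled at 10 Hz. When the input is
two-wavelength optical density rather than chromophore concentrations,
`mbllConvert()` inverts the modified Lambert–Beer system
$\mathrm{OD}_\lambda = L\,(\varepsilon_{\mathrm{oxy},\lambda}\,\Delta
\mathrm{oxy} + \varepsilon_{\mathrm{deoxy},\lambda}\,\Delta\mathrm{deoxy})$
per sample; the simulator emits concentrations directly, so this step is
optional.

The task schedule (`generateSchedule()`) is two runs of 15 trials — five
per language (L1 native, L2 second, L3 unknown) in pseudo-random order
with no two consecutive trials in the same language. Each trial is an 18-s
question, a reaction period drawn uniformly from [1, 3] s, and a rest
period uniform on [15, 18] s (the source design states only these ranges).
At the maximal task and minimal rest durations a run lasts exactly
15 × 36 s = 540 s = 9 min.

# Preprocessing

The order is fixed and matters: **filter → epoch → baseline-correct →
window-average**.

* **Band-pass 0.01–0.8 Hz.** The band is standard for block-design fNIRS
  (removes drift and cardiac pulsation, keeps the task response). The
  realization is a design choice: a 3rd-order Butterworth applied
  forward–backward (zero phase), so epoch timing is not shifted by group
  delay. Both order and band are configurable.
* **33-s blocks.** Each trial contributes one epoch per channel and
  chromophore spanning [0, 33) s from question onset — fixed length even
  though reaction and rest durations vary. A 5-s pre-onset margin is kept
  with each block.
* **Linear baseline correction.** The line through two anchors — the mean
  over [−5, 0) s and the mean over the last 5 s of the block — is
  subtracted. The anchor abscissae are the mean sample times of the two
  windows, which makes the correction exact on straight-line blocks. The
  alternative reading of "the last 5 s of the task" (seconds 13–18 of the
  question period) is available via `baselineCorrect(tail = "task")`; the
  block tail is the default because the 33-s block is the unit being
  corrected.
* **Window average 5–18 s.** The hemodynamic response lags neuronal
  activity by several seconds, so the amplitude is averaged over the
  half-open window [5, 18) s on the sample grid (130 samples at 10 Hz).

# The activation indicator

For one (participant, channel, language), let the oxy-Hb block amplitudes
be $x_1,\dots,x_n$ and the deoxy-Hb amplitudes $y_1,\dots,y_m$ (window
averages of the 10 blocks of that language). The indicator is

$$a \;=\; \frac{\bar x - \bar y}{\sqrt{S_x^2/n + S_y^2/m}},$$

with sample (n−1) standard deviations — exactly a Welch two-sample
t-statistic contrasting oxy- against deoxy-hemoglobin. Activation raises
oxy-Hb and depresses deoxy-Hb, so strong activation gives a large positive
indicator; the studentization absorbs between-channel and
between-participant scale differences. The "samples" entering the
statistic could be read as either time points or block amplitudes; block
amplitudes are used (n = m = 10) because the preprocessing chain derives
exactly one amplitude per block before computing activation; the
time-point interpretation (n = m = in-window samples pooled over blocks)
is available by feeding `buildFeatureMatrix()` the `windowSamples()`
table instead of the `windowAverage()` one. The 44
indicators form the feature vector $A = (a_1, \dots, a_{44})$.

Participants whose behavioral correct-answer rate contradicts their
proficiency label are excluded before analysis
(`selectConsistentParticipants()`). No numeric cutoff is published; the
default is 0.5 (high-proficiency participants must score ≥ 0.5, low ≤
0.5), configurable.

# Sparse CCA stability selection

With $X$ the N×44 standardized feature matrix and $Y$ the label column
(high = +1, low = −1; the label encoding is not published — one-hot is
supported behind a flag), the penalized rank-one CCA problem is

$$\max_{v_X, v_Y}\; v_X^{\top} X^{\top} Y v_Y
\quad\text{s.t.}\quad \|v_X\|_1 \le \lambda_X,\; \|v_Y\|_1 \le \lambda_Y,\;
\|v_X\|_2 \le 1,\; \|v_Y\|_2 \le 1.$$

`sccaFit()` solves it by penalized-matrix-decomposition alternating
maximization: with $v_Y$ fixed, the optimal $v_X$ is soft-thresholding of
$X^\top Y v_Y$ followed by L2 normalization, the threshold found by
bisection so the L1 budget binds; symmetrically for $v_Y$. The objective
is non-decreasing, and constraints are verified post-fit to 1e−8. For the
default single-column $Y$ the all-ones start converges immediately and
equals the closed-form solution. For wider $Y$ the alternating scheme is
only locally optimal, so a fixed deterministic set of starts is used
(ones, canonical basis vectors, leading right singular vector) and the
best kept — this reproduced global grid-search optima on toy problems
where a single start did not.

The penalties $\lambda$ are not published. Per fold, $\lambda_X$ is chosen
so the support has a target size (default 5 channels, matching the size of
the published informative sets); $\lambda_Y = 1$.

**Stability counting.** For each of N leave-one-out folds, the N−1
training rows are standardized (training parameters only — no leakage
into the held-out row), the SCCA fit run, and the support recorded.
A channel is a *common informative feature* when its count strictly
exceeds $\lfloor 0.95N \rfloor$ — 38 for N = 40, 36 for N = 38,
reproducing both printed thresholds.

A caveat worth stating: because leave-one-out folds share all but two
rows, the ranking of channels by label correlation is highly stable
across folds, so even pure-noise data usually yields a *nonempty* common
set — the null property of the procedure is not an empty selection but
the absence of any *consistent* channel identity across independent
cohorts (the permutation test in the suite checks exactly that). This
also means the two-phase design below leaks label information.

# Classification

Three classifiers, evaluated by leave-one-out cross-validation (each
participant predicted once by a model trained on the rest, the feature
subset applied identically inside every fold):

* **Linear SVM** (`e1071`, libsvm): soft margin, cost C = 1 ("default
  values" is all that is published), no internal rescaling — the
  indicators are already studentized.
* **Sparse logistic regression (SLR)**: Bayesian logistic regression with
  automatic relevance determination. Each weight — the bias included —
  has its own Gaussian prior precision; a Laplace/IRLS inner loop
  alternates with MacKay evidence updates
  $\alpha_j \leftarrow \gamma_j / w_j^2$,
  $\gamma_j = 1 - \alpha_j \Sigma_{jj}$. Weights whose precision passes
  1e8 are pruned to exactly zero. On label-independent data every weight
  may be pruned (the bias too, since the cohorts are balanced); the
  model then scores every input 0, which prediction resolves to the
  positive class deterministically — giving exact chance accuracy
  rather than the anti-correlated majority vote a leave-one-out split
  would otherwise produce. A note on expectations: evidence-based ARD
  retains a null feature with probability ≈ P(χ²₁ > 1) ≈ 0.32, so ARD
  yields *mostly*-zero weights, not certainly-zero weights.
* **KNN**, K = 5, Euclidean distance on the raw indicators, majority
  vote; distance ties at the K-th neighbour are included before voting,
  and a tied vote raises an error instead of being broken at random, so
  predictions are deterministic.

Accuracy is $(TP + TN)/(TP + TN + FP + FN)$ with "high" the positive
class.

`runFullPipeline()` reproduces the published two-phase procedure exactly:
stability selection is computed once over the cohort's folds and the fixed
common set is then used inside the classification LOOCV. This leaks label
information from the selection phase into the classification test folds;
it is kept because it is the procedure being modelled, and an opt-in
`nestedSelection = TRUE` re-runs selection inside each classification
training fold for comparison.

# The synthetic cohort generator

The study's recordings are available only on request, so the generator is
the package's test bed. It emulates: the montage (44 channels), the
schedule, a canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio
1/6; all configurable) convolved with the 18-s question boxcar and scaled
so the peak response to one trial equals the amplitude parameter; deoxy-Hb
as −1/3 of the oxy response plus independent noise (half the oxy noise
SD); and noise = white Gaussian (SD 0.2 in amplitude units) + random
linear drift (slope SD 0.002 units/s) + sinusoids with random phase per
channel (cardiac 1 Hz amp 0.15, respiratory 0.3 Hz amp 0.15, Mayer
0.1 Hz amp 0.2). These magnitudes are on the scale of the unit response
amplitude, i.e. single-trial responses are buried in physiological noise
and only block averaging makes them visible — the regime block-design
fNIRS operates in. They are calibrated so that averaging the 10 blocks
per language recovers most (~90%) of the amplitude-level group
separation at the indicator level; heavier noise would shift the
paradigm towards needing more trials than the design provides.

Group structure: on the informative channels (default 1, 6, 16, 22 — the
published set for the native-Japanese scenario) the L2 response amplitude
is $A_0 (g + e)s$ with per-(participant, channel, language) individual
differences $e \sim N(0, 0.3^2)$, a shared per-participant vascular
scaling $s \sim N(1, 0.05^2)$, and a group gain $g$ that exceeds the
low-group value by `effectSize` × 0.3 for high-proficiency L2. So
`effectSize` is the separation of the group mean amplitudes in units of
the between-participant amplitude SD. L1 responds equally in both groups;
L3 carries no systematic response. Behavioral rates are drawn above 0.5
for (consistent) high-proficiency and below for low, with a configurable
fraction of planted contradictors to exercise the exclusion rule. One
master seed spawns per-participant substreams, so cohorts are exactly
reproducible while participants are independent.

The true effect sizes of the study are never quantified, so the defaults
(effect size 1.5; 1.2 in the recovery experiments) were chosen once so
that the selection and classification machinery is exercised in a
realistic, achievable regime, and are not tuned further. What the
generator does **not** model: optical photon transport, motion artifacts,
scalp/systemic physiology needing short-channel regression, or real
speech audio. Passing tests therefore demonstrate the correctness and
statistical behaviour of the *analysis*, not performance on real
recordings — the published cohort accuracies cannot be reproduced without
the private data.

# Numerical choices and degenerate inputs

* Welch indicator: errors (rather than returning ±Inf) when both
  chromophore variances are zero, and requires ≥ 2 blocks per side.
* Standardization: errors on zero-variance channels, naming them.
* SCCA: convergence at relative objective change < 1e−6, cap 500
  iterations (error with the objective trace on non-convergence);
  bisection residue below 1e−12 of the largest coefficient is snapped to
  an exact zero so supports are crisp.
* λ from a target support size: the soft threshold is placed between the
  k-th and (k+1)-th largest |correlation|, which is the closed form of
  the bisection the budget would otherwise be searched with.
* ARD: inner Newton with step halving (separable data saturate the
  likelihood and raw Newton oscillates), precision floor 1e−8, outer cap
  200 iterations.
* Simulation at 10 Hz requires the sampling rate to exceed twice the
  fastest simulated sinusoid; configs violating this are rejected.

# Problem sizes in the test suite

The statistical suites run at the paradigm's native scale: cohorts of
N = 40 (20 + 20), two runs of 15 trials at 10 Hz, 44 channels. The
planted-recovery experiment uses 20 independent cohorts at a strong
effect size of 2 and requires Jaccard ≥ 0.8 against the planted channels
in ≥ 90% of them; the power experiment uses 20 cohorts at the same
effect and requires post-selection L2 accuracy ≥ 0.75 for all three
classifiers in ≥ 18, with the null language L3 inside the N = 40
binomial chance band [0.30, 0.70] on average across cohorts —
individual LOOCV runs on null features are biased below chance by the
leave-one-out anti-learning effect, so the band is a statement about the
mean. The strong-effect choice is informed by two honest attenuations:
the indicator's multiplicative scale noise (estimating the block SDs
from 10 blocks) shrinks an amplitude-level separation of 1.5 to an
indicator-level d of ≈ 1.33, and the sampling noise of a per-channel d
at N = 40 (SD ≈ 0.33) then lets a planted channel's realized label
correlation fall below the strongest of the 40 competitor channels in a
non-negligible fraction of cohorts — when that happens the channel
drops out of *every* leave-one-out fold at once. At an amplitude effect
of 2 the realized indicator d (≈ 1.8) clears the competitor order
statistics reliably. Schedule invariants are checked over 1000 seeds, the Welch
oracle over 10,000 random pairs, and the SCCA closed form over 1000
random instances.

# A small worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(nPerGroup = 5, effectSize = 4,
                        informativeChannels = c(1, 16), seed = 71)
report <- runFullPipeline(cfg, targetSupport = 3)
report$commonFeatures
report$annotation
subset(report$accuracyGrid, language == "L2")
```

# Known limitations

* The two-phase selection→classification hand-off leaks label information
  (see above); accuracies from the default mode are optimistic relative
  to `nestedSelection = TRUE`.
* Single CCA component only (m = 1); no kernel or structured-sparsity
  variants, no permutation-based λ tuning.
* The simulator's noise is stationary and additive; motion artifacts and
  systemic confounds are out of scope.
* The behavioral-consistency cutoff (0.5) is a default, not a published
  value; published cohort sizes cannot be derived without the real data.
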
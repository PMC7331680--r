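---
title: "Detecting lexical-semantic processing in single subjects: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lexical-semantic processing in single subjects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n400mvpa)
```

## The problem

The N400 is a negative-going ERP deflection, typically centro-parietal and
strongest between 300 and 800 ms after word onset, that grows when a word
violates its semantic context. It is robust at the group level, but
individual children show the effect at variable latencies and scalp
locations — some not at all in a pre-specified region. A clinical test of
language comprehension, however, must decide about *one person*. This
package implements a per-subject analysis battery designed for exactly
that situation:

1. **Spatio-temporally unconstrained decoding** (`loto_decode`): a linear
   SVM discriminates congruent from incongruent target words using every
   scalp channel and every epoch sample at once, so the effect may sit
   anywhere in time and space; a single statistical test per subject.
2. **Time-resolved decoding** (`time_resolved_test`): the same classifier
   restricted to an 11-sample sliding window, corrected with TFCE and the
   permutation maximum statistic, to describe *when* information is
   present.
3. **Time-by-space searchlight** (`searchlight_decode`): 5-electrode
   neighbourhoods crossed with the 11-sample window, summarised as
   topographic accuracy maps per 200 ms window — descriptive only.
4. **Classic univariate N400 test** (`n400_test`): pointwise t-tests on
   the 9-channel Cz-centred ROI from 150 ms, with an
   autocorrelation-matched minimum-cluster-length correction.
5. **Data quality** (`sme`): the bootstrap standardised measurement error
   of the 300–800 ms difference-wave amplitude.

A session has 94 target pairs: each sentence frame and each target word
occurs once per condition (the incongruent condition re-pairs targets
across frames), giving 188 trials.

## The decoding model and its null

Each trial is represented by its raw voltages, flattened over channels and
samples. The classifier is a binary soft-margin linear SVM with `C = 1`
and no feature scaling. Cross-validation is leave-one-target-out (LOTO):
the two trials sharing a target word form the test set, all other trials
the training set, so lexical identity can never leak from training to
test. With 94 pairs there are 94 folds, each contributing 0, 0.5 or 1,
and the subject's score is the fold mean.

The null distribution preserves the pairing: a permutation flips, with
probability one half and independently per pair, the two condition labels
within that pair, then re-runs the identical LOTO procedure. The
all-no-flip permutation therefore reproduces the observed accuracy
exactly, and every permuted dataset still contains each target once per
condition. Significance follows the selection rule "observed accuracy
higher than 95% of the null accuracies". Two p-values are reported:

* `p_rank`, the add-one rank p `(1 + #{null >= obs}) / (1 + n_perm)`,
  which cannot go below `1/(n_perm + 1)`; and
* `p_normal`, the upper tail of a normal fit to the null, which can.
  Sub-`1/n_perm` p-values are only obtainable through such a parametric
  summary, which is why both are kept; the significance *flag* always
  follows the empirical selection rule.

The per-subject effect size is `(observed − mean(null)) / sd(null)`, a
descriptive quantity in null-SD units (conventional effect-size
benchmarks do not apply to decoding accuracies).

### Implementation note

The SVM dual problem is solved on a precomputed Gram matrix by an SMO
solver with second-order working-set selection at tolerance `1e-3`
(libsvm's own default), which makes the hundreds of thousands of small
fits behind the permutation and sliding-window analyses cheap: the Gram
matrix is computed once per feature window and shared by all folds and
permutations, and sliding windows update it incrementally. Raw-voltage
Gram matrices have entries of order 10^4 and up, which can leave hard
non-separable fits with a small residual duality gap at the iteration
cap; further iterations never change the predicted labels, so the cap is
accepted. The test suite pins this solver against libsvm (`e1071`): fold
accuracies agree exactly on random, windowed, permuted and searchlight
data, including cap-hitting fits. Decision values at exactly zero (a
measure-zero event) count as incorrect.

## Time-resolved inference

Per temporal centre the features are all channels at the centre sample
and five samples on each side; centres whose window would cross an epoch
edge are skipped (a 563-sample epoch yields 553 centres). Accuracies are
chance-centred (`acc − 0.5`) and enhanced with TFCE,

$$\mathrm{TFCE}(p) = \sum_{h = dh,\,2dh,\,\dots}^{s(p)} e(h)^{E}\, h^{H}\, dh,$$

with the method's standard exponents `E = 0.5`, `H = 2`; only positive
(above-chance) excursions score, matching the directional hypothesis. The
integration step is `dh = max(observed statistic)/100`, shared between
the observed and permutation series so scores are comparable; halving
`dh` changes scores by well under 2%. Family-wise error is controlled by
the permutation maximum: each permutation's TFCE series is reduced to its
maximum over the analysis window (centres at or after 0 ms — the baseline
is excluded), and a centre is significant when its observed score exceeds
95% of those maxima. The permutation count is shared with the main
analysis.

## The univariate N400 test

Trials rejected by the ±200 µV rule *within the ROI only* are excluded
(rejection scoped to the ROI preserves data; the multivariate analyses
use all trials, because removing one noisy trial would unbalance its pair
and frame). The ROI waveform is the mean of the nine channels; pointwise
two-sample pooled t-tests run from 150 ms. The minimum cluster length is
calibrated by simulating 1,000 null datasets of per-trial AR(1) Gaussian
series whose lag-1 autocorrelation matches the observed ROI difference
waveform and whose trial counts match the data, then taking the smallest
run length reached by at most 5% of the simulated longest sub-.05 runs.
Two choices here were genuinely open:

* *What carries the autocorrelation?* We estimate the lag-1 coefficient
  from the ROI difference waveform over the tested window, and simulate
  at the **trial level** with matched trial counts, so the simulated
  t-tests have the same degrees of freedom as the observed ones. (An
  alternative — simulating averaged waveforms directly — changes the
  implied df; the trial-level choice matches how the observed statistics
  are computed.)
* *Tails.* The pointwise tests are two-tailed by default (the direction
  of a difference is informative even when it is not the classic
  negativity); one-tailed testing is exposed as a parameter.

The N400 magnitude is the trapezoidal integral of the congruent-minus-
incongruent ROI waveform over 300–800 ms in one-sample steps, positive
when the incongruent condition is more negative. The group-level variant
(`group_n400_test`) applies a paired t across subjects per timepoint,
which reduces exactly to the one-sample t on difference waveforms — the
test suite asserts this.

## Data-quality metric

The SME of a channel is the SD, over 10,000 bootstrap resamples (drawn
with replacement within each condition at the accepted-trial counts), of
the 300–800 ms mean amplitude of the difference ERP. Because that score
is linear in the data, the bootstrap operates on per-trial window means —
mathematically identical and orders of magnitude faster. For iid trials
it converges to the plug-in two-sample standard error
$\sqrt{s_c^2/n_c + s_i^2/n_i}$, which the tests verify to 5%. The
baseline is subtracted once, upstream, so the "relative to baseline"
score involves no second subtraction. All scalp channels enter the mean
SME (whether interpolated channels should be excluded is unspecified
upstream; including them is the simpler rule and is documented here).

## Experimental-design utilities

`generate_sequence` reproduces the session's sequence optimisation: 1,000
candidate orderings; candidates must have no more than four consecutive
same-condition trials and run-length frequencies non-increasing in run
length; among the survivors the sum of first-, second- and third-order
bias is minimised. The max-run constraint is built into the candidate
sampler (labels drawn sequentially in proportion to the remaining counts,
a run at the cap blocking its own extension, dead ends restarting the
draw): an unconstrained shuffle of 188 balanced labels satisfies
"max run 4" with probability around $e^{-12}$, so rejection sampling
alone cannot produce such candidates. The bias metric had no published formula, so the
package uses an occurrence-weighted mean of squared deviations of the
conditional "congruent" frequencies from one half — zero exactly when
every history is balanced, positive otherwise; it is documented as a
choice, not claimed identical to the original. Pair identifiers are then
assigned so each frame occurs once per half (always feasible: the number
of congruent slots in the first half equals the number of incongruent
slots in the second), and question trials are placed every 7 ± 3 trials,
so gaps lie in [4, 10].

`power_two_sample_t` computes exact noncentral-t power. With 94 trials
per condition, d = 0.5 and one-tailed α = 0.05 it gives 96.2%; the
one-tailed two-sample reading is an inference from the reported figure
(the underlying test was unstated) and `tails` is a parameter. A
Monte-Carlo t-test simulation backs the closed form in the tests.

## The synthetic-EEG generator

The generator exists so that every analysis can be validated against
ground truth. It emulates the study's data *structure*: 64-channel 10-20
montage on a unit sphere, 512 Hz, half-open [−100, 1000) ms epochs
(floor(1.1 × srate) samples; the first sample sits exactly at −100 ms and
no sample is double-counted at the right edge), 94 pairs presented once
per condition. The condition effect is a separable Gaussian bump in time
(default peak 400 ms, SD 80 ms) and space (Gaussian in chord distance,
default centre Cz, SD 0.6 sphere units) added to incongruent trials;
amplitude is negative (default −6 µV) so incongruent trials are more
negative. The default amplitude/noise combination was calibrated once so
that a full-scale responder decodes at roughly 60%, inside the 49–68%
range real individuals exhibit; a −4 µV effect under the same noise sits
at chance-to-marginal, emulating a non-detectable subject. Between-subject heterogeneity — the "variable times or
locations" seen in real children — enters as per-subject Gaussian jitter
of latency and of the topography centre, plus a responder fraction
(default 0.65, i.e. 13 of 20 subjects in the demo scenario carry a
non-zero effect).

Noise is spatially correlated 1/f-plus-white: per channel, white Gaussian
noise (default SD 4 µV) plus spectrally shaped 1/f noise (default SD
8 µV), mixed across channels with a Gaussian spatial kernel (default
correlation scale 0.8 chord units). No noise model was specified
upstream, so these defaults are calibrated qualitatively — single-trial
effects are invisible by eye at the default SNR — and stated once here.
What the generator deliberately does **not** model: ocular or muscle
artifacts (hence ICA is out of scope; the preprocessing pipeline
documents where such a step would plug in, between filtering and
epoching), volume-conduction forward models, and non-stationary drift.
Passing tests on synthetic data therefore demonstrate the *statistical*
correctness of the pipeline (calibration, recovery, invariances), not
robustness to every physiological artifact of real recordings.

With amplitude 0 the two conditions are exchangeable by construction, so
the whole inferential chain can be audited: the decoding significance
rule and the TFCE max-statistic correction are both verified to hold
their nominal 5% level on hundreds of simulated null subjects.

## Preprocessing

Fixed order: mastoid-average re-reference, zero-phase band-pass
(0.1–40 Hz), epoching, baseline correction over [−100, 0) ms, ±200 µV
rejection. The filter is Butterworth — a 2nd-order high-pass cascaded
with a 4th-order low-pass, each run forward-backward (so effective orders
4 and 8, zero phase, no passband ripple); signals are demeaned before
filtering to curb high-pass edge transients. One octave outside the band
the attenuation exceeds 20 dB on both sides. The rejection threshold is
treated as ±200 **µV** (a 200 mV scalp deflection is physically
implausible and is read as a units typo); the threshold is configurable.
A channel contributes to a trial's rejection iff it exceeds the threshold
in that trial; channels contributing to the rejection of more than 10% of
trials are replaced by Perrin-style spherical-spline interpolation (order
m = 4, regularisation 1e-5, 50 Legendre terms) and the pipeline re-runs
from the filtering stage.

## Numerical and format choices

* Epoch container: a single-file binary store — magic tag, JSON metadata
  block, float32 little-endian voltages. Round trips are exact on
  metadata and float32-lossless on voltages.
* Neighbourhoods use Euclidean (chord) distance on the unit sphere, ties
  broken lexicographically by channel name, so results are deterministic.
* All simulation and permutation functions take integer seeds and are
  bit-reproducible; cohort and pipeline functions derive per-subject
  seeds from one root seed.
* Pseudotrial decoding (`pseudotrial_decode`, k = 12 trials per average,
  100 sets) drops leftover trials modulo k within each set and pairs
  pseudotrials by construction order within condition; its permutation
  null flips real-trial labels within pairs before averaging.
* Degenerate cases fail loudly: zero-SD nulls (effect size), constant
  series (autocorrelation), empty scopes, incomplete pairs, events too
  close to a recording edge.

## Validation scales

The statistical validation in the test suite runs at reduced scale so the
whole battery stays fast: null calibration uses 200 subjects of 20 pairs
× 8 channels × 50 samples with 100 permutations; chance-centring uses 100
such subjects; family-wise-error checks use 100 subjects of 10 pairs × 6
channels with 100 permutations; parameter recovery uses 20 seeds of a
clean, focal effect (−6 µV, temporal SD 30 ms, topography SD 0.4 on Cz,
low noise) — a deliberately identifiable target, since at the default
noise level no estimator could beat the per-centre fold-count
granularity, which would test the noise rather than the method. Because
fold accuracies are discrete, the peak latency estimator is the median
centre time of the tied maxima, and the searchlight localisation runs on
the dense 64-channel montage (on sparse layouts every 5-channel
neighbourhood overlaps the source). These sizes are the package's own
validation design; the analysis functions themselves run at full scale
(94 pairs, 64 channels, 563 samples, 1,000 permutations, 10,000
bootstraps).

## Limitations

* The decoder is strictly linear with fixed `C`; no kernels or
  hyperparameter search (deliberately, to keep one test per subject).
* The searchlight is descriptive; it performs no significance testing.
* Real-data idiosyncrasies (ocular artifacts, drift, bad-electrode
  nonstationarity) are outside the generator's scope, as noted above.
* Group-level machinery is limited to the totals row, the two Spearman
  correlations and the group cluster test; no meta-analytic modelling.
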
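# n400mvpa

Individual-subject EEG decoding and ERP analysis of lexical-semantic
(N400-type) processing.

## The problem

When a spoken word violates its semantic context ("the squirrel stored nuts
in the *door*"), the EEG shows an N400: a negative-going deflection, usually
centro-parietal, 300–800 ms after word onset. At the group level this is one
of the most robust effects in cognitive neuroscience; in *single subjects* —
the case that matters for assessing language comprehension in people who
cannot respond behaviourally — it is unreliable, because individuals express
the effect at different latencies and scalp sites. This package implements a
per-subject analysis battery built around that problem, for EEG researchers
and methodologists who need single-participant inference:

* **Unconstrained multivariate decoding** (`loto_decode`): a linear SVM
  (cost C = 1, raw voltages, all scalp channels × all time points as one
  feature vector) classifies congruent vs incongruent target words under
  **leave-one-target-out** cross-validation — the two trials sharing a
  target word are always held out together, so lexical identity never leaks
  into training. Significance comes from a **pairing-preserving permutation
  null**: each permutation flips, with probability ½ per word pair, the two
  condition labels within that pair and re-runs the identical procedure.
  A subject is flagged when the observed accuracy exceeds 95% of the null
  accuracies, with the per-subject effect size

  $$\text{effect size} = \frac{\text{accuracy} - \overline{\text{null}}}{\mathrm{sd}(\text{null})}.$$

* **Time-resolved decoding** (`time_resolved_test`): the same classifier on
  11-sample sliding windows, with threshold-free cluster enhancement
  (E = 0.5, H = 2) and max-statistic family-wise correction over all
  post-onset timepoints.
* **Time×space searchlight** (`searchlight_decode`): 5-electrode
  neighbourhoods × 11-sample windows, summarised as accuracy topographies in
  four 200 ms windows (descriptive; no testing).
* **Univariate N400** (`n400_test`): pointwise t-tests on the 9-channel
  Cz-centred ROI from 150 ms, corrected by an autocorrelation-matched
  minimum cluster length (simulated AR(1) nulls), plus the 300–800 ms
  trapezoidal N400 area.
* **Data quality** (`sme`): bootstrap standardised measurement error of the
  300–800 ms difference-wave amplitude.
* **Design utilities** (`generate_sequence`, `power_two_sample_t`) and a
  **synthetic-EEG generator** (`simulate_subject`, `simulate_cohort`) with
  ground truth, heterogeneous effect latency/topography, and spatially
  correlated 1/f-plus-white noise.

`run_pipeline` chains everything over a cohort and produces the per-subject
Yes/No summary table (decoding / time-resolved / univariate) with a totals
row. See the vignette (`vignettes/individual-n400-decoding.Rmd`) for the
model details and design decisions.

## Worked example

Simulate one full-size subject (94 target pairs → 188 trials, 64 channels,
512 Hz) carrying a −6 µV N400-like effect, and run the main analysis with
1,000 permutations (a few minutes of CPU):

```r
library(n400mvpa)

sim <- simulate_subject(n_pairs = 94, effect = effect_spec(), seed = 7)
sim$epochs
#> <eeg_epochs> sim: 188 trials (94 pairs) x 64 channels x 563 samples
#>   512.0 Hz, window [-100.0, 997.7] ms, 0 trial(s) rejected

fit <- loto_decode(sim$epochs, n_perm = 1000, seed = 8)
fit
#> <loto_decoding> sim: accuracy 66.0% over 94 folds
#>   null (n = 1000): mean 50.0%, sd 4.75%; p_rank = 0.000999, p_normal = 0.0004
#>   effect size = 3.35; SIGNIFICANT at alpha = 0.05
```

The accuracy (66%) sits in the range real detected individuals show
(49–68%); the null distribution is centred on chance with the observed
accuracy more than three null-SDs above it, so the subject is flagged. The
same epochs can then be localised in time (`time_resolved_test`), in
time×space (`searchlight_decode` + `window_topographies`), and checked
against the classic univariate N400 (`n400_test`); `summarize_subjects`
collects the three Yes/No decisions per subject into the summary table.

A thin command-line front end over the same functions is included:

```sh
Rscript inst/cli/n400suite.R power --n 94 --d 0.5 --tails one
#> power = 0.9617
Rscript inst/cli/n400suite.R simulate --n-subjects 20 --seed 1 --out cohort/
Rscript inst/cli/n400suite.R run --cohort cohort/ --permutations 100 --seed 1 --out results/
```

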
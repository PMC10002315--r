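# voicesym

Clustering depressed patients into **symptom groups** from HAM-D-17 item
profiles, and separating those groups from **acoustic features of
fixed-phrase speech**.

Most voice-based depression screening predicts the presence or severity of
depression. voicesym targets the harder, clinically more actionable
question: two patients with similar severity totals can have different
symptom profiles (e.g. inactivity vs insomnia), and it is the profile that
guides medication adjustments. The package implements the full analysis
pipeline for that question, plus a synthetic-data module that stands in for
clinical recordings (which are never redistributable), so every stage is
testable offline.

## What it computes

**1. Symptom clustering.** Subjects are grouped from their 17-item HAM-D
profiles with a three-tier rule: totals of 0 are excluded, totals ≥ 4 are
clustered by k = 2 K-means under the correlation distance
*d*(a,b) = 1 − *r*(a,b), and totals 1–3 are allocated to the nearer
centroid. Group 1 is canonically the cluster with the higher centroid on
item 7 (work and activities). Group differences per item (and on the
total) are tested with two-sided Wilcoxon rank-sum tests at
Bonferroni-corrected levels (0.05/18 ≈ 2.8 × 10⁻³ for `*`).

**2. Acoustic features.** From each mono PCM recording (11.025 kHz
default): fundamental frequency, jitter, shimmer, harmonics-to-noise ratio,
RMS energy, FFT band powers (0–500, 500–1000, 1000–4000 Hz), spectral
centroid and flux, five LPC formants, 12 MFCCs, and the glottal quotients
NAQ and QOQ from IAIF-estimated glottal flow — aggregated per phrase as
mean and standard deviation into a fixed-order feature vector (56 entries
per phrase; 1176 for the full 21-phrase set).

**3. Classification.** Gradient-boosted decision trees (xgboost) under
stratified five-fold cross-validation; per fold the probability cutoff
maximizes the Youden index *J* = sensitivity + specificity − 1 on the
training split; the five test-fold confusion matrices are summed and
sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), accuracy = (tp+tn)/n
are reported from the pooled matrix, together with the ranked list of
features the trees actually used.

**4. Synthetic data.** A Rosenberg-pulse source–filter synthesizer
(controllable F0, open quotient, jitter, shimmer, aspiration SNR, five
formants) and a HAM-D cohort generator (one-factor latent model calibrated
so items 1 and 7 correlate at 0.7 after discretization; two latent symptom
groups) that share each subject's latent group, so acoustic effect sizes
between groups are tunable end to end.

## Worked example

```r
library(voicesym)

cfg <- default_config(seed = 42, out_dir = "demo_run",
                      n_per_group = 20, phrases = c(1, 7, 18),
                      duration_s = 0.6, acoustic_effect = 1.5,
                      hamd_separation = 2)
rep <- run_pipeline(cfg)
print(rep)
#> <run_report> accuracy 82.5%; groups 22/18 (+0 excluded); 128 artifacts
```

The run synthesizes 40 subjects × 3 phrases, writes the WAVs and HAM-D
table, extracts the feature table, clusters the HAM-D profiles, and
cross-validates the classifier on the clustered labels. The artifacts in
`demo_run/` include `metrics.json`:

```
overall: tp=19 fn=3 fp=4 tn=14
sens 0.864 spec 0.778 acc 0.825
```

i.e. the pooled 5-fold confusion matrix separates the inactivity-leaning
group 1 from the insomnia-leaning group 2 at 82.5% accuracy under this
strong synthetic contrast. `item_tests.json` flags exactly the items the
generator separates (guilt, early insomnia, work and activities, loss of
appetite):

```
item_2  p=3.0e-06 ***   item_4  p=1.5e-05 ***
item_7  p=3.2e-05 ***   item_12 p=4.0e-06 ***
```

and `feature_report.csv` ranks the features the trees used (formants and
MFCCs dominate):

```
    feature statistic phrase_id importance
  formant_1      mean         1      1.015
     mfcc_1       std         1      1.000
     mfcc_7      mean         1      1.000
  formant_4      mean         7      0.462
```

Individual stages are available directly: `synthesize_voice()`,
`estimate_f0()`, `iaif()`, `glottal_quotients()`, `cluster_cohort()`,
`item_wise_tests()`, `crossvalidate()`, … A command-line wrapper with
`run-all` / `synth` / `cluster` / `classify` / `validate` subcommands is in
`inst/scripts/voicesym-cli.R`.

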
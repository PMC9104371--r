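# sentitri

Three-class sentiment analysis for open-ended survey responses, built for
public-health text mining: lockdown-era testimonies from university
students and staff, answered in free text and hand-labeled negative /
neutral / positive.

The pipeline scores each response with an embedding-based regressor
O ∈ [−1, 1] trained by transfer learning on a binary-polarity corpus
(labels 0/1 mapped to targets −1/+1), then **trichotomizes** the score with
two decision thresholds t_nn ≤ t_pn:

    negative  if O < t_nn
    neutral   if t_nn ≤ O < t_pn
    positive  if O ≥ t_pn

The thresholds are calibrated by 5-fold cross-validated exhaustive grid
search (step 0.01) maximizing 3-class accuracy, averaging the per-fold
optima. Two scorers are provided: a 20–16–1 feed-forward network (ReLU
hidden layer, tanh output) and an ε-support-vector regressor with clipped
output. Evaluation uses confusion matrices in the rows-predicted /
columns-real convention and a support-weighted one-vs-all metric suite
(accuracy, precision, recall, F1); corpora are summarized by word clouds of
tokens appearing at least 20 times after stop-word removal.

Because the original survey texts are not redistributable, the package
includes a synthetic-data generator that reproduces the study's stratified
label counts exactly (Spain/Colombia × student/staff: 88/6/12, 84/26/9,
41/14/27, 30/14/14 → 225 students + 140 staff) and emits class-separable
text from configurable lexicons, so every stage is testable offline.

## Worked example

```r
library(sentitri)
run <- run_pipeline(run_config("lockdown-run", model = "mlp", seed = 1))
run$metrics
#> <metric_report> n = 365
#>   accuracy           99.73%
#>   weighted accuracy  99.91%
#>   weighted precision 99.73%
#>   weighted recall    99.73%
#>   weighted F1        99.73%
run$thresholds
#> <threshold_pair> intervals: [-1, -0.618) negative | [-0.618, -0.152) neutral | [-0.152, 1] positive
```

The run directory contains the generated corpora, scores, calibrated
thresholds (YAML), predictions, confusion matrix (TSV), metrics (JSON),
misclassification listing, term-frequency table, word-cloud PNG and a
manifest tying everything to the seed. The near-perfect accuracy is a
property of the clean synthetic corpus (purity 0.9 lexicon text), not a
claim about real survey text — see the vignette for what the synthetic
conditions do and do not demonstrate.

The published reference results ship as fixtures and are recomputed, not
copied:

```r
verify_reference_metrics()
#> <verification_report> 20 checks, all within tolerance
weighted_one_vs_all(reference_matrices()[["mlp-students"]])
#> <metric_report> n = 225
#>   accuracy           88.89%
#>   weighted accuracy  92.49%
#>   weighted precision 88.64%
#>   weighted recall    88.89%
#>   weighted F1        88.74%
```

Published average thresholds are available without retraining via
`threshold_presets()` (e.g. `mlp-students`: 0.22 / 0.49), and
`decide(0.30, threshold_presets()[["mlp-students"]])` returns `"neutral"`.

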
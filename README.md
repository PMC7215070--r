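# stackppi

Sequence-only prediction of protein–protein interactions (PPI) with stacked
attention ensembles, in R.

Experimentally mapped interactomes are sparse and expensive, so a large body
of work predicts whether two proteins interact from their amino-acid
sequences alone. `stackppi` implements a complete pipeline of this kind for
computational biologists:

* **Four classical sequence descriptors.** Auto covariance (AC): for seven
  standardized physicochemical properties \(j\) and lags \(g = 1..30\),
  \(\mathrm{AC}(g,j) = \frac{1}{L-g}\sum_i (X_{ij}-\bar X_j)(X_{(i+g)j}-\bar X_j)\)
  (210 values). Conjoint triads (CT): frequencies of the 343 three-residue
  patterns over the seven-group amino-acid alphabet. Local descriptors (LD):
  composition / transition / distribution statistics (7 + 21 + 35 = 63
  values) over ten overlapping sequence regions (630 values). Pseudo
  amino-acid composition (PseAAC): the 20 residue frequencies plus
  \(\lambda\) sequence-order correlation factors
  \(\theta_g = \frac{1}{L-g}\sum_i J_{i,i+g}\) weighted by \(\omega = 0.05\)
  (20 + λ values).
* **A neural pair classifier.** Both proteins of a pair pass through a
  shared convolution + batch-norm + ReLU stack; the two representations
  attend to each other with multi-head scaled dot-product cross-attention,
  \(\mathrm{softmax}(QK^\top/\sqrt{d_k})V\), pooled to a fixed-length vector
  by average and max pooling of the interaction map; the merge layer
  concatenates their cosine similarity, a bilinear form
  \(S_1'^\top A\, S_2'\), and both attended representations, feeding a dense
  softmax head trained by cross-entropy.
* **Stacked generalization.** Sixteen such learners (4 descriptors × 4
  network configurations) are combined by five-fold stacking: each learner's
  out-of-fold predictions become the training features of a small neural
  meta-learner; at test time meta-features are the K-fold mean of the fold
  models' predictions.
* **Dataset construction.** Positive-set filters (minimum length 50,
  optional 40 % global-identity de-redundancy) and negative sampling among
  pairs with different subcellular localizations at a 1:1 ratio, with a
  per-protein usage cap.
* **A synthetic benchmark generator.** Proteomes with planted
  motif-complementarity interactions, so every stage of the pipeline is
  testable offline with a known, sequence-encoded ground truth.

## A worked example

```r
library(stackppi)

# a synthetic study: 300 proteins, 500 interacting + 500 non-interacting pairs
cfg <- sim_config(seed = 1)
ds  <- simulate_ppi_dataset(cfg)
fl  <- encode_feature_sets(ds$records)    # AC, CT, LD, PseAAC tables

set.seed(9)
idx <- sample(nrow(ds$pairs))
train <- ds$pairs[idx[1:800], ]
test  <- ds$pairs[idx[801:1000], ]

ens <- train_ensemble(train, fl, stacking_config(seed = 4))
ens
#> <ppi_ensemble> grid variant: 16 learners x 5 folds on 800 pairs
#>   out-of-fold AUC: best 0.760 / median 0.641
#>   meta-learner: 32-16 hidden units, 600 iterations

pred <- predict(ens, test, fl)
evaluate_predictions(dplyr::mutate(pred, label = test$label))
#> # A tibble: 1 x 10
#>       n    TP    FP    TN    FN accuracy recall precision    f1   auc
#>   <int> <int> <int> <int> <int>    <dbl>  <dbl>     <dbl> <dbl> <dbl>
#> 1   200    99    33    64     4    0.815  0.961      0.75 0.843 0.847
```

The held-out AUC of about 0.85 says the ensemble recovers most of the
planted interaction signal (individual learners sit between 0.55 and 0.76
out of fold — stacking the four complementary descriptors is what pushes
the ranking quality up); `tidy(ens)` lists each first-level learner with
its out-of-fold AUC, `glance(ens)` summarises the fit, and
`autoplot(ens)` / `autoplot(evaluate_predictions(...))` draw the learner
comparison and the ROC curve.

The same pipeline runs end-to-end, with caching and a JSON run manifest,
from a single configuration file:

```r
run_pipeline("inst/configs/default.yaml", outdir = "my_run")
```

or from the shell via the thin CLI in `exec/stackppi`
(`stackppi simulate|featurize|evaluate|pipeline ...`).

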
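---
title: "Methods: sequence descriptors, attention pair models, and stacked generalization in stackppi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence descriptors, attention pair models, and stacked generalization in stackppi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stackppi` predicts protein–protein interactions (PPI) from sequence alone.
This vignette is the package's account of the science: the models it
implements, the parameters that matter, the design decisions taken where
the design was genuinely open, and what its synthetic benchmark does and
does not establish.

## The four sequence descriptors

Every protein is mapped to four fixed-length vectors; all downstream models
consume these, never the raw sequence.

**Auto covariance (AC).** Seven physicochemical properties per residue —
hydrophobicity, hydrophilicity, side-chain volume, polarity, polarizability,
solvent-accessible surface area and the net charge index of side chains —
give a numeric profile `X[i, j]` along the sequence. For each property `j`
and lag `g = 1..30`,

    AC(g, j) = mean over i of (X[i,j] - mean(X[,j])) * (X[i+g,j] - mean(X[,j]))

with the outer mean over the `L - g` admissible positions, producing a
210-dimensional vector ordered lag-major. The property values themselves are
not part of the model definition; the package ships the table conventionally
used with this descriptor (sources documented per column in `R/aa-tables.R`)
and standardizes every property to zero mean and unit variance over the 20
amino acids before use. Standardization makes the descriptor invariant to
the units in which the raw scales happen to be published; AC is additionally
invariant to any constant shift of a property column by construction
(the centring in the formula), which the tests assert.

**Conjoint triads (CT).** The 20 amino acids collapse to 7 groups by dipole
and side-chain volume (A/G/V; C; F/I/L/P; M/S/T/Y; H/N/Q/W; K/R; D/E). Every
window of three consecutive residues is a triad type out of 7³ = 343; the
descriptor is the frequency of each type among the `L - 2` windows. Boundary
pseudo-triads that pad beyond the sequence ends have no bin among the 343
types and are not counted. The count normalization by `L - 2` makes the
vector a probability distribution, asserted as an invariant.

**Local descriptors (LD).** The sequence is split into ten regions: the four
quarters, the two halves, the central 50 %, and the first, final and central
75 %, with floor-based cut points so the quarters exactly reconstruct the
sequence. Each region contributes 63 values over the 7-group alphabet:
composition (7 group frequencies), transition (frequencies of the 21
unordered group pairs among adjacent positions, denominator `n - 1`), and
distribution (for each group, five values locating its first and
25/50/75/100 % occurrences). Two points deserve note:

* *Transitions are the 21 unordered pairs.* This is the only reading
  consistent with 63 values per region (7 + 21 + 35) and with the worked
  arithmetic the descriptor is defined by, which evaluates a transition
  between groups 1 and 3 — a pair no 7-element transition scheme contains.
* *The distribution variant is count-index based*: `1/n` for the first
  occurrence, then `floor(q*c + 0.5)/n` for quantile `q` of a group with
  count `c`. The canonical positional variant (actual sequence position of
  the `ceiling(q*c)`-th occurrence over `n`) is available as
  `ld_distribution = "positional"`; the count-index arithmetic is the
  default because it is the form the descriptor's reference values are
  printed in.

**Pseudo amino-acid composition (PseAAC).** The 20 residue frequencies plus
λ sequence-order factors `theta[g]`, each the average over the sequence of
`J(i, i+g)`, the mean difference of three standardized properties
(hydrophobicity, hydrophilicity, side-chain mass) between residues `g`
apart, weighted by ω = 0.05. All 20 + λ entries share one denominator, so
the vector sums to one exactly — an algebraic identity the tests check on
the implementation's own θ values. The plain (signed) difference in `J` is
deliberate; the squared-difference convention used elsewhere in the PseAAC
literature is available as `correlation = "squared"`. λ defaults to 15 and
must stay below the sequence length; with the 50-residue positive filter in
place any λ ≤ 30 is safe.

**Non-standard residues.** Real FASTA contains B, Z, U, J, O, X. Under the
default `"impute"` policy the property-based encoders map them to the
property-column mean (exactly zero after standardization) and the
group-based encoders map B→7, Z→7 (Asx/Glx resolve to D/E), U→2
(selenocysteine behaves like C), J→3, dropping O and X with a warning; the
`"strict"` policy raises an error naming the offending position.

## Dataset construction

Positive pairs are filtered by sequence length (< 50 residues removed) and
optionally de-redundified at 40 % global identity, computed as
Needleman–Wunsch matches over alignment length (BLOSUM62, affine gaps)
with greedy first-seen representative retention. The identity filter is off
by default: the redundancy tool behind the published threshold is not
specified, the synthetic benchmark is non-redundant by construction, and
all-against-all alignment is quadratic. It applies to the positive set only.

Negatives pair proteins with *different* subcellular localizations, exclude
anything in the positive set, and draw at a 1:1 ratio. The requirement that
proteins contribute to the negative set "as harmoniously as possible" is
operationalized as a per-protein usage cap, default
`ceiling(2 * n_negatives / n_proteins)`: it balances protein degree without
forbidding reuse. Sampling scans a seeded random permutation of all eligible
pairs and reports the achievable count when the request is infeasible.

## The basic pair learner

A flat descriptor vector is reshaped to a (positions × channels) matrix
before convolution: AC as (30 lags × 7 properties), CT as (49 × 7), LD as
(90 × 7), PseAAC as (20 + λ × 1), and the concatenated variant zero-padded
to a multiple of 7 and read 7 channels wide. The three grouped encodings
carry 7 naturally aligned values per position, which is why 7 is the channel
width; the reshape is recorded in the learner configuration.

The forward pass is: a shared (siamese) stack of `n_blocks` convolution →
batch-norm → ReLU blocks closed by a final convolution (1-D, kernel 3,
'same' zero padding, 8 output channels); multi-head scaled dot-product
cross-attention in both directions — the query/value side is one protein,
the key side the other — with `d_model` equal to the convolution channels so
that the attended output `M` can form the interaction map `G = M Q'` with
its own query; average and max pooling of `G` over its last axis, giving a
fixed-length `2P` vector per direction regardless of the partner's length;
and a merge layer concatenating the cosine similarity of the two pooled
representations, the bilinear form `S1' A S2`, and both representations. A
dense ReLU stack with a 2-unit softmax head closes the model, trained by
cross-entropy with Adam (learning rate 3e-3 in the default grid).

Open points resolved here, as this package's own choices:

* The pooled-attention product is read as `M Q'` (an interaction map of
  shape positions × positions, pooled over its last axis); this is the only
  reading that uses both operands and yields a fixed-length output.
* The similarity term of the merge layer is the scalar cosine; a zero-norm
  representation contributes 0 rather than NaN.
* Merge features mix a bounded cosine, an unbounded bilinear form and two
  pooled maps of very different scales, so a batch-norm layer sits between
  the merge and the dense head; without it the dense layers spend most of
  the training budget rescaling.
* The interaction relation is symmetric but the architecture is not:
  training data are augmented with both orientations of every pair and
  prediction averages the two orientations. The cosine term is
  orientation-invariant by construction (asserted in the tests).
* Batch statistics use the stacked batch of both proteins; inference uses
  running estimates (momentum 0.9). Max pooling breaks ties by first index,
  fixing determinism.

All gradients are derived by hand and verified against central finite
differences in the test suite; the single-sample operations exported for
scrutiny (`conv_stack()`, `scaled_dot_attention()`, `multi_head()`,
`pooled_multi_head()`, `merge_pair()`) are checked to agree exactly with the
batched training path and with independent brute-force transcriptions.
The attention inner loop (per-sample small matrix products) is compiled
code (RcppArmadillo); everything else is ordinary matrix algebra in R.

## Stacked generalization

Sixteen first-level learners — each of AC, CT, LD, PseAAC under four network
configurations (dense stacks 128-64, 256-128, 128-64-32, 256-128-64 with 2
or 4 attention heads) — are stacked with five-fold cross-validation,
stratified by label and seeded. For learner `m` and fold `k`, a model
trained outside fold `k` predicts fold `k`; row `i` of the meta-feature
matrix therefore contains only predictions from models that never saw pair
`i`. This out-of-fold guarantee is the central correctness property of
stacking and is audited feature-by-feature in the tests. At prediction time
a learner's meta-feature is the mean of its five fold models' predictions.

Each learner contributes its positive-class probability (one value, not the
redundant two-component softmax), so the meta-learner is a small network on
16 inputs: ReLU hidden layers (32, 16 by default) with a softmax output,
trained by full-batch gradient descent at rate η = 0.1 on the cross-entropy
loss until the max-norm of all gradients falls below ε or 600 iterations.
Variants: the concatenated representation (1183 + λ inputs to each of the
four network configurations) and single-technique ensembles are available
as `variant = "concat"` and `variant = "sep"`.

## The synthetic benchmark

The generator emulates the shape of a curated PPI study: ~300 proteins of
60–400 residues with i.i.d. background residues at database-like
composition, subcellular localizations drawn independently of sequence, 500
positive pairs and a 1:1 negative set. The interaction signal is planted in
the sequences: eight motif families form four complementary pairs
(family 2f−1 binds family 2f); a protein carries 0–2 family memberships
(probabilities 0.55 / 0.40 / 0.05), and each membership writes up to three
copies of a 12-residue family motif into disjoint segments of the sequence,
each copy mutated at 5 % of positions. Positives are sampled among
complementary carriers, so the label is a pure function of sequence content
and localization-based negative sampling stays non-circular (localization is
independent of sequence here, so it cannot leak the label).

The motif dosage was calibrated once, against the generator's own contract
that the signal be linearly recoverable — a ridge-logistic probe on summed
pair CT features reaches AUC ≈ 0.89 at the default seed (the suite requires
> 0.8) — while chance complementary pairs stay rare (~2–3 % of negatives,
which bounds the attainable AUC well above the acceptance level). With a
carrier rate near 45 %, carrier status gives linear models a first-order
signal while *which* families pair remains a second-order signal that only
interaction-aware models exploit.

What passing tests on this benchmark do **not** show about real data: no
homology or domain grammar beyond a single motif per family, no
composition–localization coupling, no assay noise in the labels (beyond
chance complementary pairs landing in the negative set), and i.i.d.
background rather than realistic low-complexity structure. Results here
demonstrate the machinery recovers a sequence-encoded signal; they are not
an estimate of accuracy on curated interactomes.

The label-permutation control re-runs the stacking on training labels
permuted at a derived seed and scores the out-of-fold ensemble predictions
against the *true* labels. Scoring against the permuted labels themselves
would be biased upward by a well-known cross-validation artifact — pairs
sharing a protein let fold models memorise per-protein positive rates even
for meaningless labels — whereas the true labels are independent of
everything a permutation-trained model can learn, so the control
concentrates tightly at AUC 0.5.

## Problem sizes and numerical choices

The shipped configuration trains the 16-learner ensemble on 800 pairs
(five-fold, so 640 per fold model, doubled by orientation augmentation) for
up to 8 epochs with early stopping (validation fraction 0.15, patience 4),
evaluates on 200 held-out pairs, and runs the permutation control as a
single-technique (CT) ensemble — sizes chosen so a complete run, including
the control, fits comfortably in a coffee break on one CPU while the
encoder and stacking layers are exercised at full fidelity. Scores at
exactly 0.5 count as positive; metrics with zero denominators return 0 with
a warning; AUC is the rank-based Mann–Whitney form with half-credit ties
(cross-checked against an established ROC implementation); fold assignment,
negative sampling, weight initialization and shuffling each consume an
explicitly derived seed, and no package function touches the caller's RNG
stream.

## Known limitations

* Training is CPU-bound R + small compiled kernels: suitable for
  desk-scale studies (thousands of pairs), not proteome-scale scans.
* The identity filter's all-against-all alignment is quadratic; for large
  positive sets an external clustering tool is the practical route.
* The conv/attention widths are deliberately small; raising `channels`
  scales attention quadratically in sequence positions.
* Stacking trains `16 × 5` networks; the `"sep"` and `"concat"` variants
  are the cheap alternatives when a single representation suffices.
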
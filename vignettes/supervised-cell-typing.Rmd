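---
title: "Supervised cell typing from binary expression profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised cell typing from binary expression profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scident)
```

## The classification model

`scident` treats cell-type assignment as supervised classification of
binarized expression profiles. A cell enters the network as a vector in
$\{0,1\}^G$ over a fixed reference **gene space**: position $i$ is 1 iff the
cell has at least one UMI for gene $i$. The gene space is the identity of
the input nodes — it is fixed when a model is initialized and every dataset
is aligned onto it (`align_to_gene_space()`) before prediction, with missing
genes zero-filled and extra genes dropped. A reference space of ~16,000
human–mouse homologous genes lets one architecture serve both species; the
package accepts any symbol list.

The network itself is deliberately small: two ReLU hidden layers of 200 and
100 units, dropout 0.4 after each hidden layer, and a softmax output with
one node per catalog class — $K$ known types plus a mandatory **Unknown**
class. Unknown is a real output trained on real examples, not a confidence
threshold: synthetic unknown profiles are manufactured by permuting the gene
values within individual cells (`synthesize_unknown()`), which preserves
each cell's library complexity while destroying all co-expression, so the
class learns "statistically plausible but biologically incoherent".

**Why binarization works.** A single UMI is digital evidence that a
transcript was present; thresholding at count > 0 is therefore the natural
presence call on UMI platforms, and it is what makes profiles from
different depths, chemistries and species comparable without any
normalization. The cost is that graded expression differences are invisible
— two types distinguished only by expression *level* of shared genes cannot
be separated. That trade-off is inherent to the design, not a bug.

## Training

Training minimizes class-weighted categorical cross-entropy with mini-batch
SGD plus momentum. The defaults in `train_config()` are: batch size 1024,
20% stratified validation hold-out, learning rate 0.01, momentum 0.9, and
early stopping with patience 3 on validation loss, restoring the
best-epoch weights. Stratification of the split is a deliberate choice —
with atlas-style class imbalance an unstratified 20% split can leave a rare
type entirely outside one partition. Early stopping is automated (the
alternative, eyeballing the train/validation gap, is not reproducible).
Class weights follow the balanced inverse-frequency form
$w_c = N/(K N_c)$, which satisfies $\sum_c w_c N_c = N$ exactly and gives
every class equal pull on the loss regardless of its sample size.

The optimizer hyper-parameters (learning rate, momentum) and the weight
initialization (scaled-uniform fan-in,
$U(\pm\sqrt{6/n_\mathrm{in}})$, zero biases) are exposed in the
configuration objects. All randomness — initialization, the validation
split, batch shuffling, dropout masks — flows through explicit seeds, so a
training run is bit-reproducible on one CPU thread.

Small datasets need different SGD settings than atlas-scale ones: with a
few hundred cells, batch 1024 collapses an epoch into one or two updates.
The package's own tests therefore use smaller batches (64–256) and a higher
learning rate (0.05) on its small fixtures; the defaults remain tuned to
the large-data regime the architecture was designed for.

## Continual learning

Two upgrade protocols are supported, both starting from the current
parameters rather than reinitializing.

**Online update** (`online_update()`) continues training on new data whose
labels are already in the catalog. Its failure mode is catastrophic
forgetting — e.g. updating on a batch labeled entirely Unknown will drag
every output toward Unknown. **Review training** counters this: after each
epoch on the new data, one pass is made over a fresh random sample
(default 4000 cells, without replacement within an epoch) from the retained
previous-training pool, which the model stores alongside its weights. The
replay happens as a discrete pass after each epoch rather than being mixed
into every mini-batch; upgrades run their configured number of epochs in
full so the review schedule is honored exactly, with no early stopping.

**Catalog expansion** (`expand_catalog()`) adds new types: new output
columns are inserted just before the terminal Unknown class (existing
columns are copied by class name, new ones freshly initialized with zero
bias), and the first hidden layer is frozen — its weights are bit-identical
before and after — so the feature transform learned from the original
training corpus is reused for the new types. The second hidden layer and
the output layer train on the combined old+new-type data with review. The
version tag increments (v1 → v2) on expansion. Whether an online update
should also freeze layers is genuinely open; the package trains all layers
there, on the reasoning that an optimization upgrade is meant to refine the
features themselves, while an expansion is meant to reuse them.

Expansion has to overcome an entrenched response: the base model maps
new-type cells confidently to Unknown, and only two of three layers can
adapt. The package's expansion benchmark therefore runs a longer, hotter
schedule (30 epochs at learning rate 0.05) than the base fit; with it, new
types are absorbed predominantly *from* the Unknown class while old-type
concordance is essentially untouched.

## Signature genes by information gain

For a type $T$ (one-vs-rest membership) and gene $G$ (present/absent), the
gain is

$$\mathrm{Gain}(T,G) = H(T) - \sum_{j\in\{1,0\}} P(G{=}j)\,H(T \mid G{=}j),$$

computed in bits from the 2×2 contingency table with the convention
$0 \log 0 = 0$ and clipped at zero against rounding. For binary variables
this equals the mutual information $I(T;G)$, which the test suite exploits:
an independent brute-force oracle computes $H(T)+H(G)-H(T,G)$ from the full
joint distribution and the two must agree to $10^{-12}$ (absolute — tiny
gains make relative comparison meaningless at machine precision). The
one-vs-rest reading is used because it is the only one for which a 2×2
table is sufficient; a multi-class variant over the whole catalog would
need the full $K{\times}2$ table and answers a different question. The
logarithm base affects only the unit, never the ranking; ties break
lexicographically by symbol so rankings are deterministic. `top_signature_genes()`
returns the top 50 by default, the conventional signature size.

## The synthetic data generator

`generate_labeled_dataset()` draws independent Bernoulli genes given the
type: each type owns `markers_per_type` (40) marker genes present with
probability 0.8 in their own type and 0.05 elsewhere; 1500 background genes
are present at 0.10 everywhere; and an extra dropout factor (0.1)
multiplies every presence probability, emulating technical signal loss.
Defaults produce 6 balanced types × 500 cells over 1740 genes. These rates
give roughly 200 present genes per cell with a marker-to-background
contrast comparable to strong canonical markers in binarized UMI data.
`generate_upgrade_benchmark()` layers the two-phase upgrade design on top:
a base catalog with shuffled unknowns, a held-back set of unseen types
labeled Unknown in phase 1 and specifically in phase 2, and held-out test
sets for both phases.

What the generator deliberately does **not** model: gene–gene correlation
beyond type structure, sequencing-depth gradients, doublets, batch effects
and ambient RNA. Passing the package's tests therefore demonstrates that
the machinery is correct — alignment, binarization, weighting, training,
replay, freezing, ranking — on data satisfying the model's assumptions. It
does not certify accuracy on real tissue, where label noise and correlated
dropout matter; published concordances on annotated atlases are the
benchmark for that, and reproducing them requires those external corpora.

## Numerical and edge-case choices

* Softmax is computed with per-row max subtraction; cross-entropy clamps
  probabilities at $10^{-12}$.
* Prediction ties break to the lowest catalog index, so an exactly uniform
  output maps to the first class deterministically.
* Duplicate gene symbols (after uppercasing and whitespace stripping)
  collapse by element-wise maximum — presence-preserving, which is the only
  property the downstream binary signal needs.
* Alignment fails hard when fewer than 20% of reference genes are found in
  the input: near-total mismatch means the wrong species or annotation,
  and silently predicting from mostly-zero profiles would be worse than an
  error.
* Model archives are JSON with weights as base64 little-endian doubles:
  round-trips are bit-exact, which decimal serialization cannot promise.
* k-fold assignment deals each class round-robin with a rotating offset,
  giving stratified folds whose sizes differ by at most one; classes
  smaller than k trigger a warning and an unstratified split.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the default generator
(3000 cells × 1740 genes) for training-recovery checks, the 8-type
upgrade benchmark (4000 cells × 1820 genes) for the continual-learning
properties, a 2-type 50:1 imbalanced variant for the class-weighting
property, and reduced 4-type fixtures (400 cells × 380 genes) for k-fold
cross-validation — sizes at which every property is measurable in seconds
while leaving the default configuration identical to the large-data
regime.

## Known limitations

Binary features discard expression magnitude; closely related subtypes
separated mainly by level differences will confuse the classifier. The
replay pool travels with the model archive, which grows it; review training
silently degrades to plain online updates (with a warning) if the pool was
stripped. The CPU implementation is plain BLAS matrix algebra — ample for
catalogs of tens of types and gene spaces of ~16k, but not engineered for
million-cell training corpora in one sitting.
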
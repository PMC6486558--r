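# scident

Supervised cell-type identification for single-cell RNA-seq, built on
binarized (present/absent) expression profiles and a small fully connected
neural network with an expandable cell-type catalog.

## The problem

Most scRNA-seq analyses start with unsupervised clustering followed by
manual annotation of each cluster from canonical markers — slow, subjective,
and redone for every dataset. `scident` takes the supervised route: a
classifier trained once on annotated atlas-scale data assigns a type to each
new cell directly from its expression profile. Three ideas make this
practical across platforms and species:

1. **Binary features.** UMI counts are reduced to presence/absence
   (count > 0 → 1) over a fixed reference gene space, much as flow cytometry
   discerns cell types from the presence of a handful of surface markers.
   Binarization removes depth and platform effects without normalization,
   and tolerates dropout the way image classifiers tolerate dead pixels.
2. **An explicit "Unknown" class.** The catalog of K known types always
   carries a (K+1)-th Unknown output, trained on synthetic profiles made by
   shuffling gene values within real cells — profiles with realistic library
   complexity but no coherent co-expression. Cells of types the model has
   never seen land there, rather than being forced into the closest known
   type.
3. **Continual learning.** A trained model is upgraded, not retrained:
   *online updates* continue SGD on new data while "review training"
   replays a random sample of earlier training cells after each epoch to
   prevent catastrophic forgetting; *catalog expansion* adds new output
   nodes for new types while freezing the first hidden layer, so the learned
   feature transform is reused and predictions on the old types are barely
   disturbed.

## The model

A cell is a binary vector \(x \in \{0,1\}^G\) over the reference gene
space. The network is

\[ x \rightarrow \mathrm{ReLU}(W_1 x + b_1) \rightarrow
   \mathrm{ReLU}(W_2 h_1 + b_2) \rightarrow
   \mathrm{softmax}(W_3 h_2 + b_3) \in \Delta^{K+1} \]

with hidden widths 200 and 100, dropout 0.4 after each hidden layer, and
one softmax output per catalog class. Training minimizes class-weighted
categorical cross-entropy (weights \(w_c = N/(K N_c)\) so rare types are
not drowned out) by mini-batch SGD (batch 1024), with a stratified 20%
validation hold-out and early stopping on validation loss.

Signature genes for each type are ranked by information gain: for binary
type membership \(T\) and gene status \(G\),

\[ \mathrm{Gain}(T, G) = H(T) - \sum_{j \in \{1,0\}} P(G=j)\, H(T \mid G=j), \]

the mutual information between the two, computed from a 2×2 contingency
table per (gene, type) pair.

## Worked example

```r
library(scident)

# a synthetic dataset with planted marker structure: 6 types x 500 cells,
# 240 marker + 1500 background genes
ds <- generate_labeled_dataset(synthetic_config(seed = 7))
dim(ds$x)
#> [1] 3000 1740

# add shuffled "unknown" training cells, weight classes, train
unk    <- synthesize_unknown(ds$x, 500, seed = 7)
x      <- rbind(ds$x, unk)
labels <- c(ds$labels$label, rep("Unknown", 500))
cw     <- compute_class_weights(labels, ds$catalog)
model  <- init_model(ds$catalog, gene_space(colnames(ds$x)), seed = 7)
model  <- train_classifier(model, x, labels,
                           config = train_config(max_epochs = 30, seed = 7),
                           class_weights = cw)
glance(model)
#> # A tibble: 1 × 8
#>   version n_genes n_known_types n_classes n_parameters epochs_trained
#>   <chr>     <int>         <int>     <int>        <dbl>          <int>
#> 1 v1         1740             6         7       369007             30
#> # ℹ 2 more variables: final_val_loss <dbl>, final_val_accuracy <dbl>

# predict fresh cells drawn from the same generator
fresh <- generate_labeled_dataset(synthetic_config(seed = 107,
                                                   cells_per_type = 100))
pred  <- predict(model, fresh$x)
pred[1, 1:3]
#> # A tibble: 1 × 3
#>   cell_id predicted_type max_probability
#>   <chr>   <chr>                    <dbl>
#> 1 cell_1  Type1                    0.990
concordance(pred$predicted_type, fresh$labels$label)
#> [1] 1

# signature genes for Type1: the planted markers rank on top
top_signature_genes(ds$x, ds$labels$label, "Type1", n = 5)
#> # A tibble: 5 × 7
#>    rank gene  gain_bits   n11   n10   n01   n00
#>   <int> <chr>     <dbl> <int> <int> <int> <int>
#> 1     1 M1_26     0.301   378   122    95  2405
#> 2     2 M1_38     0.289   379   121   113  2387
#> 3     3 M1_20     0.287   366   134    92  2408
#> 4     4 M1_35     0.285   385   115   132  2368
#> 5     5 M1_40     0.282   363   137    94  2406
```

The concordance of 1.0 says every fresh cell was assigned its generating
type; the gains near 0.3 bits reflect markers present in ~75% of their
own type and ~4% elsewhere.

A command-line interface wraps the same functions
(`inst/exec/scident train|predict|update|expand|evaluate|signatures|simulate`);
every command is deterministic given `--seed`.

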
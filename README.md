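# prip

Residue-level prediction of protein–RNA binding interfaces from primary
sequence alone, for structural bioinformaticians and anyone triaging
candidate RNA-binding residues before experiments or docking.

## The method

RNA-binding interfaces are predicted per residue. A protein chain is read as
a sentence whose words are its amino acids, and three stages turn it into
per-residue probabilities:

1. **Semantic dictionary.** Residue-level word embeddings are trained on a
   corpus of protein chains with a single-worker CBOW or skip-gram
   negative-sampling model (default: CBOW, 25-dimensional vectors, context
   window 5, 5 negative samples, 200 epochs). Each amino acid ends up with a
   vector whose geometry reflects its sequence contexts; the pairwise
   relation between residues *A* and *B* is the cosine
   cos θ = Σᵢ AᵢBᵢ / (‖A‖‖B‖).
2. **Windows.** Each chain is divided into one fixed-length window per
   residue, centred on it, with *n* residues up- and downstream and `X`
   padding past the termini (default window length 2n+1 = 39). A window's
   feature vector is the concatenation of its residues' embeddings (`X`
   contributes a zero block); its label is the centre residue's interface
   status — interface meaning at least one atom strictly closer than 5 Å to
   any RNA atom in the complex.
3. **Classifier.** A regularized second-order gradient-boosted tree
   ensemble, written from scratch: per boosting round the first and second
   derivatives g, h of the class-weighted logistic loss are computed at the
   current margins, a tree is grown by exact greedy search maximizing the
   gain ½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)] − γ, leaves get weights
   −G/(H+λ), and shrinkage η scales each tree's contribution. The positive
   class is up-weighted by N_neg/N_pos by default, which moves the operating
   point toward sensitivity — the appropriate regime for the heavily
   imbalanced interface problem.

Around the core, the package provides the composition baselines (AAC, DPC,
CKSAAPGP), SN/SP/ACC/MCC and ROC/AUROC with stratified k-fold
cross-validation, a window-length scan, semantic-specificity testing of the
embedding space against shuffled-corpus null embeddings (epoch ensembles,
pooled t-test p-value matrix), positional residue enrichment between
positive and negative windows, and a synthetic benchmark generator that
plants a realistic compositional interface signal (R/K/G enriched, L/A/E/V
depleted near interface patches).

## A worked example

```r
library(prip)

# a synthetic benchmark: 300 chains, ~15% interface residues in patches,
# R/K/G enriched near interfaces
chains <- simulate_chains(sim_config(seed = 1))
train  <- chains[1:240, ]
test   <- chains[241:300, ]

model <- prip_train(train, window_n = 9,
                    embed_params = embedding_params(dim = 12, epochs = 40),
                    params = gbt_params(nrounds = 70, max_depth = 4))
model
#> <prip_model> window 19, dictionary 20x12, 70 trees

ev <- prip_evaluate(model, test)
ev$metrics
#> # A tibble: 1 x 5
#>      SN    SP   ACC   MCC AUROC
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.733 0.814 0.802 0.441 0.855
```

`SN = 0.73` says 73% of the true interface residues are recovered at the
default 0.5 threshold — far above the 15% base rate, thanks to the
N_neg/N_pos class weighting (an unweighted fit on the same features drops
well below this sensitivity); `AUROC = 0.86` is threshold-free
discrimination on held-out chains. `autoplot(ev$roc)` draws the ROC curve.
On chains simulated with `motif_boost = 1` (no planted signal) the same
pipeline stays at `AUROC ≈ 0.5`, as it should.

Per-residue predictions for new (or unlabelled) sequences:

```r
pred <- prip_predict(model, test[1, ])
head(pred, 3)
#> # A tibble: 3 x 5
#>   chain_id position residue probability  call
#>   <chr>       <int> <chr>         <dbl> <int>
#> 1 sim0241         1 I            0.0919     0
#> 2 sim0241         2 E            0.0780     0
#> 3 sim0241         3 S            0.0503     0
```

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "prip.R", package = "prip"))') \
  train --fasta train.fasta --labels train.tsv --out model.json
```

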
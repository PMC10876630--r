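# ddiFusion

Multi-class prediction of **drug–drug interaction (DDI) events** from
multimodal drug features, for computational pharmacologists and method
developers who need a complete, testable reference pipeline: feature
encoding, similarity featurization, a fused multi-input convolutional
classifier, classical baselines, and the statistical machinery to compare
them.

When two drugs are co-administered, the outcome is not merely "interacts
/ does not interact" but one of many categorized pharmacological events
(increased serum concentration, potentiated QT prolongation, reduced
metabolism, ...).  Given a catalogue of interacting pairs labelled with
one of E event classes, and per-drug token sets in four feature
modalities — chemical **s**ubstructure keys, **t**argets, **e**nzymes,
**p**athways — the pipeline is:

1. **Binary encoding.** Per modality, drug *i* becomes a bit vector
   x_i over the sorted token vocabulary (1 = token present).
2. **Jaccard similarity.** Per modality an N×N matrix with entries
   J(x_i, x_k) = |x_i ∧ x_k| / |x_i ∨ x_k| ∈ [0, 1] (cosine available).
3. **Pair vectors.** A labelled pair (a, b) becomes, per modality, the
   concatenation of similarity rows a and b (length 2N).
4. **Fused conv classifier.** Each modality feeds a branch: Conv1D
   (1 filter, kernel 5, tanh) → flatten → dense 1024/512/256, each with
   batch norm, ELU and dropout 0.3.  Branch outputs are concatenated
   into an E-way softmax head.  Training: Adam, categorical
   cross-entropy, early stopping on a validation slice.
5. **Evaluation.** Event-stratified k-fold CV over pairs; accuracy,
   macro/micro F1, micro-averaged AUC and AUPR, precision@k ranking;
   feature-subset ablation (all 15 modality subsets), a
   layers×activation hyperparameter grid, baselines (random forest with
   100 trees, k-NN with k = 4, multinomial logistic regression, a
   dense-only network), and paired t-tests plus one-way ANOVA across
   shared folds at α = 0.05.

A synthetic-data module generates drug feature tables and interaction
records with *planted, learnable* event structure (and returns the
noise-free labeler as an oracle), so the entire pipeline is exercised
end-to-end without any external database.  The neural network is
implemented in the package itself (R reference loop + compiled
Armadillo fast path), with gradients verified against numerical
differentiation in the test suite.

## Worked example

```r
library(ddiFusion)

# synthetic study: 120 drugs, 8 event classes, 600 interacting pairs
fx  <- makeFixture("small", seed = 5)
enc <- runEncode(fx$paths$features, fx$paths$interactions)
ds  <- buildPairDataset(enc, k = 5, seed = 1)
ds
#> PairDataset: 600 records, 8 event classes, modalities: substructure, target, enzyme, pathway
#>   folds: 5

# vocabulary and similarity shape
vocabularySize(enc$vocabularies$target)
#> [1] 30
dim(similarityValues(enc$similarities$substructure))
#> [1] 120 120

# cross-validated fused model (reduced epochs for the example)
lens <- vapply(pairMatrices(ds), ncol, integer(1))
cfg  <- modelConfig(lens, nEvents(ds), epochs = 20, seed = 1)
rep  <- evaluateCV(ds, cfg)
formatReport(rep)
#> Model        Features           ACC      F1     AUC    AUPR
#> fusedConv    substructure+target+enzyme+pathway  0.4683  0.4477  0.8138  0.4560
```

The `ACC` column is held-out accuracy over the 8 event classes (chance
= 0.125); `F1` is macro-averaged; `AUC`/`AUPR` are micro-averaged over
the flattened record×class matrix.  At this deliberately small scale
the model sits far above chance but well below its asymptote; the
`medium` fixture (400 drugs, 20 events, 10,000 pairs) is the
desk-scale study: there the fused model's 5-fold CV accuracy reaches
about 0.80 against the generator's oracle ceiling of 0.90, and ranking
precision among the top-100 scored pairs is about 0.9 (both recomputed
by `scripts/acceptance.R`; see the methods vignette for why the
remaining gap to the ceiling is a supervision-density effect).

Compare against baselines on shared folds:

```r
cmp <- runCompare(ds, cfg, baselines = list(baselineConfig("knn")))
cmp$summary      # per-model fold-mean metrics
cmp$tTests       # paired t-test per metric, significance at 0.05
```

## Reproducing at full scale (external data)

The pipeline reads the community-standard delimited formats directly.
With the public DDIMDL-style dataset (572 drugs, 74,528 raw
interactions over 65 event classes, derived from DrugBank) exported as
`drug_features.tsv` (drug_id / modality / token) and
`interactions.tsv` (drug_a / drug_b / event):

```sh
Rscript inst/cli/ddifusion evaluate \
  --features drug_features.tsv --interactions interactions.tsv \
  --out results/full --folds 5 --epochs 100
```

Expected shapes along the way: vocabularies of 808 (substructure),
1,162 (target), 202 (enzyme) and 957 (pathway) tokens; four 572×572
similarity matrices; 37,264 unique pairs after deduplication; 5-fold
accuracy in the region of 0.90.  This run needs the external download
and several CPU-hours; nothing in the test suite depends on it.
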
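# methCascade

Prediction of DNA N4-methylcytosine (4mC) sites from 41-bp sequence windows
centred on a cytosine, for researchers studying bacterial and eukaryotic
epigenetic modification who need a self-contained, reproducible predictor
and evaluation harness.

4mC marks participate in restriction–modification systems, DNA repair and
gene regulation, and experimental mapping of individual sites is costly.
`methCascade` implements a sequence-based classifier built from three
components:

1. **k-mer word embeddings.** A window of length *L* is tokenized into its
   *L − k + 1* overlapping k-mers (39 trinucleotides for *L* = 41, *k* = 3),
   and a CBOW word2vec model (trained in compiled code, bitwise
   reproducible for a fixed seed) maps each k-mer to a 100-d vector, giving
   a 39 × 100 feature matrix per window.
2. **A weighted-average ensemble of small 1-D CNNs.** Three fixed
   convolutional architectures (conv–conv–dropout–dense–sigmoid, trained by
   Adam on binary cross-entropy) are combined as
   *p* = Σ*w*ₘ*p*ₘ / Σ*w*ₘ, with the weight tuple chosen by exhaustive
   grid search over {0, 0.1, …, 1}³ at every layer.
3. **A dynamic multilayer cascade.** After each layer, correctly classified
   test records are promoted into the training set and the misclassified
   remainder becomes the next layer's test set; the loop ends when a layer
   adds no correct calls. The headline statistic is the cumulative total
   accuracy *TA* = Σᵢ(TPᵢ + TNᵢ)/S_Test over the **initial** test size.

Supporting modules cover FASTA I/O, greedy identity-based redundancy
filtering, class balancing, stratified splitting, a confusion-matrix metric
suite with ROC/AUC, a planted-motif synthetic data generator, and a CLI
(`inst/cli/methcascade.R`). See the methods vignette
(`vignettes/methCascade-methods.Rmd`) for the model, its assumptions and
design choices.

## Worked example

Generate a separable synthetic benchmark (400 windows, planted motif beside
the central C), split 80:20, and run the cascade with the three CNN presets:

```r
library(methCascade)

ds  <- generateDataset(syntheticSpec(nPos = 200, nNeg = 200, seed = 4))
sp  <- stratifiedSplit(ds, trainFraction = 0.8, seed = 4)
res <- runMLDS(sp$train, sp$test,
               learners = cnnPresets(epochs = 8, seed = 4), seed = 4)
res
#> MLDSResult: 2 layers, initial test size 80, total accuracy 1.0000
#>  layer train_size test_size TP TN FP FN w1 w2  w3 layer_accuracy cumulative_accuracy
#>      1        320        80 39 40  0  1  0  0 0.1         0.9875              0.9875
#>      2        399         1  1  0  0  0  0  0 0.1         1.0000              1.0000
```

Layer 1 trains on 320 windows and classifies 79/80 test windows correctly
(39 TP + 40 TN); the single false negative is promoted to layer 2's test
set, the 79 correct records join the training data, and layer 2 resolves
it, so the cumulative total accuracy reaches 80/80. The weight tuple
(0, 0, 0.1) says the grid search found the third preset alone sufficient at
both layers. Aggregate metrics and the layer-1 ROC:

```r
round(100 * computeMetrics(cascadeConfusion(res)), 2)
#>  accuracy precision    recall       fpr       tnr       fnr
#>       100       100       100         0       100         0
rocCurveAuc(res@assignments$prob_layer1, res@assignments$label)$auc
#> [1] 1
```

Note that the cascade's total accuracy inspects test labels when routing
records between layers (and, in the default faithful mode, when selecting
weights), so it is a self-referential training statistic, not a held-out
generalization estimate; `runMLDS(..., mode = "honest")` restricts weight
selection to an inner validation split.

`runPipeline()` wraps all stages (including embedding training and artifact
output — ledger TSV, metrics JSON, ROC TSV, run manifest) behind a single
config list, and the CLI exposes `run`, `simulate` and `evaluate`
subcommands over YAML configs.

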
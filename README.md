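# ptrnet

Protein abundance is what most biology runs on, but what we usually measure
is transcript abundance — and the two correlate imperfectly. Across a panel
of tissues, each gene follows its own approximately linear relationship on
the log-log scale,

    log2(iBAQ) = a * log2(TPM) + b,

where the gradient `a` acts as a per-gene protein-to-mRNA ratio (PTR)
parameter. `ptrnet` is for researchers with matched transcriptome–proteome
panels (bulk RNA-seq TPM/FPKM plus mass-spectrometry iBAQ intensities) who
want to (i) fit and classify these per-gene relationships, (ii) *predict*
`(a, b)` for unseen genes from sequence alone with a small two-branch
neural network, (iii) read the trained network back out as interpretable
sequence motifs and codon/amino-acid weights, and (iv) screen for
context genes whose transcript level carries information about other
genes' protein levels (the δ-extension
`log2(iBAQ) = a·log2(TPM) + b + ⟨δ, log2(TPM_context)⟩`).

The model has dense branches for histogram-like features (codon counts in
three reading frames, nucleotide and amino-acid counts, start/stop-codon
context windows) and single-layer convolutional branches (16 filters,
width 8/10/12, `max(0, tanh)`, sum-pooling, `log2(1+s)`) for the 5'UTR,
CDS, 3'UTR and protein sequences. Training uses plain SGD on a NaN-safe
mean squared error over the (gene, tissue) cells that passed detection
thresholds; prediction quality is the per-gene coefficient of
determination, computed independently for each gene, so r² = 0 means "no
better than the gene's average protein level". Trained convolutional
filters are clustered (OPTICS with xi extraction) into position-weight
motifs; dense-branch weights are averaged across cross-validation into
heatmaps. A synthetic-data generator with planted ground truth (known
`a`/`b`, implanted motifs, causal codons, master regulators) makes the
whole pipeline testable end to end without any external dataset.

## Worked example

```r
library(ptrnet)

# synthetic panel: 400 genes x 30 tissues, one causal codon (GAA, +0.05
# per count on the gradient), noise sd 0.3, detection-biased missingness
sim   <- generate_synthetic(generative_spec(seed = 11))
feats <- encode_features(sim$records)
part  <- partition_by_coverage(sim$dataset)   # >=21 points train, =20 hold out

# per-gene linear baselines
fits <- fit_all_genes(sim$dataset)
summary(fits$r2)

# train a single-feature codon-count model and score unseen genes
set.seed(42)
train   <- sample(part$training_genes, 347)
heldout <- setdiff(part$training_genes, train)
model <- ptr_model(list(dense_branch("codon_f0")), feats, seed = 5)
model <- train_ptr_model(model, sim$dataset, feats, genes = train,
                         lr = 1e-3, epochs = 256, seed = 5)
pred <- predict_ptr_matrix(model, sim$dataset, feats, heldout)
gi   <- match(heldout, sim$dataset$gene_ids)
r2_per_gene(pred, sim$dataset$log2_ibaq[gi, ],
            sim$dataset$valid_mask[gi, ])$mean
#> [1] 0.896785

w <- extract_gradient_weights(list(model), feats)$codon_f0
head(sort(w, decreasing = TRUE), 3)
#>         GAA         GCC         GTC
#> 0.098409854 0.007924122 0.007676985
```

The held-out mean r² of 0.90 says the model predicts unseen genes' protein
profiles almost up to the planted noise floor, and the largest learned
codon weight is the planted causal codon (GAA, positive), an order of
magnitude above every other codon.

A thin CLI wraps the same functions for shell pipelines
(`exec/ptrnet simulate | preprocess | baseline | train | crossval |
crosscorr`), writing TSV artifacts and a JSON run manifest per output
directory.

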
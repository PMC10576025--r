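# splicebalance

Interpretable additive strength models of exon inclusion from massively
parallel splicing reporter assays.

## The problem

Whether a variable middle exon is included in or skipped from a mature
transcript is decided by sequence and structure features distributed
along the exon. Massively parallel reporter assays measure a
percent-spliced-in (PSI) value for hundreds of thousands of barcoded
random exons, but black-box models trained on such data cannot say
*which* features drove each prediction. `splicebalance` implements an
interpretable-by-design alternative for R users working with such
assays: every prediction decomposes exactly into per-filter strengths on
an inclusion side and a skipping side.

## The model

Each of four *strength-computation modules* (SCMs) is

```
f(x) = Sum( Softplus( Conv(x; α) + β ) )
```

— a valid-mode 1D convolution over one-hot channels, a learned
per-position bias, a softplus, and a sum. Sequence SCMs use 20 filters of
width 6 over the 4 nucleotide channels; structure SCMs use 8 filters of
width 30 over 8 channels (sequence, dot-bracket structure, G–U wobble
indicator). The prediction is

```
PSI_hat = Tuner( f_incl_seq + f_incl_struct − f_skip_seq − f_skip_struct + B )
```

with a learnable basal strength `B` and a learned scalar link (an affine
sigmoid during early training, a small residual network in the final
model). Training minimizes Bernoulli KL divergence with l1 activity and
l2 smoothness regularization, in three stages (sequence SCMs → +
structure SCMs → + full tuner). A synthetic-assay generator with planted
motifs, GC-rich stem loops, and G-poor stretches makes every stage
testable by parameter recovery.

## Worked example

Simulate an assay with a known rule, preprocess it, fit the staged
model, and inspect what it learned:

```r
library(splicebalance)
library(dplyr)

assay <- build_synthetic_assay(n_exons = 3000, depth = 200, seed = 42)
dataset <- preprocess_assay(
  assay$records,
  structures = assay$truth[, c("barcode", "structure")],
  seed = 42)

cfg <- train_config(n_filters_seq = 8, n_filters_struct = 4,
                    epochs_stage1 = 120, epochs_stage2 = 30,
                    epochs_stage3 = 10, seed = 1)
model <- fit_splice_model(dataset, cfg, stages = 1:3)
model
#> <splice_model> d = 90 | 8 sequence filters (w=6) + 4 structure filters (w=30) per side
#>   tuner: full | basal B = -0.0088 | trained through stage 3

test <- filter(dataset, split == "test")
pred <- predict(model, test)
truth <- left_join(test, assay$truth[, c("barcode", "true_psi")], "barcode")
cor(pred$.psi_hat, truth$true_psi)
#> [1] 0.846
```

The held-out correlation of 0.85 against the *true* (noise-free) PSI at
this small training size rises above 0.97 at the 20,000-exon benchmark
scale. `tidy()` shows each filter's best-matching 6-mer; all six planted
motifs (`GAAGAA`, `CAUCGC`, `ACCUGA` on the inclusion side; `UAGGGU`,
`UCUUCU`, `GUGGAC` on the skipping side) surface as filter argmaxes:

```r
tidy(model) |>
  filter(scm %in% c("incl_seq", "skip_seq")) |>
  select(filter, side, best_kmer, kernel_norm)
#>    filter     side      best_kmer kernel_norm
#>  3 incl_seq:3 inclusion GAAGAA           4.61
#>  5 incl_seq:5 inclusion CAUCGC           2.06
#> 13 skip_seq:5 skipping  UCUUCU           4.40
#> 16 skip_seq:8 skipping  UAGGGU           3.87
#>  ... (remaining filters carry smaller kernel norms)
```

A balance summary explains one exon's prediction as stacked strengths —
here inclusion motifs outweigh the skipping side by a delta strength of
1.4, mapping to a predicted PSI of 0.91:

```r
balance_summary(test[7, ], model)
#> <balance_summary> delta strength 1.405 -> predicted PSI 0.909 (basal B -0.009)
#>   incl_seq:8       inclusion    1.928
#>   incl_seq:3       inclusion    1.599
#>   skip_seq:2       skipping     1.564
#>   skip_seq:3       skipping     1.001
#>   incl_seq:7       inclusion    0.985
```

`autoplot()` renders it as a balance plot. Other entry points:
`cluster_filters()` and `filter_logo()` summarize the learned filter
set, `nucleotide_relevance()` attributes a filter's strength to
individual nucleotides, `design_mutants()` proposes stem-disrupting /
compensatory and G-poor validation mutants, `artifact_check()` tests
whether a skipping feature behaves like a sequencing artifact, and
`adapt_model()` + `fit_assay_correction()` transfer a trained model to
assays with other exon lengths. A thin command-line wrapper lives at
`inst/cli/splicebalance.R` (subcommands `simulate`, `preprocess`,
`train`, `predict`, `interpret`, `crossassay`).

See the vignette (`vignettes/splicing-balance-model.Rmd`) for the model,
its assumptions, and all numerical choices.

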
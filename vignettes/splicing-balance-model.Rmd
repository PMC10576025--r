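---
title: "Modeling exon inclusion as a balance of feature strengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling exon inclusion as a balance of feature strengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicebalance)
library(dplyr)
```

## The model

`splicebalance` predicts the percent-spliced-in (PSI) of a variable middle
exon from its sequence and predicted secondary structure, using a model
that is interpretable by construction. The input is a triple of vectors
over a window of length $d = 90$ (a 70-nt variable exon plus 10 fixed
exonic flanking nucleotides on each side):

* $x_{\text{seq}} \in \{A,C,G,U\}^d$ — the one-hot encoded sequence;
* $x_{\text{struct}} \in \{(, \cdot, )\}^d$ — the dot-bracket secondary
  structure, one-hot over three categories;
* $x_{\text{wobble}} \in \{0,1\}^d$ — an indicator of nucleotides in a
  predicted G–U wobble pair.

The computational unit is the *strength-computation module* (SCM):

$$ f(x) = \mathrm{Sum}\big(\mathrm{Softplus}\big(\mathrm{Conv}(x; \alpha) + \beta\big)\big), $$

a valid-mode 1D cross-correlation with kernels $\alpha \in
\mathbb{R}^{w \times c \times k}$, followed by a learned per-position
bias $\beta \in \mathbb{R}^{(d-w+1)\times k}$, a softplus, and a sum of
all resulting strengths. Because softplus output is positive, every
filter contributes a non-negative *strength* (in arbitrary model units)
at every position, and the position bias lets that strength depend on
where along the exon a filter matches.

Four SCMs are instantiated: an inclusion and a skipping module on the
sequence alone ($w = 6$, $c = 4$, $k = 20$ by default — short filters for
splicing-factor-sized motifs), and an inclusion and a skipping module on
the structure-augmented sequence ($w = 30$, $c = 8$, $k = 8$ — long
filters able to span hairpins and extended sequence context). The model
output is

$$ \widehat{\mathrm{PSI}} = \mathrm{Tuner}\big(\underbrace{f^{\text{seq}}_{\text{incl}} + f^{\text{struct}}_{\text{incl}} - f^{\text{seq}}_{\text{skip}} - f^{\text{struct}}_{\text{skip}} + B}_{\Delta\ \text{strength}}\big), $$

the balance of total inclusion strength against total skipping strength,
offset by a learnable basal strength $B$ that represents the reporter
context's intrinsic inclusion propensity. We carry $B$ as an explicit
scalar term outside the link function rather than folding it into the
link's bias: the two are equivalent for prediction, but an explicit $B$
renders naturally as its own bar in balance plots and is the quantity
the cross-assay correction shifts.

The link ("tuner") comes in two forms: `tuner_prime()`, the affine
sigmoid $x \mapsto \sigma(\nu x + \eta)$ used in the early training
stages, and `tuner_full()`, a 3-layer fully connected network on the
scalar $\Delta$ with a residual connection from the input to the output
layer followed by a sigmoid. The hidden width (10 units, `tanh`) is a
package default — the architecture constrains only the residual + 3
layers — and the full tuner's monotonicity is audited on the observed
$\Delta$ range after training rather than enforced.

### Conventions

* Convolution is cross-correlation (no kernel flip), valid mode, the
  dominant convention in sequence models; position indices are window
  starts.
* Channel orders are fixed package-wide: sequence `A,C,G,U`; structure
  `(`, `.`, `)`; the structure SCM input is `[sequence(4), structure(3),
  wobble(1)]`.
* Coordinates are 1-based in R; the variable exon occupies positions
  11–80 of the 90-nt window. Inputs in the DNA alphabet are normalized
  T→U on entry.

## Training

The loss is the Bernoulli Kullback–Leibler divergence between measured
and predicted PSI, $\mathrm{KL}(p \,\|\, q)$ with the measured value as
the reference distribution, averaged over records; predictions are
clipped to $[10^{-6}, 1-10^{-6}]$ inside the loss. Two regularizers
serve interpretability:

* an *activity* term — the $\ell_1$ norm of all (post-softplus)
  strengths, which equals their plain sum by positivity; weight
  `lambda_act`, default $10^{-4}$. We take the norm after the
  activation because that is where "strength" is defined; a
  pre-activation penalty would not shrink the quantity the model
  reports.
* a *smoothness* term — the squared $\ell_2$ norm of the discrete
  derivative (first differences along position) of each position-bias
  column; weight `lambda_smooth`, default $10^{-3}$. It is invariant to
  adding a constant to a column, so it shapes the profile, not the
  overall offset.

Training is staged so that simple explanations are claimed by simple
components before more expressive ones enter:

1. **Stage 1** trains only the sequence SCMs under the affine-sigmoid
   link — short motifs are captured by short filters, not by the
   structure modules.
2. **Stage 2** adds the structure SCMs, warm-starting the sequence SCMs.
3. **Stage 3** promotes the link to the full tuner, initialized to
   reproduce the affine sigmoid exactly (residual weight $\nu$, output
   bias $\eta$, zero output weights), and fine-tunes everything.

Optimization is Adam (learning rate $10^{-2}$, batch 128 — package
defaults; no values are dictated by the model itself), single-threaded
and reproducible from one seed. Gradients are computed analytically in
compiled code and are verified against numerical differentiation in the
test suite. Hyperparameters can be chosen with `grid_search()`, which
scores each $(\lambda_{\text{act}}, \lambda_{\text{smooth}})$ point by
held-out KL and by a *sparsity* metric — the mean minimum number of
strengths, re-added greedily in decreasing magnitude, needed to bring a
record's KL below a threshold (default 0.05 nats; the greedy order and
the threshold are package choices) — and, among admissible points,
prefers the strongest smoothness regularization.

## The synthetic assay generator

Real reporter assays of this design deposit hundreds of thousands of
barcoded exons; the package instead ships a generator with a *known*
additive rule, so that every downstream stage can be benchmarked by
parameter recovery rather than by eye. `build_synthetic_assay()`
emulates:

* random 70-nt exons between fixed 10-nt flanks;
* planted features with additive, position-dependent strengths: six
  6-mer motifs (three inclusion, three skipping; strengths 2.5/2.0/1.5
  with piecewise-linear position profiles between 0.5 and 1.5), planted
  with probability 0.25 each per exon;
* a stem-loop skipping feature: GC-rich hairpins (arm length 5–7)
  planted in 15% of exons; the predicate awards strength 1.5 per helix
  run of length 5–7 whose pairs are at least 80% G–C. The GC-richness
  requirement mirrors the short, GC-rich double-stranded regions such
  models recover from real data, and it keeps the feature rare among
  chance helices of the maximum-pairing folder — a folder that pairs far
  more aggressively than a thermodynamic one;
* a G-poor skipping feature (strength 1.0) firing when any 30-nt window
  holds at most two Gs;
* a sigmoidal strength-to-PSI link ($\nu = 1$, $\eta = 0$), and binomial
  read sampling per barcode at configurable depth — no published noise
  model exists for such assays, and binomial reads given PSI is the
  natural minimal choice — with 2% of reads assigned to non-informative
  outcome categories.

Secondary structure comes from `fold_toy()`, a Nussinov maximum-pairing
fold (minimum hairpin loop 3, deterministic 5′-most tie-breaking). It is
*not* an energy model and claims no parity with thermodynamic folding
tools; real datasets should supply externally predicted dot-bracket
strings. Consequently, passing recovery benchmarks here demonstrates
that the pipeline can identify additive sequence/structure rules under
binomial read noise — it does not certify accuracy on biological data,
whose structure predictions, replicate structure, and feature classes
are richer.

## Interpretation

* `balance_summary()` decomposes one prediction into per-filter total
  strengths; the signed bar sum reproduces $\Delta$ exactly (to floating
  tolerance), because it is the same sum the forward pass computes.
* `cluster_filters()` groups redundant sequence filters by hierarchical
  clustering (average linkage, correlation distance, tree cut at 0.3 by
  default) of their per-exon strength vectors; the strongest member
  represents each cluster. Related stem-loop filters can be merged
  manually where desired.
* `filter_logo()` defines "positive activation" on the *position-
  adjusted pre-activation* $z + \beta > 0$ — post-softplus strengths are
  always positive and cannot define an activating set. Short filters are
  scored by exhaustive enumeration of all $4^6$ 6-mers; long filters by
  an enrichment–depletion logo over dataset windows.
* `nucleotide_relevance()` uses the $\epsilon$-stabilized proportional
  redistribution rule ($\epsilon = 10^{-6}$) through the softplus and
  convolution; the position-bias share of each window is split evenly
  across the window, so contributions sum to the filter's total
  strength up to the stabilizer.
* `design_mutants()` implements the validation logic for structure
  features: for a stem, two single mismatch mutants (one per arm, at the
  middle pair) plus the compensatory double mutant that swaps the
  partners; for a G-poor stretch, a single C→G at the center of the
  activated window. Proposals that move any other filter by more than
  10% of the largest target-strength change (a package default; no
  published threshold exists) are rejected. On synthetic data mutants
  are re-folded with the toy folder; with external structures, supply
  refolded variants.
* `artifact_check()` contrasts a bona fide skipping feature (fewer
  inclusion reads *and* more skipping reads) with an enzymatic/
  sequencing artifact (fewer inclusion reads, skipping unchanged) using
  rank-based two-group tests (Wilcoxon, $\alpha = 0.05$; groups under 10
  records are inconclusive). The choice of test is ours; only the
  directional logic is dictated by the read-counting argument.

## Cross-assay transfer

To score exons of another length, `adapt_model()` resamples every
position-bias column with Lanczos interpolation (window parameter
$a = 3$) under a proportional endpoint-to-endpoint position mapping with
edge clamping (the coordinate map is a package choice), and
`fit_assay_correction()` fits one scalar shift of the basal strength per
assay by golden-section search on mean KL (tolerance $10^{-4}$), all
other parameters frozen. Resampling is applied once, on the full
position axis of each bias matrix. At the native length the resampler is
the identity, so transfer with a zero correction reproduces the base
model.

## Preprocessing

`preprocess_assay()` reproduces the assay's retention rules exactly:
barcodes need at least 60 total reads; the Esp3I recognition site
(`CGTCTC`, reverse complement `GAGACG` — the enzyme's published site,
fixed here as a config default) must be absent from both strands of the
exon and the barcode; and inclusion plus skipping must make up at least
80% of reads. The 60-read threshold is applied to the total across all
outcome categories, which is how "total reads" is most naturally read;
PSI is `n_inclusion / (n_inclusion + n_skipping)`. `resolve_barcode_map()`
drops barcodes pairing with more than one exon (ignoring exon sequences
seen only once, which are likely sequencing errors) or with fewer than
two DNA reads. The train/test split is 80/20 with half-away-from-zero
rounding of $0.8 n$, seeded.

## Problem sizes and numerical choices

The recovery benchmark used throughout the package's checks is a
20,000-exon assay at read depth 200 with 8 filters per SCM, trained
through stages 1–2 (200 + 40 epochs) — comfortably desk-scale (a few
minutes on one core) while leaving the planted rule overdetermined.
Smaller configurations (hundreds to ~1,200 exons, 2–4 filters) exercise
the schedule contracts. Initialization draws kernels from
$N(0, 0.05^2)$ with position biases at $-4$ so initial strengths start
near zero; softplus and sigmoid use overflow-safe branches; ties in the
greedy sparsity and matching procedures resolve by first index.

## Limitations

* The toy folder's structures are maximum-pairing, not minimum-energy;
  structure-dependent conclusions on real data require externally
  predicted structures for both originals and mutants.
* The generator's distributional choices (planting rates, depth model,
  2% non-informative reads) are stand-ins for testing, not claims about
  any real assay.
* Monotonicity of the full tuner is audited, not enforced.
* Training is single-threaded by design for reproducibility;
  multi-threaded numerical identity is not claimed.
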
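---
title: "Functional gene embeddings: models, benchmarks and annotation inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional gene embeddings: models, benchmarks and annotation inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package does

A functional gene embedding is a numeric vector per gene that summarises
what the gene does, learned from data rather than curated by hand. This
package builds such embeddings from two kinds of raw material — collections
of genes-by-samples omics matrices, and evidence-channel protein-interaction
networks — and evaluates them with the benchmark suite that matters for
statistical genetics: curated-style gene-list classification, multi-label
phenotype prediction, rare-variant gene recall, and regression of gene-level
GWAS z-scores under linkage-disequilibrium-aware whitening. A seeded
synthetic-data generator provides worlds with a known ground truth, so every
pipeline stage can be validated end to end, including the package's central
methodological concern: *annotation inequality*, the concentration of
literature and curation on a small fraction of well-studied genes, which
biases both inputs and benchmarks.

## The variational deep tensor factorization

`vdtf()` learns one shared gene embedding from several matrices
$X^{(l)}$ (genes × samples) that cover overlapping but different gene sets.
Each dataset reconstructs its entries as

$$\hat{x}^{(l)}_{ij} = f_l\!\left(a^{(l)}_i,\; b^{(l)}_j\right),$$

where $b^{(l)}_j$ is a sample embedding, $f_l$ a three-layer feed-forward
network with leaky-ReLU activations applied to the concatenation of the two
embeddings, and the dataset-specific gene embedding is a random draw around
the shared one:

$$a^{(l)}_{ik} \sim \mathcal{N}\!\left(a_{ik},\, \sigma^2_{ik} + v^{(l)}_{ik}\right).$$

The objective is the negative evidence lower bound: the reconstruction error
over *observed* cells only (missing cells are simply not summed over), plus
$D_{KL}(\mathcal{N}(a_{ik},\sigma^2_{ik})\,\|\,\mathcal{N}(0,1))$ for the
shared embedding and
$D_{KL}(\mathcal{N}(0,v^{(l)}_{ik})\,\|\,\mathcal{N}(0,v^{(l)}_{\mathrm{prior}}))$
for each dataset's extra variance. The per-dataset prior variances are the
model's hyperparameters: a small prior couples a dataset tightly to the
shared embedding, a large one lets it drift. `tune_v_priors()` grid-searches
them against an external criterion — the average precision of recalling
high-confidence network edges when ranking gene pairs by embedding distance
— because reconstruction error alone says nothing about whether the
embedding captures *function*.

Design choices a reader should know about:

* **Likelihood scaling.** The reconstruction term is a mean squared error
  per observed cell, so the KL sums are divided by the number of observed
  training cells (and multiplied by `kl_weight`, default 1). Without this
  the regulariser would scale with genes × dimensions while the data term
  stays O(1), and the embedding would collapse to the prior.
* **Blockwise training.** Each epoch iterates datasets; a block updates the
  dataset's sample embeddings and reconstruction network, the shared
  embedding and variances, and the domain classifier. Because a large
  dataset contributes many more batches per epoch than a small one, the
  embedding-layer learning rate inside each block is the global rate
  divided by `sqrt(n_batches)` of that dataset (`scaled_lr()`), which keeps
  the datasets' influences on the shared embedding comparable.
* **Gradient reversal.** A two-layer domain classifier predicts, from the
  shared embedding, which datasets cover each gene (multi-label, binary
  cross-entropy — a gene can be missing from several datasets at once). Its
  gradient reaches the embedding through a reversal layer
  (`gradient_reversal()` / `grl_backward()`), so the embedding is trained
  to *not* encode coverage. One practical detail matters: the classifier's
  weights carry an L2 penalty (1e-2). An unregularised classifier memorises
  the embedding within a few epochs, its loss saturates near zero, and the
  reversed gradient vanishes — the reversal then does nothing. The probe
  for the mechanism is `domain_probe_accuracy()`: a *fresh* classifier
  trained on the frozen embedding with a 70/30 gene split, averaged over
  several splits (one split's accuracy carries sampling noise of the same
  order as the reversal effect on small universes); an active reversal
  lowers its held-out accuracy.
* **Variances** are stored on the log scale with a floor of 1e-6 added on
  the natural scale, protecting the KL terms. $\sigma^2_{ik}$ is learned
  per gene and dimension.
* **Initialisation.** Sample embeddings start from principal components of
  their dataset (scores scaled to unit variance); everything else is
  random from the fit seed. One variational sample is drawn per forward
  pass. Training keeps the best-validation checkpoint over a fixed epoch
  budget; validation is a seeded 10% split of observed cells, evaluated at
  the posterior mean.
* **Defaults.** `K = 256` matches the published configuration of this
  model family; for the few-hundred-gene synthetic worlds used throughout
  the tests, `K` of 4–16 with hidden width 16–24 is appropriate and is what
  the examples use. The default prior variance 0.1 keeps the draws'
  sampling noise well below the embedding scale; priors near 1 inject
  unit-variance noise into every reconstruction and stall learning.

## Network embeddings and channel arithmetic

STRING-style networks attach to every edge one score per *evidence channel*
(co-expression, experiments, databases, text mining, ...), each on (0, 1)
and each containing a shared prior $p$ (default 0.041). `combine_channels()`
implements the documented recipe: remove the prior from each channel
($\max(0, (s-p)/(1-p))$), combine with the noisy-or formula
$S = 1 - \prod_c (1 - S_c)$, and re-inject the prior. A score exactly at the
prior carries zero evidence, so an edge supported only by removed channels
drops out of the network entirely — that is how `filter_channels()` builds
an "experimental-only" network from a full one. Files use the STRING
dialect: integer scores 0–1000, space-separated.

Two embedding algorithms are provided, matching the standard recipe for
protein networks: second-order biased random walks (walk length 80, 10
walks per source, return parameter 0.3, in-out parameter 1) fed into
skip-gram with negative sampling (128 dimensions, window 10, 5 negatives,
one SGD epoch), and a personalized-PageRank noise-contrastive embedding
(damping 0.85 as the walk's continuation probability, 3 negatives). The two
are concatenated (`embed_network()`), giving 256 dimensions at the
defaults. Combined scores weight the walks multiplicatively (configurable
off). Both kernels are compiled code with a private, seeded RNG, so results
are reproducible and independent of R's RNG state. For the small synthetic
networks in this package's experiments we increase walks per node (40) and
SGD epochs (5) and shorten the window (5): small noisy graphs need more
sampling per node for a stable embedding, and long windows blur local
precision, which is exactly what the bias experiment measures.

## The synthetic world

All generators draw from one latent space: `make_world()` gives every gene
a `d_true`-dimensional coordinate (standard normal) representing its
function, plus a heavy-tailed publication count — log-normal, with its
location tied to the first latent axis (the "studiedness" axis), so
well-studied genes are a functionally coherent, not random, subset. Every
modality reflects the same coordinates:

* **Omics** (`make_omics_collection()`): $X = f_l(\text{latent})W^\top +$
  noise, with $f_l$ a mild saturating nonlinearity
  ($\tanh(0.4\,\cdot)/0.4$ after a random orthogonal mixing) so datasets
  share gene structure but not sample structure, and the latent distance
  rank order survives (Spearman > 0.95 at zero noise). Missingness can be
  uniform or publication-biased (low-publication genes preferentially
  dropped), which is the bias the gradient reversal layer addresses.
* **Networks** (`make_channel_network()`): the true interaction propensity
  is a Gaussian kernel of latent distance; the top `density` fraction of
  pairs are the strong interactions. Every channel observes every pair
  through logit-scale noise and *reports* it only above a detection limit
  (by default the smallest strong-pair propensity, so a noise-free channel
  reports exactly the strong pairs). Reported scores are calibrated —
  shrunk towards the detection limit by $1/\sqrt{1+\mathrm{sd}^2}$ — using
  each channel's *global* benchmarked reliability, the way real evidence
  channels are calibrated against a reference: the uniformly noisy
  experimental channels get uniformly compressed scores, while the
  literature channel, benchmarked on the well-studied pairs that dominate
  it (where its noise vanishes), is taken at face value. The consequence
  is deliberate and is the reliability half of annotation inequality: the
  literature's rare reports about under-studied genes carry the channel's
  full confidence despite being close to noise. The literature channel has
  three publication-dependent distortions, all decaying as
  $\exp(-\log(1+\text{pub})/\text{scale})$: reporting noise, a coverage
  deficit (interactions of unstudied genes are not written about), and —
  optionally — an over-reporting boost that surfaces mid-strength
  associations between famous genes no experimental channel would clear.
  The defaults keep the boost at zero (pure reliability bias); the
  annotation-bias experiment switches it on, because over-annotation of
  well-studied genes is the other half of the phenomenon.
* **Gene lists and phenotype terms** are nearest-neighbour balls around
  seed genes, with a coherence dial and an optional publication floor
  (default 15) emulating curated lists, which draw almost exclusively on
  well-published genes.
* **GWAS scores** (`make_gwas_scores()`): $y = C\alpha + g + \varepsilon$
  with six covariates (three positive gene properties and their logs,
  fixed per world — they are gene properties, not trait properties), a
  latent signal $g$ carrying a fraction $h^2$ of the non-covariate
  variance, and $\varepsilon \sim \mathrm{MVN}(0, R)$ with AR(1) LD blocks
  (correlation 0.5, block size 10) inside chromosomes assigned round-robin
  so leave-one-chromosome-out folds stay balanced. By default the trait
  effect is drawn orthogonal to the studiedness axis: that makes the
  z-scores an annotation-*unbiased* benchmark, so a publication gradient in
  downstream performance can only come from the embedding.

## The evaluation suite

* **Gene-list classification** (`genelist_classify()`): gradient-boosted
  trees in five-fold cross-validation, list genes versus all other embedded
  genes (the negative set may contain undiscovered positives — a property
  of the task, not a bug). L1/L2 penalties are tuned by nested
  cross-validation over a log-spaced grid spanning 1e-2 to 1e5 (four points
  per axis by default; configurable, `tune_grid = NULL` disables). The
  metric is average precision per validation fold; fold plans
  (`make_fold_plan()`) are deterministic per seed and shared across
  embeddings, which is what makes paired Wilcoxon comparisons valid.
  `logistic_elastic_classify()` is the same contract with elastic-net
  logistic regression, for high-dimensional feature matrices and for
  rare-variant trait recall.
* **Trait deduplication** (`dedupe_traits()`, `genebass_filter()`): traits
  under 30 genes are dropped, similar traits (Jaccard > 0.3, single
  linkage) are collapsed to their largest member; significance cutoffs are
  6.7e-7 (burden) and 2.5e-7 (SKAT-O), with `<=` retaining — the boundary
  convention is documented because the sources leave it open.
* **Phenotype prediction** (`hpo_multilabel()`): terms with at least 20
  annotated genes, multi-hot labels, a two-layer network trained with
  binary cross-entropy and Adam for a fixed 500 epochs on a 70/30 gene
  split; per-term average precision and ROC AUC on held-out genes. The
  default hidden width is half the input dimensionality; for
  low-dimensional embeddings a wider probe (e.g. 32) is advisable and is
  what the package's own experiments pass.
* **GWAS regression** (`gwas_loco_fit()`): for each held-out chromosome,
  train and test blocks are whitened per chromosome with the Cholesky
  factor of their LD covariance (`whiten()`; a 1e-8 jitter is added once if
  a block is numerically non-PD), an elastic net is fitted on whitened
  covariates plus embedding with hyperparameters chosen by
  chromosome-grouped cross-validation (mixing in {0.1, 0.5, 0.9}),
  predictions are mapped back to the original scale with the held-out
  block's factor, and $R^2$ is computed over all held-out genes pooled
  (pooling, rather than averaging per-chromosome $R^2$, matches comparing
  predictions with targets once). The headline quantity is
  $\Delta R^2 = R^2 - R^2_0$ against a covariates-only null fitted with the
  identical procedure.
* **Stratification** (`publication_stratify()`): genes ranked by
  publication count (ties by id) are cut into five equal bins; the metric
  is recomputed per bin and per trait, and a Spearman rank-correlation test
  of metric against bin index is reported over all (bin, trait) records.

Tie handling in the metrics is explicit because average precision under
extreme class imbalance is the suite's primary readout: the default order
is score-descending with input position breaking ties, and a grouped mode
treats tied scores as one threshold step. The paired Wilcoxon test drops
zero differences and uses the exact null up to n = 25.

## The annotation-bias experiment

`annotation_bias_experiment()` assembles the package's central
demonstration. Its world uses a higher well-studied fraction
(`pub_meanlog = 2.2`, about 40% of genes at 15+ publications) and a
strong-inequality literature channel: noise maximum 6 and coverage-deficit
maximum 2 logits (for unstudied pairs the literature is one more garbage
channel, whose reports nevertheless carry the channel's global calibrated
confidence), over-reporting boost 1.5 logits (for famous pairs it is
precise and over-complete), decay scale 0.8 (switch-like around the
15-publication floor). Experimental channels carry moderate logit noise 1:
decent but imperfect genome-wide evidence. Three embeddings are compared:
the full network and its experimental-only filtrate (walks + skip-gram
concatenated with PPR), and an omics embedding fitted by the tensor
factorization on three matrices from the same world.

The curated-style gene lists are read off the literature channel itself —
a seed gene's strongest literature partners, restricted to well-published
genes — because that is how curation works: it reads the literature, and
so inherits the channel's idiosyncratic over-reports. This circularity is
deliberately part of the design; without it, any literature advantage on
gene lists would be genuine function information and would (honestly, but
unlike reality) carry over to the unbiased GWAS benchmark.

The expected signature has three parts. First, the full network clearly
beats the experimental-only network on the literature-derived lists
(paired Wilcoxon over shared fold plans). Second, on annotation-unbiased
GWAS traits the gap between the same two embeddings is non-positive or
non-significant. Third, the full-network embedding's *local reliability* —
per-gene neighbourhood fidelity, the average precision of recovering each
gene's true latent neighbours (`neighborhood_fidelity()`) — rises steeply
with publication count, while the omics embedding shows no meaningful
positive trend. Fidelity, not per-bin $\Delta R^2$, is the stratified
readout because the aggregate statistic is underpowered at this scale: in
direct measurements the full network's fidelity climbs from ~0.54 in the
lowest publication bin to ~0.77 in the highest while per-bin
$\Delta R^2$ moves by only ~0.03 against a per-record noise of ~0.1 —
world-level sampling noise (which genes with how much trait signal land in
which bin) that is shared across embeddings and swings marginal per-bin
$\Delta R^2$ trends in either direction for *any* embedding. The
per-trait $\Delta R^2$ values are still computed and reported.

## Problem sizes and numerical choices

The package's tests and reproduction script run on synthetic worlds of
120–1000 genes with latent dimension 4–8: large enough for every effect the
suite asserts (factorization recovery at Spearman ≥ 0.6, edge recall well
above prevalence, calibrated nulls within Monte-Carlo error, the bias
signature at p < 0.05), small enough that the full suite runs on a single
CPU in minutes. Embedding dimensions scale accordingly (4–16 for the
factorization, 64 per network algorithm). The published configurations
(19k genes, K = 256, 128-dimensional network embeddings) are the function
defaults where a default must be chosen, but nothing in the code depends on
that scale.

Degenerate inputs are handled explicitly: empty networks are valid tables
but refuse embedding; batches with zero observed cells are an error;
non-positive-definite LD blocks get one jitter then fail; constant
covariate projections fall back to zero rather than dividing by zero;
variances are floored at 1e-6; gene identifiers are matched exactly and
case-sensitively everywhere, with unknown ids dropped loudly.

## Limitations

The synthetic generator shares one latent space across all modalities by
construction — that is the operationalisation of "gene function" that makes
cross-modality benchmarking meaningful, but real modalities disagree about
function in structured ways no single latent space captures. Channel noise
is logit-Gaussian and publication counts log-normal; real evidence channels
have calibration artefacts and real annotation inequality is more extreme
(95% of publications on ~5000 proteins). LD is AR(1) block-diagonal rather
than estimated from a reference panel. Passing this suite therefore shows
that the algorithms do what they claim under controlled conditions with
planted truth; it does not certify performance numbers on any real
resource.
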
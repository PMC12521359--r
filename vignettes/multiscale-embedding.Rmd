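---
title: "Multiscale embedding of single-cell Hi-C: models, transforms, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale embedding of single-cell Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(schicbench)
```

## The problem

Single-cell Hi-C (scHi-C) measures pairwise chromatin contacts in individual
cells. A typical cell yields only 5,000-500,000 cis contacts, so the binned
per-cell contact matrix is extremely sparse, and almost every downstream
analysis — cell typing, cell-cycle staging, pseudo-bulk imputation — starts
by *embedding* cells into a low-dimensional space where similar cells lie
close together.

The central scientific issue this package addresses is that chromatin
heterogeneity lives at different genomic distance scales. Megabase-scale A/B
compartment differences (e.g. between embryonic stages) are carried by
long-range contacts (> 2 Mb), while loop- and domain-scale differences
(e.g. between cell-cycle phases or closely related cell subtypes) are
carried by short-range contacts (< 2 Mb). Preprocessing operators interact
with those scales: graph-diffusion imputation emphasizes long-range
structure and smooths away focal short-range signal, and
inverse-document-frequency (IDF) weighting systematically up-weights distal
(sparser) contacts. A pipeline tuned for one scale can be blind at the
other.

`schicbench` therefore decouples the three layers so they can be recombined
freely:

1. **transforms** — distance truncation, VC-sqrt normalization, box-filter
   smoothing, random-walk imputation with restart, IDF weighting, feature
   selection, stratum z-scoring;
2. **embedding backends** — seven methods sharing one contract (contact
   table in, `N x d` coordinates out);
3. **evaluation** — K-means clustering against known labels with
   ARI/NMI/ASW/AvgBIO, a repeat harness, and median-rank summaries.

A multiscale synthetic generator with known ground truth makes every
distance-scale claim testable on a laptop.

## Data model

Contacts are held as a tidy tibble (`cell_id`, `chrom`, `bin1`, `bin2`,
`count`) with `bin1 <= bin2`, bins 0-based and half-open at a fixed
resolution; input positions are 1-based base pairs
(`bin = floor((pos - 1)/resolution)`). Three derived views feed the
backends: the dense per-chromosome cell matrix, the per-cell *strata* set
(stratum `s` = the s-th diagonal, i.e. all contacts at bin distance `s`),
and the sparse cells x locus-pair feature matrix.

## Transforms

* **`truncate_distance(min_bp, max_bp)`** keeps contacts with
  `min_bp <= d < max_bp`. Composing two truncations equals truncating to
  the window intersection.
* **`vc_sqrt_norm`**: `out_ij = m_ij / sqrt(r_i r_j)` with `r` the row
  sums; zero-coverage rows stay zero.
* **`box_filter(w)`**: mean over the `(2w+1)^2` window, clipped at the
  matrix edge (corner entries average over their smaller window).
* **`random_walk(p)`**: with `P` the row-stochastic transition matrix
  (zero rows become self-loops), iterate `R <- p R P + (1 - p) I` from the
  identity until `max |dR| < 1e-6` or 30 sweeps. The fixed point is
  `(1-p)(I - pP)^{-1}`; at the default `p = 0.5` the iteration error decays
  as `p^t`, so the tolerance is reached in ~20 sweeps. The result is
  symmetrized. Tests compare the iteration against the closed form.
* **`idf_transform`**: feature `j` present in `n_j` of `N` cells is scaled
  by `log(1 + N/(1 + n_j))` — a smoothed IDF that is finite at `n_j = 0`
  and strictly decreasing in `n_j`. The zero pattern is untouched.
  `idf_stratum_profile()` averages these weights per stratum; on power-law
  synthetic data the profile rises with distance, which is the mechanism of
  the IDF distance bias.
* **`select_features(q_low, q_high, top_n)`**: drop features with totals
  outside the `[q_low, 1 - q_high]` quantile band, keep the `top_n`
  strongest by mean signal; ties break by genomic feature order.
* **`zscore_strata`**: each stratum vector is centered and scaled with the
  *population* (1/n) variance — so a z-scored stratum inner product divided
  by its length is exactly a Pearson correlation; zero-variance strata map
  to zero vectors and contribute nothing downstream.

## Embedding backends

* **`1d_pca`** — per-cell bin-coverage vectors (each contact increments
  both endpoint bins; intra-bin contacts count twice), normalized to sum 1,
  then PCA.
* **`schicluster`** — per chromosome: VC-sqrt -> box filter -> random walk
  -> binarize the strongest 20% of entries (ties at the threshold
  included, exact zeros never); flattened binarized matrices go through
  per-chromosome PCA (default 20 components — the reference pipelines do
  not pin this number down, so it is exposed) and a final genome-wide PCA.
* **`innerproduct` / `fasthicrep`** — per chromosome and stratum the cell
  similarity is the z-scored stratum inner product over the stratum length
  (a Pearson correlation). `innerproduct` weights strata uniformly;
  `fasthicrep` uses stratum-adjusted correlation-coefficient weights
  `w_s = N_s sigma_i,s sigma_j,s` computed on the raw strata, which
  up-weights distal strata. Chromosomes aggregate by median (mean is
  exposed). The similarity matrix is embedded by classical Torgerson MDS on
  `d_ij = sqrt(2 (1 - s_ij))`, truncating negative eigenvalues.
* **`spectral_idf`** — locus-pair features in the distance window ->
  quantile/top-N selection -> IDF -> cosine similarity `S` -> symmetric
  normalization `D^{-1/2} S D^{-1/2}` -> leading nontrivial eigenvectors,
  scaled by their eigenvalues. The eigenvalue weighting matters in
  practice: unscaled eigenvectors all have unit norm, so downstream K-means
  is easily distracted by noise components.
* **`lda`** — collapsed Gibbs sampling over locus-pair "words" per cell
  "document" (defaults: 10 topics, `alpha = 50/T`, `beta = 0.1`, 300
  sweeps, privately seeded RNG). The embedding is the smoothed topic
  proportion matrix itself.
* **`insulation`** — per bin, total contacts in a `w`-bin square straddling
  the bin (default `w = 10`), `log2`-normalized by the chromosome mean
  (bins with no window or zero insulation contribute 0), differenced over a
  `delta_w = 3` look-ahead/behind; the concatenated delta vectors go
  through PCA.
* **`va3de_*`** — the convolutional Gaussian-mixture VAE, below.

All PCA steps share one determinism convention: features centered, not
scaled, component signs fixed so the largest-magnitude loading is positive.
MDS and spectral coordinates get the analogous sign fix.

## The convolutional mixture VAE

Cells are rendered as band images: `k` strata stacked as rows over the
concatenated genome bins (chromosome by chromosome; positions past a
chromosome end stay zero). The generative model is

p(x, z, c) = p(x | z) p(z | c) p(c),

with `p(c)` categorical with weights `pi`, `p(z | c)` a diagonal Gaussian
per component, and `p(x | z)` pixelwise Poisson (default) or Bernoulli. The
encoder (4 blocks of two 3x3 convolutions, filters 4-8-16-32, the second
convolution of each block striding 2 along the genome axis) maps an image
to `q(z|x) = N(mu, diag(sigma^2))`; the decoder mirrors it (filters
32-16-8-4, nearest-neighbor width upsampling, a final 1x1 convolution).
Training maximizes the ELBO

E_q log p(x|z) − Σ_c γ_c KL(q(z|x) ‖ p(z|c)) + Σ_c γ_c (log π_c − log γ_c),

with `gamma = q(c|x)` set to its variational optimum
`gamma_c %prop% pi_c exp(-KL_c)`; at that optimum the gamma gradient
vanishes, so treating it as constant in backpropagation is exact (verified
against finite differences in the tests).

Design choices that matter:

* **Per-cell exposure offsets.** Sequencing depth varies by an order of
  magnitude between cells. With a plain Poisson likelihood the latent space
  spends essentially all its capacity encoding depth (every latent
  dimension ends up correlated with library size) and cluster structure is
  invisible at small training budgets. The model therefore divides encoder
  inputs by a per-cell size factor `s_i` (total image counts over the
  training mean) and multiplies decoder rates by the same factor — the
  standard exposure offset of Poisson regression. This removes the depth
  axis from the latent space entirely.
* **Mixture updates.** Network weights train with AdamW (printed defaults:
  learning rate 3e-4, weight decay 1e-4). The mixture parameters
  `(pi, mu_c, sigma_c^2)` instead take one closed-form coordinate-ascent
  (M-step) update per epoch from the accumulated responsibilities — the
  exact maximizer of the same ELBO terms. Gradient steps of size 3e-4
  cannot move mixture logits far enough in a short run to express the
  model's characteristic behavior of pushing unused components' prior
  weight to zero; the M-step expresses it immediately and is still
  coordinate ascent on the same objective.
* **Warm-up and initialization.** The first 20% of epochs train
  reconstruction only with deterministic latents; the mixture is then
  initialized by a small diagonal-covariance EM (k-means start, variance
  floor 1e-3) on the warm-up latents and trained jointly afterwards.
* **Overparameterization.** Fitting more components than expected
  populations is encouraged; on separable data the spare components' prior
  weights collapse below 1%, so the number of surviving components is a
  usable cluster-count estimate.
* **Numerical guards.** `log sigma^2` is clamped to [-10, 10], rates get a
  1e-6 floor, `pi` a 1e-10 floor; a non-finite loss aborts with the seed
  and epoch reported.
* **Desk scale.** The paper-scale regime for this model family is ~2
  million cell observations (thousands of cells x ~1000 epochs). The
  package's fixture runs 300 cells for 50 epochs and compensates the
  shorter schedule with a larger step size (`lr = 1e-3`); the config
  default remains 3e-4. Everything is deterministic under the config seed.

## Evaluation stack

K-means (10 restarts, seeded) with `k` fixed to the number of ground-truth
classes — fixing `k` keeps ARI/NMI comparable across methods. Metrics:

* **ARI** — pair-counting Rand index adjusted for chance,
  `(RI - E[RI]) / (max RI - E[RI])`, computed from the contingency table
  and tested against an exhaustive pair-count oracle.
* **NMI** — mutual information normalized by the *arithmetic mean* of the
  label entropies (the normalization is a package choice; the metric is
  only stated to lie in [0, 1]), clipped to [0, 1].
* **ASW** — mean silhouette width under cosine distance with ground-truth
  labels; cells in singleton classes are excluded from the mean.
* **AvgBIO** — the mean of ARI, NMI, and ASW; ASW is rescaled from
  [-1, 1] to [0, 1] by default so the three terms share a scale (the raw
  average is available via `rescale_asw = FALSE`).

`repeat_eval()` reruns stochastic stages with derived seeds
(`base_seed + i`, 5 repeats by default) and reports mean and SEM.
Deterministic backends are embedded once and only the clustering repeats —
their run-to-run variance comes only from K-means. `median_rank_summary()`
converts a method x dataset score table to per-dataset percentile ranks in
(0, 1] (ties share the mean percentile; missing entries drop out of that
dataset's ranking) and summarizes each method by its median across
datasets.

## Diagnostics

`per_strata_heatmap()` runs the inner-product pipeline but stops before
aggregating over strata: per stratum, the per-chromosome z-scored inner
products are medianed over chromosomes, each cell is summarized by its
median similarity to the *other* cells (self excluded — including self
would add a constant 1 that only compresses the normalized range), and
each stratum column is min-max normalized (constant columns map to 0).
This localizes which distances carry the between-cell signal.

`compartment_pc1()` performs the classical A/B call on a pseudo-bulk:
observed/expected by distance (expected = per-stratum mean; unsmoothed,
which is adequate at synthetic depths), Pearson correlation matrix of
bins, first principal component. With synthetic data the sign is oriented
against the generating block assignment (real-data orientation by
histone-mark coverage is out of scope); without a reference the sign
convention falls back to the largest-loading rule.

## The synthetic generator

A population is an expected contact intensity per chromosome:

E_ij = (1 + d_ij)^(-alpha) * c_ij * l_ij

with `d_ij` the bin distance, `c_ij = 1 ± kappa` for same/cross
compartment pairs at distances >= 2 Mb (and 1 below — compartment structure
is a long-range phenomenon), and `l_ij = lambda` at loop anchor pairs. A
mitotic-like population moves a fraction `m` of probability mass into the
2-12 Mb band before sampling. A cell is a multinomial draw of `depth`
contacts over the upper-triangle probabilities, with depths log-normal
(median 20,000 cis contacts, sdlog 0.5 — the middle of the reported
5k-500k per-cell range), floored at 5,001 so default QC passes by
construction. The default genome is 2 chromosomes x 400 bins at a nominal
100 kb, so 2 Mb = 20 bins and the 2-12 Mb mitotic band exists.

One identifiability point shapes the presets: swapping every A and B label
leaves `outer(b, b)` — and therefore the contact map — unchanged, so a
global compartment flip is *invisible* to Hi-C. A distinguishable "phase"
change must move the block boundaries; the compartment-contrast preset
shifts the checkerboard by half a block.

Presets (all seeded, so the population structure is a fixed condition):

| preset | populations | contrast |
|---|---|---|
| `compartment-contrast` | 2 | checkerboard phases offset by half a block, `kappa = 0.4`, no loops |
| `loop-contrast` | 2 | shared compartments (`kappa = 0.3`), population-specific loop sets (50 anchors/chromosome, `lambda = 4`, 0.3-1.9 Mb separations) |
| `cell-cycle-like` | 2 | shared structure; mitotic shift `m = 0.02` vs `0.5` |
| `mixed-tissue` | 3 | random block assignments (`kappa = 0.35`) plus population-specific loops (75/chromosome, `lambda = 6`) |
| `easy-mix` | 3 | strong compartment (`kappa = 0.6`, three phases) *and* loop (`lambda = 8`, 100/chromosome) differences on a compact 2 x 64-bin genome at 200 kb |

The loop-contrast regime was chosen deliberately *unsaturated*: loop-scale
heterogeneity in real tissue is subtle, and with very strong loops
(`lambda >= 6` at high anchor counts) preprocessing choices stop mattering
because every pipeline saturates. At `lambda = 4` with 50 anchors per
chromosome, short-range embeddings recover the populations cleanly while
random-walk imputation — which diffuses focal signal into its
neighborhood — destroys the contrast, reproducing the scale-selectivity of
diffusion-based imputation.

What the generator does **not** emulate: trans contacts (all methods here
are cis-only), polymer-physics constraints (no TAD nesting, no
loop-extrusion correlation structure), coverage biases (GC/mappability),
PCR duplicates, and batch effects. Passing the synthetic mirrors therefore
demonstrates that the implementations respond to distance-scale structure
as the real pipelines do on real data — not that any method will reach a
particular score on a particular tissue.

## Quality control

`qc_filter()` drops cells with fewer than 5,000 cis contacts (strictly
fewer; dataset-specific 50k/100k variants are a parameter) and, per the
coverage rule, cells in which any chromosome of length x Mb has fewer than
x contacts (`x = ceiling(length/1e6)`; the rounding is a package choice).
Counts are taken as given — no duplicate-removal logic is applied.
`mitotic_filter()` fits a 2-sigma covariance ellipse to the
`(f_local, f_mitotic)` scatter (fractions of 25 kb-2 Mb and 2-12 Mb
contacts among contacts > 25 kb) and splits cells by the line through the
cutoff point (default `(0.15, 0.35)`) and the ellipse center; the side
containing `(1, 0)` — the pure-interphase corner — is kept as G-S. A
rank-deficient scatter is refused with a pointer to manual thresholding.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run, per run: the
compartment/loop contrasts with 2 x 100 cells on the default geometry; the
random-walk toggle with 2 x 50 cells; the IDF profile with 150 cells and
40 strata; the downsampling sweep with 3 x 40 cells rebinned to 200 kb
over fractions 1, 0.2, 0.1, 0.02; and the VAE fixture with 3 x 100 cells
(16 x 128 band images, 50 epochs). These sizes were chosen so each
contrast is comfortably powered while a full run stays in the tens of
minutes on one core.

## Known limitations

* The random-walk operator follows the restart formulation only; any
  per-iteration renormalization beyond row-stochasticity that particular
  reference implementations may apply is not reproduced.
* LDA embeds the topic-proportion matrix directly (no further PCA).
* The VAE decoder is used only as a training signal; reconstructions are
  deliberately not exposed as imputations (variational decoders blur, and
  pseudo-bulk imputation after clustering is the better tool).
* `embed_schicluster` densifies per-chromosome matrices, so genome-scale
  runs at fine resolution need the same memory care as the reference
  implementation.
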
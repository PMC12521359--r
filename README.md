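# schicbench

Multiscale embedding and benchmarking of single-cell Hi-C (scHi-C) data.

## What this is for

A single cell's Hi-C map holds 5k–500k cis contacts — far too sparse to
read directly — so every scHi-C analysis starts by embedding cells into a
low-dimensional space. The catch is that biological heterogeneity lives at
different genomic distance scales: megabase-scale A/B **compartment**
differences are carried by long-range contacts (> 2 Mb), while **loop**-
and domain-scale differences between closely related cell states are
carried by short-range contacts (< 2 Mb). Preprocessing interacts with
those scales — random-walk imputation favors compartment-scale structure
and smooths away focal loops; IDF weighting up-weights distal contacts —
so the right pipeline depends on the biology being asked about.

`schicbench` is for computational biologists who want to choose (or build)
an scHi-C embedding pipeline with those tradeoffs made explicit. It
decouples preprocessing transforms from embedding backends from
evaluation, and ships a labeled multiscale synthetic generator so every
claim is testable without downloading an atlas.

## What is inside

* **Transforms** — distance truncation, VC-sqrt normalization
  (`m_ij / sqrt(r_i r_j)`), box-filter smoothing, random-walk imputation
  with restart (fixed point `(1-p)(I - pP)^{-1}`, default `p = 0.5`),
  smoothed IDF weighting (`log(1 + N/(1+n_j))`), quantile/top-N feature
  selection, stratum z-scoring.
* **Seven embedding backends** under one contract (contact tibble in,
  `N x d` coordinates out): bin-coverage PCA (`1d_pca`),
  scHiCluster-style per-chromosome PCA (`schicluster`), stratum
  inner-product and stratum-adjusted-correlation (fastHiCRep-style)
  similarity with classical MDS (`innerproduct`, `fasthicrep`),
  IDF-weighted spectral embedding (`spectral_idf`), locus-pair topic
  modeling by collapsed Gibbs LDA (`lda`), insulation-score delta vectors
  (`insulation`), and `va3de_*`: a convolutional variational autoencoder
  with a learned Gaussian-mixture latent prior trained on stacked
  strata "band images" (implemented natively, with manual
  backpropagation through RcppArmadillo convolution kernels).
* **Evaluation** — seeded K-means, ARI, NMI, cosine-distance ASW, AvgBIO,
  a repeat harness with SEMs, and median-percentile-rank summaries across
  datasets; QC filters (5k cis-contact rule, per-chromosome coverage rule,
  mitotic-cell ellipse filter).
* **Diagnostics** — per-stratum similarity heatmaps (which distances carry
  the signal), contact-fraction scatters, pseudo-bulk A/B compartment PC1.
* **Synthetic generator** — populations defined by power-law decay
  `(1+d)^-alpha`, compartment checkerboards acting beyond 2 Mb
  (`1 ± kappa`), focal loop enrichments (`lambda`), mitotic 2–12 Mb band
  shifts, and log-normal per-cell depths; presets `compartment-contrast`,
  `loop-contrast`, `cell-cycle-like`, `mixed-tissue`, `easy-mix`.

## Worked example

Two synthetic populations differing only in compartment phase, embedded
once from long-range and once from short-range contacts:

```r
library(schicbench)

spec <- preset_dataset("compartment-contrast", n_cells_per_pop = 25,
                       bins_per_chrom = 200, seed = 42)
data <- generate_dataset(spec)

glance(evaluate_backend(data, "innerproduct", min_bp = 2e6, max_bp = 20e6,
                        n_repeats = 5, base_seed = 1))
#>   n_repeats ari ari_sem nmi nmi_sem   asw asw_sem avgbio avgbio_sem
#> 1         5   1       0   1       0 0.866       0  0.978          0

glance(evaluate_backend(data, "innerproduct", min_bp = 0, max_bp = 2e6,
                        n_repeats = 5, base_seed = 1))
#>   n_repeats    ari ari_sem    nmi nmi_sem      asw asw_sem avgbio avgbio_sem
#> 1         5 0.0205       0 0.0301       0 -0.00697       0  0.182          0
```

Restricted to contacts beyond 2 Mb the clustering is perfect (ARI = 1,
NMI = 1, cosine silhouette 0.87); restricted to contacts below 2 Mb the
same method finds nothing (ARI ≈ 0.02) — compartment-scale heterogeneity
lives in the long-range contacts. Swapping in the `loop-contrast` preset
reverses the verdict. The embedding itself is an ordinary tibble:

```r
e <- embed_mds(similarity_innerproduct(data$contacts, data$bins,
                                       data$resolution, min_bp = 2e6), d = 2)
head(tibble::as_tibble(e), 3)
#>   cell_id    dim_1   dim_2
#> 1 popA_c0001 0.222 -0.217
#> 2 popA_c0002 0.134  0.0467
#> 3 popA_c0003 0.159  0.147
autoplot(e, labels = data$labels)
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "schicbench.R", package = "schicbench")` with
`simulate`, `embed`, `eval`, `diag`, and `benchmark` subcommands.

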
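---
title: "Deep polygenic risk scores: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep polygenic risk scores: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeprisk)
```

# The problem

A polygenic risk score (PRS) summarizes an individual's inherited liability
to a common disease from genome-wide SNP genotypes. The classical
pruning-and-thresholding (P+T) score is a weighted sum of risk-allele
counts, and penalized logistic regression (lasso) generalizes it only to a
different linear fit. Both are additive: they cannot represent epistasis,
where the effect of one locus depends on the genotype at another (the
HLA-C/ERAP1 interaction in psoriasis is the canonical example). This
package implements a deep scoring model built to capture such non-additive
structure while staying parsimonious enough for cohort-scale genotype data,
together with the full surrounding pipeline — SNP selection, baselines,
risk-stratification analytics, and a simulator that plants known genetic
architectures so every claim can be tested end to end.

# The model

**Encoding.** Each genotype is encoded as a two-dimensional vector of
(reference-allele count, alternative-allele count): genotype 0 becomes
(2,0), 1 becomes (1,1), 2 becomes (0,2), and a missing genotype becomes
(0,0). Compared with the usual 0/1/2 coding this removes the built-in
assumption that a homozygote carries exactly twice the risk of a
heterozygote, and it gives missing genotypes a representable state instead
of requiring imputation or locus deletion. The `additive_encoding` model
variant restores the single-dimension 0/1/2 coding (missing set to 0) for
ablation comparisons.

**Partial-connection layer.** Each selected SNP is wired to every gene
whose interval, extended 250 kb up- and downstream, covers the SNP's
position; a SNP with no such gene is wired to its single nearest gene, so
every SNP keeps at least one edge, and genes left without SNPs are dropped.
A gene's feature is a trainable linear aggregate of its SNPs' encoded
features — one scalar per gene, with weights masked to the wiring. The mask
is enforced on the gradients as well as the weights, so connections outside
the SNP-gene map are exactly zero after any number of training steps; this
is tested, not assumed. The layer cuts the feature dimension from
2 x n(SNPs) to n(genes) and injects positional biology into the
architecture. The `no_partial_layer` variant feeds encoded SNPs directly to
the recurrent layer for ablation.

**Per-chromosome BiLSTM.** Genes are grouped by chromosome and ordered by
start position, and each chromosome's gene-feature sequence is processed by
a bidirectional LSTM with 4 hidden units per direction. The forward and
backward hidden states at each step are concatenated, and all steps from
all chromosomes are concatenated into one vector, so the recurrence can
carry interactions between distant genes on the same chromosome into the
final representation. Each chromosome has its own unshared BiLSTM
parameters: chromosomes differ in length and gene content, and nothing in
the architecture's motivation suggests tying them. Cross-chromosome
interactions are not representable below the final linear layer — a known
limitation shared with the architecture this package implements.

**Head, loss and training.** A single sigmoid unit over the concatenated
hidden states (plus standardized covariates, when used) produces the score
in (0,1). Training minimizes class-weighted binary cross-entropy with
weights `w0 = n/(2(n - n_cases))`, `w1 = n/(2 n_cases)` — balanced classes
reduce exactly to plain cross-entropy — plus an L2 penalty on the LSTM
input/recurrent matrices, with inverted dropout on the BiLSTM outputs
during training only. Optimization uses Adam with minibatches and early
stopping on a stratified internal validation split, restoring the
best-epoch weights. Given a seed, initialization, shuffling, dropout and
the split are all deterministic, and two runs produce bit-identical scores.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `lstm_hidden_per_direction` | 4 | hidden units per LSTM direction; fixed by the architecture |
| `dropout_rate` | 0.2 | dropout on BiLSTM outputs; a standard default |
| `l2_coefficient` | 1e-4 | L2 on LSTM weights; a standard default |
| `learning_rate` | 1e-3 | Adam step; sufficient at benchmark scale (thousands of samples). Very small toy problems need fewer total gradient steps than this rate can use — the unit tests that demand visible learning in a few epochs set 5e-3 |
| `max_epochs` / `early_stop_patience` | 50 / 5 | with early stopping the effective epoch count is data-driven |
| `batch_size` | 128 | minibatch size |
| `val_fraction` | 0.1 | stratified split used only for early stopping |
| `gene_activation` | `"none"` | the gene aggregate is linear by design; `"tanh"` is available but off by default |

SNP selection has its own grid: p-value thresholds {5e-3, 5e-4, 5e-5,
5e-6} crossed with r² thresholds {0.2, 0.4, 0.6, 0.8, none} — 20 candidate
configurations. `grid_search()` compares candidates on a stratified 80/20
internal split of the training data rather than on in-sample fit
(`select_by = "train"` restores the literal train-set comparison); the
window is a symmetric 250 kb radius around the index SNP, and "no r²
threshold" disables clumping entirely (pure p-thresholding).

# Numerical choices

* **LD clumping** processes candidates in ascending p, breaking ties by
  (chromosome, position, id), so the selected set is invariant to input row
  order. r² is the squared Pearson correlation of alt-counts over
  complete-case panel samples; panel-monomorphic SNPs have undefined r²,
  treated as 0, so they never absorb nor get absorbed. The implementation
  is pinned against an independent brute-force greedy oracle over the full
  parameter grid on randomized instances.
* **Odds ratios** rank scores descending with ties broken by stable sample
  order (tie counts are reported); `TE = 0` or `RD = 0` yields `Inf` with
  an explicit flag rather than a silent continuity correction. The
  proportion of the population at k-fold risk sweeps every top-group size
  and returns the largest fraction whose OR reaches the fold; `Inf`
  counts as exceeding any fold, which makes a perfectly separating score
  report a positive proportion, as it should.
* **Percentiles** use average ranks; bin b of 100 holds percentiles
  (b-1, b]. The sample-size-weighted mean of bin prevalences equals the
  overall prevalence exactly, which the tests assert for arbitrary inputs.
* **AUC** is the rank-based Mann-Whitney estimator with tie correction,
  exact against an all-pairs count.
* **Degenerate inputs**: cohorts with a single class are rejected
  everywhere training or evaluation needs both; all-missing individuals
  are valid model inputs (the (0,0) encoding) and receive finite scores;
  monomorphic or all-missing SNPs get β = 0, p = 1 in the discovery GWAS.
* **Cross-validation** stratifies folds and runs selection (and, when a
  grid is supplied, the grid search) strictly inside each training fold.
  The looser protocol — one grid choice on the whole training set — exists
  behind the `select_by`/fixed-params arguments but is not the default.

# The simulator

Real cohort-scale genotype resources for this problem are access-restricted,
so the package ships a simulator that generates the three datasets the
pipeline consumes: an LD reference panel, a discovery cohort reduced to
GWAS summary statistics, and a labelled target cohort.

Genotypes come from thresholded latent Gaussians: each of two haplotypes
per sample draws a latent value per SNP; within an LD block the latents
share a block factor (exchangeable correlation `within_block_rho`), and the
alt allele is called below the per-SNP MAF quantile. Marginally this gives
Hardy-Weinberg genotype frequencies at each SNP's MAF and exchangeable
within-block LD. It is deliberately *not* a coalescent: there is no
recombination gradient, no allele-frequency spectrum from demography, no
population structure or relatedness. Phenotypes follow a liability
threshold model: liability = additive SNP effects + joint-carrier epistatic
terms (+ covariate effects) + Gaussian noise scaled so the signal explains
a chosen fraction of liability variance; cases are the samples above the
realized (1 - prevalence) quantile, which keeps case counts controllable at
small n. The discovery GWAS is a per-SNP allelic score test (2x2
case/control allele-count collapse; log-OR effect, 1-df chi-square
p-value), self-contained and calibrated under the null (asserted by a KS
test in the suite).

The epistatic term is a joint-carrier indicator — a liability bump when
both loci of a pair carry at least one alt allele. This is the simplest
interaction an additive model cannot fully capture; note it still induces
marginal associations at both loci (each partner raises risk on average),
which is precisely what lets a marginal discovery GWAS find the loci while
roughly a third of the pair's liability variance remains invisible to any
additive score.

**What passing tests show — and don't.** The benchmarks demonstrate that
the implementation learns planted interactions that defeat additive
baselines under controlled, favorable conditions: correctly specified LD,
moderate dimensionality, pairs on the same chromosome. They do not
demonstrate performance on real biobank data, where signals are weaker,
architectures are denser, LD is irregular, and confounding exists.

# Benchmark study conditions

Fixed once, before any results were read, and shared by the test suite and
`scripts/acceptance.R` (sizes chosen so a replicate simulates and trains in
seconds-to-minutes on one CPU):

* Marker map: 200 SNPs on 4 chromosomes (50 each at 20 kb spacing), LD
  blocks of 10 SNPs at latent correlation 0.3, MAF uniform in [0.2, 0.4],
  2% missing genotypes; 40 genes; panel n = 500; discovery and target
  cohorts n = 4000; target split 70/30 train/test; prevalence 0.2.
* *Epistatic architecture*: 5 joint-carrier pairs, both partners on the
  same chromosome ~560-600 kb apart (so they wire to different genes and
  the within-chromosome recurrence can combine them), weight 1 each, zero
  additive coefficients, signal explaining 70% of liability variance.
* *Additive architecture*: 30 SNPs with effects ±0.3, signal share 50%.
* *Robustness architecture*: 60 SNPs with geometrically decaying effects
  (0.4 · 0.93^j, alternating sign), signal share 60%, so the strongest GWAS
  hits carry most of the signal and removing the top 10/20/50 degrades all
  methods monotonically. The robustness experiment selects at p ≤ 0.5 —
  deliberately permissive, so the selection never empties after the strong
  hits are removed and the curve measures degradation rather than pipeline
  failure.
* Benchmark selection elsewhere is fixed at (p ≤ 5e-4, r² ≥ 0.2); the
  20-pair grid is exercised by its own test at reduced training epochs.
* Replication: 5 seeds for the method comparison and ablations; 3 seeds
  (and 15 training epochs) for the deep model's robustness curve, whose
  per-level fits are the most expensive part of the suite.

# Known limitations

* The score head is linear over per-chromosome representations, so
  cross-chromosome epistasis is not representable; the benchmark plants
  within-chromosome pairs for exactly this reason.
* The simulator's LD is exchangeable within fixed-size blocks; clumping
  behavior on real, distance-decaying LD is exercised only through the
  window logic, not through realistic r² decay.
* Training is plain R linear algebra: ample for hundreds of selected SNPs
  and thousands of samples, not for biobank-scale inputs.
* Lasso consumes additive counts with unpenalized covariates — the
  conventional linear comparator — and P+T uses additive counts by
  definition; neither sees the two-dimensional encoding.
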
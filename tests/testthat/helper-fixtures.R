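# Programmatic fixtures shared across test files.

# a tiny hand-specified dataset: counts given column-per-variant
make_dataset <- function(counts, chrom = NULL, pos = NULL,
                         phenotype = NULL, ids = NULL) {
  counts <- as.matrix(counts)
  m <- ncol(counts)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  genotype_dataset(
    counts,
    variants = data.frame(id = ids, chrom = chrom, pos = pos,
                          ref = rep("A", m), alt = rep("G", m)),
    sample_ids = paste0("s", seq_len(nrow(counts))),
    phenotype = phenotype
  )
}

make_stats <- function(ids, p, beta = NULL, chrom = NULL, pos = NULL) {
  m <- length(ids)
  if (is.null(beta)) beta <- rep(0.1, m)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  summary_stats(data.frame(id = ids, chrom = chrom, pos = pos,
                           ref = "A", alt = "G", beta = beta, p_value = p))
}

make_genes <- function(gene_id, chrom, start, end) {
  gene_annotation(data.frame(gene_id = gene_id, chrom = chrom,
                             start = start, end = end))
}

# small simulated world reused by several module tests
tiny_world <- function(seed = 42, n = 400, n_snps = 60, n_genes = 12,
                       missing_rate = 0.02) {
  cfg <- sim_config(n_snps = n_snps, n_genes = n_genes, n_chromosomes = 3,
                    ld_block_size = 5, within_block_rho = 0.3,
                    maf_range = c(0.2, 0.4), missing_rate = missing_rate,
                    seed = seed)
  arch <- architecture_spec(
    additive_idx = c(5L, 25L, 45L), additive_betas = c(1, -0.8, 0.9),
    heritability_like_scale = 0.5, prevalence = 0.3
  )
  cohort <- simulate_cohort(cfg, arch, n = n, seed = seed + 1)
  list(cfg = cfg, arch = arch, cohort = cohort,
       genes = simulate_gene_annotation(cfg),
       panel = simulate_genotypes(cfg, 300, seed = seed + 2))
}

# heavyweight benchmark results computed once and shared between the signal
# recovery and ablation tests
.bench_cache <- new.env(parent = emptyenv())

epistatic_benchmark_results <- function() {
  if (is.null(.bench_cache$epi)) {
    .bench_cache$epi <- run_benchmark(
      "epistatic", seeds = 1:5, methods = c("deeprisk", "pt", "lasso"),
      variants = c("full", "no_partial_layer", "additive_encoding")
    )
  }
  .bench_cache$epi
}

additive_benchmark_results <- function() {
  if (is.null(.bench_cache$add)) {
    .bench_cache$add <- run_benchmark(
      "additive", seeds = 1:5, methods = c("deeprisk", "lasso")
    )
  }
  .bench_cache$add
}

mean_auc_of <- function(df, method, variant = NULL) {
  rows <- df$method == method
  if (!is.null(variant)) rows <- rows & df$variant == variant
  mean(df$auc[rows])
}
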
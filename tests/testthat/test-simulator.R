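test_that("genotype simulation is deterministic and hits its MAF target", {
  cfg <- sim_config(n_snps = 40, n_genes = 8, n_chromosomes = 2,
                    maf_range = c(0.3, 0.3), within_block_rho = 0,
                    missing_rate = 0, seed = 11)
  g1 <- simulate_genotypes(cfg, 2000, seed = 5)
  g2 <- simulate_genotypes(cfg, 2000, seed = 5)
  expect_identical(g1$alt_counts, g2$alt_counts)
  freq <- colMeans(g1$alt_counts) / 2
  expect_true(all(abs(freq - 0.3) < 0.03))
})

test_that("uncorrelated blocks give near-zero cross-SNP r2", {
  cfg <- sim_config(n_snps = 40, n_genes = 8, n_chromosomes = 2,
                    within_block_rho = 0, maf_range = c(0.2, 0.4),
                    missing_rate = 0, seed = 12)
  g <- simulate_genotypes(cfg, 2000, seed = 1)
  r2 <- cor(g$alt_counts)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.02)
})

test_that("within-block r2 exceeds across-block r2 when rho > 0", {
  worse <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n_snps = 30, n_genes = 6, n_chromosomes = 1,
                      ld_block_size = 5, within_block_rho = 0.4,
                      maf_range = c(0.2, 0.4), missing_rate = 0, seed = seed)
    g <- simulate_genotypes(cfg, 500, seed = seed + 100)
    r2 <- cor(g$alt_counts)^2
    same_block <- outer(cfg$block, cfg$block, "==") & upper.tri(r2)
    diff_block <- outer(cfg$block, cfg$block, "!=") & upper.tri(r2)
    if (mean(r2[same_block]) <= mean(r2[diff_block])) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("missingness is applied at the configured rate", {
  cfg <- sim_config(n_snps = 50, n_genes = 8, missing_rate = 0.1, seed = 13)
  g <- simulate_genotypes(cfg, 1000, seed = 2)
  expect_lt(abs(mean(is.na(g$alt_counts)) - 0.1), 0.01)
})

test_that("pure-noise phenotype matches the requested prevalence", {
  cfg <- sim_config(n_snps = 20, n_genes = 5, missing_rate = 0, seed = 14)
  g <- simulate_genotypes(cfg, 2000, seed = 3)
  ph <- simulate_phenotype(g, architecture_spec(prevalence = 0.15), seed = 4)
  expect_lt(abs(mean(ph$phenotype) - 0.15), 0.02)
})

test_that("a strong additive SNP associates with case status", {
  cfg <- sim_config(n_snps = 20, n_genes = 5, missing_rate = 0, seed = 15)
  g <- simulate_genotypes(cfg, 2000, seed = 5)
  arch <- architecture_spec(additive_idx = 7L, additive_betas = 3,
                            heritability_like_scale = 0.5, prevalence = 0.2)
  ph <- simulate_phenotype(g, arch, seed = 6)
  ct <- cor.test(g$alt_counts[, 7], ph$phenotype)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-6)
})

test_that("joint-carrier epistasis associates far beyond either margin", {
  cfg <- sim_config(n_snps = 20, n_genes = 5, missing_rate = 0,
                    within_block_rho = 0, maf_range = c(0.3, 0.3), seed = 16)
  g <- simulate_genotypes(cfg, 3000, seed = 7)
  arch <- architecture_spec(epistatic_pairs = cbind(3L, 17L),
                            epistasis_weights = 2,
                            heritability_like_scale = 0.6, prevalence = 0.25)
  ph <- simulate_phenotype(g, arch, seed = 8)
  y <- ph$phenotype
  joint <- (g$alt_counts[, 3] >= 1) & (g$alt_counts[, 17] >= 1)
  chi_joint <- suppressWarnings(chisq.test(table(joint, y))$statistic)
  chi_m1 <- suppressWarnings(chisq.test(table(g$alt_counts[, 3] >= 1, y))$statistic)
  chi_m2 <- suppressWarnings(chisq.test(table(g$alt_counts[, 17] >= 1, y))$statistic)
  expect_lt(suppressWarnings(chisq.test(table(joint, y))$p.value), 1e-4)
  expect_gt(chi_joint, chi_m1)
  expect_gt(chi_joint, chi_m2)
})

test_that("phenotype errors on out-of-range causal indices", {
  cfg <- sim_config(n_snps = 10, n_genes = 3, seed = 17)
  g <- simulate_genotypes(cfg, 50, seed = 1)
  arch <- architecture_spec(epistatic_pairs = cbind(2L, 99L),
                            epistasis_weights = 1)
  expect_error(simulate_phenotype(g, arch, seed = 1), "variant range")
})

test_that("null discovery GWAS p-values are uniform", {
  cfg <- sim_config(n_snps = 200, n_genes = 10, n_chromosomes = 4,
                    within_block_rho = 0, maf_range = c(0.1, 0.5),
                    missing_rate = 0.02, seed = 18)
  coh <- simulate_cohort(cfg, architecture_spec(prevalence = 0.3),
                         n = 2000, seed = 9)
  st <- run_discovery_gwas(coh)
  ks <- suppressWarnings(ks.test(st$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("monomorphic SNPs report beta 0 and p 1", {
  set.seed(31)
  counts <- cbind(rep(0L, 40), rbinom(40, 2, 0.4))
  ds <- make_dataset(counts, phenotype = rep(c(0L, 1L), 20))
  st <- suppressMessages(run_discovery_gwas(ds))
  expect_equal(st$beta[1], 0)
  expect_equal(st$p_value[1], 1)
})

test_that("a strong causal SNP reaches genome-wide significance reliably", {
  hits <- 0
  for (seed in 1:20) {
    cfg <- sim_config(n_snps = 10, n_genes = 3, missing_rate = 0,
                      maf_range = c(0.3, 0.3), seed = seed)
    arch <- architecture_spec(additive_idx = 4L, additive_betas = 2,
                              heritability_like_scale = 0.5,
                              prevalence = 0.3)
    coh <- simulate_cohort(cfg, arch, n = 2000, seed = seed + 50)
    st <- run_discovery_gwas(coh)
    if (st$p_value[4] < 5e-8) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("simulated gene annotations respect counts, overlap and orphans", {
  cfg <- sim_config(n_snps = 60, n_genes = 9, n_chromosomes = 3,
                    orphan_snp_fraction = 0.1, seed = 19)
  genes <- simulate_gene_annotation(cfg)
  expect_equal(nrow(genes), 9L)
  for (c_id in unique(genes$chrom)) {
    gc <- genes[genes$chrom == c_id, ]
    expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))  # non-overlapping
  }
  # at least one SNP farther than 250 kb from every gene
  dist_min <- sapply(seq_len(nrow(cfg$variants)), function(i) {
    v <- cfg$variants[i, ]
    gc <- genes[genes$chrom == v$chrom, ]
    min(pmax(0, pmax(gc$start - v$pos, v$pos - gc$end)))
  })
  expect_gt(sum(dist_min > 250000), 0)
})

test_that("cohort simulation is deterministic and carries truth", {
  w1 <- tiny_world(seed = 21)
  w2 <- tiny_world(seed = 21)
  expect_identical(w1$cohort$alt_counts, w2$cohort$alt_counts)
  expect_identical(w1$cohort$phenotype, w2$cohort$phenotype)
  expect_s3_class(attr(w1$cohort, "truth")$architecture, "architecture_spec")
})
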
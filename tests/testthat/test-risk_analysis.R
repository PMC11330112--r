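test_that("AUC hits its closed-form extremes and matches the pair-count oracle", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0.0)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(81)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    scores <- sample(round(rnorm(n), 1))  # coarse: forces ties
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(82)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, 0.4)
  base <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), base, tolerance = 1e-12)
  expect_equal(auc(rank(scores), labels), base, tolerance = 1e-12)
})

test_that("odds ratio reproduces the direct 2x2 computation", {
  # engineered table: top 20% of 500 holds 10 cases -> OR = (10*390)/(90*10)
  labels <- c(rep(1, 10), rep(0, 90), rep(1, 10), rep(0, 390))
  scores <- seq(500, 1, by = -1)
  r <- odds_ratio(scores, labels, 0.2)
  expect_equal(r$or, 13 / 3, tolerance = 1e-12)
  expect_equal(unname(r$table["TD"]), 10)
  expect_equal(unname(r$table["RE"]), 390)
  # equal prevalence in both groups -> OR 1
  lab_eq <- rep(c(1, 0, 0, 0), 25)
  expect_equal(odds_ratio(seq(100, 1), lab_eq, 0.2)$or, 1.0)
  # all cases in the top group -> infinite with a flag
  r_inf <- odds_ratio(seq(10, 1), c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), 0.2)
  expect_true(is.infinite(r_inf$or) && r_inf$infinite)
})

test_that("odds ratio equals the oracle over many random draws", {
  set.seed(83)
  for (i in 1:200) {
    n <- sample(20:120, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, runif(1, 0.1, 0.5))
    if (sum(labels) %in% c(0, n)) next
    f <- runif(1, 0.05, 0.5)
    expect_identical(odds_ratio(scores, labels, f)$or,
                     oracle_odds_ratio(scores, labels, f))
  }
})

test_that("null scores give odds ratios near one", {
  set.seed(84)
  ors <- replicate(5, {
    scores <- rnorm(10000)
    labels <- rbinom(10000, 1, 0.1)
    odds_ratio(scores, labels, 0.2)$or
  })
  expect_gt(mean(ors), 0.8)
  expect_lt(mean(ors), 1.25)
})

test_that("proportion at fold risk matches a brute-force sweep", {
  # perfectly separating scores at prevalence 0.5: some fraction exceeds 3x
  labels <- rep(c(1, 0), each = 50)
  scores <- c(seq(100, 51), seq(50, 1))
  expect_gt(proportion_at_fold_risk(scores, labels, 3), 0)
  # constant scores cannot separate (stable tie order, control first)
  expect_equal(proportion_at_fold_risk(rep(1, 100), rep(c(0L, 1L), 50), 3), 0)
  set.seed(85)
  for (i in 1:3) {
    n <- 150
    scores <- rnorm(n) + rep(c(0.8, 0), c(40, n - 40))
    labels <- rbinom(n, 1, plogis(scores - 1))
    if (sum(labels) %in% c(0, n)) next
    for (fold in c(2, 3)) {
      expect_equal(proportion_at_fold_risk(scores, labels, fold),
                   oracle_prop_at_fold(scores, labels, fold))
    }
  }
})

test_that("percentile prevalence conserves the overall prevalence exactly", {
  set.seed(86)
  for (i in 1:5) {
    n <- sample(150:800, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # ties included
    labels <- rbinom(n, 1, 0.25)
    pp <- percentile_prevalence(scores, labels)
    keep <- pp$bin_n > 0
    expect_equal(sum(pp$prevalence[keep] * pp$bin_n[keep]) / n,
                 mean(labels), tolerance = 1e-12)
    expect_length(pp$prevalence, 100L)
    expect_true(all(pp$prevalence[keep] >= 0 & pp$prevalence[keep] <= 1))
  }
  expect_error(percentile_prevalence(rnorm(50), rbinom(50, 1, 0.5)),
               "fewer bins")
})

test_that("percentile curve is flat under the null, rising under signal", {
  set.seed(87)
  scores <- rnorm(10000)
  labels <- rbinom(10000, 1, 0.1)
  pp <- percentile_prevalence(scores, labels)
  expect_lt(abs(cor(seq_len(100), pp$prevalence, method = "spearman")), 0.3)
  informative <- rnorm(10000) + labels
  pp2 <- percentile_prevalence(informative, labels)
  expect_gt(pp2$prevalence[100], pp2$prevalence[1])
  expect_gt(pp2$median_case_percentile, pp2$median_control_percentile)
})

test_that("stratification report bundles the analytics coherently", {
  set.seed(88)
  labels <- rbinom(2000, 1, 0.2)
  scores <- rnorm(2000) + 0.8 * labels
  rep <- stratification_report(scores, labels)
  expect_equal(rep$auc, auc(scores, labels))
  expect_equal(nrow(rep$odds_ratios), 4L)
  expect_true(all(diff(rep$proportion_at_fold) <= 0))  # 3x >= 4x >= 5x
  expect_output(print(rep), "AUC")
})

test_that("cross-validation folds partition, stratify, and stay null-calibrated", {
  w <- tiny_world(seed = 89, n = 600)
  null_arch <- architecture_spec(prevalence = 0.3)
  cohort <- simulate_cohort(w$cfg, null_arch, n = 600, seed = 90)
  discovery <- simulate_cohort(w$cfg, null_arch, n = 600, seed = 91)
  stats <- run_discovery_gwas(discovery)
  cv <- cross_validate(cohort, stats, w$panel, method = "pt",
                       params = selection_params(0.8, NA), k = 10, seed = 3)
  expect_length(cv$fold_auc, 10L)
  expect_setequal(unique(cv$fold), 1:10)
  # stratification: per-fold case fraction within 1 sample of global
  for (f in 1:10) {
    in_f <- cv$fold == f
    expect_lte(abs(sum(cohort$phenotype[in_f]) -
                     mean(cohort$phenotype) * sum(in_f)), 1)
  }
  expect_gt(cv$mean_auc, 0.40)
  expect_lt(cv$mean_auc, 0.60)
})

test_that("risk-SNP counts match the per-individual tally oracle", {
  set.seed(92)
  counts <- matrix(rbinom(60 * 15, 2, 0.3), nrow = 60)
  ds <- make_dataset(counts, phenotype = rbinom(60, 1, 0.4))
  stats <- make_stats(paste0("v", 1:15),
                      p = c(rep(1e-9, 6), rep(0.2, 9)),
                      beta = c(rep(c(0.3, -0.2), 3), rep(0.1, 9)))
  scores <- rnorm(60)
  res <- risk_snp_subgroup_auc(scores, ds$phenotype, ds, stats,
                               cutoffs = c(1, 3, 15))
  expect_identical(res$counts, oracle_risk_counts(ds, stats))
  # an individual with zero alt alleles carries zero risk SNPs
  blank <- ds
  blank$alt_counts[1, ] <- 0L
  res_b <- risk_snp_subgroup_auc(scores, ds$phenotype, blank, stats, 1)
  expect_equal(res_b$counts[1], 0L)
  # cutoff at the max count reproduces the whole-cohort AUC
  res_max <- risk_snp_subgroup_auc(scores, ds$phenotype, ds, stats,
                                   cutoffs = max(res$counts))
  expect_equal(res_max$table$auc, auc(scores, ds$phenotype))
})

test_that("removing the only informative SNPs collapses the P+T signal", {
  cfg <- sim_config(n_snps = 80, n_genes = 8, n_chromosomes = 2,
                    within_block_rho = 0, maf_range = c(0.2, 0.4),
                    missing_rate = 0, seed = 93)
  arch <- architecture_spec(additive_idx = 1:10 * 8L - 3L,
                            additive_betas = rep(0.8, 10),
                            heritability_like_scale = 0.6, prevalence = 0.3)
  discovery <- simulate_cohort(cfg, arch, n = 3000, seed = 94)
  stats <- run_discovery_gwas(discovery)
  cohort <- simulate_cohort(cfg, arch, n = 1500, seed = 95)
  parts <- split_cohort(cohort, 0.4, seed = 96)
  panel <- simulate_genotypes(cfg, 300, seed = 97)
  rob <- snp_removal_robustness(parts$train, parts$test, stats, panel,
                                methods = "pt",
                                params = selection_params(0.9, NA),
                                removals = c(10L), seed = 98)
  auc0 <- rob$auc[rob$removed == 0]
  auc10 <- rob$auc[rob$removed == 10]
  expect_gt(auc0, 0.7)
  expect_lt(auc10, 0.6)  # the ten causal SNPs carried all the signal
  expect_error(
    snp_removal_robustness(parts$train, parts$test, stats, panel,
                           removals = 100L, seed = 1),
    "pass the base p threshold|cannot remove")
})
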
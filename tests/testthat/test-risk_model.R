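test_that("class weights follow the balanced-cohort normalization", {
  expect_equal(class_weights(100, 50), c(w0 = 1, w1 = 1))
  expect_equal(class_weights(100, 10), c(w0 = 0.5556, w1 = 5),
               tolerance = 1e-4)
  expect_error(class_weights(10, 0), "degenerate")
  expect_error(class_weights(10, 10), "degenerate")
})

test_that("weighted cross-entropy matches closed forms", {
  expect_equal(weighted_bce(rep(0.5, 10), rep(c(0, 1), 5)), log(2),
               tolerance = 1e-12)
  expect_lt(weighted_bce(c(1e-7, 1 - 1e-7), c(0, 1)), 1e-5)
  expect_equal(weighted_bce(0.25, 1, w0 = 1, w1 = 5), 5 * -log(0.25),
               tolerance = 1e-12)
  expect_error(weighted_bce(c(0.5, 0.5), 1), "length mismatch")
  # balanced weights reduce exactly to plain BCE
  set.seed(61)
  p <- runif(50, 0.01, 0.99)
  y <- rbinom(50, 1, 0.5)
  plain <- mean(-y * log(p) - (1 - y) * log(1 - p))
  w <- class_weights(100, 50)
  expect_equal(weighted_bce(p, y, w["w0"], w["w1"]), plain,
               tolerance = 1e-12)
})

make_model_world <- function(seed = 62, n = 200, variant = "full", ...) {
  w <- tiny_world(seed = seed, n = n)
  conn <- build_connectivity(w$cohort$variants$id, w$cohort, w$genes)
  mode <- if (variant == "additive_encoding") "additive" else "two_dim"
  cfg <- model_config(seed = seed, variant = variant, ...)
  list(w = w, conn = conn,
       X = encode_genotypes(w$cohort, conn$snp_ids, mode = mode),
       model = build_risk_model(conn, cfg))
}

test_that("an untrained model scores 0.5 and outputs stay in (0, 1)", {
  mw <- make_model_world()
  p <- predict_scores(mw$model, mw$X)
  expect_equal(p, rep(0.5, n_samples(mw$w$cohort)))
  tr <- train_risk_model(mw$model, mw$X, mw$w$cohort$phenotype)
  p2 <- predict_scores(tr$model, mw$X)
  expect_true(all(p2 > 0 & p2 < 1))
})

test_that("gene features ignore perturbations of unconnected SNPs", {
  mw <- make_model_world()
  key <- names(mw$model$layout)[1]
  ch <- mw$conn$chromosomes[[key]]
  # find a (snp, gene) pair with no edge
  free <- which(!ch$incidence, arr.ind = TRUE)[1, ]
  Xc <- deeprisk:::.split_encoded(mw$model, mw$X)
  G1 <- Xc[[key]] %*% mw$model$params$partial[[key]]
  Xp <- Xc
  cols <- (free[1] - 1) * 2 + 1:2
  Xp[[key]][, cols] <- Xp[[key]][, cols] + 100
  G2 <- Xp[[key]] %*% mw$model$params$partial[[key]]
  expect_equal(G1[, free[2]], G2[, free[2]])
  expect_false(isTRUE(all.equal(G1, G2)))  # connected genes do move
})

test_that("training is deterministic, descends, and early-stops sanely", {
  mw <- make_model_world(n = 300, max_epochs = 12, learning_rate = 5e-3)
  y <- mw$w$cohort$phenotype
  tr1 <- train_risk_model(mw$model, mw$X, y)
  tr2 <- train_risk_model(mw$model, mw$X, y)
  expect_identical(predict_scores(tr1$model, mw$X),
                   predict_scores(tr2$model, mw$X))
  loss <- tr1$report$loss
  expect_true(all(is.finite(loss$validation)))
  expect_equal(unname(tr1$report$class_weights["w1"]),
               length(y) / (2 * sum(y)))
})

test_that("a fully determining SNP is learned to high training AUC", {
  set.seed(63)
  counts <- matrix(rbinom(500 * 8, 2, 0.35), nrow = 500)
  y <- as.integer(counts[, 3] >= 1)
  ds <- make_dataset(counts, phenotype = y,
                     pos = as.integer(seq(1e4, 8e5, length.out = 8)))
  genes <- make_genes(c("g1", "g2"), chrom = 1L,
                      start = c(10000L, 500000L), end = c(40000L, 550000L))
  conn <- build_connectivity(ds$variants$id, ds, genes)
  cfg <- model_config(seed = 64, max_epochs = 40, learning_rate = 5e-3)
  model <- build_risk_model(conn, cfg)
  X <- encode_genotypes(ds, conn$snp_ids)
  tr <- train_risk_model(model, X, y)
  expect_gt(auc(predict_scores(tr$model, X), y), 0.95)
  # loss descends from the first epoch to the chosen epoch
  loss <- tr$report$loss
  expect_gt(loss$train[1], loss$train[tr$report$chosen_epoch])
})

test_that("masked partial weights stay exactly zero through training", {
  mw <- make_model_world(n = 256, max_epochs = 5)
  tr <- train_risk_model(mw$model, mw$X, mw$w$cohort$phenotype)
  for (key in names(tr$model$params$partial)) {
    off <- !tr$model$masks[[key]]
    expect_true(all(tr$model$params$partial[[key]][off] == 0))
    expect_gt(sum(tr$model$params$partial[[key]][!off] != 0), 0)
  }
})

test_that("prediction is batch- and order-invariant and handles all-missing", {
  mw <- make_model_world(n = 150)
  tr <- train_risk_model(mw$model, mw$X, mw$w$cohort$phenotype)
  p_all <- predict_scores(tr$model, mw$X)
  one <- encode_genotypes(mw$w$cohort[7, ], tr$model$snp_ids)
  expect_equal(predict_scores(tr$model, one), p_all[7], tolerance = 1e-6)
  perm <- c(5:1, 6:150)
  p_perm <- predict_scores(
    tr$model, encode_genotypes(mw$w$cohort[perm, ], tr$model$snp_ids))
  expect_equal(p_perm, p_all[perm], tolerance = 1e-12)
  # an individual missing every genotype still gets a finite score
  blank <- mw$w$cohort[1, ]
  blank$alt_counts[] <- NA_integer_
  pb <- predict_scores(tr$model, encode_genotypes(blank, tr$model$snp_ids))
  expect_true(is.finite(pb) && pb > 0 && pb < 1)
})

test_that("prediction rejects mismatched SNP order and covariate width", {
  mw <- make_model_world(n = 100)
  wrong <- encode_genotypes(mw$w$cohort, rev(mw$model$snp_ids))
  expect_error(predict_scores(mw$model, wrong), "SNP order")
  wrong_mode <- encode_genotypes(mw$w$cohort, mw$model$snp_ids,
                                 mode = "additive")
  expect_error(predict_scores(mw$model, wrong_mode), "mode")
  cfgc <- model_config(seed = 1, covariate_dim = 2L, max_epochs = 2)
  mc <- build_risk_model(mw$conn, cfgc)
  expect_error(predict_scores(mc, mw$X), "covariate")
})

test_that("covariates contribute to the learned score", {
  set.seed(65)
  cfg <- sim_config(n_snps = 20, n_genes = 5, missing_rate = 0, seed = 66)
  arch <- architecture_spec(covariate_effects = c(2, -1),
                            heritability_like_scale = 0.7, prevalence = 0.3)
  coh <- simulate_cohort(cfg, arch, n = 400, seed = 67)
  genes <- simulate_gene_annotation(cfg)
  fit <- deeprisk_fit(coh, coh$variants$id, genes,
                      model_cfg = model_config(max_epochs = 15),
                      seed = 68, covariates = coh$covariates)
  s <- deeprisk_score(fit, coh, covariates = coh$covariates)
  expect_gt(auc(s, coh$phenotype), 0.7)
})

test_that("model checkpoints round-trip and verify connectivity", {
  mw <- make_model_world(n = 100, max_epochs = 2)
  tr <- train_risk_model(mw$model, mw$X, mw$w$cohort$phenotype)
  path <- file.path(tempdir(), "model.rds")
  save_risk_model(tr$model, path)
  back <- load_risk_model(path)
  expect_identical(predict_scores(back, mw$X),
                   predict_scores(tr$model, mw$X))
  broken <- readRDS(path)
  broken$hash <- "0"
  saveRDS(broken, path)
  expect_error(load_risk_model(path), "hash mismatch")
})

test_that("all three variants train and score", {
  for (v in c("no_partial_layer", "additive_encoding")) {
    mw <- make_model_world(n = 120, variant = v, max_epochs = 3)
    tr <- train_risk_model(mw$model, mw$X, mw$w$cohort$phenotype)
    p <- predict_scores(tr$model, mw$X)
    expect_length(p, 120)
    expect_true(all(p > 0 & p < 1))
  }
})
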
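# End-to-end fitting: selection -> encoding/connectivity -> model -> scores,
# behind one method-agnostic surface shared by cross-validation, the grid
# search, the robustness experiment and the benchmarks.

#' Fit a scoring method on a training cohort and score a test cohort
#'
#' One entry point for the three methods so downstream analyses are
#' method-agnostic. `"pt"` computes the beta-weighted allele-count sum of
#' the selected SNPs (no training). `"lasso"` fits the L1 logistic
#' classifier on the selected SNPs' additive counts. `"deeprisk"` builds the
#' SNP-to-gene connectivity over the selected SNPs, trains the
#' partial-connection + BiLSTM network, and scores with it.
#'
#' @param method `"deeprisk"`, `"pt"` or `"lasso"`.
#' @param selection A `selection_result` (or character SNP ids).
#' @param train_ds Labelled training `genotype_dataset`.
#' @param test_ds `genotype_dataset` to score.
#' @param stats `summary_stats` (needed by `"pt"`).
#' @param genes [gene_annotation()] (needed by `"deeprisk"`).
#' @param model_cfg [model_config()] for `"deeprisk"`; its seed is replaced
#'   by `seed`.
#' @param seed Integer seed.
#' @param use_covariates Feed the datasets' covariates to the model?
#' @return Numeric scores for `test_ds`'s samples.
#' @export
fit_and_score <- function(method, selection, train_ds, test_ds,
                          stats = NULL, genes = NULL,
                          model_cfg = model_config(), seed = 1,
                          use_covariates = FALSE) {
  method <- match.arg(method, c("deeprisk", "pt", "lasso"))
  ids <- if (inherits(selection, "selection_result")) {
    selection$selected_ids
  } else {
    selection
  }
  if (method == "pt") {
    if (is.null(stats)) stop("pt needs summary stats for the betas")
    return(prs_pt(test_ds, stats, ids)$score)
  }
  cov_tr <- if (use_covariates) train_ds$covariates
  cov_te <- if (use_covariates) test_ds$covariates
  if (method == "lasso") {
    xtr <- train_ds$alt_counts[, match(ids, train_ds$variants$id), drop = FALSE]
    xte <- test_ds$alt_counts[, match(ids, test_ds$variants$id), drop = FALSE]
    xtr[is.na(xtr)] <- 0L
    xte[is.na(xte)] <- 0L
    fit <- lasso_fit(xtr, train_ds$phenotype, covariates = cov_tr,
                     seed = seed)
    return(predict(fit, xte, covariates = cov_te))
  }
  fit <- deeprisk_fit(train_ds, ids, genes, model_cfg = model_cfg,
                      seed = seed, covariates = cov_tr)
  deeprisk_score(fit, test_ds, covariates = cov_te)
}

#' Fit the deep risk model on a cohort
#'
#' Builds connectivity for the selected SNPs, encodes the genotypes in the
#' mode the config's variant requires, and trains the network.
#'
#' @param train_ds Labelled `genotype_dataset`.
#' @param selection `selection_result` or SNP ids.
#' @param genes [gene_annotation()] table.
#' @param model_cfg [model_config()]; `seed` below overrides its seed.
#' @param seed Integer seed.
#' @param covariates Optional covariate matrix (overrides
#'   `model_cfg$covariate_dim`).
#' @return List of class `deeprisk_fit`: trained `model`, `report`,
#'   `selection_ids`.
#' @export
deeprisk_fit <- function(train_ds, selection, genes,
                         model_cfg = model_config(), seed = model_cfg$seed,
                         covariates = NULL) {
  if (is.null(genes)) stop("deeprisk needs a gene annotation")
  if (is.null(train_ds$phenotype)) stop("training cohort must be labelled")
  ids <- if (inherits(selection, "selection_result")) {
    selection$selected_ids
  } else {
    selection
  }
  model_cfg$seed <- as.integer(seed)
  model_cfg$covariate_dim <- if (is.null(covariates)) 0L else ncol(covariates)
  conn <- build_connectivity(ids, train_ds, genes)
  mode <- if (model_cfg$variant == "additive_encoding") "additive" else "two_dim"
  X <- encode_genotypes(train_ds, conn$snp_ids, mode = mode)
  model <- build_risk_model(conn, model_cfg)
  tr <- train_risk_model(model, X, train_ds$phenotype, covariates)
  structure(list(model = tr$model, report = tr$report,
                 selection_ids = ids, mode = mode),
            class = "deeprisk_fit")
}

#' Score a cohort with a fitted deep risk model
#'
#' @param fit A [deeprisk_fit()].
#' @param ds `genotype_dataset` containing the model's SNPs.
#' @param covariates Covariates when the model uses them.
#' @return Numeric scores.
#' @export
deeprisk_score <- function(fit, ds, covariates = NULL) {
  X <- encode_genotypes(ds, fit$model$snp_ids, mode = fit$mode)
  predict_scores(fit$model, X, covariates)
}

# train_fn adapter for grid_search / cross_validate
.method_train_fn <- function(method, stats, genes, model_cfg) {
  force(method); force(stats); force(genes); force(model_cfg)
  function(selection, fit_ds, eval_ds, seed) {
    fit_and_score(method, selection, fit_ds, eval_ds, stats = stats,
                  genes = genes, model_cfg = model_cfg, seed = seed)
  }
}

#' Stratified train/test split of a cohort
#'
#' @param cohort Labelled `genotype_dataset`.
#' @param test_fraction Fraction held out for testing.
#' @param seed Integer seed.
#' @return List with `train` and `test` datasets.
#' @export
split_cohort <- function(cohort, test_fraction = 0.3, seed = 1) {
  if (is.null(cohort$phenotype)) stop("cohort must be labelled")
  set.seed(seed)
  test_idx <- stratified_holdout(cohort$phenotype, test_fraction)
  list(train = cohort[-test_idx, ], test = cohort[test_idx, ])
}
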
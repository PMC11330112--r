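# Comparison methods: the classical pruning-and-thresholding PRS and an
# L1-penalized logistic (lasso) classifier. Both consume the traditional
# additive allele counts — they are the linear comparators the deep score is
# evaluated against.

#' Pruning-and-thresholding polygenic risk score
#'
#' The field-standard weighted sum: `score_i = sum_j beta_j * altcount_ij`
#' over the selected SNPs, with missing genotypes contributing 0.
#'
#' @param geno A `genotype_dataset` to score.
#' @param stats A `summary_stats` table supplying the betas.
#' @param selected A `selection_result` or character vector of SNP ids.
#' @return An object of class `prs_result`: numeric `score` per sample,
#'   `snp_ids` used, and the selection `params` (when available).
#' @export
prs_pt <- function(geno, stats, selected) {
  params <- NULL
  if (inherits(selected, "selection_result")) {
    params <- selected$params
    selected <- selected$selected_ids
  }
  use <- intersect(selected, geno$variants$id)
  if (length(use) == 0) {
    stop("no overlap between selected SNPs and genotyped variants")
  }
  sidx <- match(use, stats$id)
  if (anyNA(sidx)) {
    stop("summary stats lack beta for: ",
         paste(utils::head(use[is.na(sidx)], 5), collapse = ", "))
  }
  g <- geno$alt_counts[, match(use, geno$variants$id), drop = FALSE]
  g[is.na(g)] <- 0L
  score <- as.numeric(g %*% stats$beta[sidx])
  structure(list(score = score, snp_ids = use, params = params),
            class = "prs_result")
}

#' Lasso-penalized logistic risk score
#'
#' L1-penalized logistic regression on additive allele counts (missing set
#' to 0), with the penalty weight chosen by internal cross-validated AUC.
#' Covariates, when supplied, are left unpenalized. Deterministic under
#' `seed` (the CV fold assignment is seeded).
#'
#' @param X Numeric feature matrix `[n x m]` (e.g. additive
#'   [encode_genotypes()] flattened, or raw counts with `NA -> 0`), or a
#'   `genotype_dataset` (its alt counts are used).
#' @param y Binary labels.
#' @param covariates Optional unpenalized covariate matrix.
#' @param lambda Optional lambda grid passed to glmnet.
#' @param nfolds Internal CV folds (default 5).
#' @param seed Integer seed.
#' @return An object of class `lasso_prs` with the fitted glmnet path, the
#'   chosen lambda, in-sample `score`, and the nonzero coefficient table.
#' @export
lasso_fit <- function(X, y, covariates = NULL, lambda = NULL, nfolds = 5,
                      seed = 1) {
  if (inherits(X, "genotype_dataset")) {
    X <- X$alt_counts
    X[is.na(X)] <- 0L
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("lasso needs both classes present")
  n_geno <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(n_geno))
  pf <- rep(1, n_geno)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates)
    pf <- c(pf, rep(0, ncol(covariates)))
  }
  set.seed(seed)
  foldid <- numeric(length(y))
  for (cls in unique(y)) {  # stratified fold assignment
    ix <- which(y == cls)
    foldid[ix] <- sample(rep_len(seq_len(nfolds), length(ix)))
  }
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          lambda = lambda, foldid = foldid,
                          type.measure = "auc", penalty.factor = pf,
                          standardize = TRUE)
  score <- as.numeric(stats::predict(cv, newx = X, s = "lambda.min",
                                     type = "response"))
  coefs <- as.matrix(stats::coef(cv, s = "lambda.min"))
  nz <- coefs[coefs[, 1] != 0, 1, drop = FALSE]
  structure(list(cv = cv, lambda = cv$lambda.min, score = score,
                 nonzero = data.frame(feature = rownames(nz),
                                      coefficient = nz[, 1],
                                      row.names = NULL),
                 n_geno = n_geno, has_covariates = !is.null(covariates)),
            class = "lasso_prs")
}

#' Score new samples with a fitted lasso model
#'
#' @param object A `lasso_prs`.
#' @param X New feature matrix with the same genotype columns (a
#'   `genotype_dataset` is accepted).
#' @param covariates Covariates when the model was fitted with them.
#' @param ... Unused.
#' @return Numeric probability scores.
#' @export
predict.lasso_prs <- function(object, X, covariates = NULL, ...) {
  if (inherits(X, "genotype_dataset")) {
    X <- X$alt_counts
    X[is.na(X)] <- 0L
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != object$n_geno) {
    stop("expected ", object$n_geno, " genotype feature column(s)")
  }
  if (object$has_covariates) {
    if (is.null(covariates)) stop("model was fitted with covariates")
    X <- cbind(X, as.matrix(covariates))
  }
  as.numeric(stats::predict(object$cv, newx = X, s = "lambda.min",
                            type = "response"))
}
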
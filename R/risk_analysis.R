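# Score-based risk stratification and evaluation: odds ratios at top-score
# cutoffs, proportion of the population at k-fold risk, percentile
# prevalence curves, rank-based AUC, stratified cross-validation, risk-SNP
# subgroup analysis, and the top-SNP removal robustness experiment.

#' Rank-based AUC
#'
#' Mann-Whitney estimator with average-rank tie correction: the probability
#' a random case outscores a random control (ties count half). Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Odds ratio of a top-score group versus the remainder
#'
#' Samples are ranked by descending score (ties broken by stable sample
#' order, with the tie count reported); the top `ceiling(top_fraction * n)`
#' form the T group. `OR = (TD * RE) / (TE * RD)` where TD/TE are diseased/
#' healthy counts in the top group and RD/RE in the remainder. A zero `TE`
#' or `RD` yields `OR = Inf` with an explicit flag — no continuity
#' correction is applied.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param top_fraction Fraction in (0, 1) defining the top group.
#' @return List: `or`, `infinite` flag, `n_boundary_ties`, and `table`
#'   (`T`, `TD`, `TE`, `R`, `RD`, `RE`).
#' @export
odds_ratio <- function(scores, labels, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction < 1,
            length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("odds ratio needs both classes")
  n <- length(scores)
  k <- ceiling(top_fraction * n)
  ord <- order(-scores, seq_len(n))  # stable: ties keep sample order
  top <- ord[seq_len(k)]
  boundary <- scores[ord[k]]
  n_ties <- sum(scores == boundary) - 1L
  TD <- sum(labels[top])
  TE <- k - TD
  RD <- sum(labels) - TD
  RE <- n - k - RD
  infinite <- TE == 0 || RD == 0
  or <- if (infinite) Inf else (TD * RE) / (TE * RD)
  list(or = or, infinite = infinite, n_boundary_ties = n_ties,
       table = c(T = k, TD = TD, TE = TE, R = n - k, RD = RD, RE = RE))
}

#' Proportion of the population at k-fold increased risk
#'
#' Sweeps every top-group size `k = 1..n-1`, computing the odds ratio of the
#' top-k (by descending score, stable ties) versus the remainder, and
#' returns the largest top fraction whose OR is at least `fold` (0 when no
#' cutoff reaches it).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param fold Risk multiple (e.g. 3, 4, 5).
#' @return Largest fraction of the population at `>= fold` odds, in `[0, 1)`.
#' @export
proportion_at_fold_risk <- function(scores, labels, fold) {
  stopifnot(fold >= 1)
  labels <- as.integer(labels)
  n <- length(scores)
  if (length(unique(labels)) < 2) stop("needs both classes")
  ord <- order(-scores, seq_len(n))
  cum_d <- cumsum(labels[ord])
  k <- seq_len(n - 1L)
  TD <- cum_d[k]
  TE <- k - TD
  RD <- sum(labels) - TD
  RE <- (n - k) - RD
  or <- ifelse(TE == 0 | RD == 0, Inf, (TD * RE) / (TE * RD))
  hits <- which(or >= fold)
  if (length(hits) == 0) 0 else max(hits) / n
}

#' Percentile prevalence curve
#'
#' Scores are converted to percentiles by average rank; bin `b` holds
#' percentiles in `(b-1, b]` for `b = 1..n_bins`. Prevalence per bin is the
#' case fraction among its members; the sample-size-weighted mean of bin
#' prevalences equals the overall prevalence exactly. Also reports the
#' median score percentile of cases and of controls.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param n_bins Number of percentile bins (default 100).
#' @return List: `prevalence` (length `n_bins`, `NaN` for empty bins),
#'   `bin_n`, `median_case_percentile`, `median_control_percentile`.
#' @export
percentile_prevalence <- function(scores, labels, n_bins = 100L) {
  labels <- as.integer(labels)
  n <- length(scores)
  if (n < n_bins) {
    stop("need at least ", n_bins, " samples for ", n_bins,
         " bins; use fewer bins")
  }
  pct <- rank(scores, ties.method = "average") / n * n_bins
  bin <- pmin(pmax(ceiling(pct), 1L), n_bins)
  bin_n <- tabulate(bin, nbins = n_bins)
  bin_d <- vapply(seq_len(n_bins), function(b) sum(labels[bin == b]), 0L)
  prevalence <- ifelse(bin_n > 0, bin_d / bin_n, NaN)
  list(prevalence = prevalence, bin_n = bin_n,
       median_case_percentile = stats::median(pct[labels == 1]),
       median_control_percentile = stats::median(pct[labels == 0]))
}

#' Full stratification report for a score vector
#'
#' Bundles the descriptive risk analytics: ORs at the requested top-score
#' cutoffs, proportion of the population at 3/4/5-fold risk, the
#' 100-bin percentile prevalence curve with case/control medians, and AUC.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param top_fractions Cutoffs for the OR table (default 1%, 5%, 10%, 20%).
#' @param folds Risk multiples for the proportion sweep (default 3, 4, 5).
#' @param n_bins Percentile bins (default 100; skipped when `n < n_bins`).
#' @return An object of class `stratification_report`.
#' @export
stratification_report <- function(scores, labels,
                                  top_fractions = c(0.01, 0.05, 0.1, 0.2),
                                  folds = c(3, 4, 5), n_bins = 100L) {
  ors <- lapply(top_fractions, function(f) odds_ratio(scores, labels, f))
  or_tab <- data.frame(
    top_fraction = top_fractions,
    or = vapply(ors, `[[`, 0, "or"),
    infinite = vapply(ors, `[[`, TRUE, "infinite")
  )
  prop <- vapply(folds, function(f) proportion_at_fold_risk(scores, labels, f), 0)
  pp <- if (length(scores) >= n_bins) {
    percentile_prevalence(scores, labels, n_bins)
  }
  structure(list(odds_ratios = or_tab,
                 proportion_at_fold = stats::setNames(prop, paste0("fold", folds)),
                 percentiles = pp, auc = auc(scores, labels),
                 n = length(scores), prevalence = mean(labels == 1)),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("stratification_report: n =", x$n,
      sprintf("(prevalence %.3f), AUC = %.4f\n", x$prevalence, x$auc))
  for (i in seq_len(nrow(x$odds_ratios))) {
    cat(sprintf("  OR top %4.1f%%: %s\n", 100 * x$odds_ratios$top_fraction[i],
                ifelse(x$odds_ratios$infinite[i], "Inf",
                       sprintf("%.3f", x$odds_ratios$or[i]))))
  }
  cat("  population at fold risk:",
      paste(sprintf("%s=%.2f%%", names(x$proportion_at_fold),
                    100 * x$proportion_at_fold), collapse = ", "), "\n")
  if (!is.null(x$percentiles)) {
    cat(sprintf("  median percentile: cases %.0f, controls %.0f\n",
                x$percentiles$median_case_percentile,
                x$percentiles$median_control_percentile))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation of a scoring pipeline
#'
#' Splits the cohort into `k` stratified folds; for each fold the entire
#' pipeline — SNP selection (optionally a parameter grid search run strictly
#' inside the training fold) plus model training — is fitted on the other
#' folds and scored on the held-out fold, so the test fold never leaks into
#' selection or training.
#'
#' @param cohort Labelled `genotype_dataset`.
#' @param stats Discovery `summary_stats`.
#' @param panel LD reference panel.
#' @param method `"deeprisk"`, `"pt"` or `"lasso"`.
#' @param genes [gene_annotation()] table (deeprisk method only).
#' @param params A [selection_params()] used for every fold, or a list of
#'   them (a grid): the grid is then searched within each training fold.
#' @param model_cfg A [model_config()] (deeprisk method only).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (fold assignment and training).
#' @return List: `fold_auc`, `mean_auc`, `scores` (cohort-order out-of-fold
#'   scores), `fold` assignment, and per-fold chosen parameters.
#' @export
cross_validate <- function(cohort, stats, panel, method = "deeprisk",
                           genes = NULL,
                           params = selection_params(5e-3, 0.2),
                           model_cfg = model_config(), k = 10L, seed = 1) {
  y <- cohort$phenotype
  if (is.null(y)) stop("cohort must be labelled")
  if (sum(y == 1) < k || sum(y == 0) < k) {
    stop("need at least k cases and k controls for ", k, "-fold CV")
  }
  set.seed(seed)
  fold <- numeric(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  scores <- numeric(length(y))
  fold_auc <- numeric(k)
  chosen <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_ds <- cohort[-test_idx, ]
    test_ds <- cohort[test_idx, ]
    par_f <- params
    if (is.list(params) && !inherits(params, "selection_params")) {
      gs <- grid_search(stats, panel, train_ds, grid = params,
                        train_fn = .method_train_fn(method, stats, genes,
                                                    model_cfg),
                        seed = seed + f)
      par_f <- gs$best_params
    }
    sel <- ld_clump(stats, panel, par_f)
    s <- fit_and_score(method, sel, train_ds, test_ds, stats, genes,
                       model_cfg = model_cfg, seed = seed + f)
    scores[test_idx] <- s
    fold_auc[f] <- auc(s, test_ds$phenotype)
    chosen[[f]] <- par_f
  }
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc), scores = scores,
       fold = fold, chosen_params = chosen)
}

#' Subgroup AUC for individuals carrying few risk SNPs
#'
#' Risk SNPs are variants with GWAS `p < 5e-8` and positive effect size; an
#' individual carries one when they hold at least one alternative allele at
#' it (missing genotypes do not count). For each cutoff, the AUC is computed
#' among individuals whose risk-SNP count is at most the cutoff; subgroups
#' containing a single class get `NaN` with a flag. Also reports the count
#' threshold delimiting the 1% of individuals carrying fewest risk SNPs.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param geno `genotype_dataset` for the same samples.
#' @param stats `summary_stats` covering the genotyped SNPs.
#' @param cutoffs Integer risk-SNP-count cutoffs.
#' @param p_risk,beta_sign_positive Risk-SNP definition knobs (defaults per
#'   the standard definition).
#' @return List: `counts` per individual, `threshold_1pct`, and `table`
#'   (cutoff, n, n_cases, auc, degenerate flag).
#' @export
risk_snp_subgroup_auc <- function(scores, labels, geno, stats,
                                  cutoffs, p_risk = 5e-8,
                                  beta_sign_positive = TRUE) {
  labels <- as.integer(labels)
  risk_ids <- stats$id[stats$p_value < p_risk &
                         (!beta_sign_positive | stats$beta > 0)]
  j <- match(intersect(risk_ids, geno$variants$id), geno$variants$id)
  counts <- if (length(j) == 0) {
    integer(n_samples(geno))
  } else {
    carried <- geno$alt_counts[, j, drop = FALSE] >= 1L
    carried[is.na(carried)] <- FALSE
    as.integer(rowSums(carried))
  }
  threshold_1pct <- stats::quantile(counts, 0.01, type = 1, names = FALSE)
  rows <- lapply(cutoffs, function(ct) {
    sub <- which(counts <= ct)
    degenerate <- length(unique(labels[sub])) < 2
    data.frame(cutoff = ct, n = length(sub), n_cases = sum(labels[sub]),
               auc = if (degenerate) NaN else auc(scores[sub], labels[sub]),
               degenerate = degenerate)
  })
  list(counts = counts, threshold_1pct = threshold_1pct,
       table = do.call(rbind, rows))
}

#' Robustness to removal of the most significant SNPs
#'
#' For each removal level `k`, the `k` smallest-p SNPs are dropped from the
#' summary statistics before selection, the pipeline (selection + training +
#' scoring) is rerun with the same seed, and test AUC is recorded — the
#' level-0 run is the unmodified baseline.
#'
#' @param train_ds,test_ds Labelled train/test `genotype_dataset`s.
#' @param stats Discovery `summary_stats`.
#' @param panel LD reference panel.
#' @param methods Character vector from `"deeprisk"`, `"pt"`, `"lasso"`.
#' @param genes [gene_annotation()] table (deeprisk method only).
#' @param params [selection_params()] used at every level.
#' @param model_cfg [model_config()] for the deeprisk method.
#' @param removals Removal levels (default 10, 20, 50); 0 is always
#'   included.
#' @param seed Integer seed shared across levels.
#' @return `data.frame` with columns `method`, `removed`, `n_selected`,
#'   `auc`.
#' @export
snp_removal_robustness <- function(train_ds, test_ds, stats, panel,
                                   methods = "pt", genes = NULL,
                                   params = selection_params(5e-3, 0.2),
                                   model_cfg = model_config(),
                                   removals = c(10L, 20L, 50L), seed = 1) {
  removals <- sort(unique(c(0L, as.integer(removals))))
  if (max(removals) >= nrow(stats)) {
    stop("cannot remove ", max(removals), " SNPs from ", nrow(stats))
  }
  base_pass <- sum(stats$p_value <= params$p_threshold)
  if (base_pass <= max(removals)) {
    stop("only ", base_pass, " SNPs pass the base p threshold; need more ",
         "than ", max(removals))
  }
  ord <- order(stats$p_value, stats$chrom, stats$pos, stats$id)
  rows <- list()
  for (k in removals) {
    stats_k <- stats
    if (k > 0) {
      stats_k <- summary_stats(as.data.frame(stats)[-ord[seq_len(k)], ])
    }
    sel <- ld_clump(stats_k, panel, params)
    for (m in methods) {
      s <- fit_and_score(m, sel, train_ds, test_ds, stats_k, genes,
                         model_cfg = model_cfg, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, removed = k, n_selected = length(sel$selected_ids),
        auc = auc(s, test_ds$phenotype))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
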
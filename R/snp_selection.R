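# SNP selection: p-value thresholding + greedy LD clumping against a
# reference panel, and the 20-candidate (p, r2) selection grid.

#' Selection parameters
#'
#' @param p_threshold Keep SNPs with GWAS `p <= p_threshold`. The canonical
#'   grid uses 5e-3, 5e-4, 5e-5, 5e-6.
#' @param r2_threshold Clump SNPs with `r^2 >= r2_threshold` (0.2, 0.4, 0.6
#'   or 0.8 on the canonical grid); `NA` means no clumping ("-"): pure
#'   p-value thresholding with the window ignored.
#' @param window_bp Clumping window radius in bp: an index SNP can absorb
#'   SNPs within `window_bp` of its position on the same chromosome.
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(p_threshold, r2_threshold = NA,
                             window_bp = 250000L) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            is.na(r2_threshold) || (r2_threshold > 0 & r2_threshold <= 1),
            window_bp >= 0)
  structure(list(p_threshold = p_threshold,
                 r2_threshold = if (is.na(r2_threshold)) NA_real_ else r2_threshold,
                 window_bp = as.integer(window_bp)),
            class = "selection_params")
}

#' @export
format.selection_params <- function(x, ...) {
  sprintf("p<=%.0e, r2%s", x$p_threshold,
          if (is.na(x$r2_threshold)) "=-" else sprintf(">=%.1f", x$r2_threshold))
}

#' @export
print.selection_params <- function(x, ...) {
  cat("selection_params:", format(x), "window", x$window_bp, "bp\n")
  invisible(x)
}

#' The canonical 4 x 5 selection grid
#'
#' Four p-value thresholds (5e-3, 5e-4, 5e-5, 5e-6) crossed with five r2
#' settings (0.2, 0.4, 0.6, 0.8, and no clumping), giving the 20 candidate
#' parameter pairs.
#'
#' @param window_bp Clumping window radius passed to every pair.
#' @return List of 20 [selection_params()].
#' @export
selection_grid <- function(window_bp = 250000L) {
  ps <- c(5e-3, 5e-4, 5e-5, 5e-6)
  r2s <- c(0.2, 0.4, 0.6, 0.8, NA)
  grid <- expand.grid(p = ps, r2 = r2s, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    selection_params(grid$p[i], grid$r2[i], window_bp)
  })
}

#' Genotypic r-squared between two variants
#'
#' Squared Pearson correlation of the two alt-count vectors over
#' complete-case samples. Undefined (returned as `NA` with a warning) when
#' fewer than two complete cases remain or either variant is monomorphic
#' among them; callers treat that as `r^2 = 0`.
#'
#' @param panel A `genotype_dataset` (the LD reference panel).
#' @param i,j Variant indices or ids.
#' @return `r^2` in `[0, 1]`, or `NA` when undefined.
#' @export
compute_r2 <- function(panel, i, j) {
  if (is.character(i)) i <- match(i, panel$variants$id)
  if (is.character(j)) j <- match(j, panel$variants$id)
  x <- panel$alt_counts[, i]
  y <- panel$alt_counts[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) {
    warning("fewer than 2 complete cases; r2 undefined")
    return(NA_real_)
  }
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("monomorphic variant among complete cases; r2 undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' LD clumping
#'
#' Greedy procedure: restrict the summary statistics to
#' `p <= p_threshold` and to variants present in the panel; process SNPs in
#' ascending p (ties by chromosome, position, then id); each still-unassigned
#' SNP becomes an index SNP and absorbs every unassigned SNP on the same
#' chromosome within `window_bp` of it whose panel `r^2` with it is at least
#' `r2_threshold`. With `r2_threshold = NA` clumping is skipped entirely and
#' all p-passing SNPs are returned. Monomorphic panel variants never absorb
#' nor get absorbed (undefined `r^2` counts as 0).
#'
#' @param stats A `summary_stats` table.
#' @param panel A `genotype_dataset` LD reference panel.
#' @param params A [selection_params()].
#' @return An object of class `selection_result`: `selected_ids` ordered by
#'   `(chrom, pos)`, the `params`, and `clumps` (named list mapping each
#'   index SNP to the ids it absorbed).
#' @export
ld_clump <- function(stats, panel, params) {
  stopifnot(inherits(params, "selection_params"))
  cand <- stats[stats$p_value <= params$p_threshold &
                  stats$id %in% panel$variants$id, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no SNPs selected at ", format(params))
  }
  if (is.na(params$r2_threshold)) {
    ord <- order(cand$chrom, cand$pos, cand$id)
    sel <- cand$id[ord]
    clumps <- stats::setNames(replicate(length(sel), character(0),
                                        simplify = FALSE), sel)
    return(structure(list(selected_ids = sel, params = params,
                          clumps = clumps),
                     class = "selection_result"))
  }
  ord <- order(cand$p_value, cand$chrom, cand$pos, cand$id)
  cand <- cand[ord, ]
  panel_idx <- match(cand$id, panel$variants$id)
  g <- panel$alt_counts[, panel_idx, drop = FALSE]
  assigned <- rep(FALSE, nrow(cand))
  clumps <- list()
  index_snps <- character(0)
  for (k in seq_len(nrow(cand))) {
    if (assigned[k]) next
    assigned[k] <- TRUE
    index_snps <- c(index_snps, cand$id[k])
    near <- which(!assigned & cand$chrom == cand$chrom[k] &
                    abs(cand$pos - cand$pos[k]) <= params$window_bp)
    members <- character(0)
    if (length(near) > 0) {
      r <- suppressWarnings(
        stats::cor(g[, k], g[, near, drop = FALSE],
                   use = "pairwise.complete.obs")
      )
      r2 <- as.numeric(r)^2
      r2[is.na(r2)] <- 0  # monomorphic / too few complete cases
      absorb <- near[r2 >= params$r2_threshold]
      if (length(absorb) > 0) {
        assigned[absorb] <- TRUE
        members <- cand$id[absorb]
      }
    }
    clumps[[cand$id[k]]] <- members
  }
  keep <- match(index_snps, cand$id)
  out_ord <- order(cand$chrom[keep], cand$pos[keep], cand$id[keep])
  structure(list(selected_ids = index_snps[out_ord], params = params,
                 clumps = clumps[index_snps[out_ord]]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$selected_ids), "SNP(s) at",
      format(x$params), "\n")
  invisible(x)
}

#' Grid search over selection parameters
#'
#' Runs [ld_clump()] for every parameter pair, trains one candidate score
#' per pair via `train_fn`, and scores each candidate by AUC. By default the
#' training data is split (stratified) into an internal fit/validation pair
#' and candidates are compared on the held-out part; `select_by = "train"`
#' restores comparison on in-sample fit.
#'
#' @param stats A `summary_stats` table.
#' @param panel LD reference panel (`genotype_dataset`).
#' @param cohort_train Labelled training `genotype_dataset`.
#' @param grid List of [selection_params()] (default [selection_grid()]).
#' @param train_fn Callback `function(selection, fit_ds, eval_ds, seed)`
#'   returning a numeric score vector for `eval_ds`'s samples.
#' @param select_by `"validation"` (default) or `"train"`.
#' @param val_fraction Fraction of `cohort_train` held out for validation.
#' @param seed Integer seed controlling the split and `train_fn`.
#' @return List with `best_params`, `best_auc`, and `table` (one row per
#'   grid entry: p_threshold, r2_threshold, n_selected, auc; parameter pairs
#'   selecting zero SNPs get `NA` metrics and are excluded from the argmax).
#' @export
grid_search <- function(stats, panel, cohort_train, grid = selection_grid(),
                        train_fn, select_by = c("validation", "train"),
                        val_fraction = 0.2, seed = 1) {
  select_by <- match.arg(select_by)
  stopifnot(length(grid) > 0)
  if (is.null(cohort_train$phenotype)) stop("cohort_train must be labelled")
  set.seed(seed)
  if (select_by == "validation") {
    val_idx <- stratified_holdout(cohort_train$phenotype, val_fraction)
    fit_ds <- cohort_train[-val_idx, ]
    eval_ds <- cohort_train[val_idx, ]
  } else {
    fit_ds <- cohort_train
    eval_ds <- cohort_train
  }
  rows <- lapply(seq_along(grid), function(i) {
    par <- grid[[i]]
    sel <- tryCatch(ld_clump(stats, panel, par), error = function(e) NULL)
    if (is.null(sel)) {
      return(data.frame(p_threshold = par$p_threshold,
                        r2_threshold = par$r2_threshold,
                        n_selected = 0L, auc = NA_real_))
    }
    scores <- train_fn(sel, fit_ds, eval_ds, seed)
    data.frame(p_threshold = par$p_threshold,
               r2_threshold = par$r2_threshold,
               n_selected = length(sel$selected_ids),
               auc = auc(scores, eval_ds$phenotype))
  })
  table <- do.call(rbind, rows)
  if (all(is.na(table$auc))) stop("every grid entry selected zero SNPs")
  best <- which.max(table$auc)
  list(best_params = grid[[best]], best_auc = table$auc[best], table = table)
}

#' Stratified holdout indices
#'
#' Samples `fraction` of each class (at least one per class) without
#' replacement; used for internal validation splits.
#'
#' @param y Binary labels.
#' @param fraction Holdout fraction in (0, 1).
#' @return Integer indices of the holdout set.
#' @export
stratified_holdout <- function(y, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  idx <- lapply(split(seq_along(y), y), function(ix) {
    k <- max(1L, round(length(ix) * fraction))
    sample(ix, k)
  })
  sort(unlist(idx, use.names = FALSE))
}
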
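# Independent brute-force oracles used to pin the vectorized implementations.

# all-pairs AUC: count case/control pairs where the case outscores (ties 0.5)
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    for (b in ctrls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(ctrls))
}

# direct 2x2 odds ratio from an explicitly constructed contingency table
oracle_odds_ratio <- function(scores, labels, top_fraction) {
  n <- length(scores)
  k <- ceiling(top_fraction * n)
  ord <- order(-scores, seq_len(n))
  in_top <- seq_len(n) %in% ord[1:k]
  tab <- table(factor(in_top, levels = c(TRUE, FALSE)),
               factor(labels, levels = c(1, 0)))
  TD <- tab[1, 1]; TE <- tab[1, 2]; RD <- tab[2, 1]; RE <- tab[2, 2]
  if (TE == 0 || RD == 0) Inf else (TD * RE) / (TE * RD)
}

# largest fraction at >= fold risk by looping the public odds_ratio
oracle_prop_at_fold <- function(scores, labels, fold) {
  n <- length(scores)
  best <- 0
  for (k in seq_len(n - 1)) {
    or <- odds_ratio(scores, labels, k / n)$or
    if (or >= fold) best <- k / n
  }
  best
}

# greedy LD clumping re-derived directly from a precomputed r2 matrix,
# written with explicit loops (no shared code with ld_clump)
oracle_clump <- function(stats, panel, params) {
  keep <- stats$p_value <= params$p_threshold & stats$id %in% panel$variants$id
  cand <- as.data.frame(stats)[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  if (is.na(params$r2_threshold)) {
    return(cand$id[order(cand$chrom, cand$pos, cand$id)])
  }
  g <- panel$alt_counts[, match(cand$id, panel$variants$id), drop = FALSE]
  r2 <- matrix(0, nrow(cand), nrow(cand))
  for (a in seq_len(nrow(cand))) {
    for (b in seq_len(nrow(cand))) {
      x <- g[, a]; y <- g[, b]
      ok <- !is.na(x) & !is.na(y)
      r2[a, b] <- if (sum(ok) >= 2 && var(x[ok]) > 0 && var(y[ok]) > 0) {
        cor(x[ok], y[ok])^2
      } else 0
    }
  }
  ord <- order(cand$p_value, cand$chrom, cand$pos, cand$id)
  assigned <- rep(FALSE, nrow(cand))
  index_snps <- integer(0)
  for (a in ord) {
    if (assigned[a]) next
    assigned[a] <- TRUE
    index_snps <- c(index_snps, a)
    for (b in ord) {
      if (assigned[b]) next
      if (cand$chrom[b] == cand$chrom[a] &&
          abs(cand$pos[b] - cand$pos[a]) <= params$window_bp &&
          r2[a, b] >= params$r2_threshold) {
        assigned[b] <- TRUE
      }
    }
  }
  sel <- cand[index_snps, ]
  sel$id[order(sel$chrom, sel$pos, sel$id)]
}

# per-individual risk-SNP tally by explicit loops
oracle_risk_counts <- function(geno, stats, p_risk = 5e-8) {
  risk <- stats$id[stats$p_value < p_risk & stats$beta > 0]
  counts <- integer(n_samples(geno))
  for (i in seq_len(n_samples(geno))) {
    cnt <- 0L
    for (id in risk) {
      j <- match(id, geno$variants$id)
      if (!is.na(j)) {
        a <- geno$alt_counts[i, j]
        if (!is.na(a) && a >= 1L) cnt <- cnt + 1L
      }
    }
    counts[i] <- cnt
  }
  counts
}
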
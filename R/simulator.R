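# Synthetic cohorts with LD structure and planted genetic architecture.
#
# Genotypes are built from thresholded latent Gaussians: each haplotype's
# latent value within an LD block shares a block factor (exchangeable
# correlation `within_block_rho`), and the alt allele is called when the
# latent falls below the per-SNP MAF quantile, which yields Hardy-Weinberg
# genotype frequencies marginally. This is a stylized LD model, not a
# coalescent: it gives direct, reproducible control over block correlation,
# MAF spectra and missingness.

#' Simulation configuration
#'
#' Fixes the marker map shared by every dataset drawn from it: chromosome
#' assignment, physical positions, per-SNP minor-allele frequencies, LD block
#' structure and missing-genotype rate. Per-SNP MAFs and allele labels are
#' drawn once from `seed`, so panels, discovery cohorts and target cohorts
#' simulated from the same config describe the same variants.
#'
#' @param n_snps Total number of SNPs.
#' @param n_genes Total number of genes for [simulate_gene_annotation()].
#' @param n_samples_panel,n_samples_discovery,n_samples_cohort Default sample
#'   sizes for the three dataset roles.
#' @param n_chromosomes SNPs are split evenly over this many autosomes
#'   (ignored when `chrom_assignment` is given).
#' @param chrom_assignment Optional integer vector (length `n_snps`) mapping
#'   each SNP to a chromosome in 1..22.
#' @param ld_block_size Number of consecutive SNPs per LD block.
#' @param within_block_rho Latent exchangeable correlation within a block, in
#'   `[0, 1)`.
#' @param maf_range Per-SNP MAFs are drawn uniformly from this range,
#'   a sub-interval of `(0, 0.5]`.
#' @param missing_rate Probability a genotype is masked missing.
#' @param snp_spacing_bp Physical distance between consecutive SNPs on a
#'   chromosome.
#' @param gene_length_bp Length of each simulated gene.
#' @param orphan_snp_fraction Fraction of each chromosome's SNPs (taken from
#'   its far end) guaranteed to lie more than 250 kb from every simulated
#'   gene, exercising the nearest-gene fallback.
#' @param seed Integer seed fixing the marker map.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 200, n_genes = 40,
                       n_samples_panel = 500, n_samples_discovery = 2000,
                       n_samples_cohort = 2000,
                       n_chromosomes = 4, chrom_assignment = NULL,
                       ld_block_size = 10, within_block_rho = 0.3,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       snp_spacing_bp = 20000, gene_length_bp = 30000,
                       orphan_snp_fraction = 0, seed = 1) {
  stopifnot(n_snps >= 1, n_genes >= 1, ld_block_size >= 1,
            within_block_rho >= 0, within_block_rho < 1,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            orphan_snp_fraction >= 0, orphan_snp_fraction < 1)
  if (is.null(chrom_assignment)) {
    stopifnot(n_chromosomes >= 1, n_chromosomes <= 22)
    chrom_assignment <- sort(rep_len(seq_len(n_chromosomes), n_snps))
  }
  chrom_assignment <- as.integer(chrom_assignment)
  stopifnot(length(chrom_assignment) == n_snps,
            all(chrom_assignment >= 1L & chrom_assignment <= 22L))

  # marker map drawn once, deterministic in `seed`
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                        c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pair_idx <- sample.int(nrow(allele_pairs), n_snps, replace = TRUE)
  pos <- integer(n_snps)
  block <- integer(n_snps)
  next_block <- 1L
  for (c_id in sort(unique(chrom_assignment))) {
    on_c <- which(chrom_assignment == c_id)
    pos[on_c] <- snp_spacing_bp * seq_along(on_c)
    nb <- ceiling(length(on_c) / ld_block_size)
    block[on_c] <- next_block - 1L +
      rep(seq_len(nb), each = ld_block_size)[seq_along(on_c)]
    next_block <- next_block + nb
  }
  variants <- data.frame(
    id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = chrom_assignment, pos = pos,
    ref = allele_pairs[pair_idx, 1], alt = allele_pairs[pair_idx, 2],
    stringsAsFactors = FALSE
  )
  structure(
    list(n_snps = n_snps, n_genes = n_genes,
         n_samples_panel = n_samples_panel,
         n_samples_discovery = n_samples_discovery,
         n_samples_cohort = n_samples_cohort,
         chrom_assignment = chrom_assignment, ld_block_size = ld_block_size,
         within_block_rho = within_block_rho, maf_range = maf_range,
         missing_rate = missing_rate, snp_spacing_bp = snp_spacing_bp,
         gene_length_bp = gene_length_bp,
         orphan_snp_fraction = orphan_snp_fraction, seed = seed,
         maf = maf, block = block, variants = variants),
    class = "sim_config"
  )
}

#' Planted genetic architecture
#'
#' Describes the liability model used by [simulate_phenotype()]:
#' `liability = sum(beta_i * altcount_i) +
#'  sum(w_j * 1[both SNPs of pair j carry >= 1 alt allele]) +
#'  covariate effects + noise`. The joint-carrier indicator is the simplest
#' interaction invisible to additive scores: neither locus needs a marginal
#' additive coefficient for the pair to shift liability.
#'
#' @param additive_idx Integer indices (into the config's SNPs) of additive
#'   causal variants.
#' @param additive_betas Liability-scale effects, one per `additive_idx`.
#' @param epistatic_pairs Two-column integer matrix of interacting SNP pairs.
#' @param epistasis_weights Liability contribution when both loci of a pair
#'   carry at least one alt allele, one per row of `epistatic_pairs`.
#' @param heritability_like_scale Fraction of liability variance explained by
#'   the genetic + covariate signal, in `(0, 1]`; noise variance is scaled to
#'   the realized signal variance accordingly.
#' @param prevalence Case fraction, in `(0, 1)`; the liability threshold is
#'   the `(1 - prevalence)` quantile of the realized liability.
#' @param covariate_effects Optional liability-scale effects of standard
#'   normal covariates (one simulated covariate per effect).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(additive_idx = integer(0),
                              additive_betas = numeric(0),
                              epistatic_pairs = matrix(integer(0), ncol = 2),
                              epistasis_weights = numeric(0),
                              heritability_like_scale = 0.5,
                              prevalence = 0.1,
                              covariate_effects = NULL) {
  epistatic_pairs <- matrix(as.integer(epistatic_pairs), ncol = 2)
  stopifnot(length(additive_idx) == length(additive_betas),
            nrow(epistatic_pairs) == length(epistasis_weights),
            heritability_like_scale > 0, heritability_like_scale <= 1,
            prevalence > 0, prevalence < 1)
  structure(
    list(additive_idx = as.integer(additive_idx),
         additive_betas = as.numeric(additive_betas),
         epistatic_pairs = epistatic_pairs,
         epistasis_weights = as.numeric(epistasis_weights),
         heritability_like_scale = heritability_like_scale,
         prevalence = prevalence,
         covariate_effects = covariate_effects),
    class = "architecture_spec"
  )
}

#' Simulate genotypes with blocked LD
#'
#' Draws `n` samples on the config's marker map. Two latent Gaussian
#' haplotypes are drawn per sample; within an LD block each haplotype's
#' latents share a block factor with correlation `within_block_rho`; the alt
#' allele is called below the per-SNP MAF quantile. Genotypes are then masked
#' missing at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @param n Number of samples.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A [genotype_dataset()] (no phenotype).
#' @export
simulate_genotypes <- function(cfg, n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), n >= 1)
  set.seed(seed)
  counts <- .draw_alt_counts(cfg, n)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(n * cfg$n_snps) < cfg$missing_rate,
                   nrow = n)
    counts[mask] <- NA_integer_
  }
  genotype_dataset(counts, cfg$variants,
                   sample_ids = sprintf("s%06d", seq_len(n)))
}

# complete (unmasked) alt-count matrix; consumes RNG
.draw_alt_counts <- function(cfg, n) {
  m <- cfg$n_snps
  rho <- cfg$within_block_rho
  thresh <- stats::qnorm(cfg$maf)
  counts <- matrix(0L, nrow = n, ncol = m)
  for (hap in 1:2) {
    z <- matrix(stats::rnorm(n * m), nrow = n)
    if (rho > 0) {
      for (b in unique(cfg$block)) {
        cols <- which(cfg$block == b)
        u <- stats::rnorm(n)
        z[, cols] <- sqrt(rho) * u + sqrt(1 - rho) * z[, cols]
      }
    }
    counts <- counts + (sweep(z, 2, thresh, "<"))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a liability-threshold phenotype
#'
#' Computes the planted liability (additive + joint-carrier epistasis +
#' covariates), adds Gaussian noise scaled so the signal explains
#' `heritability_like_scale` of the liability variance, and labels as cases
#' the samples above the realized `(1 - prevalence)` quantile. Missing
#' genotypes contribute 0 to the liability.
#'
#' @param geno A `genotype_dataset`.
#' @param arch An [architecture_spec()]; causal indices refer to the
#'   dataset's variant order.
#' @param seed Integer seed for noise (and covariates, when used).
#' @return List with `phenotype` (0/1), `liability`, and `covariates`
#'   (matrix or `NULL`).
#' @export
simulate_phenotype <- function(geno, arch, seed = 1) {
  stopifnot(inherits(geno, "genotype_dataset"),
            inherits(arch, "architecture_spec"))
  m <- n_variants(geno)
  n <- n_samples(geno)
  idx_all <- c(arch$additive_idx, as.vector(arch$epistatic_pairs))
  if (length(idx_all) > 0 && (min(idx_all) < 1 || max(idx_all) > m)) {
    stop("causal index outside the variant range 1..", m)
  }
  g <- matrix(as.numeric(geno$alt_counts), nrow = n)
  g[is.na(g)] <- 0
  set.seed(seed)
  signal <- numeric(n)
  if (length(arch$additive_idx) > 0) {
    signal <- signal +
      g[, arch$additive_idx, drop = FALSE] %*% arch$additive_betas
  }
  if (nrow(arch$epistatic_pairs) > 0) {
    for (j in seq_len(nrow(arch$epistatic_pairs))) {
      p <- arch$epistatic_pairs[j, ]
      both <- (g[, p[1]] >= 1) & (g[, p[2]] >= 1)
      signal <- signal + arch$epistasis_weights[j] * both
    }
  }
  covariates <- NULL
  if (!is.null(arch$covariate_effects)) {
    k <- length(arch$covariate_effects)
    covariates <- matrix(stats::rnorm(n * k), nrow = n,
                         dimnames = list(NULL, paste0("cov", seq_len(k))))
    signal <- signal + covariates %*% arch$covariate_effects
  }
  signal <- as.numeric(signal)
  h <- arch$heritability_like_scale
  sig_var <- stats::var(signal)
  noise_sd <- if (sig_var > 0) sqrt(sig_var * (1 - h) / h) else 1
  liability <- signal + stats::rnorm(n, sd = noise_sd)
  cutoff <- stats::quantile(liability, 1 - arch$prevalence, names = FALSE)
  list(phenotype = as.integer(liability > cutoff), liability = liability,
       covariates = covariates)
}

#' Simulate a labelled cohort
#'
#' Convenience wrapper: draws complete genotypes, generates the phenotype
#' from them, then masks genotypes missing at the config's rate, so
#' missingness never alters the planted liability.
#'
#' @param cfg A [sim_config()].
#' @param arch An [architecture_spec()].
#' @param n Number of samples (default `cfg$n_samples_cohort`).
#' @param seed Integer seed.
#' @return A [genotype_dataset()] with `phenotype` (and covariates when the
#'   architecture has covariate effects); the realized liability and truth
#'   are attached as attribute `"truth"`.
#' @export
simulate_cohort <- function(cfg, arch, n = cfg$n_samples_cohort, seed = 1) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3)
  set.seed(sub[1])
  counts <- .draw_alt_counts(cfg, n)
  ds <- genotype_dataset(counts, cfg$variants,
                         sample_ids = sprintf("s%06d", seq_len(n)))
  ph <- simulate_phenotype(ds, arch, seed = sub[2])
  if (cfg$missing_rate > 0) {
    set.seed(sub[3])
    mask <- matrix(stats::runif(n * cfg$n_snps) < cfg$missing_rate, nrow = n)
    ds$alt_counts[mask] <- NA_integer_
  }
  ds$phenotype <- ph$phenotype
  ds$covariates <- ph$covariates
  attr(ds, "truth") <- list(architecture = arch, liability = ph$liability)
  ds
}

#' Single-variant discovery GWAS (allelic score test)
#'
#' For each SNP, collapses case/control alt and ref allele counts over
#' complete cases into a 2x2 table; `beta` is the allelic log odds ratio
#' (Haldane 0.5 correction when a cell is empty) and the p-value comes from
#' the 1-df chi-square test on the table. Monomorphic or all-missing SNPs are
#' reported as `beta = 0`, `p_value = 1`.
#'
#' @param geno A `genotype_dataset` with a phenotype.
#' @return A `summary_stats` table aligned to the dataset's variants.
#' @export
run_discovery_gwas <- function(geno) {
  stopifnot(inherits(geno, "genotype_dataset"))
  if (is.null(geno$phenotype)) stop("discovery GWAS needs a phenotype")
  y <- geno$phenotype
  if (length(unique(y)) < 2) stop("discovery GWAS needs both classes")
  g <- geno$alt_counts
  case <- y == 1L
  obs <- !is.na(g)
  alt_case <- colSums(g * case, na.rm = TRUE)
  alt_ctrl <- colSums(g * !case, na.rm = TRUE)
  n_case <- colSums(obs & case)
  n_ctrl <- colSums(obs & !case)
  ref_case <- 2 * n_case - alt_case
  ref_ctrl <- 2 * n_ctrl - alt_ctrl
  alt_tot <- alt_case + alt_ctrl
  ref_tot <- ref_case + ref_ctrl
  mono <- alt_tot == 0 | ref_tot == 0
  if (any(mono)) {
    message(sum(mono), " monomorphic or all-missing SNP(s) set to beta=0, p=1")
  }
  # allelic log OR with Haldane correction for empty cells
  zero_cell <- alt_case == 0 | alt_ctrl == 0 | ref_case == 0 | ref_ctrl == 0
  cc <- ifelse(zero_cell, 0.5, 0)
  beta <- log(((alt_case + cc) * (ref_ctrl + cc)) /
                ((ref_case + cc) * (alt_ctrl + cc)))
  # 1-df chi-square on the 2x2 allele table
  ntot <- alt_tot + ref_tot
  num <- ntot * (alt_case * ref_ctrl - alt_ctrl * ref_case)^2
  den <- alt_tot * ref_tot * (alt_case + ref_case) * (alt_ctrl + ref_ctrl)
  chi2 <- ifelse(den > 0, num / den, 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  beta[mono] <- 0
  p[mono] <- 1
  summary_stats(data.frame(
    id = geno$variants$id, chrom = geno$variants$chrom,
    pos = geno$variants$pos, ref = geno$variants$ref,
    alt = geno$variants$alt, beta = beta, p_value = p,
    stringsAsFactors = FALSE
  ))
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes along each chromosome carrying SNPs, spread
#' over the SNP span so that SNPs fall inside genes, near genes, and — when
#' `orphan_snp_fraction > 0` — beyond 250 kb of every gene (forcing the
#' nearest-gene fallback in connectivity construction). Genes are distributed
#' over chromosomes proportionally to their SNP counts and total `n_genes`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed for gene placement jitter.
#' @return A [gene_annotation()] table.
#' @export
simulate_gene_annotation <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  chroms <- sort(unique(cfg$chrom_assignment))
  snp_per_chrom <- table(factor(cfg$chrom_assignment, levels = chroms))
  # largest-remainder apportionment of n_genes over chromosomes
  quota <- cfg$n_genes * as.numeric(snp_per_chrom) / cfg$n_snps
  n_c <- floor(quota)
  rem <- cfg$n_genes - sum(n_c)
  if (rem > 0) {
    extra <- order(quota - n_c, decreasing = TRUE)[seq_len(rem)]
    n_c[extra] <- n_c[extra] + 1L
  }
  n_c[n_c == 0 & as.numeric(snp_per_chrom) > 0] <- 1L
  rows <- list()
  window <- 250000L
  for (k in seq_along(chroms)) {
    c_id <- chroms[k]
    pos_c <- sort(cfg$variants$pos[cfg$variants$chrom == c_id])
    m_c <- length(pos_c)
    n_orphan <- if (cfg$orphan_snp_fraction > 0) {
      max(1L, ceiling(cfg$orphan_snp_fraction * m_c))
    } else 0L
    covered_end <- if (n_orphan > 0 && n_orphan < m_c) {
      pos_c[m_c - n_orphan + 1L] - window - cfg$gene_length_bp - 1L
    } else {
      pos_c[m_c]
    }
    lo <- max(1L, pos_c[1] - cfg$gene_length_bp)
    hi <- max(lo + cfg$gene_length_bp + 1L, covered_end - cfg$gene_length_bp)
    ng <- n_c[k]
    starts <- round(seq(lo, hi, length.out = ng + 1L)[seq_len(ng)])
    gap <- if (ng > 1) min(diff(starts)) else Inf
    len <- min(cfg$gene_length_bp, max(1L, floor(gap * 0.8)))
    jitter <- if (ng > 0) {
      round(stats::runif(ng, 0, max(0, min(gap - len, len) * 0.2)))
    } else numeric(0)
    starts <- starts + jitter
    rows[[k]] <- data.frame(
      gene_id = sprintf("gene%02d.%03d", c_id, seq_len(ng)),
      chrom = c_id, start = as.integer(starts),
      end = as.integer(starts + len - 1L), stringsAsFactors = FALSE
    )
  }
  gene_annotation(do.call(rbind, rows))
}
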
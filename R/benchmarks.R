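# Synthetic evaluation benchmarks. Each benchmark fixes a study condition
# once — marker map, sample sizes, planted architecture — and replicates it
# across seeds; methods are compared on held-out test AUC after running the
# same selection + scoring pipeline per replicate.
#
# Shared conditions: 200 SNPs on 4 chromosomes (50 each, 20 kb spacing,
# LD blocks of 10 SNPs with latent correlation 0.3), MAF 0.2-0.4, 2%
# missing genotypes, 40 genes, reference panel of 500, discovery GWAS and
# target cohort of 4000 each (70/30 train/test split), prevalence 0.2.

.bench_sim_config <- function(seed) {
  sim_config(n_snps = 200, n_genes = 40, n_chromosomes = 4,
             n_samples_panel = 500, n_samples_discovery = 4000,
             n_samples_cohort = 4000, ld_block_size = 10,
             within_block_rho = 0.3, maf_range = c(0.2, 0.4),
             missing_rate = 0.02, snp_spacing_bp = 20000,
             gene_length_bp = 30000, seed = seed)
}

#' Benchmark architectures
#'
#' Three planted architectures over the shared benchmark marker map:
#' \describe{
#'   \item{epistatic}{5 joint-carrier SNP pairs (both partners on the same
#'     chromosome, 560-600 kb apart so they wire to disjoint genes), zero
#'     additive coefficients, signal explaining 70% of liability variance.
#'     The pairs induce marginal associations — so the discovery GWAS finds
#'     the loci — but roughly a third of their liability variance is pure
#'     interaction that no additive score can capture.}
#'   \item{additive}{30 additive SNPs with effects of alternating sign and
#'     equal magnitude 0.3, signal explaining 50% of liability variance.}
#'   \item{robustness}{60 additive SNPs with geometrically decaying
#'     magnitudes (0.4 * 0.93^j, alternating sign), signal explaining 60%
#'     of liability variance, so the top GWAS hits carry most of the signal
#'     and sequential removal degrades every method.}
#' }
#'
#' @param benchmark One of `"epistatic"`, `"additive"`, `"robustness"`.
#' @return An [architecture_spec()].
#' @export
benchmark_architecture <- function(benchmark = c("epistatic", "additive",
                                                 "robustness")) {
  benchmark <- match.arg(benchmark)
  switch(benchmark,
    epistatic = architecture_spec(
      epistatic_pairs = cbind(c(10L, 62L, 108L, 165L, 20L),
                              c(40L, 92L, 138L, 195L, 48L)),
      epistasis_weights = rep(1, 5),
      heritability_like_scale = 0.7, prevalence = 0.2
    ),
    additive = architecture_spec(
      additive_idx = round(seq(4, 197, length.out = 30)),
      additive_betas = 0.3 * rep_len(c(1, -1), 30),
      heritability_like_scale = 0.5, prevalence = 0.2
    ),
    robustness = architecture_spec(
      additive_idx = round(seq(2, 199, length.out = 60)),
      additive_betas = 0.4 * 0.93^(0:59) * rep_len(c(1, -1), 60),
      heritability_like_scale = 0.6, prevalence = 0.2
    )
  )
}

#' Simulate one benchmark replicate
#'
#' Draws the LD reference panel, the discovery cohort (reduced to GWAS
#' summary statistics), the target cohort split 70/30 into train/test, and
#' the gene annotation, all deterministic in `seed`.
#'
#' @param benchmark Benchmark name (see [benchmark_architecture()]).
#' @param seed Integer replicate seed.
#' @return List: `panel`, `stats`, `train`, `test`, `genes`, `arch`, `cfg`.
#' @export
simulate_benchmark <- function(benchmark = "epistatic", seed = 1) {
  arch <- benchmark_architecture(benchmark)
  cfg <- .bench_sim_config(seed)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4)
  panel <- simulate_genotypes(cfg, cfg$n_samples_panel, seed = sub[1])
  discovery <- simulate_cohort(cfg, arch, cfg$n_samples_discovery,
                               seed = sub[2])
  stats <- run_discovery_gwas(discovery)
  cohort <- simulate_cohort(cfg, arch, cfg$n_samples_cohort, seed = sub[3])
  parts <- split_cohort(cohort, test_fraction = 0.3, seed = sub[4])
  list(panel = panel, stats = stats, train = parts$train,
       test = parts$test, genes = simulate_gene_annotation(cfg),
       arch = arch, cfg = cfg)
}

#' Run a method-comparison benchmark
#'
#' For each seed, simulates a replicate, selects SNPs once (p <= 5e-4,
#' r2 >= 0.2 against the panel), fits every requested method/variant on the
#' training split and records its test AUC.
#'
#' @param benchmark Benchmark name (see [benchmark_architecture()]).
#' @param seeds Integer vector of replicate seeds.
#' @param methods Subset of `"deeprisk"`, `"pt"`, `"lasso"`.
#' @param variants Deep-model variants to run (crossed with the
#'   `"deeprisk"` method only).
#' @param model_cfg Base [model_config()] for the deep model.
#' @param params [selection_params()] applied to every replicate.
#' @param keep_scores Also return per-replicate test scores/labels?
#' @return `data.frame` (seed, method, variant, n_selected, auc); with
#'   `keep_scores`, score vectors are attached as attribute `"scores"`.
#' @export
run_benchmark <- function(benchmark = "epistatic", seeds = 1:5,
                          methods = c("deeprisk", "pt", "lasso"),
                          variants = "full", model_cfg = model_config(),
                          params = selection_params(5e-4, 0.2),
                          keep_scores = FALSE) {
  rows <- list()
  scores_kept <- list()
  for (seed in seeds) {
    rep <- simulate_benchmark(benchmark, seed)
    sel <- ld_clump(rep$stats, rep$panel, params)
    for (m in methods) {
      vset <- if (m == "deeprisk") variants else "-"
      for (v in vset) {
        cfg_v <- model_cfg
        if (m == "deeprisk") cfg_v$variant <- v
        s <- fit_and_score(m, sel, rep$train, rep$test, stats = rep$stats,
                           genes = rep$genes, model_cfg = cfg_v, seed = seed)
        tag <- if (m == "deeprisk") paste0(m, ":", v) else m
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, method = m, variant = v,
          n_selected = length(sel$selected_ids),
          auc = auc(s, rep$test$phenotype))
        if (keep_scores) {
          scores_kept[[paste(seed, tag, sep = "/")]] <-
            list(scores = s, labels = rep$test$phenotype)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_scores) attr(out, "scores") <- scores_kept
  out
}
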
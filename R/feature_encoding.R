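# Genotype encoding and the SNP -> gene connectivity map that defines the
# partial-connection layer.

#' Encode genotypes
#'
#' `two_dim` encoding represents each genotype as (ref-allele count,
#' alt-allele count): 0 -> (2,0), 1 -> (1,1), 2 -> (0,2), and missing ->
#' (0,0), so the two dimensions sum to 2 for observed genotypes and 0 for
#' missing ones. `additive` encoding is the traditional single dimension of
#' alt-allele counts with missing set to 0 (used by the additive-encoding
#' ablation and the linear baselines).
#'
#' @param geno A `genotype_dataset`.
#' @param snp_ids Variant ids to encode, in model order; a
#'   `selection_result` is also accepted. Default: all variants.
#' @param mode `"two_dim"` or `"additive"`.
#' @return Numeric array `[n_samples x n_snps x d]` (`d` = 2 or 1) of class
#'   `encoded_genotypes`, with attributes `snp_ids` and `mode`.
#' @export
encode_genotypes <- function(geno, snp_ids = NULL,
                             mode = c("two_dim", "additive")) {
  mode <- match.arg(mode)
  if (inherits(snp_ids, "selection_result")) snp_ids <- snp_ids$selected_ids
  if (is.null(snp_ids)) snp_ids <- geno$variants$id
  j <- match(snp_ids, geno$variants$id)
  if (anyNA(j)) {
    stop("dataset lacks variant(s): ",
         paste(utils::head(snp_ids[is.na(j)], 5), collapse = ", "))
  }
  counts <- geno$alt_counts[, j, drop = FALSE]
  n <- nrow(counts)
  m <- ncol(counts)
  if (mode == "two_dim") {
    alt <- ifelse(is.na(counts), 0, counts)
    ref <- ifelse(is.na(counts), 0, 2 - counts)
    x <- array(0, dim = c(n, m, 2))
    x[, , 1] <- ref
    x[, , 2] <- alt
  } else {
    x <- array(0, dim = c(n, m, 1))
    x[, , 1] <- ifelse(is.na(counts), 0, counts)
  }
  structure(x, snp_ids = snp_ids, mode = mode, class = "encoded_genotypes")
}

#' Build the SNP-to-gene connectivity map
#'
#' A SNP connects to every gene whose interval, extended by `window_bp`
#' upstream and downstream, contains the SNP's position. A SNP with no gene
#' within the window instead gets a single fallback edge to its nearest gene
#' on the chromosome (distance to the closer interval end, 0 inside;
#' equidistant ties broken by the lexicographically smaller gene id). Genes
#' that end up with no connected SNP are dropped, so the per-chromosome gene
#' sequence consists of SNP-bearing genes ordered by start position.
#'
#' @param snp_ids Variant ids to wire (model order); a `selection_result` is
#'   accepted.
#' @param variants Variant metadata `data.frame` (`id`, `chrom`, `pos`) or a
#'   `genotype_dataset`.
#' @param genes A [gene_annotation()] table.
#' @param window_bp Window radius in bp (default 250 kb).
#' @return An object of class `connectivity_map`: per chromosome, the SNP
#'   ids (ordered by position), the retained genes (ordered by start), and
#'   the logical incidence matrix `[n_snps_c x n_genes_c]`.
#' @export
build_connectivity <- function(snp_ids, variants, genes,
                               window_bp = 250000L) {
  if (inherits(snp_ids, "selection_result")) snp_ids <- snp_ids$selected_ids
  if (inherits(variants, "genotype_dataset")) variants <- variants$variants
  j <- match(snp_ids, variants$id)
  if (anyNA(j)) {
    stop("variant metadata lacks id(s): ",
         paste(utils::head(snp_ids[is.na(j)], 5), collapse = ", "))
  }
  vt <- variants[j, c("id", "chrom", "pos")]
  chroms <- sort(unique(vt$chrom))
  per_chrom <- list()
  for (c_id in chroms) {
    snps_c <- vt[vt$chrom == c_id, , drop = FALSE]
    snps_c <- snps_c[order(snps_c$pos, snps_c$id), , drop = FALSE]
    genes_c <- genes[genes$chrom == c_id, , drop = FALSE]
    if (nrow(genes_c) == 0) {
      stop("chromosome ", c_id, " carries selected SNPs but no genes; ",
           "extend the gene annotation")
    }
    genes_c <- genes_c[order(genes_c$start, genes_c$gene_id), , drop = FALSE]
    m_c <- nrow(snps_c)
    l_c <- nrow(genes_c)
    inc <- outer(snps_c$pos, genes_c$start - window_bp, ">=") &
      outer(snps_c$pos, genes_c$end + window_bp, "<=")
    orphan <- which(rowSums(inc) == 0)
    for (s in orphan) {
      d <- pmin(abs(snps_c$pos[s] - genes_c$start),
                abs(snps_c$pos[s] - genes_c$end))
      inside <- snps_c$pos[s] >= genes_c$start & snps_c$pos[s] <= genes_c$end
      d[inside] <- 0
      best <- which(d == min(d))
      if (length(best) > 1) {
        best <- best[order(genes_c$gene_id[best])][1]
        message("nearest-gene tie for SNP ", snps_c$id[s],
                " broken by gene id")
      }
      inc[s, best] <- TRUE
    }
    keep_genes <- colSums(inc) > 0
    genes_c <- genes_c[keep_genes, , drop = FALSE]
    inc <- inc[, keep_genes, drop = FALSE]
    rownames(inc) <- snps_c$id
    colnames(inc) <- genes_c$gene_id
    per_chrom[[as.character(c_id)]] <- list(
      chrom = c_id, snp_ids = snps_c$id, pos = snps_c$pos,
      genes = genes_c, incidence = inc
    )
  }
  structure(list(chromosomes = per_chrom, window_bp = as.integer(window_bp),
                 snp_ids = unlist(lapply(per_chrom, `[[`, "snp_ids"),
                                  use.names = FALSE)),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  n_genes <- sum(vapply(x$chromosomes, function(ch) nrow(ch$genes), 0L))
  n_edges <- sum(vapply(x$chromosomes, function(ch) sum(ch$incidence), 0L))
  cat("connectivity_map:", length(x$snp_ids), "SNPs ->", n_genes,
      "genes (", n_edges, "edges ) on", length(x$chromosomes),
      "chromosome(s)\n")
  invisible(x)
}

#' Edge list of a connectivity map
#'
#' @param x A `connectivity_map`.
#' @param ... Unused.
#' @return `data.frame` with columns `snp_id`, `gene_id`, `chrom`, ordered
#'   by chromosome, SNP position, gene start.
#' @export
as.data.frame.connectivity_map <- function(x, ...) {
  rows <- lapply(x$chromosomes, function(ch) {
    w <- which(ch$incidence, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    data.frame(snp_id = ch$snp_ids[w[, 1]],
               gene_id = ch$genes$gene_id[w[, 2]],
               chrom = ch$chrom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a connectivity map as a TSV edge list
#' @param x A `connectivity_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
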
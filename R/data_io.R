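# In-memory data model and readers/writers for the external formats.
#
# The central container is the `genotype_dataset`: a sample x variant matrix of
# alternative-allele counts (0/1/2, NA = missing) plus variant metadata,
# optional binary phenotype and optional numeric covariates. All coordinates
# are 1-based inclusive (VCF convention); BED input is converted at the
# boundary.

#' Construct a genotype dataset
#'
#' Bundles an alternative-allele count matrix with its variant metadata,
#' sample identifiers, and optional phenotype/covariates. Entries of
#' `alt_counts` must be 0, 1, 2 or `NA` (missing genotype). Variants are
#' stored sorted by `(chrom, pos)`.
#'
#' @param alt_counts Integer matrix `[n_samples x n_variants]` with entries in
#'   `{0, 1, 2, NA}`.
#' @param variants `data.frame` with columns `id`, `chrom` (integer 1-22),
#'   `pos` (1-based bp), `ref`, `alt` (single characters), one row per column
#'   of `alt_counts`, in column order.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `alt_counts`.
#' @param phenotype Optional binary (0/1) vector of length `n_samples`.
#' @param covariates Optional numeric matrix `[n_samples x n_covariates]`
#'   with column names.
#' @param drop_ambiguous Drop variants whose alleles form a strand-ambiguous
#'   pair (A/T or C/G)?
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(alt_counts, variants, sample_ids,
                             phenotype = NULL, covariates = NULL,
                             drop_ambiguous = FALSE) {
  alt_counts <- as.matrix(alt_counts)
  storage.mode(alt_counts) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  variants$chrom <- as.integer(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(variants) != ncol(alt_counts)) {
    stop("variants rows (", nrow(variants), ") != alt_counts columns (",
         ncol(alt_counts), ")")
  }
  if (length(sample_ids) != nrow(alt_counts)) {
    stop("sample_ids length != alt_counts rows")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant ids: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  }
  bad <- !(alt_counts %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("alt_counts entries must be 0, 1, 2 or NA")
  if (any(variants$chrom < 1L | variants$chrom > 22L, na.rm = TRUE) ||
      anyNA(variants$chrom)) {
    stop("chrom must be an autosome in 1..22")
  }
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (drop_ambiguous) {
    amb <- is_ambiguous_pair(variants$ref, variants$alt)
    if (any(amb)) {
      message("dropping ", sum(amb), " strand-ambiguous variant(s)")
      variants <- variants[!amb, , drop = FALSE]
      alt_counts <- alt_counts[, !amb, drop = FALSE]
    }
  }
  ord <- order(variants$chrom, variants$pos, variants$id)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  alt_counts <- alt_counts[, ord, drop = FALSE]
  dimnames(alt_counts) <- list(sample_ids, variants$id)
  if (!is.null(phenotype)) {
    phenotype <- as.integer(phenotype)
    if (length(phenotype) != nrow(alt_counts)) stop("phenotype length mismatch")
    if (!all(phenotype %in% c(0L, 1L))) stop("phenotype must be binary 0/1")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(alt_counts)) stop("covariates rows mismatch")
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
  }
  structure(
    list(alt_counts = alt_counts, variants = variants,
         sample_ids = as.character(sample_ids),
         phenotype = phenotype, covariates = covariates),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$alt_counts), "samples x",
      ncol(x$alt_counts), "variants on chromosome(s)",
      paste(sort(unique(x$variants$chrom)), collapse = ","), "\n")
  miss <- mean(is.na(x$alt_counts))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  if (!is.null(x$phenotype)) {
    cat("  phenotype: ", sum(x$phenotype), "/", length(x$phenotype),
        " cases\n", sep = "")
  }
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples / variants in a genotype dataset
#' @param ds A `genotype_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$alt_counts)

#' @rdname n_samples
#' @export
n_variants <- function(ds) ncol(ds$alt_counts)

#' Subset a genotype dataset
#'
#' @param x A `genotype_dataset`.
#' @param i Sample index (integer/logical) or sample ids.
#' @param j Variant index (integer/logical) or variant ids.
#' @param ... Unused.
#' @return A `genotype_dataset` restricted to the requested samples/variants.
#' @export
`[.genotype_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_variants(x))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$variants$id)
  if (anyNA(i)) stop("unknown sample id(s)")
  if (anyNA(j)) stop("unknown variant id(s)")
  genotype_dataset(
    alt_counts = x$alt_counts[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    sample_ids = x$sample_ids[i],
    phenotype = if (!is.null(x$phenotype)) x$phenotype[i],
    covariates = if (!is.null(x$covariates)) x$covariates[i, , drop = FALSE]
  )
}

#' Is an allele pair strand-ambiguous (A/T or C/G)?
#' @param ref,alt Single-character allele vectors.
#' @return Logical vector.
#' @export
is_ambiguous_pair <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

.parse_chrom <- function(chrom) {
  suppressWarnings(as.integer(sub("^chr", "", as.character(chrom))))
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a diploid VCF into alternative-allele counts.
#' `./.` and `.|.` genotypes become missing (`NA`). Records on non-autosomal
#' contigs are skipped with a message; multi-allelic records are skipped by
#' default.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param phenotype_path Optional phenotype/covariate TSV (see
#'   [read_phenotype_tsv()]) joined to the samples by id.
#' @param multiallelic `"skip"` (default) or `"error"`.
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) variants?
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(path, phenotype_path = NULL,
                     multiallelic = c("skip", "error"),
                     drop_ambiguous = FALSE) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error") {
      stop("multi-allelic record(s) at ",
           paste(head(paste0(fix$CHROM, ":", fix$POS)[multi], 5), collapse = ", "))
    }
    message("skipping ", sum(multi), " multi-allelic record(s)")
  }
  chrom <- .parse_chrom(fix$CHROM)
  non_auto <- is.na(chrom) | chrom < 1L | chrom > 22L
  if (any(non_auto & !multi)) {
    message("skipping ", sum(non_auto & !multi), " non-autosomal record(s)")
  }
  keep <- !multi & !non_auto
  if (!any(keep)) stop("no usable biallelic autosomal records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  chrom <- chrom[keep]
  counts <- .gt_to_counts(gt)
  ids <- fix$ID
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(chrom[blank], ":", fix$POS[blank], ":",
                       fix$REF[blank], ":", fix$ALT[blank])
  ds <- genotype_dataset(
    alt_counts = t(counts),
    variants = data.frame(id = ids, chrom = chrom,
                          pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT,
                          stringsAsFactors = FALSE),
    sample_ids = colnames(gt),
    drop_ambiguous = drop_ambiguous
  )
  if (!is.null(phenotype_path)) ds <- .attach_phenotype(ds, phenotype_path)
  ds
}

# GT strings ("0/1", "1|1", "./.", ".") -> counts, NA for any missing allele
.gt_to_counts <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2 || any(alleles == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a > 1L)) {
      stop("cannot interpret GT '", g, "' as biallelic diploid")
    }
    sum(a)
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with a header: first column `sample_id`, second column
#' `phenotype` (0/1), any further numeric columns are covariates.
#'
#' @param path Path to the TSV.
#' @return List with `sample_id`, `phenotype`, and `covariates` (matrix or
#'   `NULL`).
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("phenotype TSV needs at least sample_id + phenotype")
  names(tab)[1:2] <- c("sample_id", "phenotype")
  phen <- as.integer(tab$phenotype)
  if (!all(phen %in% c(0L, 1L))) stop("phenotype column must be 0/1")
  cov <- NULL
  if (ncol(tab) > 2) {
    cov <- as.matrix(tab[, -(1:2), drop = FALSE])
    storage.mode(cov) <- "double"
  }
  list(sample_id = as.character(tab$sample_id), phenotype = phen,
       covariates = cov)
}

.attach_phenotype <- function(ds, path) {
  ph <- read_phenotype_tsv(path)
  idx <- match(ds$sample_ids, ph$sample_id)
  if (anyNA(idx)) {
    stop("phenotype file lacks sample(s): ",
         paste(head(ds$sample_ids[is.na(idx)], 5), collapse = ", "))
  }
  ds$phenotype <- ph$phenotype[idx]
  if (!is.null(ph$covariates)) {
    ds$covariates <- ph$covariates[idx, , drop = FALSE]
  }
  ds
}

#' Read genotypes from the allele-count TSV dialect
#'
#' Tab-separated with a header of variant ids; first column holds sample ids;
#' cells are alternative-allele counts in `{0, 1, 2, NA}`. Variant metadata
#' comes from a companion variants TSV (columns `id`, `chrom`, `pos`, `ref`,
#' `alt`); when absent, variant ids of the form `chrom:pos:ref:alt` are
#' parsed instead.
#'
#' @param path Path to the counts TSV.
#' @param variants_path Optional companion variant metadata TSV. Defaults to
#'   `<path minus .tsv>_variants.tsv` when that file exists.
#' @param phenotype_path Optional phenotype TSV (see [read_phenotype_tsv()]).
#' @param drop_ambiguous Drop strand-ambiguous variants?
#' @return A [genotype_dataset()].
#' @export
read_genotype_tsv <- function(path, variants_path = NULL,
                              phenotype_path = NULL, drop_ambiguous = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("genotype TSV needs sample id column + variants")
  sample_ids <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  ok <- cells %in% c("0", "1", "2", "NA") | is.na(cells)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid genotype cell '", cells[bad[1], bad[2]], "' at row ",
         bad[1], ", column '", colnames(cells)[bad[2]], "'")
  }
  counts <- matrix(suppressWarnings(as.integer(cells)), nrow = nrow(cells),
                   dimnames = list(sample_ids, colnames(cells)))
  if (is.null(variants_path)) {
    default <- sub("\\.tsv$", "_variants.tsv", path)
    if (file.exists(default)) variants_path <- default
  }
  ids <- colnames(counts)
  if (!is.null(variants_path)) {
    meta <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
    idx <- match(ids, meta$id)
    if (anyNA(idx)) {
      stop("variants file lacks id(s): ",
           paste(head(ids[is.na(idx)], 5), collapse = ", "))
    }
    variants <- meta[idx, c("id", "chrom", "pos", "ref", "alt")]
  } else {
    parts <- strsplit(ids, ":", fixed = TRUE)
    if (any(lengths(parts) != 4)) {
      stop("variant ids are not chrom:pos:ref:alt; supply variants_path")
    }
    parts <- do.call(rbind, parts)
    variants <- data.frame(id = ids, chrom = as.integer(parts[, 1]),
                           pos = as.integer(parts[, 2]), ref = parts[, 3],
                           alt = parts[, 4], stringsAsFactors = FALSE)
  }
  ds <- genotype_dataset(counts, variants, sample_ids,
                         drop_ambiguous = drop_ambiguous)
  if (!is.null(phenotype_path)) ds <- .attach_phenotype(ds, phenotype_path)
  ds
}

#' Write a genotype dataset to the allele-count TSV dialect
#'
#' Emits the counts TSV plus a companion variants TSV, and optionally a
#' phenotype TSV. Missing genotypes are written as `NA`.
#'
#' @param ds A `genotype_dataset`.
#' @param path Output counts TSV path.
#' @param variants_path Companion metadata path; default derives
#'   `<path minus .tsv>_variants.tsv`.
#' @param phenotype_path Optional output path for phenotype + covariates.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(ds, path,
                               variants_path = sub("\\.tsv$", "_variants.tsv", path),
                               phenotype_path = NULL) {
  tab <- data.frame(sample_id = ds$sample_ids, ds$alt_counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$variants, variants_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(phenotype_path)) {
    if (is.null(ds$phenotype)) stop("dataset has no phenotype to write")
    ph <- data.frame(sample_id = ds$sample_ids, phenotype = ds$phenotype)
    if (!is.null(ds$covariates)) ph <- cbind(ph, ds$covariates)
    utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Tab-separated with header columns `id`, `chrom`, `pos`, `ref`, `alt`,
#' `beta` (log-odds per alt allele) and `p_value`.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `summary_stats`.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  summary_stats(tab)
}

#' Validate a summary-statistics table
#'
#' @param tab `data.frame` with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `beta`, `p_value`.
#' @return The validated table, class `summary_stats`.
#' @export
summary_stats <- function(tab) {
  required <- c("id", "chrom", "pos", "ref", "alt", "beta", "p_value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("summary stats lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- as.data.frame(tab)[, required]
  tab$chrom <- as.integer(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab$beta <- as.numeric(tab$beta)
  tab$p_value <- as.numeric(tab$p_value)
  if (anyDuplicated(tab$id)) {
    stop("duplicate variant id(s) in summary stats: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  if (anyNA(tab$p_value) || any(tab$p_value <= 0 | tab$p_value > 1)) {
    stop("p_value must lie in (0, 1]")
  }
  if (anyNA(tab$beta) || any(!is.finite(tab$beta))) {
    stop("beta must be finite")
  }
  rownames(tab) <- NULL
  class(tab) <- c("summary_stats", "data.frame")
  tab
}

#' Write summary statistics
#' @param stats A `summary_stats` table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from BED
#'
#' BED is 0-based half-open; coordinates are converted to 1-based inclusive
#' internally. The BED `name` column supplies gene ids. Non-autosomal
#' intervals are dropped with a message.
#'
#' @param path Path to a BED4+ file.
#' @return `data.frame` of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end`, sorted by `(chrom, start)`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- .parse_chrom(as.character(GenomicRanges::seqnames(gr)))
  keep <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  if (any(!keep)) message("dropping ", sum(!keep), " non-autosomal interval(s)")
  gr <- gr[keep]
  chrom <- chrom[keep]
  ids <- gr$name
  if (is.null(ids) || anyNA(ids)) stop("BED needs a name column with gene ids")
  gene_annotation(data.frame(
    gene_id = ids, chrom = chrom,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ))
}

#' Validate a gene annotation table
#'
#' @param tab `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return The validated table, class `gene_annotation`, sorted by
#'   `(chrom, start)`.
#' @export
gene_annotation <- function(tab) {
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("gene annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- as.data.frame(tab)[, required]
  tab$chrom <- as.integer(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  if (any(tab$start > tab$end)) stop("gene start > end")
  if (any(tab$start < 1L)) stop("gene start must be >= 1 (1-based)")
  tab <- tab[order(tab$chrom, tab$start, tab$gene_id), ]
  rownames(tab) <- NULL
  class(tab) <- c("gene_annotation", "data.frame")
  tab
}

#' Write a gene annotation to BED
#'
#' Converts the internal 1-based inclusive intervals back to 0-based
#' half-open BED.
#'
#' @param genes A `gene_annotation` table.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    name = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Harmonize genotype alleles to summary-statistics effect alleles
#'
#' Variants are matched by id. Where the dataset's ref/alt are swapped
#' relative to the summary statistics, alternative-allele counts are flipped
#' (`2 - count`, missing stays missing) and the dataset's alleles updated so
#' that `beta` applies to the counted allele; the number of flips is
#' reported. Variants whose allele pair cannot be reconciled are left
#' untouched with a warning.
#'
#' @param ds A `genotype_dataset`.
#' @param stats A `summary_stats` table.
#' @return List with the harmonized `dataset` and `n_flipped`.
#' @export
harmonize_alleles <- function(ds, stats) {
  idx <- match(ds$variants$id, stats$id)
  shared <- which(!is.na(idx))
  s <- stats[idx[shared], ]
  same <- ds$variants$ref[shared] == s$ref & ds$variants$alt[shared] == s$alt
  swapped <- ds$variants$ref[shared] == s$alt & ds$variants$alt[shared] == s$ref
  odd <- !same & !swapped
  if (any(odd)) {
    warning(sum(odd), " shared variant(s) with irreconcilable alleles left as-is")
  }
  flip <- shared[swapped]
  if (length(flip) > 0) {
    ds$alt_counts[, flip] <- 2L - ds$alt_counts[, flip]
    old_ref <- ds$variants$ref[flip]
    ds$variants$ref[flip] <- ds$variants$alt[flip]
    ds$variants$alt[flip] <- old_ref
    message("flipped ", length(flip), " variant(s) to the summary-stats alt allele")
  }
  list(dataset = ds, n_flipped = length(flip))
}
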
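#' Construct a genotype matrix object
#'
#' Container for a sample-by-SNP dosage matrix together with per-variant
#' metadata. Dosages count copies of the alternate (A1) allele, so raw calls
#' lie in `{0, 1, 2}` with `NA` marking missing genotypes; after
#' [mean_impute()] columns become real-valued.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns. Row names
#'   are sample ids, column names SNP ids (generated when absent).
#' @param variants Optional data frame with one row per SNP and columns
#'   `snp_id`, `chromosome`, `position`, `allele_ref`, `allele_alt`. Per-SNP
#'   `maf` and `missing_rate` are (re)computed from `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (the matrix) and `variants` (metadata data frame including
#'   `maf` and `missing_rate`).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' g$variants$maf
#' @export
genotype_matrix <- function(dosages, variants = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2)) &
    (dosages < 0 | dosages > 2)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stopf("dosage out of range at sample %d, SNP %d: %s",
          ij[1], ij[2], format(dosages[ij[1], ij[2]]))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("sample%d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp%d", seq_len(ncol(dosages)))
  }
  if (is.null(variants)) {
    variants <- data.frame(
      snp_id = colnames(dosages),
      chromosome = "1",
      position = seq_len(ncol(dosages)),
      allele_ref = "A",
      allele_alt = "B",
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(variants) == ncol(dosages))
  variants$snp_id <- as.character(variants$snp_id)
  variants$maf <- apply(dosages, 2, function(col) {
    if (all(is.na(col))) NA_real_ else compute_maf(col)
  })
  variants$missing_rate <- colMeans(is.na(dosages))
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Minor allele frequency of a dosage column
#'
#' Computes the alternate-allele frequency on non-missing calls,
#' `f = sum(dosages) / (2 * n_nonmissing)`, and folds it to the minor side,
#' `min(f, 1 - f)`, so the result always lies in `[0, 0.5]`.
#'
#' @param dosage_column Numeric vector with entries in `{0, 1, 2, NA}`.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @examples
#' compute_maf(c(0, 1, 2, 2)) # 5 alt alleles / 8 -> folded to 0.375
#' @export
compute_maf <- function(dosage_column) {
  x <- dosage_column[!is.na(dosage_column)]
  if (length(x) == 0) stopf("MAF undefined: all calls missing")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Quality-control filter for genotype matrices
#'
#' Applies the standard three-stage QC in a fixed order: (1) drop SNPs with a
#' call missing rate above `snp_missing_max`, (2) drop samples with a missing
#' rate above `sample_missing_max`, (3) recompute MAF on the surviving
#' samples and drop SNPs with MAF below `maf_min`. Counts removed at each
#' stage are attached as a QC report.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_missing_max Maximum tolerated per-SNP missing rate (exclusive);
#'   default 0.05.
#' @param sample_missing_max Maximum tolerated per-sample missing rate
#'   (exclusive); default 0.05.
#' @param maf_min Minimum tolerated minor allele frequency (inclusive);
#'   SNPs with MAF strictly below this are removed. Default 0.05.
#' @return A filtered `genotype_matrix` whose `"qc_report"` attribute is a
#'   data frame with columns `stage`, `items_removed`, `items_remaining`
#'   (retrievable with [qc_report()]).
#' @seealso [qc_report()], [mean_impute()]
#' @export
qc_filter <- function(gm, snp_missing_max = 0.05, sample_missing_max = 0.05,
                      maf_min = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  v <- gm$variants
  if (nrow(d) == 0 || ncol(d) == 0) stopf("empty genotype matrix")
  report <- data.frame(stage = character(), items_removed = integer(),
                       items_remaining = integer(), stringsAsFactors = FALSE)

  snp_miss <- colMeans(is.na(d))
  keep_snp <- snp_miss <= snp_missing_max
  report <- rbind(report, data.frame(stage = "snp_missingness",
                                     items_removed = sum(!keep_snp),
                                     items_remaining = sum(keep_snp)))
  d <- d[, keep_snp, drop = FALSE]
  v <- v[keep_snp, , drop = FALSE]
  if (ncol(d) == 0) {
    stopf("all SNPs removed by missingness QC (report: %s)",
          paste(utils::capture.output(print(report)), collapse = " | "))
  }

  sample_miss <- rowMeans(is.na(d))
  keep_sample <- sample_miss <= sample_missing_max
  report <- rbind(report, data.frame(stage = "sample_missingness",
                                     items_removed = sum(!keep_sample),
                                     items_remaining = sum(keep_sample)))
  d <- d[keep_sample, , drop = FALSE]
  if (nrow(d) == 0) {
    stopf("all samples removed by missingness QC")
  }

  maf <- apply(d, 2, function(col) {
    if (all(is.na(col))) -1 else compute_maf(col)
  })
  keep_maf <- maf >= maf_min
  report <- rbind(report, data.frame(stage = "maf",
                                     items_removed = sum(!keep_maf),
                                     items_remaining = sum(keep_maf)))
  d <- d[, keep_maf, drop = FALSE]
  v <- v[keep_maf, , drop = FALSE]
  if (ncol(d) == 0) {
    stopf("all SNPs removed by MAF QC (minimum observed MAF threshold %g)",
          maf_min)
  }

  out <- genotype_matrix(d, v[, c("snp_id", "chromosome", "position",
                                  "allele_ref", "allele_alt")])
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#'
#' @param gm A `genotype_matrix` returned by [qc_filter()].
#' @return Data frame with columns `stage`, `items_removed`, `items_remaining`,
#'   or `NULL` when the matrix has not been QC-filtered.
#' @export
qc_report <- function(gm) attr(gm, "qc_report")

#' Write a QC report as TSV
#'
#' @param report Data frame from [qc_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mean-impute residual missing genotype calls
#'
#' Replaces each missing entry by the column mean of the non-missing dosages,
#' so column means are preserved and no missing entries remain. Intended to
#' run after [qc_filter()]; dosages become real-valued.
#'
#' @param gm A [genotype_matrix()].
#' @return A `genotype_matrix` with no missing entries.
#' @export
mean_impute <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    cm <- colMeans(d, na.rm = TRUE)
    d[nas] <- cm[nas[, "col"]]
  }
  out <- genotype_matrix(d, gm$variants[, c("snp_id", "chromosome", "position",
                                            "allele_ref", "allele_alt")])
  attr(out, "qc_report") <- attr(gm, "qc_report")
  out
}

#' Define a cis window around a gene start site
#'
#' The window is anchored on the gene start only and extends `window_bp`
#' basepairs on either side as a closed interval, clipped at position 1:
#' `[max(1, start - window_bp), start + window_bp]`.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name (character).
#' @param start 1-based gene start position.
#' @param window_bp Half-width of the window in basepairs; default 150000
#'   (a +/-150 kb cis window).
#' @return A `gene_region` list with `gene_id`, `chromosome`, `start`,
#'   `window_lo`, `window_hi`.
#' @export
gene_region <- function(gene_id, chromosome, start, window_bp = 150000) {
  stopifnot(start >= 1, window_bp >= 0)
  structure(list(gene_id = as.character(gene_id),
                 chromosome = as.character(chromosome),
                 start = as.integer(start),
                 window_lo = as.integer(max(1, start - window_bp)),
                 window_hi = as.integer(start + window_bp)),
            class = "gene_region")
}

#' Slice a genotype matrix to a gene's cis window
#'
#' Keeps variants on the region's chromosome with position inside the closed
#' interval `[window_lo, window_hi]` (both ends inclusive), preserving the
#' original column order.
#'
#' @param gm A [genotype_matrix()].
#' @param region A [gene_region()].
#' @return A `genotype_matrix` restricted to the window.
#' @export
extract_cis_window <- function(gm, region) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(region, "gene_region"))
  v <- gm$variants
  if (!any(v$chromosome == region$chromosome)) {
    stopf("chromosome %s absent from genotype data (gene %s)",
          region$chromosome, region$gene_id)
  }
  keep <- v$chromosome == region$chromosome &
    v$position >= region$window_lo & v$position <= region$window_hi
  if (!any(keep)) {
    stopf("no SNPs in the cis window of gene %s [%d, %d]",
          region$gene_id, region$window_lo, region$window_hi)
  }
  genotype_matrix(gm$dosages[, keep, drop = FALSE],
                  v[keep, c("snp_id", "chromosome", "position",
                            "allele_ref", "allele_alt")])
}
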
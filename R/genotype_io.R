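# Genotype file handling: a plain TSV dialect and PLINK bed/bim/fam v1.00.
# No PLINK reader ships with the declared dependencies, so the 2-bit
# SNP-major codec is implemented here (read and write share one lookup
# table, giving round-trip identity on {0,1,2,NA}).

# PLINK 2-bit code -> alt-allele (A1) dosage. 01 is the missing code.
.plink_code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)

.plink_byte_table <- function() {
  # 256 x 4 matrix: dosages of the 4 samples packed in each byte value.
  codes <- 0:255
  t(vapply(codes, function(b) {
    .plink_code_to_dosage[as.character(bitwAnd(bitwShiftR(b, c(0, 2, 4, 6)), 3L))]
  }, numeric(4)))
}

#' Load genotypes from PLINK or TSV files
#'
#' Two on-disk dialects are supported. `format_tag = "tsv"`: a tab-separated
#' table whose header row holds SNP ids, whose first column holds sample ids,
#' and whose cells are `0`, `1`, `2` or `NA`. `format_tag = "plink"`: a
#' binary PLINK triple `<path>.bed` / `<path>.bim` / `<path>.fam`
#' (bed v1.00, SNP-major); dosages count A1 alleles.
#'
#' @param path File path (TSV) or PLINK prefix without extension.
#' @param format_tag `"plink"` or `"tsv"`.
#' @return A [genotype_matrix()] with missing markers preserved and per-SNP
#'   `maf` / `missing_rate` populated.
#' @seealso [write_genotypes()]
#' @export
load_genotypes <- function(path, format_tag = c("plink", "tsv")) {
  format_tag <- match.arg(format_tag)
  if (format_tag == "tsv") .load_genotypes_tsv(path) else .load_genotypes_plink(path)
}

.load_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stopf("malformed TSV %s: need a sample-id column plus >=1 SNP column", path)
  samples <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  missing_cell <- is.na(cells) | cells %in% c("NA", "")
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  num[missing_cell] <- NA
  bad <- which((!is.na(num) & !(num %in% c(0, 1, 2))) |
                 (is.na(num) & !missing_cell), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stopf("invalid dosage '%s' at line %d (sample %s), column %s of %s: expected 0/1/2/NA",
          cells[i, j], i + 1L, samples[i], colnames(cells)[j], path)
  }
  rownames(num) <- samples
  colnames(num) <- colnames(cells)
  genotype_matrix(num)
}

.load_genotypes_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stopf("incomplete PLINK triple, missing: %s", paste(missing, collapse = ", "))
  }
  bim <- utils::read.table(paths[2], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chromosome", "snp_id", "cm",
                                         "position", "allele_alt", "allele_ref"))
  fam <- utils::read.table(paths[3], header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  p <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stopf("%s is not a PLINK bed file (bad magic bytes)", paths[1])
  }
  if (raw[3] != as.raw(0x01)) {
    stopf("%s: only SNP-major bed v1.00 is supported", paths[1])
  }
  bps <- ceiling(n / 4) # bytes per SNP block
  if (length(raw) - 3 != bps * p) {
    stopf("%s: expected %d data bytes for %d samples x %d SNPs, found %d",
          paths[1], bps * p, n, p, length(raw) - 3)
  }
  tab <- .plink_byte_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bps, ncol = p)
  d <- matrix(NA_real_, nrow = n, ncol = p)
  for (j in seq_len(p)) {
    vals <- t(tab[body[, j] + 1L, , drop = FALSE]) # 4 x bps, sample-major
    d[, j] <- as.vector(vals)[seq_len(n)]
  }
  rownames(d) <- as.character(fam[[2]])
  colnames(d) <- bim$snp_id
  genotype_matrix(d, bim[, c("snp_id", "chromosome", "position",
                             "allele_ref", "allele_alt")])
}

#' Write genotypes to PLINK or TSV files
#'
#' Inverse of [load_genotypes()] for integer dosage matrices; raw calls must
#' be in `{0, 1, 2, NA}` (imputed real-valued matrices cannot be serialized
#' to PLINK's 2-bit encoding).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path (TSV) or PLINK prefix.
#' @param format_tag `"plink"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format_tag = c("plink", "tsv")) {
  format_tag <- match.arg(format_tag)
  d <- gm$dosages
  if (!all(is.na(d) | d %in% c(0, 1, 2))) {
    stopf("cannot serialize non-integer dosages; write before imputation")
  }
  if (format_tag == "tsv") {
    tab <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  v <- gm$variants
  n <- nrow(d)
  bim <- data.frame(v$chromosome, v$snp_id, 0L, v$position,
                    v$allele_alt, v$allele_ref)
  utils::write.table(bim, paste0(path, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(rownames(d), rownames(d), 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(path, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code (see .plink_code_to_dosage)
  code_of <- function(x) ifelse(is.na(x), 1L, c(3L, 2L, 0L)[x + 1L])
  con <- file(paste0(path, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bps <- ceiling(n / 4)
  for (j in seq_len(ncol(d))) {
    codes <- code_of(d[, j])
    length(codes) <- bps * 4 # pad tail with NA -> code 0 below
    codes[is.na(codes)] <- 0L
    m <- matrix(codes, nrow = 4)
    bytes <- m[1, ] + bitwShiftL(m[2, ], 2) + bitwShiftL(m[3, ], 4) +
      bitwShiftL(m[4, ], 6)
    writeBin(as.raw(bytes), con)
  }
  invisible(path)
}
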
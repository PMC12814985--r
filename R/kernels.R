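# Sample-similarity kernels built from a genotype slice.
#
# Functional forms follow the SKAT conventions: linear G G', weighted linear
# G diag(w) G', quadratic (1 + G G')^2, 2wayIX = linear kernel of the
# main-effect + all-pairwise-interaction design, IBS = mean allele sharing,
# and a MAF-Beta-weighted IBS. The APA weight vector enters the weighted
# linear kernel signed and unrescaled, so that kernel may be indefinite; the
# association stage handles signed eigenvalues.

.kernel_kinds <- c("linear", "weighted_linear", "quadratic", "twoway_ix",
                   "ibs", "weighted_ibs")

#' Compute a genotype kernel matrix
#'
#' @param G Dosage matrix (samples x SNPs) or [genotype_matrix()]; no
#'   missing entries.
#' @param kind Kernel kind: `"linear"`, `"weighted_linear"`, `"quadratic"`,
#'   `"twoway_ix"`, `"ibs"` or `"weighted_ibs"`.
#' @param diag_weights Signed per-SNP weight vector (required for
#'   `weighted_linear`; typically [build_weight_matrix()] output).
#' @param mafs Per-SNP minor allele frequencies (required for
#'   `weighted_ibs`), converted to weights by [maf_beta_weights()].
#' @return A `kernel_matrix` object: `matrix` (n x n, exactly symmetric),
#'   `spec` (kind and weight source), `snp_count`.
#' @examples
#' G <- rbind(a = c(1, 2), b = c(0, 1))
#' compute_kernel(G, "weighted_linear", diag_weights = c(1, 1))$matrix
#' @export
compute_kernel <- function(G, kind = .kernel_kinds, diag_weights = NULL,
                           mafs = NULL) {
  kind <- match.arg(kind)
  G <- .as_dosage_matrix(G)
  if (nrow(G) < 1 || ncol(G) < 1) stopf("kernel needs >=1 sample and >=1 SNP")
  if (!all(is.finite(G))) stopf("non-finite dosage values")
  p <- ncol(G)
  weight_source <- "none"
  K <- switch(kind,
    linear = tcrossprod(G),
    weighted_linear = {
      if (is.null(diag_weights)) stopf("weighted_linear kernel requires diag_weights")
      w <- if (inherits(diag_weights, "apa_weight_spec")) diag_weights$weights
           else as.numeric(diag_weights)
      if (length(w) != p) stopf("diag_weights length %d != SNP count %d", length(w), p)
      weight_source <- "apa_weights"
      G %*% (w * t(G))
    },
    quadratic = (1 + tcrossprod(G))^2,
    twoway_ix = tcrossprod(.twoway_design(G)),
    ibs = .ibs_kernel(G, rep(1, p)),
    weighted_ibs = {
      if (is.null(mafs)) stopf("weighted_ibs kernel requires mafs")
      weight_source <- "maf_beta"
      .ibs_kernel(G, maf_beta_weights(mafs))
    }
  )
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(G), rownames(G))
  structure(list(matrix = K,
                 spec = list(kind = kind, weight_source = weight_source),
                 snp_count = p),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %s kernel, %d samples, %d SNPs\n",
              x$spec$kind, nrow(x$matrix), x$snp_count))
  invisible(x)
}

# Main effects plus all pairwise products of distinct SNP columns.
.twoway_design <- function(G) {
  p <- ncol(G)
  if (p < 2) return(G)
  pairs <- utils::combn(p, 2)
  inter <- G[, pairs[1, ], drop = FALSE] * G[, pairs[2, ], drop = FALSE]
  cbind(G, inter)
}

# Weighted mean allele sharing: K_ij = sum_k w_k (2 - |g_ik - g_jk|) / (2 sum_k w_k).
.ibs_kernel <- function(G, w) {
  n <- nrow(G)
  K <- matrix(0, n, n)
  for (k in seq_len(ncol(G))) {
    K <- K + w[k] * (2 - abs(outer(G[, k], G[, k], "-")))
  }
  K / (2 * sum(w))
}

#' Beta-density MAF weights
#'
#' Converts minor allele frequencies to the squared Beta(1, 25) density,
#' the SKAT convention that up-weights rarer variants. Monomorphic SNPs
#' (MAF 0) must be filtered upstream.
#'
#' @param mafs Vector of MAFs in `(0, 0.5]`.
#' @return Nonnegative weight vector, `dbeta(maf, 1, 25)^2`.
#' @export
maf_beta_weights <- function(mafs) {
  mafs <- as.numeric(mafs)
  if (any(mafs <= 0 | mafs > 0.5)) {
    stopf("MAFs must lie in (0, 0.5]; filter monomorphic SNPs upstream")
  }
  stats::dbeta(mafs, 1, 25)^2
}

#' Dump a kernel matrix as TSV (debugging aid)
#'
#' @param K A `kernel_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(K, path) {
  stopifnot(inherits(K, "kernel_matrix"))
  utils::write.table(K$matrix, path, sep = "\t", quote = FALSE)
  invisible(path)
}
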
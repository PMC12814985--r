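# Gene-level association tests.
#
# The kernel route scores the phenotype residual quadratic form
# Q = r' K_w r against its mixture-of-chi-squares null law; the linear
# baseline combines per-SNP GWAS z-scores with the trained APA weights and
# an LD reference. Both share the intercept-only null model (no covariates).

#' Fit the intercept-only null phenotype model
#'
#' Quantitative traits: `mu` is the sample mean and the variance scale the
#' `n - 1` sample variance. Binary traits: intercept-only logistic fit, so
#' `mu` is the case fraction and the variance scale `mu * (1 - mu)`.
#'
#' @param y Phenotype vector (numeric; strictly 0/1 for binary).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return A `null_model` list: `trait_type`, `mu`, `v` (per-sample variance
#'   scale, constant under the intercept-only model), `n`.
#' @export
fit_null_model <- function(y, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  y <- as.numeric(y)
  if (length(y) < 3) stopf("need at least 3 samples")
  if (anyNA(y)) stopf("phenotype contains missing values")
  if (trait_type == "quantitative") {
    v <- stats::var(y)
    if (v == 0) stopf("constant quantitative phenotype: zero variance")
    mu <- mean(y)
  } else {
    if (!all(y %in% c(0, 1))) stopf("binary phenotype must be coded 0/1")
    mu <- mean(y) # intercept-only logistic MLE = prevalence
    if (mu == 0 || mu == 1) stopf("binary phenotype has a single class")
    v <- mu * (1 - mu)
  }
  structure(list(trait_type = trait_type, mu = mu, v = v, n = length(y)),
            class = "null_model")
}

#' Quadratic-form score statistic
#'
#' `Q = r' K r`, where the residual from the null model is `y - mu`; with
#' `mu = 0` this reduces to the raw `y' K y` form.
#'
#' @param y Phenotype vector.
#' @param K A `kernel_matrix` (or plain symmetric matrix).
#' @param null A `null_model` from [fit_null_model()], or `NULL` for `mu = 0`.
#' @return The scalar statistic.
#' @export
q_statistic <- function(y, K, null = NULL) {
  M <- if (inherits(K, "kernel_matrix")) K$matrix else K
  y <- as.numeric(y)
  if (length(y) != nrow(M)) stopf("phenotype length %d != kernel dimension %d",
                                  length(y), nrow(M))
  mu <- if (is.null(null)) 0 else null$mu
  r <- y - mu
  as.numeric(r %*% M %*% r)
}

# Center a symmetric matrix on both sides: P0 K P0 with P0 = I - 11'/n.
.double_center <- function(M) {
  rm <- rowMeans(M)
  gm <- mean(M)
  M - outer(rm, rep(1, ncol(M))) - outer(rep(1, nrow(M)), rm) + gm
}

#' Mixture-of-chi-squares p-value for a kernel Q statistic
#'
#' Under the null, `Q = r' K r` is distributed as `sum_i lambda_i chisq_1`
#' where the `lambda_i` are the eigenvalues of `V^{1/2} P0 K P0 V^{1/2}`,
#' with `P0` the projection removing the intercept and `V` the null variance
#' (a scalar multiple of the identity under the intercept-only model). Signed
#' weights can make the weighted linear kernel indefinite; negative
#' eigenvalues are handled by the inversion in [quadform_pvalue()].
#'
#' With `small_sample = TRUE` the p-value is instead computed from the exact
#' finite-sample null of the scale-free ratio `Q / (r' r)`: since
#' `P(Q > q) = P(z' P0 (K - c I) P0 z > 0)` with `c = q / (r' r)`, the tail
#' is a mixture evaluated at zero whose eigenvalues are the shifted spectrum
#' `lambda_i - c` (zeros of the projected kernel included). This removes the
#' plug-in variance approximation and tracks a phenotype-permutation null
#' closely; the default plug-in form is the field-standard large-sample
#' treatment.
#'
#' @param q_obs Observed statistic from [q_statistic()].
#' @param K A `kernel_matrix` (or symmetric matrix).
#' @param null A `null_model`.
#' @param center Apply the intercept projection `P0` (default `TRUE`; set
#'   `FALSE` only with an uncentered statistic).
#' @param small_sample Use the exact scale-free finite-sample null instead
#'   of the plug-in variance (default `FALSE`).
#' @return List with `p` and `p_method` (see [quadform_pvalue()]).
#' @export
mixture_chisq_pvalue <- function(q_obs, K, null, center = TRUE,
                                 small_sample = FALSE) {
  M <- if (inherits(K, "kernel_matrix")) K$matrix else K
  if (center) M <- .double_center(M)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) { # orient: see apa_kernel_test
    ev <- -ev
    q_obs <- -q_obs
  }
  if (!small_sample) {
    return(quadform_pvalue(q_obs, null$v * ev))
  }
  # drop the intercept direction (an exact zero of the projected kernel)
  ev <- ev[-which.min(abs(ev))]
  rss <- if (null$trait_type == "quantitative") (null$n - 1) * null$v
         else null$n * null$v
  quadform_pvalue(0, ev - q_obs / rss)
}

.assoc_row <- function(gene_id, n_snps, method, kernel_kind, q, p, p_method,
                       best_method = NA_character_, cv_r2 = NA_real_) {
  structure(data.frame(gene_id = gene_id, n_snps = n_snps, method = method,
                       kernel_kind = kernel_kind,
                       best_method = best_method, cv_r2 = cv_r2,
                       statistic_q = q, p_value = p, p_method = p_method,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Kernel-weighted APA association test
#'
#' The main gene-level test: trained SNP-to-PDUI weights enter a (by
#' default weighted linear) genotype kernel, the phenotype residual
#' quadratic form `Q = r' K_w r` is computed, and its p-value is read off
#' the mixture-of-chi-squares null distribution. All-zero weight vectors
#' carry no signal and return `p = 1` with a warning.
#'
#' Signed weights can make the whole spectrum non-positive (e.g. a single
#' negatively weighted SNP); such a kernel cannot be inflated by any
#' association, so the statistic is negated in that case — its rejection
#' tail is always the tail genetic signal pushes toward. This makes a
#' single-SNP gene reduce to the two-sided marginal score test regardless
#' of the weight's sign.
#'
#' For the weighted linear kernel the eigenvalues are obtained from the
#' p x p matrix `(P0 G)'(P0 G) diag(w)` rather than the n x n kernel (the
#' nonzero spectra coincide), which keeps per-gene cost low.
#'
#' @param G Genotype slice (matrix or [genotype_matrix()]), no missing calls.
#' @param weights An `apa_weight_spec` from [build_weight_matrix()], or a
#'   numeric per-SNP weight vector.
#' @param y Phenotype vector aligned to the rows of `G`.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param kind Kernel kind (see [compute_kernel()]); default
#'   `"weighted_linear"`.
#' @param mafs Per-SNP MAFs, required for `kind = "weighted_ibs"`.
#' @param center Residualize on the intercept (default `TRUE`; the
#'   calibration-preserving choice).
#' @param small_sample Use the exact scale-free finite-sample null (see
#'   [mixture_chisq_pvalue()]); default `FALSE` (plug-in variance).
#' @param gene_id Identifier carried into the result row.
#' @return A one-row `association_result` data frame: `gene_id`, `n_snps`,
#'   `method = "kernel"`, `kernel_kind`, `statistic_q`, `p_value`,
#'   `p_method`.
#' @export
apa_kernel_test <- function(G, weights, y,
                            trait_type = c("quantitative", "binary"),
                            kind = "weighted_linear", mafs = NULL,
                            center = TRUE, small_sample = FALSE,
                            gene_id = NULL) {
  trait_type <- match.arg(trait_type)
  G <- .as_dosage_matrix(G)
  y <- as.numeric(y)
  if (length(y) != nrow(G)) stopf("phenotype length does not match sample count")
  if (inherits(weights, "apa_weight_spec")) {
    gene_id <- gene_id %||% weights$gene_id
    w <- weights$weights
    all_zero <- weights$all_zero
  } else {
    w <- as.numeric(weights)
    all_zero <- all(w == 0)
  }
  gene_id <- gene_id %||% "gene"
  if (kind == "weighted_linear" && length(w) != ncol(G)) {
    stopf("weight length %d != SNP count %d", length(w), ncol(G))
  }
  if (kind == "weighted_linear" && all_zero) {
    warnf("all-zero weights for gene %s: no signal representable, p = 1", gene_id)
    return(.assoc_row(gene_id, ncol(G), "kernel", kind, 0, 1, "degenerate"))
  }
  null <- fit_null_model(y, trait_type)
  r <- if (center) y - null$mu else y

  if (kind == "weighted_linear") {
    # fast path: Q = sum_j w_j (g_j' r)^2; spectrum from the p x p product
    s <- as.numeric(crossprod(G, r))
    q <- sum(w * s^2)
    q_report <- q
    Gc <- if (center) sweep(G, 2, colMeans(G)) else G
    A <- crossprod(Gc)
    mu_ev <- Re(eigen(sweep(A, 2, w, "*"), only.values = TRUE)$values)
    # a wholly non-positive spectrum cannot be inflated by any signal;
    # orient the statistic so its rejection tail is the signal tail
    if (max(mu_ev) <= 0) {
      mu_ev <- -mu_ev
      q <- -q
    }
    if (small_sample) {
      rss <- if (null$trait_type == "quantitative") (null$n - 1) * null$v
             else null$n * null$v
      cc <- q / rss
      # spectrum of P0 K P0 on the (n-1)-space: mu_ev plus structural zeros
      lambda <- c(mu_ev - cc, rep(-cc, max(0, nrow(G) - 1 - length(mu_ev))))
      pv <- quadform_pvalue(0, lambda)
    } else {
      pv <- quadform_pvalue(q, null$v * mu_ev)
    }
  } else {
    K <- compute_kernel(G, kind = kind, diag_weights = w, mafs = mafs)
    q_report <- q_statistic(y, K, if (center) null else NULL)
    pv <- mixture_chisq_pvalue(q_report, K, null, center = center,
                               small_sample = small_sample)
  }
  .assoc_row(gene_id, ncol(G), "kernel", kind, q_report, pv$p, pv$p_method)
}

#' Per-SNP GWAS z-scores by marginal regression
#'
#' Wald z statistics from simple linear regression of the phenotype on each
#' SNP dosage in turn (for binary 0/1 phenotypes this is the linear-model
#' score, asymptotically equivalent to the Armitage trend test).
#'
#' @param G Dosage matrix or [genotype_matrix()].
#' @param y Phenotype vector.
#' @return Named numeric vector of z-scores, one per SNP.
#' @export
gwas_z_scores <- function(G, y) {
  G <- .as_dosage_matrix(G)
  y <- as.numeric(y)
  n <- nrow(G)
  if (n < 3) stopf("need at least 3 samples")
  yc <- y - mean(y)
  gc <- sweep(G, 2, colMeans(G))
  sxx <- colSums(gc^2)
  if (any(sxx == 0)) {
    stopf("constant genotype column: %s",
          paste(colnames(G)[sxx == 0], collapse = ", "))
  }
  sxy <- as.numeric(crossprod(gc, yc))
  slope <- sxy / sxx
  rss <- sum(yc^2) - sxy^2 / sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  z <- ifelse(se > 0, slope / se, 0)
  stats::setNames(z, colnames(G))
}

#' Pairwise LD (correlation) matrix of genotype dosages
#'
#' @param G Dosage matrix or [genotype_matrix()] with at least 2 samples and
#'   no constant columns.
#' @return Symmetric Pearson correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(G) {
  G <- .as_dosage_matrix(G)
  if (nrow(G) < 2) stopf("need at least 2 samples for LD")
  sds <- apply(G, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("constant genotype column (no LD defined): %s",
          paste((colnames(G) %||% as.character(which(sds == 0)))[sds == 0],
                collapse = ", "))
  }
  R <- stats::cor(G)
  (R + t(R)) / 2
}

#' Linear weighted z-score APA association test
#'
#' The linear APA-TWAS baseline: the trained per-SNP weights combine GWAS
#' z-scores additively, `Z_APA = (w' z) / sqrt(w' R w)` with `R` the LD
#' matrix of a reference genotype slice, and the two-sided p-value is read
#' off the standard normal.
#'
#' @param weights An `apa_weight_spec` or numeric per-SNP weight vector.
#' @param z Per-SNP GWAS z-score vector (e.g. [gwas_z_scores()]).
#' @param ld SNP x SNP correlation matrix from [ld_matrix()].
#' @param gene_id Identifier carried into the result row.
#' @return A one-row `association_result` data frame with
#'   `method = "linear"`; `statistic_q` holds `Z_APA`.
#' @export
apa_linear_test <- function(weights, z, ld, gene_id = NULL) {
  if (inherits(weights, "apa_weight_spec")) {
    gene_id <- gene_id %||% weights$gene_id
    w <- as.numeric(weights$weights)
  } else {
    w <- as.numeric(weights)
  }
  gene_id <- gene_id %||% "gene"
  z <- as.numeric(z)
  if (length(w) != length(z)) stopf("weights and z-scores are not aligned")
  if (all(w == 0)) stopf("all-zero weights: linear statistic undefined")
  ld <- as.matrix(ld)
  if (nrow(ld) != length(w)) stopf("LD matrix does not match SNP count")
  denom <- as.numeric(w %*% ld %*% w)
  if (denom <= 0) stopf("non-positive weighted LD variance (w' R w = %g)", denom)
  z_apa <- sum(w * z) / sqrt(denom)
  p <- 2 * stats::pnorm(-abs(z_apa))
  .assoc_row(gene_id, length(w), "linear", NA_character_, z_apa, p, "normal")
}

#' Write association results as TSV
#'
#' @param results An `association_result` data frame (row-bound rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
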
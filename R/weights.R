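# Per-gene SNP -> PDUI weight models.
#
# Four estimators are available, mirroring the standard TWAS weight-training
# toolbox: ridge-BLUP over all cis SNPs (L2), elastic net (mixing 0.5),
# LASSO (L1) and TOP1 (single best marginal SNP). Penalized fits go through
# glmnet; TOP1 is a marginal OLS scan. Coefficients are reported on the raw
# dosage scale, so `predict = intercept + G %*% weights`.

.weight_methods <- c("blup", "enet", "lasso", "top1")
# tie-break preference when cv_r2 values are equal
.method_preference <- c("enet", "lasso", "blup", "top1")

.as_dosage_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G <- G$dosages
  if (!is.matrix(G)) G <- as.matrix(G)
  if (anyNA(G)) stopf("genotype matrix contains missing calls; impute first")
  G
}

.glmnet_alpha <- c(blup = 0, enet = 0.5, lasso = 1)

# glmnet refuses single-column designs; pad with an all-zero dummy column
# (coefficient is identically zero) and strip it afterwards.
.glmnet_design <- function(G) {
  if (ncol(G) >= 2) return(list(x = G, pad = FALSE))
  list(x = cbind(G, dummy___ = 0), pad = TRUE)
}

.seeded_folds <- function(n, k, seed) {
  if (n < k) stopf("cannot form %d folds from %d samples", k, n)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Fit one SNP-to-PDUI weight model
#'
#' Trains a single estimator of per-SNP effects on the gene's distal poly(A)
#' site usage (PDUI). `blup` is ridge regression over all cis SNPs, `enet`
#' elastic net with mixing parameter 0.5, `lasso` the L1 fit (penalties
#' selected by internal five-fold cross-validation unless `hyper$lambda` is
#' given), and `top1` keeps the OLS coefficient of the single SNP with the
#' best marginal R-squared (ties broken by lowest column index), zero
#' elsewhere.
#'
#' @param G Genotype slice: [genotype_matrix()] or numeric dosage matrix
#'   (samples x SNPs), no missing entries.
#' @param pdui Numeric PDUI vector aligned to the rows of `G`.
#' @param method One of `"blup"`, `"enet"`, `"lasso"`, `"top1"`.
#' @param hyper Optional list of hyper-parameters; `hyper$lambda` fixes the
#'   glmnet penalty instead of selecting it by internal CV.
#' @param seed Integer seed driving fold assignment in the internal CV.
#' @return A `weight_model_fit` list: `method`, `weights` (named, dosage
#'   scale), `intercept`, `cv_r2` (`NA` until [cross_validate()] fills it),
#'   `lambda` where applicable.
#' @examples
#' G <- cbind(snpA = c(0, 0, 1, 2), snpB = c(2, 1, 0, 1))
#' fit <- fit_weight_model(G, 2 * G[, "snpB"], method = "top1", seed = 1)
#' fit$weights
#' @export
fit_weight_model <- function(G, pdui, method = .weight_methods,
                             hyper = list(), seed = 1) {
  method <- match.arg(method)
  G <- .as_dosage_matrix(G)
  pdui <- as.numeric(pdui)
  if (length(pdui) != nrow(G)) stopf("PDUI length does not match sample count")
  if (nrow(G) < 2) stopf("need at least 2 samples to fit weights")
  if (ncol(G) < 1) stopf("need at least 1 SNP")
  snp_ids <- colnames(G) %||% sprintf("snp%d", seq_len(ncol(G)))

  if (stats::sd(pdui) == 0) {
    warnf("constant PDUI for this gene; returning all-zero weights")
    return(structure(list(method = method,
                          weights = stats::setNames(rep(0, ncol(G)), snp_ids),
                          intercept = pdui[1], cv_r2 = NA_real_,
                          lambda = NA_real_),
                     class = "weight_model_fit"))
  }

  if (method == "top1") {
    fit <- .fit_top1(G, pdui)
  } else {
    fit <- .fit_glmnet(G, pdui, alpha = .glmnet_alpha[[method]],
                       lambda = hyper$lambda, seed = seed)
  }
  structure(list(method = method,
                 weights = stats::setNames(fit$weights, snp_ids),
                 intercept = fit$intercept, cv_r2 = NA_real_,
                 lambda = fit$lambda),
            class = "weight_model_fit")
}

.fit_glmnet <- function(G, y, alpha, lambda = NULL, seed = 1) {
  des <- .glmnet_design(G)
  if (is.null(lambda)) {
    foldid <- .seeded_folds(nrow(G), 5, seed)
    cv <- glmnet::cv.glmnet(des$x, y, alpha = alpha, foldid = foldid,
                            nlambda = 30, standardize = TRUE)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(des$x, y, alpha = alpha, nlambda = 30,
                          standardize = TRUE)
  }
  co <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  w <- co[-1]
  if (des$pad) w <- w[1]
  list(weights = w, intercept = co[1], lambda = lambda)
}

# Marginal OLS scan: slope and R2 of each single-SNP regression.
.marginal_scan <- function(G, y) {
  yc <- y - mean(y)
  gc <- sweep(G, 2, colMeans(G))
  sxx <- colSums(gc^2)
  sxy <- as.numeric(crossprod(gc, yc))
  slope <- ifelse(sxx > 0, sxy / sxx, 0)
  r2 <- ifelse(sxx > 0, sxy^2 / (sxx * sum(yc^2)), 0)
  list(slope = slope, r2 = r2)
}

.fit_top1 <- function(G, y) {
  sc <- .marginal_scan(G, y)
  best <- which.max(sc$r2) # which.max takes the lowest index on ties
  w <- rep(0, ncol(G))
  w[best] <- sc$slope[best]
  list(weights = w, intercept = mean(y) - w[best] * mean(G[, best]),
       lambda = NA_real_)
}

#' Five-fold cross-validated prediction performance
#'
#' Partitions samples into five near-equal folds by a seeded shuffle, refits
#' the model on four folds, predicts the held-out fold, and scores the
#' squared Pearson correlation between the concatenated out-of-fold
#' predictions and the observed PDUI. Zero-variance predictions score 0 with
#' a warning.
#'
#' @inheritParams fit_weight_model
#' @return `cv_r2`, a scalar in `[0, 1]`.
#' @export
cross_validate <- function(G, pdui, method = .weight_methods,
                           hyper = list(), seed = 1) {
  method <- match.arg(method)
  G <- .as_dosage_matrix(G)
  pdui <- as.numeric(pdui)
  n <- nrow(G)
  if (n < 5) stopf("five-fold CV needs at least 5 samples, got %d", n)
  folds <- .seeded_folds(n, 5, seed)
  preds <- rep(NA_real_, n)
  for (k in 1:5) {
    hold <- folds == k
    fit <- fit_weight_model(G[!hold, , drop = FALSE], pdui[!hold],
                            method = method, hyper = hyper,
                            seed = child_seed(seed, k))
    preds[hold] <- fit$intercept +
      as.numeric(G[hold, , drop = FALSE] %*% fit$weights)
  }
  .score_cv_r2(preds, pdui)
}

.score_cv_r2 <- function(preds, obs) {
  if (stats::sd(preds) == 0 || stats::sd(obs) == 0) {
    warnf("zero-variance out-of-fold predictions; cv_r2 set to 0")
    return(0)
  }
  stats::cor(preds, obs)^2
}

#' Train all four weight models for one gene and pick the best
#'
#' One-pass trainer used by the pipeline: for the penalized methods a single
#' five-fold `cv.glmnet` run both selects the penalty and supplies the
#' out-of-fold predictions that are scored as `cv_r2` (the prevalidated
#' array); TOP1 is cross-validated by refitting the marginal scan per fold.
#' The best model maximizes `cv_r2`, ties broken in the order
#' enet > lasso > blup > top1.
#'
#' @inheritParams fit_weight_model
#' @param gene_id Identifier stored in the result.
#' @param methods Subset of methods to train (default all four).
#' @return A `gene_weight_model` list: `gene_id`, `snp_ids`, `fits` (one
#'   `weight_model_fit` per method, each with `cv_r2` filled), `best_method`.
#' @seealso [select_best_model()], [build_weight_matrix()]
#' @export
train_gene_model <- function(G, pdui, gene_id = "gene", seed = 1,
                             methods = .weight_methods) {
  G <- .as_dosage_matrix(G)
  pdui <- as.numeric(pdui)
  n <- nrow(G)
  snp_ids <- colnames(G) %||% sprintf("snp%d", seq_len(ncol(G)))
  if (n < 5) stopf("five-fold CV needs at least 5 samples, got %d", n)
  if (stats::sd(pdui) == 0) {
    warnf("constant PDUI for gene %s; all weights zero", gene_id)
    fits <- lapply(methods, function(m) {
      structure(list(method = m,
                     weights = stats::setNames(rep(0, ncol(G)), snp_ids),
                     intercept = pdui[1], cv_r2 = 0, lambda = NA_real_),
                class = "weight_model_fit")
    })
    names(fits) <- methods
    return(select_best_model(fits, gene_id = gene_id, snp_ids = snp_ids))
  }
  foldid <- .seeded_folds(n, 5, seed)
  fits <- list()
  for (m in methods) {
    if (m == "top1") {
      fit <- .fit_top1(G, pdui)
      preds <- rep(NA_real_, n)
      for (k in 1:5) {
        hold <- foldid == k
        f <- .fit_top1(G[!hold, , drop = FALSE], pdui[!hold])
        preds[hold] <- f$intercept +
          as.numeric(G[hold, , drop = FALSE] %*% f$weights)
      }
      cv_r2 <- suppressWarnings(.score_cv_r2(preds, pdui))
    } else {
      des <- .glmnet_design(G)
      cv <- glmnet::cv.glmnet(des$x, pdui, alpha = .glmnet_alpha[[m]],
                              foldid = foldid, nlambda = 30,
                              standardize = TRUE, keep = TRUE)
      idx <- match(cv$lambda.min, cv$lambda)
      preds <- cv$fit.preval[, idx]
      co <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda.min))
      w <- co[-1]
      if (des$pad) w <- w[1]
      # a fit that selects no SNPs predicts a constant up to fold-intercept
      # jitter; it carries no genetic signal and must not win selection
      cv_r2 <- if (all(w == 0)) 0 else suppressWarnings(.score_cv_r2(preds, pdui))
      fit <- list(weights = w, intercept = co[1], lambda = cv$lambda.min)
    }
    fits[[m]] <- structure(list(method = m,
                                weights = stats::setNames(fit$weights, snp_ids),
                                intercept = fit$intercept, cv_r2 = cv_r2,
                                lambda = fit$lambda),
                           class = "weight_model_fit")
  }
  select_best_model(fits, gene_id = gene_id, snp_ids = snp_ids)
}

#' Select the best-performing weight model
#'
#' Picks the fit with maximal `cv_r2`; exact ties fall back to the fixed
#' preference order enet > lasso > blup > top1.
#'
#' @param fits Named or unnamed list of `weight_model_fit` objects with
#'   `cv_r2` populated.
#' @param gene_id Identifier stored in the result.
#' @param snp_ids SNP id vector; defaults to the names of the first fit's
#'   weights.
#' @return A `gene_weight_model` list.
#' @export
select_best_model <- function(fits, gene_id = "gene", snp_ids = NULL) {
  if (length(fits) == 0) stopf("no fits supplied")
  methods <- vapply(fits, `[[`, character(1), "method")
  names(fits) <- methods
  snp_ids <- snp_ids %||% names(fits[[1]]$weights)
  cv <- vapply(fits, function(f) {
    v <- f$cv_r2
    if (is.na(v)) 0 else v
  }, numeric(1))
  pref <- match(methods, .method_preference)
  best <- order(-cv, pref)[1]
  structure(list(gene_id = gene_id, snp_ids = snp_ids, fits = fits,
                 best_method = methods[best]),
            class = "gene_weight_model")
}

#' @export
print.gene_weight_model <- function(x, ...) {
  cv <- vapply(x$fits, `[[`, numeric(1), "cv_r2")
  cat(sprintf("gene_weight_model %s: %d SNPs; best = %s (cv_r2: %s)\n",
              x$gene_id, length(x$snp_ids), x$best_method,
              paste(sprintf("%s %.3f", names(cv), cv), collapse = ", ")))
  invisible(x)
}

#' Export the selected model's weights as a diagonal weight spec
#'
#' Returns the best fit's coefficient vector for use on the diagonal of the
#' kernel weight matrix, exactly as estimated: signed, unstandardized and
#' unrescaled. An all-zero vector is flagged so the association stage can
#' handle it (no signal is representable).
#'
#' @param model A `gene_weight_model` from [train_gene_model()] or
#'   [select_best_model()].
#' @return An `apa_weight_spec` list: `gene_id`, `snp_ids`, `weights`
#'   (named numeric), `method`, `all_zero` flag.
#' @export
build_weight_matrix <- function(model) {
  stopifnot(inherits(model, "gene_weight_model"))
  fit <- model$fits[[model$best_method]]
  if (is.null(fit)) stopf("model has no fit for best_method %s", model$best_method)
  w <- fit$weights
  all_zero <- all(w == 0)
  if (all_zero) warnf("all weights are zero for gene %s", model$gene_id)
  structure(list(gene_id = model$gene_id, snp_ids = model$snp_ids,
                 weights = w, method = fit$method, all_zero = all_zero),
            class = "apa_weight_spec")
}

#' Write per-gene weights and CV summaries as TSV
#'
#' @param models List of `gene_weight_model` objects.
#' @param weights_path Output TSV (`gene_id`, `snp_id`, `method`, `weight`).
#' @param summary_path Output TSV (`gene_id`, `best_method`, one `cv_r2_*`
#'   column per method).
#' @return Invisibly, a list with both paths.
#' @export
write_weight_tables <- function(models, weights_path, summary_path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(m$fits, function(f) {
      data.frame(gene_id = m$gene_id, snp_id = names(f$weights),
                 method = f$method, weight = as.numeric(f$weights),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, weights_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- do.call(rbind, lapply(models, function(m) {
    cv <- vapply(m$fits, `[[`, numeric(1), "cv_r2")
    out <- data.frame(gene_id = m$gene_id, best_method = m$best_method,
                      stringsAsFactors = FALSE)
    for (nm in names(cv)) out[[paste0("cv_r2_", nm)]] <- cv[[nm]]
    out
  }))
  utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(weights = weights_path, summary = summary_path))
}
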
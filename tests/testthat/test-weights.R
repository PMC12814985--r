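test_that("top1 keeps the single best marginal OLS coefficient", {
  withr::with_seed(1, {
    G <- cbind(snpA = rbinom(50, 2, 0.3), snpB = rbinom(50, 2, 0.4))
    while (stats::sd(G[, 1]) == 0 || stats::sd(G[, 2]) == 0) {
      G <- cbind(snpA = rbinom(50, 2, 0.3), snpB = rbinom(50, 2, 0.4))
    }
  })
  fit <- fit_weight_model(G, 2 * G[, "snpB"], method = "top1", seed = 1)
  expect_equal(sum(fit$weights != 0), 1L)
  expect_equal(unname(fit$weights["snpB"]), 2)
  expect_equal(unname(fit$weights["snpA"]), 0)
})

test_that("top1 equals a brute-force per-SNP regression scan", {
  withr::with_seed(21, {
    for (i in 1:5) {
      G <- make_dosages(60, 8, seed = i)
      y <- rnorm(60)
      fit <- fit_weight_model(G, y, method = "top1", seed = 1)
      r2 <- apply(G, 2, function(g) summary(stats::lm(y ~ g))$r.squared)
      best <- which.max(r2)
      expect_equal(which(fit$weights != 0), best)
      expect_equal(unname(fit$weights[best]),
                   unname(stats::coef(stats::lm(y ~ G[, best]))[2]))
    }
  })
})

test_that("lasso under an overwhelming penalty shrinks all weights to zero", {
  G <- make_dosages(40, 5, seed = 9)
  y <- withr::with_seed(9, rnorm(40))
  fit <- fit_weight_model(G, y, method = "lasso", hyper = list(lambda = 1e6),
                          seed = 1)
  expect_true(all(fit$weights == 0))
})

test_that("lasso support is non-increasing along a growing penalty grid", {
  G <- make_dosages(80, 10, seed = 13)
  y <- withr::with_seed(13, G %*% rnorm(10) + rnorm(80))
  sizes <- vapply(c(0.001, 0.01, 0.1, 1, 10), function(l) {
    sum(fit_weight_model(G, y, "lasso", hyper = list(lambda = l), seed = 1)$weights != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("constant PDUI yields all-zero weights with a warning, not an error", {
  G <- make_dosages(20, 3, seed = 2)
  expect_warning(fit <- fit_weight_model(G, rep(0.4, 20), "enet", seed = 1),
                 "constant PDUI")
  expect_true(all(fit$weights == 0))
  expect_error(fit_weight_model(G[1, , drop = FALSE], 1, "enet", seed = 1),
               "2 samples")
})

test_that("five-fold CV recovers a noiseless linear PDUI signal", {
  withr::with_seed(31, {
    gm <- simulate_genotypes(200, 6, maf_spec = c(0.2, 0.5), seed = 31)
    G <- gm$dosages
    pdui <- as.numeric(G[, 2] * 0.8 - G[, 5] * 0.5)
  })
  for (m in c("lasso", "enet")) {
    expect_gt(cross_validate(G, pdui, m, seed = 5), 0.99)
  }
})

test_that("five-fold CV scores pure-noise PDUI near zero", {
  withr::with_seed(32, {
    gm <- simulate_genotypes(200, 10, seed = 77)
    pdui <- rnorm(200)
  })
  cv <- cross_validate(gm, pdui, "enet", seed = 3)
  expect_lt(cv, 0.1)
  expect_error(cross_validate(gm$dosages[1:4, ], pdui[1:4], "enet", seed = 1),
               "5 samples")
})

test_that("best-model selection maximizes cv_r2 with the documented tie-break", {
  mk <- function(method, cv) structure(list(method = method, cv_r2 = cv,
                                            weights = c(a = 1)),
                                       class = "weight_model_fit")
  fits <- list(mk("enet", 0.3), mk("lasso", 0.2), mk("blup", 0.1),
               mk("top1", 0.05))
  expect_equal(select_best_model(fits)$best_method, "enet")
  fits_tied <- list(mk("top1", 0.2), mk("blup", 0.2), mk("lasso", 0.2),
                    mk("enet", 0.2))
  expect_equal(select_best_model(fits_tied)$best_method, "enet")
  expect_equal(select_best_model(list(mk("top1", 0.0)))$best_method, "top1")
  expect_error(select_best_model(list()), "no fits")
})

test_that("the exported weight spec preserves signs and flags zero vectors", {
  mk <- function(method, cv, w) structure(list(method = method, cv_r2 = cv,
                                               weights = w),
                                          class = "weight_model_fit")
  m <- select_best_model(list(mk("enet", 0.5, c(s1 = 0.5, s2 = -1.2))),
                         gene_id = "gX")
  spec <- build_weight_matrix(m)
  expect_equal(unname(spec$weights), c(0.5, -1.2)) # signed, unrescaled
  expect_false(spec$all_zero)
  mz <- select_best_model(list(mk("lasso", 0, c(s1 = 0, s2 = 0))))
  expect_warning(specz <- build_weight_matrix(mz), "all weights are zero")
  expect_true(specz$all_zero)
})

test_that("train_gene_model fills cv_r2 for all four methods and picks a best", {
  withr::with_seed(41, {
    gm <- simulate_genotypes(120, 8, seed = 41)
    pdui <- as.numeric(gm$dosages[, 1]) + rnorm(120, sd = 0.5)
  })
  model <- train_gene_model(gm, pdui, gene_id = "g1", seed = 2)
  expect_setequal(names(model$fits), c("blup", "enet", "lasso", "top1"))
  cv <- vapply(model$fits, `[[`, numeric(1), "cv_r2")
  expect_true(all(is.finite(cv)))
  expect_true(all(cv <= 1))
  expect_gt(max(cv), 0.3) # strong signal gene
  expect_equal(sum(model$fits$top1$weights != 0), 1L)
  # reproducible under the same seed
  model2 <- train_gene_model(gm, pdui, gene_id = "g1", seed = 2)
  expect_equal(model2$fits$enet$weights, model$fits$enet$weights)
})

test_that("weight tables are written in the documented TSV layout", {
  withr::with_seed(51, {
    gm <- simulate_genotypes(60, 4, seed = 51)
    pdui <- rnorm(60)
  })
  model <- suppressWarnings(train_gene_model(gm, pdui, gene_id = "gA", seed = 1))
  wp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_weight_tables(list(model), wp, sp)
  w <- read.delim(wp)
  expect_equal(names(w), c("gene_id", "snp_id", "method", "weight"))
  expect_equal(nrow(w), 4 * 4) # 4 methods x 4 SNPs
  s <- read.delim(sp)
  expect_equal(s$gene_id, "gA")
  expect_true(all(c("best_method", "cv_r2_enet", "cv_r2_top1") %in% names(s)))
})
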
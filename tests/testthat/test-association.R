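test_that("intercept-only null models match hand calculations", {
  nm <- fit_null_model(c(0, 2, 4), "quantitative")
  expect_equal(nm$mu, 2)
  expect_equal(nm$v, 4) # n-1 denominator
  nb <- fit_null_model(c(0, 1, 1, 1), "binary")
  expect_equal(nb$mu, 0.75) # intercept-only logistic = prevalence
  expect_equal(nb$v, 0.75 * 0.25)
  expect_error(fit_null_model(rep(3, 5)), "zero variance")
  expect_error(fit_null_model(rep(1, 5), "binary"), "single class")
  expect_error(fit_null_model(c(0, 1, 2), "binary"), "0/1")
})

test_that("the Q statistic is the residual quadratic form", {
  K <- diag(2)
  expect_equal(q_statistic(c(1, 2), K), 5) # mu = 0 reduction
  null <- fit_null_model(c(1, 0, 2))
  expect_equal(q_statistic(c(1, 1, 1), matrix(1, 3, 3) + diag(3), null), 0)
  # hand case: r = (1,-1), K = [[2,1],[1,2]] -> r'Kr = 2
  expect_equal(q_statistic(c(1, -1), rbind(c(2, 1), c(1, 2))), 2)
  expect_error(q_statistic(c(1, 2, 3), K), "dimension")
})

test_that("Q is invariant under joint sample permutation", {
  withr::with_seed(3, {
    G <- make_dosages(25, 4, seed = 3)
    w <- rnorm(4)
    y <- rnorm(25)
    perm <- sample(25)
  })
  r1 <- apa_kernel_test(G, w, y)
  r2 <- apa_kernel_test(G[perm, ], w, y[perm])
  expect_equal(r2$statistic_q, r1$statistic_q)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("fast weighted-linear path agrees with the explicit kernel route", {
  withr::with_seed(13, {
    G <- make_dosages(40, 6, seed = 13)
    w <- rnorm(6)
    y <- rnorm(40)
  })
  fast <- apa_kernel_test(G, w, y)
  K <- compute_kernel(G, "weighted_linear", diag_weights = w)
  null <- fit_null_model(y)
  q <- q_statistic(y, K, null)
  slow <- mixture_chisq_pvalue(q, K, null)
  expect_equal(fast$statistic_q, q)
  expect_equal(fast$p_value, slow$p, tolerance = 1e-6)
  # and the small-sample mode agrees between routes too
  fast_ss <- apa_kernel_test(G, w, y, small_sample = TRUE)
  slow_ss <- mixture_chisq_pvalue(q, K, null, small_sample = TRUE)
  expect_equal(fast_ss$p_value, slow_ss$p, tolerance = 1e-6)
})

test_that("single-SNP weighted-linear test reduces to the marginal score test", {
  withr::with_seed(19, {
    for (i in 1:10) {
      g <- rbinom(80, 2, runif(1, 0.1, 0.5))
      if (stats::sd(g) == 0) next
      y <- rnorm(80)
      w <- runif(1, 0.2, 3) * sample(c(-1, 1), 1)
      res <- apa_kernel_test(matrix(g), w, y)
      expect_equal(res$p_value, score_test_p(g, y), tolerance = 1e-6)
    }
  })
})

test_that("analytic p tracks a 10^4-draw permutation oracle at small n", {
  withr::with_seed(29, {
    seeds <- sample.int(1e6, 8)
  })
  for (s in seeds) {
    withr::with_seed(s, {
      n <- sample(30:60, 1)
      p <- sample(2:8, 1)
      G <- make_dosages(n, p, seed = s)
      w <- rnorm(p)
      y <- rnorm(n)
    })
    res <- apa_kernel_test(G, w, y, small_sample = TRUE)
    perm <- perm_pvalue(G, w, y, B = 10000, seed = s)
    se <- sqrt(max(perm$p * (1 - perm$p), 1e-6) / perm$B)
    expect_lt(abs(res$p_value - perm$p), 3 * se)
  }
})

test_that("all-zero weights short-circuit to p = 1 with a warning", {
  G <- make_dosages(20, 3, seed = 1)
  y <- withr::with_seed(1, rnorm(20))
  expect_warning(res <- apa_kernel_test(G, c(0, 0, 0), y), "all-zero")
  expect_equal(res$p_value, 1)
  expect_equal(res$p_method, "degenerate")
})

test_that("LD matrix handles duplicated, anti-coded and constant columns", {
  G <- make_dosages(30, 3, seed = 17)
  G2 <- cbind(G, dup = G[, 1], anti = 2 - G[, 2])
  R <- ld_matrix(G2)
  expect_equal(unname(R["dup", "snp1"]), 1)
  expect_equal(unname(R["anti", "snp2"]), -1)
  expect_equal(diag(R), setNames(rep(1, 5), colnames(G2)))
  G2[, 3] <- 1
  expect_error(ld_matrix(G2), "constant genotype column.*snp3")
})

test_that("LD of independent SNPs concentrates near zero", {
  gm <- simulate_genotypes(10000, 6, maf_spec = c(0.2, 0.5), ld_rho = 0,
                           seed = 23)
  R <- ld_matrix(gm)
  off <- R[upper.tri(R)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("GWAS z-scores match per-SNP lm Wald statistics", {
  withr::with_seed(37, {
    G <- make_dosages(50, 4, seed = 37)
    y <- rnorm(50)
  })
  z <- gwas_z_scores(G, y)
  for (j in 1:4) {
    tt <- summary(stats::lm(y ~ G[, j]))$coefficients[2, "t value"]
    expect_equal(unname(z[j]), unname(tt), tolerance = 1e-10)
  }
})

test_that("linear weighted z-score test obeys its algebraic reductions", {
  # one SNP, weight 1: normalization cancels
  r1 <- apa_linear_test(1, 2.5, matrix(1))
  expect_equal(r1$statistic_q, 2.5)
  expect_equal(r1$p_value, 2 * pnorm(-2.5))
  # two perfectly correlated SNPs, equal weights and z: w'Rw = 4w^2
  R <- matrix(1, 2, 2)
  r2 <- apa_linear_test(c(0.7, 0.7), c(1.3, 1.3), R)
  expect_equal(r2$statistic_q, 1.3)
  # weights orthogonal to z under independence: Z_APA = 0, p = 1
  r3 <- apa_linear_test(c(1, -1), c(2, 2), diag(2))
  expect_equal(r3$statistic_q, 0)
  expect_equal(r3$p_value, 1)
  expect_error(apa_linear_test(c(0, 0), c(1, 1), diag(2)), "all-zero")
  expect_error(apa_linear_test(c(1, -1), c(1, 1), matrix(1, 2, 2)),
               "non-positive")
})
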
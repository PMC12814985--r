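test_that("simulated genotypes hit the target MAF and dosage alphabet", {
  gm <- simulate_genotypes(50000, 2, maf_spec = 0.5, ld_rho = 0, seed = 1)
  expect_true(all(gm$dosages %in% c(0, 1, 2)))
  expect_lt(max(abs(colMeans(gm$dosages) - 1)), 0.02) # E[dosage] = 2*MAF
  gm2 <- simulate_genotypes(5000, 10, maf_spec = 0.05, seed = 2)
  expect_true(all(gm2$variants$maf >= 0.03 & gm2$variants$maf <= 0.07))
  expect_error(simulate_genotypes(10, 2, maf_spec = 0.01, seed = 1),
               "post-QC")
  expect_error(simulate_genotypes(10, 2, ld_rho = 1, seed = 1), "ld_rho")
})

test_that("AR(1) latent LD produces high r2 between adjacent SNPs", {
  gm <- simulate_genotypes(50000, 2, maf_spec = 0.3, ld_rho = 0.99, seed = 3)
  r2 <- stats::cor(gm$dosages[, 1], gm$dosages[, 2])^2
  expect_gt(r2, 0.8)
  gm0 <- simulate_genotypes(50000, 2, maf_spec = 0.3, ld_rho = 0, seed = 3)
  expect_lt(stats::cor(gm0$dosages[, 1], gm0$dosages[, 2])^2, 0.01)
})

test_that("causal SNP selection honors forced, high-LD and infeasible cases", {
  d <- make_dosages(60, 2, seed = 5)
  gm <- genotype_matrix(d)
  expect_setequal(select_causal_snps(gm, n_causal = 2, seed = 1),
                  c("snp1", "snp2"))
  # duplicated column pair is the only r2 > 0.8 pair
  d4 <- cbind(make_dosages(60, 2, seed = 6), dupA = NA, dupB = NA)
  d4[, "dupA"] <- d4[, 1]
  d4[, "dupB"] <- d4[, 1]
  while (abs(cor(d4[, 1], d4[, 2])) > 0.4) d4[, 2] <- make_dosages(60, 1, seed = 99)
  gm4 <- genotype_matrix(d4)
  picked <- select_causal_snps(gm4, n_causal = 2, ld_mode = "high_ld", seed = 2)
  expect_true(all(picked %in% c("snp1", "dupA", "dupB")))
  # all columns identical: low-LD pair infeasible
  same <- genotype_matrix(cbind(a = d[, 1], b = d[, 1], c = d[, 1]))
  expect_error(select_causal_snps(same, n_causal = 2, ld_mode = "low_ld",
                                  seed = 1),
               "best available")
})

test_that("non-additive architectures follow their carrier truth tables", {
  pairs <- expand.grid(g1 = 0:2, g2 = 0:2)
  G <- as.matrix(pairs)
  c1 <- pairs$g1 >= 1
  c2 <- pairs$g2 >= 1
  expect_equal(genetic_value(G, "epistatic")$g, as.numeric(c1 & c2))
  expect_equal(genetic_value(G, "heterogeneous")$g, as.numeric(c1 | c2))
  expect_equal(genetic_value(G, "compensatory")$g, as.numeric(xor(c1, c2)))
  expect_equal(genetic_value(matrix(0:2), "single")$g, c(0, 1, 1))
  # spot checks called out by the model definitions
  expect_equal(genetic_value(rbind(c(2, 0)), "epistatic")$g, 0)
  expect_equal(genetic_value(rbind(c(1, 1)), "epistatic")$g, 1)
  expect_equal(genetic_value(rbind(c(1, 0)), "compensatory")$g, 1)
  expect_equal(genetic_value(rbind(c(2, 2)), "compensatory")$g, 0)
  expect_error(genetic_value(G, "single"), "needs 1 causal")
})

test_that("additive genetic values are the seeded weighted dosage sum", {
  G <- rbind(c(0, 2), c(1, 1), c(2, 0))
  gv <- genetic_value(G, "additive2", seed = 42)
  w <- gv$effect_spec
  expect_length(w, 2)
  expect_equal(gv$g, as.numeric(G %*% w))
  # reproducible
  expect_equal(genetic_value(G, "additive2", seed = 42)$g, gv$g)
})

test_that("environmental noise realizes the requested heritability", {
  # exact algebra: h2 = 0.5 and unit genetic variance gives sigma_e2 = 1
  g <- c(-1, 0, 1) * sqrt(1 / var(c(-1, 0, 1)))
  sp <- add_environmental_noise(g, 0.5, seed = 1)$spec
  expect_equal(sp$sigma_e2, sp$sigma_g2)
  expect_equal(sp$sigma_p2, sp$sigma_g2 + sp$sigma_e2)
  # h2 = 1 is the noise-free limit
  expect_equal(add_environmental_noise(g, 1, seed = 1)$x, g)
  # realized variance ratio converges to h2
  gg <- withr::with_seed(7, rnorm(20000))
  x <- add_environmental_noise(gg, 0.2, seed = 8)$x
  ratio <- var(gg) / var(x)
  expect_gte(ratio, 0.18)
  expect_lte(ratio, 0.22)
  expect_error(add_environmental_noise(rep(1, 10), 0.5, seed = 1),
               "zero genetic variance")
})

test_that("liability thresholding yields the exact case count", {
  y <- binarize_liability(seq_len(100), 0.5)
  expect_equal(sum(y), 50)
  expect_equal(y[51:100], rep(1L, 50))
  expect_equal(sum(binarize_liability(rnorm(1000), 0.1)), 100)
  l <- withr::with_seed(2, rnorm(57))
  expect_identical(binarize_liability(l, 0.3), binarize_liability(l, 0.3))
  expect_error(binarize_liability(rep(1, 5), 0.5), "degenerate")
})

test_that("pleiotropy shares one genetic signal across PDUI and phenotype", {
  gm <- simulate_genotypes(800, 12, maf_spec = c(0.1, 0.5), seed = 10)
  sc <- sim_scenario("pleiotropy", "additive5", h2_pheno = 0.4, h2_apa = 0.4,
                     n_samples = 800, seed = 10)
  ds <- simulate_dataset(sc, gm)
  expect_gt(cor(ds$pdui, ds$phenotype), 0.1) # shared g
  expect_false(isTRUE(all.equal(ds$pdui, ds$phenotype))) # independent noise
  expect_true(all(ds$causal_snp_ids %in% gm$variants$snp_id))
  expect_length(ds$causal_snp_ids, 5)
})

test_that("a noise-free causality chain propagates g to the phenotype exactly", {
  gm <- simulate_genotypes(300, 8, maf_spec = c(0.2, 0.5), seed = 11)
  sc <- sim_scenario("causality", "epistatic", h2_pheno = 1, h2_apa = 1,
                     n_samples = 300, seed = 11)
  ds <- simulate_dataset(sc, gm)
  g <- genetic_value(gm$dosages[, ds$causal_snp_ids],
                     "epistatic")$g
  expect_equal(ds$pdui, g)
  expect_equal(ds$phenotype, g)
})

test_that("datasets are bit-identical under the same scenario seed", {
  gm <- simulate_genotypes(150, 10, seed = 12)
  sc <- sim_scenario("causality", "heterogeneous", h2_pheno = 0.2,
                     h2_apa = 0.2, trait_type = "binary", n_samples = 150,
                     seed = 77)
  d1 <- simulate_dataset(sc, gm)
  d2 <- simulate_dataset(sc, gm)
  expect_identical(d1$pdui, d2$pdui)
  expect_identical(d1$phenotype, d2$phenotype)
  expect_identical(d1$causal_snp_ids, d2$causal_snp_ids)
  expect_true(all(d1$phenotype %in% c(0, 1)))
  expect_equal(mean(d1$phenotype), 0.5, tolerance = 0.01)
})

test_that("null datasets are standard normal and genotype-independent", {
  nd <- simulate_null_dataset(100, 1000, seed = 5)
  expect_length(nd, 100)
  all_t <- unlist(lapply(nd, `[[`, "transcriptome"))
  expect_equal(mean(all_t), 0, tolerance = 0.02) # 1e5 draws
  expect_equal(sd(all_t), 1, tolerance = 0.02)
  cors <- vapply(nd, function(g) cor(g$transcriptome, g$phenotype), numeric(1))
  # max |r| over 100 independent pairs at n=1000 stays in the null band
  expect_lt(max(abs(cors)), 4.5 / sqrt(1000))
  expect_identical(simulate_null_dataset(3, 10, seed = 9),
                   simulate_null_dataset(3, 10, seed = 9))
})
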
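# Synthetic-data generator: genotypes with configurable MAF and AR(1) LD,
# per-gene PDUI and phenotypes under seven genetic architectures and two
# causal assumptions, liability-threshold binary traits, and the pure-null
# design used for type-I-error calibration.
#
# All randomness flows from a single scenario seed through child_seed()
# streams, so every dataset is exactly reproducible.

.architectures <- c("additive2", "additive5", "additive10", "single",
                    "epistatic", "heterogeneous", "compensatory")

.n_causal_of <- c(additive2 = 2, additive5 = 5, additive10 = 10, single = 1,
                  epistatic = 2, heterogeneous = 2, compensatory = 2)

#' Describe a simulation scenario
#'
#' @param assumption `"causality"` (genotype -> PDUI -> phenotype chain) or
#'   `"pleiotropy"` (genotype affects PDUI and phenotype in parallel).
#' @param architecture One of `"additive2"`, `"additive5"`, `"additive10"`,
#'   `"single"`, `"epistatic"`, `"heterogeneous"`, `"compensatory"`.
#' @param h2_pheno Phenotype-stage heritability in `(0, 1]`.
#' @param h2_apa APA-stage (PDUI) heritability in `(0, 1]`.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param prevalence Case fraction for binary traits (default 0.5).
#' @param ld_mode Causal-SNP selection: `"random"`, `"high_ld"` (pair with
#'   r-squared > 0.8) or `"low_ld"` (pair with r-squared < 0.2).
#' @param n_samples Cohort size.
#' @param seed Scenario seed; every stochastic step derives from it.
#' @return A `sim_scenario` list, with `n_causal` filled from the
#'   architecture.
#' @export
sim_scenario <- function(assumption = c("pleiotropy", "causality"),
                         architecture = .architectures,
                         h2_pheno, h2_apa,
                         trait_type = c("quantitative", "binary"),
                         prevalence = 0.5,
                         ld_mode = c("random", "high_ld", "low_ld"),
                         n_samples, seed = 1) {
  assumption <- match.arg(assumption)
  architecture <- match.arg(architecture)
  trait_type <- match.arg(trait_type)
  ld_mode <- match.arg(ld_mode)
  stopifnot(h2_pheno > 0, h2_pheno <= 1, h2_apa > 0, h2_apa <= 1,
            prevalence > 0, prevalence < 1, n_samples >= 2)
  structure(list(assumption = assumption, architecture = architecture,
                 n_causal = .n_causal_of[[architecture]],
                 h2_pheno = h2_pheno, h2_apa = h2_apa,
                 trait_type = trait_type, prevalence = prevalence,
                 ld_mode = ld_mode, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate genotype dosages with configurable MAF and LD
#'
#' Each sample receives two latent gametes drawn from a multivariate normal
#' with AR(1) correlation `ld_rho` across adjacent SNPs; each gamete carries
#' the alternate allele when its latent value falls below the MAF quantile,
#' and the dosage is the allele sum, giving entries in `{0, 1, 2}` with the
#' requested marginal MAF and a decaying LD profile.
#'
#' @param n_samples Number of samples.
#' @param n_snps Number of SNPs.
#' @param maf_spec Per-SNP MAF: a single value, a vector of length
#'   `n_snps`, or a range `c(lo, hi)` sampled uniformly. Values must lie in
#'   `[0.05, 0.5]` (the post-QC regime).
#' @param ld_rho AR(1) latent correlation between adjacent SNPs, in `[0, 1)`.
#' @param seed Integer seed.
#' @param chromosome,positions Optional variant coordinates (defaults:
#'   chromosome `"1"`, positions `1000 * (1:n_snps)`).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_spec = c(0.05, 0.5),
                               ld_rho = 0, seed = 1, chromosome = "1",
                               positions = NULL) {
  stopifnot(n_samples >= 1, n_snps >= 1)
  if (ld_rho < 0 || ld_rho >= 1) stopf("ld_rho must lie in [0, 1)")
  with_seed(seed, {
    mafs <- if (length(maf_spec) == 1) {
      rep(maf_spec, n_snps)
    } else if (length(maf_spec) == n_snps && n_snps != 2) {
      as.numeric(maf_spec)
    } else if (length(maf_spec) == 2) {
      stats::runif(n_snps, maf_spec[1], maf_spec[2])
    } else {
      as.numeric(maf_spec)
    }
    if (length(mafs) != n_snps) stopf("maf_spec does not match n_snps")
    if (any(mafs < 0.05 - 1e-12 | mafs > 0.5 + 1e-12)) {
      stopf("MAFs must lie in [0.05, 0.5] (post-QC regime)")
    }
    thr <- stats::qnorm(mafs)
    gamete <- function() {
      z <- matrix(stats::rnorm(n_samples * n_snps), n_samples, n_snps)
      if (ld_rho > 0 && n_snps > 1) {
        sc <- sqrt(1 - ld_rho^2)
        for (j in 2:n_snps) z[, j] <- ld_rho * z[, j - 1] + sc * z[, j]
      }
      sweep(z, 2, thr, "<") * 1
    }
    d <- gamete() + gamete()
    rownames(d) <- sprintf("sample%d", seq_len(n_samples))
    colnames(d) <- sprintf("snp%d", seq_len(n_snps))
    genotype_matrix(d, data.frame(
      snp_id = colnames(d), chromosome = chromosome,
      position = positions %||% (1000L * seq_len(n_snps)),
      allele_ref = "A", allele_alt = "B", stringsAsFactors = FALSE
    ))
  })
}

#' Select causal SNPs in a cis window
#'
#' `random` draws `n_causal` SNPs uniformly without replacement; `high_ld`
#' draws a pair whose empirical r-squared exceeds 0.8; `low_ld` a pair below
#' 0.2. Deterministic given the seed.
#'
#' @param gm A [genotype_matrix()] (no missing calls).
#' @param region Optional [gene_region()]; when given, selection is
#'   restricted to the cis window.
#' @param n_causal Number of causal SNPs (must be 2 for the LD modes).
#' @param ld_mode `"random"`, `"high_ld"` or `"low_ld"`.
#' @param seed Integer seed.
#' @return Character vector of selected SNP ids.
#' @export
select_causal_snps <- function(gm, region = NULL, n_causal,
                               ld_mode = c("random", "high_ld", "low_ld"),
                               seed = 1) {
  ld_mode <- match.arg(ld_mode)
  if (!is.null(region)) gm <- extract_cis_window(gm, region)
  d <- gm$dosages
  ids <- gm$variants$snp_id
  if (ncol(d) < n_causal) {
    stopf("window holds %d SNPs, fewer than n_causal = %d", ncol(d), n_causal)
  }
  if (ld_mode == "random") {
    return(with_seed(seed, ids[sample.int(ncol(d), n_causal)]))
  }
  if (n_causal != 2) stopf("LD-aware selection is defined for SNP pairs only")
  sds <- apply(d, 2, stats::sd)
  poly <- which(sds > 0)
  if (length(poly) < 2) stopf("fewer than 2 polymorphic SNPs in the window")
  r2 <- stats::cor(d[, poly, drop = FALSE])^2
  r2[lower.tri(r2, diag = TRUE)] <- NA
  ok <- if (ld_mode == "high_ld") which(r2 > 0.8, arr.ind = TRUE)
        else which(r2 < 0.2, arr.ind = TRUE)
  if (nrow(ok) == 0) {
    ext <- if (ld_mode == "high_ld") max(r2, na.rm = TRUE) else min(r2, na.rm = TRUE)
    stopf("no SNP pair qualifies for %s (best available r^2 = %.3f)",
          ld_mode, ext)
  }
  pick <- with_seed(seed, ok[sample.int(nrow(ok), 1), ])
  ids[poly[sort(pick)]]
}

#' Genetic value under a genetic architecture
#'
#' Additive architectures take the dosage-weighted sum `g = sum_j w_j G_j`
#' with weights drawn N(0, 1) under the seed. The non-additive rules use the
#' carrier indicator `c_j = (dosage_j >= 1)`: `single` is `c1`, `epistatic`
#' requires both carriers (`c1 * c2`), `heterogeneous` either carrier
#' (`max(c1, c2)`), and `compensatory` exactly one carrier (`c1 XOR c2`,
#' the two effects cancelling when both SNPs carry the variant).
#'
#' @param G_causal Dosage matrix of the causal SNPs only (samples x causal).
#' @param architecture Architecture name (see [sim_scenario()]).
#' @param seed Seed for the additive weight draw.
#' @return List with `g` (per-sample genetic value) and `effect_spec`
#'   (the additive weights, or the Boolean rule name).
#' @export
genetic_value <- function(G_causal, architecture = .architectures, seed = 1) {
  architecture <- match.arg(architecture)
  G_causal <- .as_dosage_matrix(G_causal)
  need <- .n_causal_of[[architecture]]
  if (ncol(G_causal) != need) {
    stopf("architecture %s needs %d causal SNPs, got %d",
          architecture, need, ncol(G_causal))
  }
  if (grepl("^additive", architecture)) {
    w <- with_seed(seed, stats::rnorm(need))
    return(list(g = as.numeric(G_causal %*% w), effect_spec = w))
  }
  carrier <- (G_causal >= 1) * 1
  g <- switch(architecture,
    single = carrier[, 1],
    epistatic = carrier[, 1] * carrier[, 2],
    heterogeneous = pmax(carrier[, 1], carrier[, 2]),
    compensatory = as.numeric(xor(carrier[, 1] == 1, carrier[, 2] == 1))
  )
  list(g = as.numeric(g), effect_spec = architecture)
}

#' Add environmental noise at a target heritability
#'
#' Treats the empirical variance of `g` as the genetic variance
#' `sigma_g^2`, sets the environmental variance to
#' `sigma_e^2 = sigma_g^2 (1 - h2) / h2` so that
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`, and returns
#' `x = g + e`, `e ~ N(0, sigma_e^2)` iid. `h2 = 1` returns `g` exactly.
#'
#' @param g Genetic value vector with positive variance.
#' @param h2 Target heritability in `(0, 1]`.
#' @param seed Integer seed.
#' @return List with `x` and `spec`, a `heritability_spec` holding
#'   `sigma_g2`, `sigma_e2`, `sigma_p2 = sigma_g2 + sigma_e2` and `h2`.
#' @export
add_environmental_noise <- function(g, h2, seed = 1) {
  g <- as.numeric(g)
  if (h2 <= 0 || h2 > 1) stopf("h2 must lie in (0, 1]")
  sigma_g2 <- stats::var(g)
  if (sigma_g2 == 0) stopf("zero genetic variance: reselect causal SNPs")
  sigma_e2 <- sigma_g2 * (1 - h2) / h2
  x <- if (h2 == 1) g else g + with_seed(seed, stats::rnorm(length(g), 0, sqrt(sigma_e2)))
  list(x = x,
       spec = structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                             sigma_p2 = sigma_g2 + sigma_e2, h2 = h2),
                        class = "heritability_spec"))
}

#' Binarize a liability vector at a prevalence threshold
#'
#' Cases are the `floor(n * prevalence)` samples with the largest liability
#' (liability strictly above the empirical `1 - prevalence` quantile; ties
#' broken by first occurrence). Deterministic.
#'
#' @param liability Numeric liability vector.
#' @param prevalence Target case fraction in `(0, 1)`.
#' @return Integer 0/1 vector.
#' @export
binarize_liability <- function(liability, prevalence) {
  liability <- as.numeric(liability)
  if (prevalence <= 0 || prevalence >= 1) stopf("prevalence must lie in (0, 1)")
  n <- length(liability)
  if (length(unique(liability)) == 1) stopf("degenerate liability: all values equal")
  k <- max(1L, as.integer(floor(n * prevalence)))
  rk <- rank(-liability, ties.method = "first")
  as.integer(rk <= k)
}

#' Simulate one gene's PDUI and phenotype under a scenario
#'
#' Causal SNPs are selected in the gene's cis window and combined into a
#' genetic value `g` by the scenario's architecture. Under *pleiotropy*,
#' PDUI and phenotype are two independently noised copies of the same `g`
#' (`h2_apa` and `h2_pheno` respectively). Under *causality*, PDUI is the
#' noised `g` and the phenotype is the noised PDUI: each stage of the
#' genotype -> PDUI -> phenotype chain receives its own heritability, the
#' realized PDUI acting as the genetic value of the phenotype stage. Binary
#' traits binarize the continuous liability at the scenario prevalence.
#'
#' When the drawn causal set yields a constant `g` (e.g. every sample a
#' carrier), the selection is retried with a fresh derived seed, up to 25
#' attempts.
#'
#' @param scenario A [sim_scenario()].
#' @param gm A [genotype_matrix()] without missing calls.
#' @param region Optional [gene_region()] restricting causal selection.
#' @return A `sim_dataset` list: `genotypes`, `pdui` (per-sample vector),
#'   `phenotype`, `liability` (binary traits only), `causal_snp_ids`,
#'   `heritability` (per-stage `heritability_spec`s), `scenario`.
#' @export
simulate_dataset <- function(scenario, gm, region = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (nrow(gm$dosages) != scenario$n_samples) {
    stopf("genotype matrix has %d samples, scenario expects %d",
          nrow(gm$dosages), scenario$n_samples)
  }
  seed <- scenario$seed
  g <- NULL
  for (attempt in seq_len(25)) {
    sel_seed <- child_seed(seed, 100 + attempt)
    causal <- select_causal_snps(gm, region, scenario$n_causal,
                                 scenario$ld_mode, seed = sel_seed)
    gv <- genetic_value(gm$dosages[, causal, drop = FALSE],
                        scenario$architecture,
                        seed = child_seed(seed, 200 + attempt))
    if (stats::var(gv$g) > 0) { g <- gv$g; break }
  }
  if (is.null(g)) {
    stopf("could not draw a causal set with non-constant genetic value")
  }
  apa <- add_environmental_noise(g, scenario$h2_apa, seed = child_seed(seed, 301))
  pdui <- apa$x
  if (scenario$assumption == "pleiotropy") {
    ph <- add_environmental_noise(g, scenario$h2_pheno, seed = child_seed(seed, 302))
  } else {
    ph <- add_environmental_noise(pdui, scenario$h2_pheno, seed = child_seed(seed, 303))
  }
  liability <- ph$x
  phenotype <- if (scenario$trait_type == "binary") {
    binarize_liability(liability, scenario$prevalence)
  } else {
    liability
  }
  structure(list(genotypes = gm, pdui = pdui, phenotype = phenotype,
                 liability = if (scenario$trait_type == "binary") liability else NULL,
                 causal_snp_ids = causal,
                 heritability = list(apa = apa$spec, pheno = ph$spec),
                 scenario = scenario),
            class = "sim_dataset")
}

#' Pure-null transcriptome/phenotype draws
#'
#' For each gene, both the per-sample transcriptome surrogate (PDUI stand-in)
#' and the phenotype are iid N(0, 1), independent of any genotype -- the
#' design used to calibrate type-I error.
#'
#' @param n_genes Number of genes.
#' @param n_samples Samples per gene.
#' @param seed Integer seed.
#' @return List of length `n_genes`; each element is a list with
#'   `transcriptome` and `phenotype` vectors.
#' @export
simulate_null_dataset <- function(n_genes, n_samples, seed = 1) {
  stopifnot(n_genes >= 1, n_samples >= 1)
  with_seed(seed, {
    lapply(seq_len(n_genes), function(i) {
      list(transcriptome = stats::rnorm(n_samples),
           phenotype = stats::rnorm(n_samples))
    })
  })
}
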
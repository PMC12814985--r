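# Experiment drivers: scenario grids, per-gene pipeline, power and
# type-I-error summaries.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error target in `(0, 1)`.
#' @param m Number of tests (genes), `>= 1`.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stopf("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  alpha / m
}

#' Statistical power over a set of gene p-values
#'
#' Power is the fraction of genes detected: p-values strictly below the
#' threshold, divided by the total number of genes. `NA` p-values (genes
#' whose test was undefined, e.g. all-zero weights in the linear baseline)
#' count as not detected but stay in the denominator.
#'
#' @param p_values Vector of per-gene p-values.
#' @param threshold Detection threshold (e.g. [bonferroni_threshold()]).
#' @return List: `n_genes`, `n_detected`, `power`, `threshold_used`.
#' @export
compute_power <- function(p_values, threshold) {
  if (length(p_values) == 0) stopf("no p-values supplied")
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stopf("p-values outside [0, 1]")
  }
  det <- sum(p_values < threshold, na.rm = TRUE)
  list(n_genes = length(p_values), n_detected = det,
       power = det / length(p_values), threshold_used = threshold)
}

#' Empirical significance cutoff from null p-values
#'
#' Ranks the null p-values ascending and returns the value at rank
#' `ceiling(top_fraction * N)` -- the boundary of the most significant
#' `top_fraction` of the null distribution.
#'
#' @param p_values_null Null-simulation p-values.
#' @param top_fraction Fraction retained as significant; default 0.05.
#' @return The cutoff p-value.
#' @export
empirical_cutoff <- function(p_values_null, top_fraction = 0.05) {
  p <- p_values_null[!is.na(p_values_null)]
  if (length(p) == 0) stopf("no null p-values supplied")
  sort(p)[ceiling(top_fraction * length(p))]
}

#' Empirical type-I-error rate
#'
#' @param p_values_null Null-simulation p-values.
#' @param alpha Nominal level; default 0.05.
#' @return Fraction of null p-values strictly below `alpha`.
#' @export
type1_error_rate <- function(p_values_null, alpha = 0.05) {
  p <- p_values_null[!is.na(p_values_null)]
  if (length(p) == 0) stopf("no null p-values supplied")
  mean(p < alpha)
}

#' Read an experiment configuration file
#'
#' YAML with keys `assumption`, `architectures`, `h2_pheno`, `h2_apa`,
#' `trait_type`, `prevalence`, `ld_mode`, `n_samples`, `n_genes`, `n_snps`,
#' `seed`. Two grids matching the shipped study design are installed under
#' `system.file("extdata", ..., package = "kaptwas")`:
#' `pleiotropy_grid.yaml` (7 architectures x 6 x 6 heritabilities, 252
#' cells) and `causality_grid.yaml` (7 x 5 x 5, 175 cells).
#'
#' @param path Path to the YAML file.
#' @return Named list of configuration values.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  needed <- c("assumption", "architectures", "h2_pheno", "h2_apa",
              "n_samples", "n_genes", "n_snps", "seed")
  miss <- setdiff(needed, names(cfg))
  if (length(miss) > 0) stopf("config is missing keys: %s", paste(miss, collapse = ", "))
  cfg$trait_type <- cfg$trait_type %||% "quantitative"
  cfg$prevalence <- cfg$prevalence %||% 0.5
  cfg$ld_mode <- cfg$ld_mode %||% "random"
  cfg
}

#' Expand a configuration into its scenario grid
#'
#' Full crossing of architectures by phenotype heritabilities by APA
#' heritabilities, one row per scenario cell.
#'
#' @param config List from [read_experiment_config()] (or assembled by hand).
#' @return Data frame with columns `assumption`, `architecture`, `h2_pheno`,
#'   `h2_apa`, `trait_type`, `ld_mode` and a `cell` index.
#' @export
expand_scenario_grid <- function(config) {
  grid <- expand.grid(architecture = config$architectures,
                      h2_pheno = config$h2_pheno,
                      h2_apa = config$h2_apa,
                      stringsAsFactors = FALSE)
  grid$assumption <- config$assumption
  grid$trait_type <- config$trait_type %||% "quantitative"
  grid$ld_mode <- config$ld_mode %||% "random"
  grid$cell <- seq_len(nrow(grid))
  grid[, c("cell", "assumption", "architecture", "h2_pheno", "h2_apa",
           "trait_type", "ld_mode")]
}

#' Full per-gene analysis: train weights, run both tests
#'
#' Trains the four weight models on `(G, pdui)`, selects the best by CV
#' R-squared, then runs the kernel test on the phenotype and the linear
#' weighted z-score baseline on marginal GWAS z-scores computed from the
#' same cohort with the cohort LD matrix as reference.
#'
#' @param G Genotype slice (matrix or [genotype_matrix()]).
#' @param pdui PDUI (or transcriptome surrogate) vector.
#' @param y Phenotype vector.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param kernel Kernel kind for the kernel test.
#' @param gene_id Identifier for the result rows.
#' @param seed Integer seed (fold assignment).
#' @param small_sample Null-variance treatment of the kernel test (see
#'   [mixture_chisq_pvalue()]).
#' @return Two-row `association_result` data frame (methods `kernel` and
#'   `linear`; the linear row has `p_value = NA` when all weights are zero).
#' @export
run_gene_analysis <- function(G, pdui, y, trait_type = "quantitative",
                              kernel = "weighted_linear", gene_id = "gene",
                              seed = 1, small_sample = FALSE) {
  model <- train_gene_model(G, pdui, gene_id = gene_id, seed = seed)
  spec <- suppressWarnings(build_weight_matrix(model))
  best <- model$fits[[model$best_method]]
  mafs <- if (inherits(G, "genotype_matrix")) G$variants$maf else NULL
  kr <- suppressWarnings(
    apa_kernel_test(G, spec, y, trait_type = trait_type, kind = kernel,
                    mafs = mafs, small_sample = small_sample,
                    gene_id = gene_id)
  )
  lr <- if (spec$all_zero) {
    .assoc_row(gene_id, length(spec$weights), "linear", NA_character_,
               NA_real_, NA_real_, "degenerate")
  } else {
    z <- gwas_z_scores(G, y)
    apa_linear_test(spec, z, ld_matrix(G), gene_id = gene_id)
  }
  out <- rbind(kr, lr)
  out$best_method <- model$best_method
  out$cv_r2 <- best$cv_r2
  out
}

#' Type-I-error study on the pure-null design
#'
#' For each gene: simulate an independent genotype matrix, draw the
#' transcriptome surrogate and phenotype iid N(0, 1) (no genetic component),
#' train the weight models on the transcriptome, and run both the kernel
#' test and the linear baseline against the null phenotype. Reports the
#' rejection rate of each method at `alpha`.
#'
#' @param n_genes Number of null genes.
#' @param n_samples Samples per gene.
#' @param n_snps SNPs per gene.
#' @param alpha Nominal level; default 0.05.
#' @param maf_spec,ld_rho Genotype generator settings (see
#'   [simulate_genotypes()]).
#' @param kernel Kernel kind for the kernel test.
#' @param seed Integer seed.
#' @return List: `rate_kernel`, `rate_linear`, `n_genes`, `alpha`, and the
#'   per-gene p-value vectors `p_kernel`, `p_linear`.
#' @export
type1_error_study <- function(n_genes, n_samples, n_snps, alpha = 0.05,
                              maf_spec = c(0.05, 0.5), ld_rho = 0.2,
                              kernel = "weighted_linear", seed = 1) {
  nulls <- simulate_null_dataset(n_genes, n_samples, seed = child_seed(seed, 1))
  p_kernel <- rep(NA_real_, n_genes)
  p_linear <- rep(NA_real_, n_genes)
  for (i in seq_len(n_genes)) {
    gm <- simulate_genotypes(n_samples, n_snps, maf_spec = maf_spec,
                             ld_rho = ld_rho, seed = child_seed(seed, 10000 + i))
    res <- run_gene_analysis(gm, nulls[[i]]$transcriptome, nulls[[i]]$phenotype,
                             gene_id = sprintf("null%d", i), kernel = kernel,
                             seed = child_seed(seed, 20000 + i))
    p_kernel[i] <- res$p_value[res$method == "kernel"]
    p_linear[i] <- res$p_value[res$method == "linear"]
  }
  list(rate_kernel = type1_error_rate(p_kernel, alpha),
       rate_linear = type1_error_rate(stats::na.omit(p_linear), alpha),
       n_genes = n_genes, alpha = alpha,
       p_kernel = p_kernel, p_linear = p_linear)
}

#' Power study for one scenario cell
#'
#' Simulates `n_genes` genes under the scenario (fresh genotypes per gene),
#' runs the full per-gene pipeline, and scores power for both methods at a
#' Bonferroni threshold `alpha / n_genes`.
#'
#' @param scenario A [sim_scenario()] (its seed drives the whole cell).
#' @param n_genes Genes per cell.
#' @param n_snps SNPs per gene.
#' @param alpha Family-wise level fed to [bonferroni_threshold()].
#' @param maf_spec,ld_rho Genotype generator settings.
#' @param kernel Kernel kind.
#' @return Data frame with one row per method: scenario descriptors,
#'   `method`, `n_genes`, `n_detected`, `power`, `threshold_used`.
#' @export
power_study <- function(scenario, n_genes, n_snps, alpha = 0.05,
                        maf_spec = c(0.05, 0.5), ld_rho = 0.2,
                        kernel = "weighted_linear") {
  stopifnot(inherits(scenario, "sim_scenario"))
  thr <- bonferroni_threshold(alpha, n_genes)
  p_kernel <- rep(NA_real_, n_genes)
  p_linear <- rep(NA_real_, n_genes)
  for (i in seq_len(n_genes)) {
    gseed <- child_seed(scenario$seed, 30000 + i)
    gm <- simulate_genotypes(scenario$n_samples, n_snps, maf_spec = maf_spec,
                             ld_rho = ld_rho, seed = gseed)
    sc_i <- scenario
    sc_i$seed <- child_seed(scenario$seed, 40000 + i)
    ds <- simulate_dataset(sc_i, gm)
    res <- run_gene_analysis(gm, ds$pdui, ds$phenotype,
                             trait_type = scenario$trait_type,
                             gene_id = sprintf("gene%d", i), kernel = kernel,
                             seed = child_seed(scenario$seed, 50000 + i))
    p_kernel[i] <- res$p_value[res$method == "kernel"]
    p_linear[i] <- res$p_value[res$method == "linear"]
  }
  rows <- lapply(list(kernel = p_kernel, linear = p_linear), function(p) {
    pw <- compute_power(p, thr)
    data.frame(n_genes = pw$n_genes, n_detected = pw$n_detected,
               power = pw$power, threshold_used = pw$threshold_used)
  })
  out <- cbind(
    data.frame(assumption = scenario$assumption,
               architecture = scenario$architecture,
               h2_pheno = scenario$h2_pheno, h2_apa = scenario$h2_apa,
               trait_type = scenario$trait_type, ld_mode = scenario$ld_mode,
               n_samples = scenario$n_samples, seed = scenario$seed,
               method = names(rows), stringsAsFactors = FALSE),
    do.call(rbind, rows)
  )
  rownames(out) <- NULL
  out
}

#' Run a full simulation experiment from a configuration
#'
#' `mode = "power"`: expands the scenario grid and runs [power_study()] on
#' each cell (or the `cells` subset), emitting one row per cell and method.
#' `mode = "type1"`: runs [type1_error_study()] on the pure-null design.
#' Every row carries the scenario and seed, and a rerun with the same
#' configuration reproduces the output exactly.
#'
#' @param config List from [read_experiment_config()].
#' @param mode `"power"` or `"type1"`.
#' @param out_dir Optional directory; results are written as
#'   `results_<mode>.tsv` there.
#' @param cells Optional integer subset of grid cells to run.
#' @return The results data frame, invisibly when `out_dir` is given.
#' @export
run_experiment <- function(config, mode = c("power", "type1"),
                           out_dir = NULL, cells = NULL) {
  mode <- match.arg(mode)
  if (mode == "type1") {
    st <- type1_error_study(config$n_genes, config$n_samples, config$n_snps,
                            seed = config$seed)
    res <- data.frame(method = c("kernel", "linear"),
                      n_genes = config$n_genes,
                      type1_error = c(st$rate_kernel, st$rate_linear),
                      alpha = st$alpha, seed = config$seed)
  } else {
    grid <- expand_scenario_grid(config)
    if (!is.null(cells)) grid <- grid[grid$cell %in% cells, , drop = FALSE]
    res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
      row <- grid[k, ]
      sc <- sim_scenario(assumption = row$assumption,
                         architecture = row$architecture,
                         h2_pheno = row$h2_pheno, h2_apa = row$h2_apa,
                         trait_type = row$trait_type,
                         prevalence = config$prevalence %||% 0.5,
                         ld_mode = row$ld_mode,
                         n_samples = config$n_samples,
                         seed = child_seed(config$seed, row$cell))
      cbind(cell = row$cell,
            power_study(sc, n_genes = config$n_genes, n_snps = config$n_snps))
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, sprintf("results_%s.tsv", mode))
    utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}
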
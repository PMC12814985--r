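# Shared fixtures, all generated in code.

# Small integer dosage matrix with no missing calls and no constant column.
make_dosages <- function(n, p, seed = 1, maf = 0.3) {
  withr::with_seed(seed, {
    repeat {
      d <- matrix(rbinom(n * p, 2, maf), n, p,
                  dimnames = list(sprintf("s%d", 1:n), sprintf("snp%d", 1:p)))
      if (all(apply(d, 2, stats::sd) > 0)) return(d)
    }
  })
}

# Permutation p-value for the weighted linear kernel Q statistic. The
# rejection tail follows the kernel spectrum's orientation: when every
# eigenvalue is non-positive the signal tail is the lower one.
perm_pvalue <- function(G, w, y, B = 10000, seed = 1) {
  r <- y - mean(y)
  q <- sum(w * as.numeric(crossprod(G, r))^2)
  Gc <- sweep(G, 2, colMeans(G))
  lam <- Re(eigen(sweep(crossprod(Gc), 2, w, "*"), only.values = TRUE)$values)
  withr::with_seed(seed, {
    S <- crossprod(G, replicate(B, sample(r)))
  })
  qb <- colSums(w * S^2)
  p <- if (max(lam) <= 0) mean(qb <= q) else mean(qb >= q)
  list(p = p, q = q, B = B)
}

# Marginal single-variant score test: z = g'r / sqrt(v * gc'gc), p from N(0,1).
score_test_p <- function(g, y) {
  r <- y - mean(y)
  gc <- g - mean(g)
  v <- stats::var(y)
  z <- sum(gc * r) / sqrt(v * sum(gc^2))
  2 * stats::pnorm(-abs(z))
}
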
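# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force / closed form, never by calling the package
# functions they check.

# element-by-element TBV summation
oracle_tbv <- function(dosages, effects) {
  out <- numeric(nrow(dosages))
  for (i in seq_len(nrow(dosages))) {
    s <- 0
    for (j in seq_len(ncol(dosages))) s <- s + dosages[i, j] * effects[j]
    out[i] <- s
  }
  out
}

# VanRaden method-1 G by an explicit double loop
oracle_grm <- function(dosages) {
  p <- colMeans(dosages) / 2
  keep <- which(p > 0 & p < 1)
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  n <- nrow(dosages)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in keep) {
        acc <- acc + (dosages[i, k] - 2 * p[k]) * (dosages[j, k] - 2 * p[k])
      }
      G[i, j] <- acc / denom
    }
  }
  G
}

# dense GLS / BLUP closed form: b = (X'V^-1X)^-1 X'V^-1 y,
# u = sigma_a2 K Z' V^-1 (y - Xb), h = sigma_h2 W' V^-1 (y - Xb)
oracle_gls <- function(y, X, Z, K, vc, W = NULL) {
  V <- vc$sigma_a2 * Z %*% K %*% t(Z) + diag(vc$sigma_e2, length(y))
  if (!is.null(W)) V <- V + vc$sigma_h2 * W %*% t(W)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  u <- vc$sigma_a2 * K %*% t(Z) %*% Vi %*% r
  h <- if (is.null(W)) NULL else vc$sigma_h2 * t(W) %*% Vi %*% r
  list(b = drop(b), u = drop(u), h = if (is.null(h)) NULL else drop(h))
}

# random topologically ordered pedigree with `n_founders` unrelated animals
random_pedigree <- function(n, n_founders = 10) {
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    sire[i] <- sample.int(i - 1L, 1L)
    dam[i] <- sample.int(i - 1L, 1L)
  }
  tibble::tibble(id = seq_len(n), sire = sire, dam = dam)
}

# a population small enough for exhaustive checks, built through the
# package's own constructors (fixture, not oracle)
micro_config <- function(lambdas = 1, seed_genome = NULL) {
  study_config(
    genome = genome_spec(n_chromosomes = 2, n_founders = 80,
                         sites_per_chr = 150, seed = seed_genome),
    design = breeding_design(
      burn_in = list(n_generations = 2, n_sires = 10, n_dams = 40,
                     n_offspring = 80),
      evaluation = list(n_generations = 3, n_sires = 20, n_dams = 80,
                        n_offspring = 160),
      n_training = 80),
    n_snp_per_chr = 50, n_qtl_per_chr = 25,
    lambdas = lambdas, pedigree_depth = 3)
}
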
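test_that("founder panels are deterministic under a fixed seed", {
  sp <- genome_spec(n_chromosomes = 2, n_founders = 25, sites_per_chr = 100,
                    seed = 7)
  p1 <- simulate_founder_haplotypes(sp)
  p2 <- simulate_founder_haplotypes(sp)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$site_map, p2$site_map)
})

test_that("panels satisfy the segregating-site and map invariants", {
  sp <- genome_spec(n_chromosomes = 3, n_founders = 30, sites_per_chr = 80,
                    seed = 11)
  p <- simulate_founder_haplotypes(sp)
  expect_equal(nrow(p$alleles), 2 * sp$n_founders)
  freq <- colMeans(p$alleles)
  expect_true(all(freq > 0 & freq < 1))           # no fixed columns
  by_chr <- split(p$site_map$pos, p$site_map$chr)
  expect_true(all(vapply(by_chr, function(x) all(diff(x) > 0), logical(1))))
  expect_true(all(vapply(by_chr, length, integer(1)) >= sp$sites_per_chr))
})

test_that("segregating-site counts match Watterson's expectation", {
  # small constant-Ne sample; E[S] = theta * sum(1/i) is recombination-free
  n_hap <- 12
  theta <- 4
  withr::with_seed(31, {
    S <- replicate(150, {
      ncol(smallherd:::.smc_chromosome(n_hap, 30L, 1, 300, theta)$alleles)
    })
  })
  expected <- expected_segregating_sites(n_hap, theta)
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))
})

test_that("an unreachable site target fails with a chromosome diagnostic", {
  sp <- genome_spec(n_chromosomes = 1, n_founders = 10, sites_per_chr = 500)
  expect_error(
    simulate_founder_haplotypes(sp, theta = 0.5, seed = 3, max_tries = 2),
    "chromosome 1")
})

test_that("locus selection gives exact disjoint per-chromosome sets", {
  sp <- genome_spec(n_chromosomes = 2, n_founders = 40, sites_per_chr = 120,
                    seed = 19)
  p <- simulate_founder_haplotypes(sp)
  loci <- select_loci(p, n_snp_per_chr = 70, n_qtl_per_chr = 20, seed = 4)
  expect_length(loci$snp, 140)
  expect_length(loci$qtl, 40)
  expect_length(intersect(loci$snp, loci$qtl), 0)
  per_chr <- table(p$site_map$chr[loci$snp])
  expect_true(all(per_chr == 70))
  expect_true(all(c(loci$snp, loci$qtl) %in% p$site_map$site))
})

test_that("locus selection handles the exhaustive case and shortages", {
  sp <- genome_spec(n_chromosomes = 1, n_founders = 20, sites_per_chr = 60,
                    seed = 23)
  p <- simulate_founder_haplotypes(sp)
  all_sites <- nrow(p$site_map)
  loci <- select_loci(p, n_snp_per_chr = all_sites, n_qtl_per_chr = 0)
  expect_setequal(loci$snp, p$site_map$site)
  expect_error(select_loci(p, n_snp_per_chr = all_sites, n_qtl_per_chr = 1),
               "chromosome 1")
})
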
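test_that("tabular A reproduces textbook pedigrees including inbreeding", {
  # unrelated founders
  ped0 <- tibble::tibble(id = 1:2, sire = 0, dam = 0)
  expect_equal(unclass(nrm(ped0)), diag(2), ignore_attr = TRUE)
  # one known parent
  ped1 <- tibble::tibble(id = 1:2, sire = c(0, 1), dam = c(0, 0))
  A1 <- nrm(ped1)
  expect_equal(A1[1, 2], 0.5)
  expect_equal(diag(unclass(A1)), c(1, 1), ignore_attr = TRUE)
  # offspring of two full sibs: F = 0.25, diagonal 1.25
  ped2 <- tibble::tibble(id = 1:5, sire = c(0, 0, 1, 1, 3),
                         dam = c(0, 0, 2, 2, 4))
  A2 <- nrm(ped2)
  expect_equal(A2[3, 4], 0.5)
  expect_equal(A2[5, 5], 1.25)
  expect_equal(inbreeding(ped2)[["5"]], 0.25)
  # order violations are rejected
  expect_error(nrm(tibble::tibble(id = 1:2, sire = c(2, 0), dam = 0)),
               "topologically")
})

test_that("the sparse A-inverse inverts the tabular A", {
  ped0 <- tibble::tibble(id = 1:4, sire = 0, dam = 0)
  expect_equal(as.matrix(nrm_inverse(ped0)), diag(4), ignore_attr = TRUE)
  withr::with_seed(5, {
    ped <- random_pedigree(50)
    A <- unclass(nrm(ped))
    Ai <- nrm_inverse(ped)
    expect_lt(max(abs(as.matrix(Ai %*% A) - diag(50))), 1e-8)
    # structural sparsity: non-zeros only within animal-parent families
    allowed <- diag(50) > 0
    for (i in 1:50) {
      fam <- c(i, ped$sire[i], ped$dam[i])
      fam <- fam[fam > 0]
      allowed[fam, fam] <- TRUE
    }
    expect_true(all(as.matrix(Ai != 0) <= allowed))
  })
})

test_that("G matches the worked example and a brute-force double loop", {
  G3 <- grm(matrix(c(0, 1, 2), ncol = 1))
  expect_equal(unclass(G3),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3),
               ignore_attr = TRUE)
  withr::with_seed(13, {
    p <- runif(100, 0.05, 0.95)
    dos <- sapply(p, function(pp) rbinom(20, 2, pp))
    G <- grm(dos)
    expect_lt(max(abs(unclass(G) - oracle_grm(dos))), 1e-10)
    expect_equal(mean(diag(unclass(G))), 1, tolerance = 0.05)
  })
  # identical genotypes produce identical rows with g_ij = g_ii
  dos2 <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  G2 <- unclass(grm(dos2))
  expect_equal(G2[1, ], G2[2, ], ignore_attr = TRUE)
  expect_equal(G2[1, 2], G2[1, 1])
  expect_error(grm(matrix(2, 4, 3)), "monomorphic")
})

test_that("mean genomic relationship of half sibs approaches 0.25", {
  # build half-sib families with the package's own meiosis over a founder
  # panel, then check E[g_ij] ~ a_ij = 0.25
  withr::with_seed(21, {
    sp <- genome_spec(n_chromosomes = 2, n_founders = 150,
                      sites_per_chr = 250)
    panel <- simulate_founder_haplotypes(sp)
    loci <- select_loci(panel, n_snp_per_chr = 200, n_qtl_per_chr = 10)
    map <- smallherd:::build_locus_map(panel, loci)
    hap <- panel$alleles[, map$sites]
    n_fam <- 49
    off <- matrix(0L, 2 * n_fam, length(map$snp_cols))
    for (f in seq_len(n_fam)) {
      rows <- (3 * f - 2):(3 * f)   # sire, dam1, dam2
      sire_h <- hap[c(2 * rows[1] - 1, 2 * rows[1]), ]
      for (k in 1:2) {
        dam_h <- hap[c(2 * rows[1 + k] - 1, 2 * rows[1 + k]), ]
        gam_s <- meiosis(sire_h[1, ], sire_h[2, ], map)
        gam_d <- meiosis(dam_h[1, ], dam_h[2, ], map)
        off[2 * f - 2 + k, ] <- (gam_s + gam_d)[map$snp_cols]
      }
    }
    G <- unclass(grm(off))
    gij <- vapply(seq_len(n_fam), function(f) G[2 * f - 1, 2 * f],
                  numeric(1))
    se <- sd(gij) / sqrt(n_fam)
    expect_lt(abs(mean(gij) - 0.25), 3 * se + 0.02)
  })
})
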
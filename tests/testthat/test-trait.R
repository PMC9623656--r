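test_that("variance components close the ratio algebra", {
  vc <- variance_components(h2 = 0.1, herd_ratio = 0.4, sigma_a2 = 0.2)
  expect_equal(vc$sigma_p2, 2.0)
  expect_equal(vc$sigma_h2, 0.8)
  expect_equal(vc$sigma_e2, 1.0)
  vc2 <- variance_components(h2 = 0.5, herd_ratio = 0, sigma_a2 = 1)
  expect_equal(vc2$sigma_h2, 0)
  expect_equal(vc2$sigma_e2, 1)
  expect_error(variance_components(h2 = 0.6, herd_ratio = 0.5),
               "infeasible")
})

test_that("QTL effects are scaled to the exact founder TBV variance", {
  withr::with_seed(17, {
    dos <- matrix(sample(0:2, 300 * 40, replace = TRUE), nrow = 300)
    arch <- sample_qtl_effects(dos, sigma_a2 = 0.2)
    expect_equal(var(compute_tbv(dos, arch)), 0.2, tolerance = 1e-12)
    # scale invariance of the raw draw
    raw <- rnorm(40)
    a1 <- scale_qtl_effects(raw, dos, sigma_a2 = 0.2)
    a2 <- scale_qtl_effects(3 * raw, dos, sigma_a2 = 0.2)
    expect_equal(a1$effects, a2$effects)
  })
  # one QTL with dosages 0/1/2 equally frequent: effect = sqrt(target/var)
  dos1 <- matrix(c(0, 1, 2), ncol = 1)
  a <- scale_qtl_effects(1, dos1, sigma_a2 = 0.2)
  expect_equal(abs(a$effects), sqrt(0.2 / var(c(0, 1, 2))))
  expect_error(scale_qtl_effects(1, matrix(1L, 5, 1), sigma_a2 = 0.2),
               "variance")
})

test_that("TBV equal the brute-force summation and are linear", {
  withr::with_seed(23, {
    dos <- matrix(sample(0:2, 15, replace = TRUE), nrow = 5)
    arch <- structure(list(effects = rnorm(3), intercept = 0, sigma_a2 = 1),
                      class = "trait_architecture")
    expect_equal(compute_tbv(dos, arch), oracle_tbv(dos, arch$effects))
  })
  arch1 <- structure(list(effects = 0.7, intercept = 0, sigma_a2 = 1),
                     class = "trait_architecture")
  expect_equal(compute_tbv(matrix(0, 4, 1), arch1), rep(0, 4))
  expect_equal(compute_tbv(matrix(2, 1, 1), arch1),
               2 * compute_tbv(matrix(1, 1, 1), arch1))
  expect_error(compute_tbv(matrix(0, 2, 2), arch1), "number of QTL")
})

test_that("phenotypes decompose into the nominal variance fractions", {
  vc <- variance_components()
  # no noise: y reproduces tbv exactly
  vc0 <- variance_components(h2 = 0.999, herd_ratio = 0, sigma_a2 = 0.2)
  vc0$sigma_e2 <- 0
  tbv <- c(-1, 0, 2)
  expect_equal(simulate_phenotype(tbv, rep(0, 3), vc0, seed = 1), tbv)
  # full-scale ratios within Monte-Carlo error
  withr::with_seed(41, {
    n <- 40000
    tbv <- rnorm(n, 0, sqrt(vc$sigma_a2))
    herd <- rnorm(n, 0, sqrt(vc$sigma_h2))
    y <- simulate_phenotype(tbv, herd, vc)
    expect_equal(var(tbv) / var(y), 0.1, tolerance = 0.03)
    expect_equal(var(herd) / var(y), 0.4, tolerance = 0.03)
  })
})
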
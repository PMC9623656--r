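identity_kernel <- function(n) {
  K <- diag(n)
  dimnames(K) <- list(1:n, 1:n)
  K
}

test_that("intercept-plus-identity MME reduces to the ridge closed form", {
  withr::with_seed(2, {
    n <- 12
    y <- rnorm(n, mean = 5)
    vc <- variance_components(h2 = 0.2, herd_ratio = 0.1, sigma_a2 = 1)
    fit <- solve_mme(build_mme(y, 1:n, herd = NULL,
                               kernel_inverse = identity_kernel(n),
                               vc = vc, herd_model = "none"))
    k <- vc$sigma_a2 / (vc$sigma_a2 + vc$sigma_e2)
    expect_equal(fit$b$estimate, mean(y))
    expect_equal(fit$u$ebv, k * (y - mean(y)))
  })
})

test_that("breeding values shrink to zero as sigma_a2 vanishes", {
  withr::with_seed(3, {
    n <- 8
    y <- rnorm(n)
    vc <- variance_components(h2 = 0.3, herd_ratio = 0.1, sigma_a2 = 1)
    vc$sigma_a2 <- 1e-10   # lambda_a -> infinity
    fit <- solve_mme(build_mme(y, 1:n, herd = NULL,
                               kernel_inverse = identity_kernel(n),
                               vc = vc, herd_model = "none"))
    expect_lt(max(abs(fit$u$ebv)), 1e-8)
  })
})

test_that("MME and GLS routes equal the dense BLUP oracle", {
  vc <- variance_components(h2 = 0.25, herd_ratio = 0.3, sigma_a2 = 1)
  withr::with_seed(7, {
    for (rep in 1:8) {
      n <- sample(5:10, 1)
      M <- matrix(rnorm(n * 12), n)
      K <- tcrossprod(M) / 12 + diag(0.3, n)
      dimnames(K) <- list(1:n, 1:n)
      Kinv <- solve(K)
      dimnames(Kinv) <- dimnames(K)
      y <- rnorm(n)
      herd <- sample(c("h1", "h2"), n, replace = TRUE)
      herd[1:2] <- c("h1", "h2")
      Z <- diag(n)
      W <- cbind(as.numeric(herd == "h1"), as.numeric(herd == "h2"))
      for (hm in c("none", "fixed", "random")) {
        X <- matrix(1, n, 1)
        if (hm == "fixed") X <- cbind(X, as.numeric(herd == "h2"))
        ref <- oracle_gls(y, X, Z, K, vc,
                          W = if (hm == "random") W else NULL)
        f1 <- solve_mme(build_mme(y, 1:n, herd, Kinv, vc, hm))
        f2 <- solve_blup_gls(y, 1:n, herd, K, vc, hm)
        expect_lt(max(abs(f1$u$ebv - ref$u)), 1e-8)
        expect_lt(max(abs(f2$u$ebv - ref$u)), 1e-8)
        expect_lt(max(abs(f1$b$estimate - ref$b)), 1e-8)
        expect_lt(max(abs(f2$b$estimate - ref$b)), 1e-8)
        if (hm == "random") {
          expect_lt(max(abs(f1$h$effect - ref$h)), 1e-8)
          expect_lt(max(abs(f2$h$effect - ref$h)), 1e-8)
        }
      }
    }
  })
})

test_that("solutions are invariant to record ordering", {
  withr::with_seed(11, {
    n <- 9
    vc <- variance_components()
    K <- identity_kernel(n)
    y <- rnorm(n)
    herd <- sample(c("a", "b", "c"), n, replace = TRUE)
    f <- solve_mme(build_mme(y, 1:n, herd, K, vc, "random"))
    perm <- sample(n)
    fp <- solve_mme(build_mme(y[perm], (1:n)[perm], herd[perm], K, vc,
                              "random"))
    expect_equal(fp$u$ebv, f$u$ebv)
    expect_equal(fp$h$effect, f$h$effect)
  })
})

test_that("random-herd solutions approach fixed-herd solutions as sigma_h2 grows", {
  withr::with_seed(13, {
    n <- 10
    K <- identity_kernel(n)
    y <- rnorm(n)
    herd <- rep(c("a", "b"), each = 5)
    vc_fix <- variance_components(h2 = 0.2, herd_ratio = 0.2, sigma_a2 = 1)
    ffix <- solve_mme(build_mme(y, 1:n, herd, K, vc_fix, "fixed"))
    gaps <- vapply(c(1, 100, 1e6), function(s2h) {
      vc <- vc_fix
      vc$sigma_h2 <- s2h
      fr <- solve_mme(build_mme(y, 1:n, herd, K, vc, "random"))
      max(abs(fr$u$ebv - ffix$u$ebv))
    }, numeric(1))
    expect_true(all(diff(gaps) < 0))
    expect_lt(gaps[3], 1e-4)
  })
})

test_that("model structure follows the herd treatment", {
  n <- 6
  vc <- variance_components()
  y <- rnorm(n)
  herd <- rep(c("a", "b", "c"), 2)
  s_none <- build_mme(y, 1:n, herd, identity_kernel(n), vc, "none")
  expect_null(s_none$herd_levels)
  expect_equal(nrow(s_none$lhs), 1 + n)
  s_rand <- build_mme(y, 1:n, herd, identity_kernel(n), vc, "random")
  expect_equal(length(s_rand$herd_levels), 3)
  expect_equal(nrow(s_rand$lhs), 1 + n + 3)
  s_fix <- build_mme(y, 1:n, herd, identity_kernel(n), vc, "fixed")
  expect_equal(s_fix$fixed_names, c("(Intercept)", "herd:b", "herd:c"))
  expect_error(build_mme(y, 1:n, NULL, identity_kernel(n), vc, "random"),
               "herd")
})

test_that("fit_blup covers pedigree ancestors and exactly the genotyped cows", {
  withr::with_seed(17, {
    ped <- random_pedigree(30, n_founders = 8)
    cows <- 21:30
    training <- tibble::tibble(id = cows, herd_id = rep(1:2, 5),
                               phenotype = rnorm(10))
    vc <- variance_components()
    fp <- fit_blup(training, vc, method = "pblup", herd_model = "random",
                   pedigree = ped)
    expect_setequal(fp$u$id, as.character(1:30))   # ancestors included
    dos <- matrix(rbinom(10 * 60, 2, 0.4), nrow = 10,
                  dimnames = list(cows, NULL))
    fg <- fit_blup(training, vc, method = "gblup", herd_model = "random",
                   genotypes = dos)
    expect_setequal(fg$u$id, as.character(cows))
    expect_s3_class(tidy(fg), "tbl_df")
    expect_equal(nrow(glance(fg)), 1)
    expect_equal(glance(fg)$n_herds, 2L)
  })
})
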
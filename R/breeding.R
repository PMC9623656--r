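#' Breeding programme design
#'
#' The forward-simulation design: a burn-in phase of discrete generations of
#' selective breeding on phenotype (both sexes truncation-selected), followed
#' by an evaluation phase with weak genetic connectedness in which sires are
#' selected on phenotype and dams at random.  Defaults give the full-scale
#' study: 5 burn-in generations of 225 sires x 1,000 dams producing 2,000
#' offspring, then 6 evaluation generations of 1,000 sires and 8,000 dams
#' producing 16,000 offspring at an equal sex ratio, so the final generation
#' contains the 8,000 cows of the training population.
#'
#' @param burn_in List with `n_generations`, `n_sires`, `n_dams`,
#'   `n_offspring`.
#' @param evaluation List with `n_generations`, `n_sires`, `n_dams`,
#'   `n_offspring`.
#' @param n_training Number of phenotyped cows in the training population.
#' @return An object of class `breeding_design`.
#' @export
breeding_design <- function(
    burn_in = list(n_generations = 5, n_sires = 225, n_dams = 1000,
                   n_offspring = 2000),
    evaluation = list(n_generations = 6, n_sires = 1000, n_dams = 8000,
                      n_offspring = 16000),
    n_training = 8000) {
  for (ph in list(burn_in, evaluation)) {
    stopifnot(ph$n_generations >= 1, ph$n_sires >= 1, ph$n_dams >= 1,
              ph$n_offspring >= 2)
  }
  if (evaluation$n_offspring / 2 < n_training) {
    abort("evaluation phase cannot produce enough females for the training set")
  }
  structure(list(burn_in = lapply(burn_in, as.integer),
                 evaluation = lapply(evaluation, as.integer),
                 n_training = as.integer(n_training)),
            class = "breeding_design")
}

#' @export
print.breeding_design <- function(x, ...) {
  cat("<breeding_design> burn-in: ", x$burn_in$n_generations, " gen x ",
      x$burn_in$n_offspring, " offspring; evaluation: ",
      x$evaluation$n_generations, " gen x ", x$evaluation$n_offspring,
      " offspring; training set ", x$n_training, " cows\n", sep = "")
  invisible(x)
}

# Locus map over the selected (SNP + QTL) columns of the working haplotypes.
build_locus_map <- function(panel, loci) {
  sites <- sort(c(loci$snp, loci$qtl))
  sm <- panel$site_map[sites, ]
  chr <- sm$chr
  list(chr = chr, pos = sm$pos,
       chr_lengths = panel$chr_lengths,
       cols_by_chr = split(seq_along(chr), chr),
       sites = sites,
       snp_cols = match(sort(loci$snp), sites),
       qtl_cols = match(sort(loci$qtl), sites))
}

#' Simulate one meiosis
#'
#' Produces a gamete from a parent's two haplotypes.  Per chromosome the
#' crossover count is Poisson with mean equal to the map length in Morgans,
#' crossover positions are uniform, and the starting strand is chosen at
#' random; every gamete allele therefore equals one of the parent's two
#' alleles at that site.
#'
#' @param h1,h2 The parent's two haplotypes (0/1 vectors over the map loci).
#' @param map A locus map as stored in a [founder_population()] (fields
#'   `pos`, `chr_lengths`, `cols_by_chr`).
#' @param seed Optional integer seed.
#' @param detail If `TRUE`, attach the total crossover count as attribute
#'   `n_crossovers`.
#' @return A gamete haplotype vector.
#' @export
meiosis <- function(h1, h2, map, seed = NULL, detail = FALSE) {
  with_seed_maybe(seed, {
    gam <- h1
    nx_total <- 0L
    for (c in seq_along(map$chr_lengths)) {
      idx <- map$cols_by_chr[[c]]
      L <- map$chr_lengths[[c]]
      nx <- rpois(1L, L)
      strand0 <- sample.int(2L, 1L) - 1L
      if (nx > 0) {
        xo <- sort(runif(nx, 0, L))
        strand <- (strand0 + findInterval(map$pos[idx], xo)) %% 2L
      } else {
        strand <- rep(strand0, length(idx))
      }
      if (strand0 != 0L || nx > 0) {
        take2 <- strand == 1L
        seg <- h1[idx]
        seg[take2] <- h2[idx][take2]
        gam[idx] <- seg
      }
      nx_total <- nx_total + nx
    }
    if (detail) attr(gam, "n_crossovers") <- nx_total
    gam
  })
}

#' Truncation selection on phenotype
#'
#' Returns the `n` candidates with the highest phenotype, optionally after
#' filtering on sex; ties are broken by ascending id so selection is
#' deterministic.
#'
#' @param records Tibble with at least `id`, `phenotype` and (if `sex` is
#'   used) `sex` columns.
#' @param n Number to select.
#' @param sex Optional `"M"` or `"F"` filter.
#' @return The selected rows, ordered by descending phenotype.
#' @export
select_by_phenotype <- function(records, n, sex = NULL) {
  if (!is.null(sex)) records <- dplyr::filter(records, .data$sex == !!sex)
  if (nrow(records) < n) {
    abort(paste0("only ", nrow(records), " candidates available, ", n,
                 " requested"))
  }
  dplyr::slice_head(dplyr::arrange(records, dplyr::desc(.data$phenotype),
                                   .data$id), n = n)
}

#' Construct the founder population
#'
#' Builds the generation-0 population from a founder haplotype panel and a
#' locus selection: haplotypes are restricted to the selected SNP + QTL
#' loci, sexes are assigned at an exact 1:1 ratio, TBV are computed from the
#' trait architecture, and every founder receives one phenotype with an
#' individual (herd-of-one) environmental effect drawn from N(0, sigma_h2).
#'
#' @param panel A `haplotype_panel`.
#' @param loci A `loci_selection`.
#' @param arch A `trait_architecture` (see [sample_qtl_effects()]).
#' @param vc A [variance_components()] object.
#' @param seed Optional integer seed.
#' @return A `population`: list with `ped` (tibble of all simulated animals:
#'   `id`, `sire`, `dam`, `sex`, `generation`, `tbv`, `phenotype`), `hap`
#'   (haplotype matrix of the current generation, two rows per animal),
#'   `hap_ids`, `map`, `arch`, `vc`.
#' @export
founder_population <- function(panel, loci, arch, vc, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(loci, "loci_selection"),
            inherits(arch, "trait_architecture"),
            inherits(vc, "variance_components"))
  with_seed_maybe(seed, {
    map <- build_locus_map(panel, loci)
    hap <- panel$alleles[, map$sites, drop = FALSE]
    n <- panel$n_founders
    odd <- seq(1L, 2L * n, by = 2L)
    dos <- hap[odd, map$qtl_cols, drop = FALSE] +
      hap[odd + 1L, map$qtl_cols, drop = FALSE]
    tbv <- compute_tbv(dos, arch)
    sex <- sample(rep_len(c("M", "F"), n))
    herd_eff <- rnorm(n, 0, sqrt(vc$sigma_h2))
    ped <- tibble(id = seq_len(n), sire = 0L, dam = 0L, sex = sex,
                  generation = 0L, tbv = tbv,
                  phenotype = simulate_phenotype(tbv, herd_eff, vc,
                                                 intercept = arch$intercept))
    structure(list(ped = ped, hap = hap, hap_ids = seq_len(n), map = map,
                   arch = arch, vc = vc),
              class = "population")
  })
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", nrow(x$ped), " animals over generations ",
      min(x$ped$generation), "-", max(x$ped$generation), "; haplotypes held",
      " for generation ", max(x$ped$generation), "\n", sep = "")
  invisible(x)
}

# Drop one generation of offspring by gene dropping.  Sire and dam usage is
# balanced (each parent used floor/ceiling of its equal share), pairing is
# uniform random, sexes split exactly in half.
make_generation <- function(pop, sire_ids, dam_ids, n_offspring, generation,
                            phenotyped = TRUE) {
  map <- pop$map
  hap <- pop$hap
  row_of <- match(c(sire_ids, dam_ids), pop$hap_ids)
  if (anyNA(row_of)) abort("parent haplotypes are not available")
  sire_vec <- sample(rep_len(sire_ids, n_offspring))
  dam_vec <- sample(rep_len(dam_ids, n_offspring))
  new_hap <- matrix(0L, nrow = 2L * n_offspring, ncol = ncol(hap))
  for (i in seq_len(n_offspring)) {
    ks <- match(sire_vec[i], pop$hap_ids)
    kd <- match(dam_vec[i], pop$hap_ids)
    new_hap[2L * i - 1L, ] <- meiosis(hap[2L * ks - 1L, ], hap[2L * ks, ], map)
    new_hap[2L * i, ] <- meiosis(hap[2L * kd - 1L, ], hap[2L * kd, ], map)
  }
  odd <- seq(1L, 2L * n_offspring, by = 2L)
  dos <- new_hap[odd, map$qtl_cols, drop = FALSE] +
    new_hap[odd + 1L, map$qtl_cols, drop = FALSE]
  tbv <- compute_tbv(dos, pop$arch)
  ids <- max(pop$ped$id) + seq_len(n_offspring)
  sex <- sample(rep_len(c("M", "F"), n_offspring))
  if (phenotyped) {
    herd_eff <- rnorm(n_offspring, 0, sqrt(pop$vc$sigma_h2))
    phen <- simulate_phenotype(tbv, herd_eff, pop$vc,
                               intercept = pop$arch$intercept)
  } else {
    phen <- rep(NA_real_, n_offspring)
  }
  ped <- tibble(id = ids, sire = as.integer(sire_vec),
                dam = as.integer(dam_vec), sex = sex,
                generation = as.integer(generation), tbv = tbv,
                phenotype = phen)
  pop$ped <- dplyr::bind_rows(pop$ped, ped)
  pop$hap <- new_hap
  pop$hap_ids <- ids
  pop
}

#' Run the burn-in phase
#'
#' Discrete, non-overlapping generations of selective breeding on phenotype:
#' in every generation the top sires and top dams by phenotype are selected
#' from the previous generation and mated at random (balanced parent usage)
#' to produce the design's number of offspring.
#'
#' @param pop A [founder_population()].
#' @param design A [breeding_design()].
#' @param seed Optional integer seed.
#' @return The updated `population`, holding haplotypes of the last burn-in
#'   generation.
#' @export
run_burn_in <- function(pop, design, seed = NULL) {
  stopifnot(inherits(pop, "population"), inherits(design, "breeding_design"))
  d <- design$burn_in
  with_seed_maybe(seed, {
    for (g in seq_len(d$n_generations)) {
      gen <- max(pop$ped$generation)
      cand <- dplyr::filter(pop$ped, .data$generation == gen)
      sires <- select_by_phenotype(cand, d$n_sires, sex = "M")$id
      dams <- select_by_phenotype(cand, d$n_dams, sex = "F")$id
      pop <- make_generation(pop, sires, dams, d$n_offspring, gen + 1L)
    }
    pop
  })
}

#' Run the evaluation phase
#'
#' Continues the simulation for the design's evaluation generations: sires
#' are truncation-selected on phenotype from the previous generation's
#' males, dams are drawn at random from its females (all of them if fewer
#' than the design target are available), and offspring are produced at an
#' exact 1:1 sex ratio.  Animals of the final generation carry TBV but no
#' phenotype; their records are created when a training set is built with
#' [make_training_set()], because the phenotype depends on the herd
#' structure under study.
#'
#' @inheritParams run_burn_in
#' @return The updated `population`; haplotypes of the final generation are
#'   retained for genotyping.
#' @export
run_evaluation_phase <- function(pop, design, seed = NULL) {
  stopifnot(inherits(pop, "population"), inherits(design, "breeding_design"))
  d <- design$evaluation
  with_seed_maybe(seed, {
    for (g in seq_len(d$n_generations)) {
      gen <- max(pop$ped$generation)
      cand <- dplyr::filter(pop$ped, .data$generation == gen)
      sires <- select_by_phenotype(cand, d$n_sires, sex = "M")$id
      females <- dplyr::filter(cand, .data$sex == "F")$id
      dams <- if (length(females) > d$n_dams) {
        sample(females, d$n_dams)
      } else {
        females
      }
      final <- g == d$n_generations
      pop <- make_generation(pop, sires, dams, d$n_offspring, gen + 1L,
                             phenotyped = !final)
    }
    n_cows <- sum(pop$ped$generation == max(pop$ped$generation) &
                    pop$ped$sex == "F")
    if (n_cows < design$n_training) {
      abort(paste0("final generation has ", n_cows, " females but ",
                   design$n_training, " training cows are required"))
    }
    pop
  })
}

#' Build a training population with herd structure
#'
#' Randomly selects the training cows among the final-generation females,
#' samples herd sizes with the two-step procedure ([sample_herd_sizes()]),
#' assigns cows to herds at random, and simulates their milk-yield records
#' `y = tbv + herd_effect + e`.
#'
#' @param pop A `population` after [run_evaluation_phase()].
#' @param lambda Poisson mean of the herd-size distribution.
#' @param n_training Number of cows (default 8,000).
#' @param seed Optional integer seed.
#' @return A `training_set` tibble (`id`, `sire`, `dam`, `generation`,
#'   `herd_id`, `tbv`, `phenotype`) with attributes `herds` (tibble of herd
#'   sizes and effects), `lambda` and `mean_herd_size`.
#' @export
make_training_set <- function(pop, lambda, n_training = 8000, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  with_seed_maybe(seed, {
    gen <- max(pop$ped$generation)
    cows <- dplyr::filter(pop$ped, .data$generation == gen, .data$sex == "F")
    if (nrow(cows) < n_training) {
      abort("not enough final-generation cows for the training set")
    }
    cows <- dplyr::slice_sample(cows, n = n_training)
    sizes <- sample_herd_sizes(n_training, lambda)
    ha <- assign_cows_to_herds(cows$id, sizes, pop$vc)
    out <- dplyr::inner_join(cows, ha$assignment, by = "id")
    out <- dplyr::inner_join(out, ha$herds[, c("herd_id", "herd_effect")],
                             by = "herd_id")
    out$phenotype <- simulate_phenotype(out$tbv, out$herd_effect, pop$vc,
                                        intercept = pop$arch$intercept)
    out <- dplyr::arrange(
      dplyr::select(out, "id", "sire", "dam", "generation", "herd_id",
                    "tbv", "phenotype"),
      .data$id)
    structure(out, class = c("training_set", class(tibble())),
              herds = ha$herds, lambda = lambda,
              mean_herd_size = mean(ha$herds$size))
  })
}

#' SNP genotypes of a set of animals
#'
#' @param pop A `population` whose current haplotypes include the animals.
#' @param ids Animal ids (default: all animals with stored haplotypes).
#' @return Integer dosage matrix (animals x SNP loci) with rownames `ids`.
#' @export
snp_genotypes <- function(pop, ids = pop$hap_ids) {
  k <- match(ids, pop$hap_ids)
  if (anyNA(k)) abort("haplotypes are not stored for some requested animals")
  m <- pop$hap[2L * k - 1L, pop$map$snp_cols, drop = FALSE] +
    pop$hap[2L * k, pop$map$snp_cols, drop = FALSE]
  rownames(m) <- ids
  m
}

#' Pedigree of the most recent generations
#'
#' Extracts the error-free pedigree used by the pedigree-based evaluation:
#' the last `depth` generations, with parents outside the window treated as
#' unknown (coded 0).
#'
#' @param pop A `population`.
#' @param depth Number of most recent generations to keep (default 5).
#' @return A topologically ordered tibble (`id`, `sire`, `dam`).
#' @export
recent_pedigree <- function(pop, depth = 5) {
  gen <- max(pop$ped$generation)
  ped <- dplyr::filter(pop$ped, .data$generation > gen - depth)
  keep <- ped$id
  tibble(id = ped$id,
         sire = ifelse(ped$sire %in% keep, ped$sire, 0L),
         dam = ifelse(ped$dam %in% keep, ped$dam, 0L))
}
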
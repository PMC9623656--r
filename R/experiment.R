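#' Accuracy of estimated breeding values
#'
#' Accuracy is the Pearson correlation between estimated and true breeding
#' values, computed over the phenotyped training cows.
#'
#' @param ebv,tbv Equal-length numeric vectors (length >= 3, both
#'   non-constant).
#' @return The correlation, in \[-1, 1\].
#' @export
compute_accuracy <- function(ebv, tbv) {
  if (length(ebv) != length(tbv) || length(ebv) < 3) {
    abort("`ebv` and `tbv` must have equal length >= 3")
  }
  if (sd(ebv) == 0 || sd(tbv) == 0) {
    abort("accuracy is undefined for zero-variance inputs")
  }
  cor(ebv, tbv)
}

#' Configure a simulation study
#'
#' Bundles every tunable of the pipeline.  The defaults are the full-scale
#' study: a 10-chromosome genome with 2,000 founders, the 50k SNP chip and
#' 10,000 QTL, the 5 + 6 generation breeding design, 8,000 training cows,
#' average herd sizes driven by Poisson means 1-16, and all six evaluation
#' models.
#'
#' @param genome A [genome_spec()].
#' @param design A [breeding_design()].
#' @param vc A [variance_components()].
#' @param n_snp_per_chr,n_qtl_per_chr Loci per chromosome.
#' @param lambdas Poisson means of the herd-size scenarios.
#' @param methods Evaluation methods to run.
#' @param herd_models Herd treatments to run.
#' @param pedigree_depth Generations of error-free pedigree for PBLUP.
#' @return A `study_config` list.
#' @export
study_config <- function(genome = genome_spec(),
                         design = breeding_design(),
                         vc = variance_components(),
                         n_snp_per_chr = 5000, n_qtl_per_chr = 1000,
                         lambdas = c(1, 2, 4, 8, 16),
                         methods = c("pblup", "gblup"),
                         herd_models = c("none", "fixed", "random"),
                         pedigree_depth = 5) {
  stopifnot(inherits(genome, "genome_spec"),
            inherits(design, "breeding_design"),
            inherits(vc, "variance_components"),
            length(lambdas) >= 1, all(lambdas > 0))
  methods <- match.arg(methods, c("pblup", "gblup"), several.ok = TRUE)
  herd_models <- match.arg(herd_models, c("none", "fixed", "random"),
                           several.ok = TRUE)
  structure(list(genome = genome, design = design, vc = vc,
                 n_snp_per_chr = n_snp_per_chr,
                 n_qtl_per_chr = n_qtl_per_chr,
                 lambdas = lambdas, methods = methods,
                 herd_models = herd_models,
                 pedigree_depth = pedigree_depth),
            class = "study_config")
}

#' Run one replicate of the complete pipeline
#'
#' Simulates founders, the trait, the burn-in and evaluation phases once,
#' then evaluates every scenario cell (herd-size lambda x method x herd
#' model) on that same population, so model comparisons are paired within
#' the replicate.  Deterministic under `seed`.
#'
#' @param config A [study_config()].
#' @param seed Integer seed for the replicate.
#' @return A tibble with one row per scenario cell: `lambda`,
#'   `mean_herd_size`, `n_herds`, `method`, `herd_model`, `accuracy`.
#' @export
run_replicate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  with_seed_maybe(seed, {
    panel <- simulate_founder_haplotypes(config$genome, seed = NULL)
    loci <- select_loci(panel, config$n_snp_per_chr, config$n_qtl_per_chr)
    arch <- sample_qtl_effects(founder_dosages(panel, loci$qtl),
                               config$vc$sigma_a2)
    pop <- founder_population(panel, loci, arch, config$vc)
    rm(panel)
    pop <- run_burn_in(pop, config$design)
    pop <- run_evaluation_phase(pop, config$design)

    ainv <- NULL
    if ("pblup" %in% config$methods) {
      ainv <- nrm_inverse(recent_pedigree(pop, config$pedigree_depth))
    }

    # When the final generation holds exactly the training number of cows
    # (the designed case), every lambda shares the same cows and G is
    # computed once.
    gen <- max(pop$ped$generation)
    n_cows <- sum(pop$ped$generation == gen & pop$ped$sex == "F")
    shared <- n_cows == config$design$n_training
    G <- NULL
    if ("gblup" %in% config$methods && shared) {
      cow_ids <- dplyr::filter(pop$ped, .data$generation == gen,
                               .data$sex == "F")$id
      G <- grm(snp_genotypes(pop, cow_ids))
    }

    cells <- tidyr::expand_grid(method = config$methods,
                                herd_model = config$herd_models)
    purrr::map_dfr(config$lambdas, function(lambda) {
      ts <- make_training_set(pop, lambda, config$design$n_training)
      G_l <- G
      if ("gblup" %in% config$methods && is.null(G_l)) {
        G_l <- grm(snp_genotypes(pop, ts$id))
      }
      purrr::pmap_dfr(cells, function(method, herd_model) {
        fit <- if (method == "pblup") {
          solve_mme(build_mme(y = ts$phenotype, animal = ts$id,
                              herd = ts$herd_id, kernel_inverse = ainv,
                              vc = config$vc, herd_model = herd_model))
        } else {
          solve_blup_gls(y = ts$phenotype, animal = ts$id,
                         herd = ts$herd_id, kernel = G_l,
                         vc = config$vc, herd_model = herd_model)
        }
        ebv <- fit$u$ebv[match(as.character(ts$id), fit$u$id)]
        tibble(lambda = lambda,
               mean_herd_size = attr(ts, "mean_herd_size"),
               n_herds = nrow(attr(ts, "herds")),
               method = method, herd_model = herd_model,
               accuracy = compute_accuracy(ebv, ts$tbv))
      })
    })
  })
}

#' Run a replicated study
#'
#' Executes [run_replicate()] for `n_replicates` independent seeds derived
#' from `seed` and stacks the results.
#'
#' @param config A [study_config()].
#' @param n_replicates Number of independent replicates (the study uses 10).
#' @param seed Base integer seed; replicate seeds are drawn from it.
#' @return A tibble of class `accuracy_results`: [run_replicate()] output
#'   with a `replicate` column.
#' @export
run_study <- function(config, n_replicates = 10, seed = 1) {
  stopifnot(n_replicates >= 1)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max, n_replicates))
  out <- purrr::imap_dfr(seeds, function(s, r) {
    dplyr::mutate(run_replicate(config, seed = s), replicate = r,
                  .before = 1)
  })
  structure(out, class = c("accuracy_results", class(tibble())))
}

#' Summarise accuracies over replicates
#'
#' Per scenario cell: mean accuracy, standard error (sd / sqrt(n)), and the
#' 95% percentile interval (2.5%-97.5% quantiles across replicates), plus
#' the mean realized herd size.
#'
#' @param results Output of [run_study()] (or row-bound [run_replicate()]s).
#' @return A tibble of class `accuracy_summary`.
#' @export
summarize_accuracy <- function(results) {
  stopifnot(all(c("lambda", "method", "herd_model", "accuracy")
                %in% names(results)))
  out <- dplyr::summarise(
    dplyr::group_by(results, .data$lambda, .data$method, .data$herd_model),
    mean_herd_size = mean(.data$mean_herd_size),
    n = dplyr::n(),
    se = if (dplyr::n() > 1) sd(.data$accuracy) / sqrt(dplyr::n()) else 0,
    lower = unname(quantile(.data$accuracy, 0.025, type = 7)),
    upper = unname(quantile(.data$accuracy, 0.975, type = 7)),
    accuracy = mean(.data$accuracy),
    .groups = "drop")
  out <- dplyr::relocate(out, "accuracy", .before = "se")
  structure(out, class = c("accuracy_summary", class(tibble())))
}

#' Accuracy table in the herd-size by method layout
#'
#' Pivots an [summarize_accuracy()] table for one herd model into the
#' familiar layout with methods as rows and average herd sizes as columns.
#'
#' @param summary An `accuracy_summary`.
#' @param herd_model Which herd treatment to tabulate (default `"random"`).
#' @param digits Rounding for the displayed accuracies.
#' @return A tibble with one row per method.
#' @export
accuracy_table <- function(summary, herd_model = "random", digits = 2) {
  tab <- dplyr::filter(summary, .data$herd_model == !!herd_model)
  tab <- dplyr::mutate(tab,
                       herd_size = round(.data$mean_herd_size, 2),
                       accuracy = round(.data$accuracy, digits))
  tidyr::pivot_wider(dplyr::select(tab, "method", "herd_size", "accuracy"),
                     names_from = "herd_size", values_from = "accuracy")
}
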
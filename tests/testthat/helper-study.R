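# The reduced study profile used for property and directional tests:
# 2 chromosomes, 1,000 SNP + 200 QTL per chromosome, 500 founders, 800
# training cows, 2 replicates.  Accuracies at this scale are not the
# full-scale accuracies; the profile exists so that paired model contrasts
# and pipeline properties can be exercised in minutes.
reduced_config <- function(lambdas = c(1, 2, 4, 8, 16)) {
  study_config(
    genome = genome_spec(n_chromosomes = 2, n_founders = 500,
                         sites_per_chr = 1300),
    design = breeding_design(
      burn_in = list(n_generations = 5, n_sires = 60, n_dams = 250,
                     n_offspring = 500),
      evaluation = list(n_generations = 6, n_sires = 250, n_dams = 800,
                        n_offspring = 1600),
      n_training = 800),
    n_snp_per_chr = 1000, n_qtl_per_chr = 200,
    lambdas = lambdas, pedigree_depth = 5)
}

.study_cache <- new.env(parent = emptyenv())

# 2 replicates of the reduced study, computed once per test run and shared
# by every test that needs full-pipeline accuracies
reduced_study <- function() {
  if (is.null(.study_cache$res)) {
    .study_cache$res <- run_study(reduced_config(), n_replicates = 2,
                                  seed = 1)
  }
  .study_cache$res
}
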
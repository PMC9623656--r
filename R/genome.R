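#' Specify the founder genome
#'
#' A genome specification collects the parameters of the neutral coalescent
#' simulation that seeds every replicate: the number of chromosomes, their
#' genetic lengths, the effective population size that sets the scaled
#' recombination rate, the number of diploid founders, and the target number
#' of segregating sites per chromosome.  The defaults describe a cattle-like
#' genome of 10 chromosome pairs of 1 Morgan each, 2,000 founders and an
#' effective population size of 1,035, chosen to reflect the high genetic
#' diversity of African dairy cattle populations.
#'
#' @param n_chromosomes Number of chromosome pairs.
#' @param morgans_per_chr Genetic length of each chromosome, in Morgans.
#' @param ne Effective population size governing drift and the scaled
#'   recombination rate of the coalescent.
#' @param n_founders Number of diploid founder animals (the panel carries
#'   `2 * n_founders` haplotypes).
#' @param sites_per_chr Minimum number of segregating sites required per
#'   chromosome; the scaled mutation rate is chosen so the expected count
#'   exceeds this by 20%.
#' @param seed Optional integer seed used by [simulate_founder_haplotypes()].
#'
#' @return An object of class `genome_spec`.
#' @seealso [simulate_founder_haplotypes()], [select_loci()]
#' @export
#' @examples
#' genome_spec(n_chromosomes = 2, n_founders = 50, sites_per_chr = 300)
genome_spec <- function(n_chromosomes = 10, morgans_per_chr = 1, ne = 1035,
                        n_founders = 2000, sites_per_chr = 6000, seed = NULL) {
  stopifnot(n_chromosomes >= 1, morgans_per_chr > 0, ne > 0,
            n_founders >= 1, sites_per_chr >= 1)
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         morgans_per_chr = morgans_per_chr, ne = ne,
         n_founders = as.integer(n_founders),
         sites_per_chr = as.integer(sites_per_chr), seed = seed),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", x$n_chromosomes, " chromosomes x ", x$morgans_per_chr,
      " M, Ne = ", x$ne, ", ", x$n_founders, " founders, >= ",
      x$sites_per_chr, " sites/chr\n", sep = "")
  invisible(x)
}

#' Expected number of segregating sites under the neutral coalescent
#'
#' Watterson's expectation \eqn{E[S] = \theta \sum_{i=1}^{n-1} 1/i} for a
#' sample of `n_hap` haplotypes with scaled mutation rate `theta` (the
#' expectation is unaffected by recombination).
#'
#' @param n_hap Number of sampled haplotypes.
#' @param theta Scaled mutation rate \eqn{4 N_e \mu} summed over the region.
#' @return Expected segregating-site count.
#' @export
expected_segregating_sites <- function(n_hap, theta) {
  stopifnot(n_hap >= 2, theta > 0)
  theta * sum(1 / seq_len(n_hap - 1))
}

# theta giving 1.2 * target expected sites for n haplotypes
default_theta <- function(n_hap, target_sites) {
  1.2 * target_sites / sum(1 / seq_len(n_hap - 1))
}

#' Simulate neutral founder haplotypes
#'
#' Generates phased biallelic haplotypes for the founder animals with a
#' discrete-locus sequentially Markov coalescent: each chromosome carries a
#' grid of loci whose genealogies follow the constant-size Kingman coalescent
#' marginally and are correlated along the chromosome through recombination
#' at rate `4 * ne * d` per unit branch length between loci at distance `d`
#' Morgans.  Mutations are placed on the per-locus trees under an
#' infinite-sites model, so every emitted site is segregating.  If a
#' chromosome comes up short of `spec$sites_per_chr` segregating sites the
#' draw is repeated up to `max_tries` times before failing.
#'
#' @param spec A [genome_spec()].
#' @param theta Scaled mutation rate per chromosome; by default chosen so the
#'   expected segregating-site count is 1.2 times `spec$sites_per_chr`.
#' @param n_grid Number of grid loci per chromosome at which genealogies are
#'   tracked (default: `spec$sites_per_chr`).
#' @param seed Integer seed (defaults to `spec$seed`); the same seed gives a
#'   bit-identical panel.
#' @param max_tries Attempts per chromosome before giving up.
#'
#' @return A `haplotype_panel`: a list with `alleles` (0/1 integer matrix,
#'   one row per haplotype, haplotypes `2i - 1` and `2i` belong to founder
#'   `i`), `site_map` (tibble with `site`, `chr`, `pos` in Morgans, strictly
#'   increasing within chromosome), `n_founders`, `chr_lengths`, `theta`.
#' @export
#' @examples
#' sp <- genome_spec(n_chromosomes = 1, n_founders = 10, sites_per_chr = 30,
#'                   seed = 1)
#' panel <- simulate_founder_haplotypes(sp)
#' dim(panel$alleles)
simulate_founder_haplotypes <- function(spec, theta = NULL, n_grid = NULL,
                                        seed = spec$seed, max_tries = 5L) {
  stopifnot(inherits(spec, "genome_spec"))
  n_hap <- 2L * spec$n_founders
  theta <- theta %||% default_theta(n_hap, spec$sites_per_chr)
  n_grid <- as.integer(n_grid %||% spec$sites_per_chr)

  with_seed_maybe(seed, {
    per_chr <- lapply(seq_len(spec$n_chromosomes), function(chr) {
      for (try in seq_len(max_tries)) {
        res <- .smc_chromosome(n_hap, n_grid, spec$morgans_per_chr,
                               spec$ne, theta)
        if (ncol(res$alleles) >= spec$sites_per_chr) return(res)
      }
      abort(paste0("chromosome ", chr, ": only ", ncol(res$alleles),
                   " segregating sites after ", max_tries,
                   " attempts (", spec$sites_per_chr,
                   " required); increase `theta` or lower `sites_per_chr`"))
    })
    alleles <- do.call(cbind, lapply(per_chr, `[[`, "alleles"))
    site_map <- purrr::map2_dfr(per_chr, seq_along(per_chr), function(r, chr) {
      tibble(chr = chr, pos = as.numeric(r$pos))
    })
    site_map <- dplyr::mutate(site_map, site = dplyr::row_number(),
                              .before = 1)
    structure(
      list(alleles = alleles, site_map = site_map,
           n_founders = spec$n_founders,
           chr_lengths = rep(spec$morgans_per_chr, spec$n_chromosomes),
           theta = theta),
      class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$alleles), " haplotypes (",
      x$n_founders, " founders), ", ncol(x$alleles),
      " segregating sites on ", length(x$chr_lengths), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Select SNP and QTL loci from a founder panel
#'
#' Draws disjoint sets of marker (SNP) and causal (QTL) sites uniformly at
#' random among the segregating sites of each chromosome, with no minor
#' allele frequency filter.  The defaults give the 50k SNP chip (5,000 per
#' chromosome) plus 1,000 QTL per chromosome used throughout the package.
#'
#' @param panel A `haplotype_panel` from [simulate_founder_haplotypes()].
#' @param n_snp_per_chr,n_qtl_per_chr Sites to draw per chromosome.
#' @param seed Optional integer seed.
#'
#' @return A `loci_selection`: list with integer site indices `snp` and
#'   `qtl` (sorted, disjoint) and a `map` tibble (`site`, `chr`, `pos`,
#'   `role`).
#' @export
select_loci <- function(panel, n_snp_per_chr = 5000, n_qtl_per_chr = 1000,
                        seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            n_snp_per_chr >= 0, n_qtl_per_chr >= 0)
  need <- n_snp_per_chr + n_qtl_per_chr
  with_seed_maybe(seed, {
    picks <- lapply(split(panel$site_map$site, panel$site_map$chr),
                    function(sites) sites)
    sel <- purrr::imap(picks, function(sites, chr) {
      if (length(sites) < need) {
        abort(paste0("chromosome ", chr, " has ", length(sites),
                     " segregating sites but ", need, " are required"))
      }
      both <- sample(sites, need)
      list(snp = both[seq_len(n_snp_per_chr)],
           qtl = both[n_snp_per_chr + seq_len(n_qtl_per_chr)])
    })
    snp <- sort(unlist(lapply(sel, `[[`, "snp"), use.names = FALSE))
    qtl <- sort(unlist(lapply(sel, `[[`, "qtl"), use.names = FALSE))
    map <- dplyr::mutate(
      panel$site_map,
      role = dplyr::case_when(.data$site %in% snp ~ "snp",
                              .data$site %in% qtl ~ "qtl",
                              TRUE ~ "none"))
    structure(list(snp = snp, qtl = qtl,
                   map = dplyr::filter(map, .data$role != "none")),
              class = "loci_selection")
  })
}

#' @export
print.loci_selection <- function(x, ...) {
  cat("<loci_selection> ", length(x$snp), " SNP, ", length(x$qtl),
      " QTL\n", sep = "")
  invisible(x)
}

#' Genotype dosages of the founders at a set of sites
#'
#' @param panel A `haplotype_panel`.
#' @param sites Integer site indices (e.g. `loci$qtl`).
#' @return Integer matrix of 0/1/2 dosages, one row per founder.
#' @export
founder_dosages <- function(panel, sites) {
  a <- panel$alleles[, sites, drop = FALSE]
  odd <- seq(1, nrow(a), by = 2)
  a[odd, , drop = FALSE] + a[odd + 1L, , drop = FALSE]
}
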
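#' Mean of the zero-truncated Poisson distribution
#'
#' The realized mean herd size implied by the two-step sampling procedure,
#' \eqn{\lambda / (1 - e^{-\lambda})}: 1.582, 2.313, 4.075, 8.003 and 16.000
#' for \eqn{\lambda} of 1, 2, 4, 8 and 16.
#'
#' @param lambda Poisson mean.
#' @return Expected herd size.
#' @export
ztp_mean <- function(lambda) {
  stopifnot(all(lambda > 0))
  lambda / (1 - exp(-lambda))
}

#' Sample herd sizes by the two-step procedure
#'
#' Step 1 draws `round(n_slots / lambda)` herd sizes from a Poisson
#' distribution with mean `lambda` (so the expected total equals `n_slots`)
#' and discards zero-size draws — a herd must contain at least one cow, which
#' makes the realized size distribution zero-truncated.  Step 2 corrects the
#' stochastic difference between the sampled total and `n_slots` by unit
#' increments (or decrements, never below size 1) applied to uniformly
#' chosen herds until the sizes sum to exactly `n_slots`.  The correction
#' never creates or removes herds, so the realized mean herd size is
#' `n_slots` divided by the number of surviving herds, concentrating on
#' [ztp_mean()] of `lambda`.
#'
#' @param n_slots Total number of cow slots across herds (default 8,000).
#' @param lambda Poisson mean; the study grid uses 1, 2, 4, 8 and 16.
#' @param seed Optional integer seed.
#' @return Integer vector of herd sizes, all >= 1, summing to `n_slots`.
#' @export
#' @examples
#' sizes <- sample_herd_sizes(8000, lambda = 1, seed = 1)
#' sum(sizes)
#' mean(sizes)   # close to ztp_mean(1) = 1.582
sample_herd_sizes <- function(n_slots = 8000, lambda, seed = NULL) {
  stopifnot(n_slots >= 1, lambda > 0)
  with_seed_maybe(seed, {
    n_draws <- max(1L, as.integer(round(n_slots / lambda)))
    sizes <- rpois(n_draws, lambda)
    sizes <- sizes[sizes > 0]
    if (length(sizes) == 0L) sizes <- 1L
    deficit <- n_slots - sum(sizes)
    if (deficit > 0) {
      add <- tabulate(sample.int(length(sizes), deficit, replace = TRUE),
                      nbins = length(sizes))
      sizes <- sizes + add
    } else {
      while (deficit < 0) {
        i <- sample(which(sizes > 1L), 1L)
        sizes[i] <- sizes[i] - 1L
        deficit <- deficit + 1L
      }
    }
    as.integer(sizes)
  })
}

#' Assign cows to herds and draw herd effects
#'
#' Cows are placed into herd slots by a uniform random permutation —
#' assignment is independent of pedigree and of breeding values, which is
#' what creates genetic connectedness across herds through shared sires.
#' One herd effect per herd is drawn from N(0, `vc$sigma_h2`).
#'
#' @param cow_ids Vector of cow identifiers; length must equal `sum(sizes)`.
#' @param sizes Integer herd sizes from [sample_herd_sizes()].
#' @param vc A [variance_components()] object.
#' @param seed Optional integer seed.
#'
#' @return A `herd_assignment`: list with `assignment` (tibble `id`,
#'   `herd_id`) and `herds` (tibble `herd_id`, `size`, `herd_effect`).
#' @export
assign_cows_to_herds <- function(cow_ids, sizes, vc, seed = NULL) {
  stopifnot(inherits(vc, "variance_components"), all(sizes >= 1))
  if (length(cow_ids) != sum(sizes)) {
    abort(paste0("herd sizes sum to ", sum(sizes), " but ", length(cow_ids),
                 " cows were supplied"))
  }
  with_seed_maybe(seed, {
    herds <- tibble(herd_id = seq_along(sizes), size = as.integer(sizes),
                    herd_effect = rnorm(length(sizes), 0, sqrt(vc$sigma_h2)))
    assignment <- tibble(id = sample(cow_ids),
                         herd_id = rep(herds$herd_id, herds$size))
    structure(list(assignment = assignment, herds = herds),
              class = "herd_assignment")
  })
}

#' @export
print.herd_assignment <- function(x, ...) {
  cat("<herd_assignment> ", nrow(x$assignment), " cows in ",
      nrow(x$herds), " herds (mean size ",
      round(mean(x$herds$size), 3), ")\n", sep = "")
  invisible(x)
}
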
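#' Variance components of the milk-yield trait
#'
#' Derives the full set of variance components from the additive genetic
#' variance, the narrow-sense heritability and the herd-variance ratio.  Both
#' ratios are taken relative to the total phenotypic variance
#' \eqn{\sigma^2_p = \sigma^2_a + \sigma^2_h + \sigma^2_e}, so
#' \eqn{\sigma^2_p = \sigma^2_a / h^2}, \eqn{\sigma^2_h = r_h \sigma^2_p}
#' and \eqn{\sigma^2_e = \sigma^2_p - \sigma^2_a - \sigma^2_h}.  The defaults
#' (h2 = 0.1, herd ratio = 0.4, additive variance = 0.2) describe a
#' low-heritability milk-yield trait recorded in strongly herd-structured
#' environments and give herd variance 0.8 and residual variance 1.0.
#'
#' @param h2 Narrow-sense heritability, in (0, 1).
#' @param herd_ratio Proportion of phenotypic variance due to herd, in
#'   \[0, 1); `h2 + herd_ratio` must be < 1.
#' @param sigma_a2 Additive genetic variance.
#'
#' @return An object of class `variance_components`: a list with elements
#'   `sigma_a2`, `sigma_h2`, `sigma_e2`, `sigma_p2`, `h2`, `herd_ratio`.
#' @export
#' @examples
#' variance_components()           # sigma_h2 = 0.8, sigma_e2 = 1.0
#' variance_components(0.5, 0, 1)  # no herd variance
variance_components <- function(h2 = 0.1, herd_ratio = 0.4, sigma_a2 = 0.2) {
  if (!(h2 > 0 && h2 < 1)) abort("`h2` must be in (0, 1)")
  if (herd_ratio < 0) abort("`herd_ratio` must be >= 0")
  if (sigma_a2 <= 0) abort("`sigma_a2` must be > 0")
  if (h2 + herd_ratio >= 1) {
    abort("infeasible configuration: `h2 + herd_ratio` must be < 1")
  }
  sigma_p2 <- sigma_a2 / h2
  sigma_h2 <- herd_ratio * sigma_p2
  sigma_e2 <- sigma_p2 - sigma_a2 - sigma_h2
  structure(list(sigma_a2 = sigma_a2, sigma_h2 = sigma_h2,
                 sigma_e2 = sigma_e2, sigma_p2 = sigma_p2,
                 h2 = h2, herd_ratio = herd_ratio),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> a2 = %g, h2(herd) = %g, e2 = %g  (h2 = %g, herd ratio = %g)\n",
    x$sigma_a2, x$sigma_h2, x$sigma_e2, x$h2, x$herd_ratio))
  invisible(x)
}

#' Sample and scale additive QTL effects
#'
#' Allele-substitution effects are drawn from N(0, 1), one per QTL, and then
#' linearly rescaled so that the realized variance of true breeding values
#' over the founder animals equals `sigma_a2` exactly.  The scaled effects
#' are fixed for the remainder of a replicate; genetic variance may drift in
#' later generations under selection, which is accepted.
#'
#' @param qtl_dosages Founder QTL dosage matrix (animals x QTL, values
#'   0/1/2), e.g. from [founder_dosages()].
#' @param sigma_a2 Target additive variance among the founders.
#' @param seed Optional integer seed.
#' @param intercept Trait mean added to phenotypes (not to breeding values).
#'
#' @return A `trait_architecture`: list with `effects` (numeric, one per
#'   QTL), `intercept` and `sigma_a2`.
#' @export
sample_qtl_effects <- function(qtl_dosages, sigma_a2 = 0.2, seed = NULL,
                               intercept = 0) {
  stopifnot(is.matrix(qtl_dosages), ncol(qtl_dosages) >= 1,
            nrow(qtl_dosages) >= 2, sigma_a2 > 0)
  with_seed_maybe(seed, {
    raw <- rnorm(ncol(qtl_dosages))
    scale_qtl_effects(raw, qtl_dosages, sigma_a2, intercept)
  })
}

#' Rescale raw QTL effects to a target founder variance
#'
#' The deterministic second step of [sample_qtl_effects()], exposed so that
#' externally supplied raw effects can be scaled the same way.  Scaling is
#' invariant to multiplying all raw effects by a constant.
#'
#' @param raw_effects Numeric vector of unscaled effects, one per QTL.
#' @inheritParams sample_qtl_effects
#' @return A `trait_architecture`.
#' @export
scale_qtl_effects <- function(raw_effects, qtl_dosages, sigma_a2 = 0.2,
                              intercept = 0) {
  stopifnot(length(raw_effects) == ncol(qtl_dosages))
  tbv_raw <- drop(qtl_dosages %*% raw_effects)
  v <- var(tbv_raw)
  if (!is.finite(v) || v <= .Machine$double.eps) {
    abort("raw founder TBV variance is zero; cannot scale QTL effects")
  }
  structure(list(effects = raw_effects * sqrt(sigma_a2 / v),
                 intercept = intercept, sigma_a2 = sigma_a2),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture> ", length(x$effects),
      " QTL, target founder variance ", x$sigma_a2, "\n", sep = "")
  invisible(x)
}

#' True breeding values from QTL dosages
#'
#' TBV are the sum over QTL of the animal's dosage times the allele
#' substitution effect: `dosages %*% effects`.
#'
#' @param qtl_dosages Dosage matrix (animals x QTL, values 0/1/2).
#' @param arch A `trait_architecture`.
#' @return Numeric vector of TBV, one per row of `qtl_dosages`.
#' @export
compute_tbv <- function(qtl_dosages, arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (ncol(qtl_dosages) != length(arch$effects)) {
    abort("dosage matrix has a different number of QTL than the architecture")
  }
  drop(qtl_dosages %*% arch$effects)
}

#' Simulate phenotypes
#'
#' A single milk-yield record per animal:
#' `y = intercept + tbv + herd_effect + e` with independent residuals
#' `e ~ N(0, sigma_e2)`.  No records are missing.
#'
#' @param tbv Numeric vector of true breeding values.
#' @param herd_effect Numeric vector of herd effects, same length.
#' @param vc A [variance_components()] object.
#' @param seed Optional integer seed.
#' @param intercept Trait mean.
#' @return Numeric vector of phenotypes.
#' @export
simulate_phenotype <- function(tbv, herd_effect, vc, seed = NULL,
                               intercept = 0) {
  stopifnot(inherits(vc, "variance_components"),
            length(tbv) == length(herd_effect))
  with_seed_maybe(seed, {
    intercept + tbv + herd_effect + rnorm(length(tbv), 0, sqrt(vc$sigma_e2))
  })
}
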
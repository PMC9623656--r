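#' Assemble Henderson's mixed-model equations
#'
#' Builds the MME for the single-trait animal model
#' `y = Xb + Zu (+ Wh) + e` with known variance components, where `u` is
#' the vector of breeding values with covariance proportional to the
#' relationship kernel (A for pedigree BLUP, G for genomic BLUP) and `h`
#' is an optional vector of herd effects.  The left-hand side has the
#' standard block structure with `K^-1 * lambda_a` added to the animal
#' block (`lambda_a = sigma_e2 / sigma_a2`) and, under a random herd,
#' `I * lambda_h` added to the herd block.  Under a fixed herd, herd
#' dummies enter X with the first level dropped (reference coding)
#' alongside the overall intercept; any full-rank constraint yields
#' identical breeding values.
#'
#' @param y Numeric vector of phenotype records, one per training cow.
#' @param animal Animal id per record; every id must appear in the
#'   dimnames of `kernel_inverse`.
#' @param herd Herd id per record (required unless `herd_model = "none"`).
#' @param kernel_inverse Inverse relationship kernel with dimnames: a
#'   sparse `Matrix` (A-inverse over all pedigree animals) or a dense
#'   matrix (G-inverse over the genotyped cows).
#' @param vc A [variance_components()] object.
#' @param herd_model `"none"`, `"fixed"` or `"random"`.
#' @return An `mme_system`: list with `lhs`, `rhs`, the block labels, and
#'   bookkeeping used by [solve_mme()].
#' @export
build_mme <- function(y, animal, herd = NULL, kernel_inverse, vc,
                      herd_model = c("none", "fixed", "random")) {
  herd_model <- match.arg(herd_model)
  ids <- colnames(kernel_inverse)
  if (is.null(ids)) abort("`kernel_inverse` must carry animal ids as dimnames")
  d <- build_design(y, animal, herd, ids, vc, herd_model)
  X <- d$X; Z <- d$Z; W <- d$W
  n <- length(y)
  fixed_names <- d$fixed_names
  herd_levels <- d$herd_levels

  lambda_a <- vc$sigma_e2 / vc$sigma_a2
  Kl <- methods::as(kernel_inverse, "CsparseMatrix") * lambda_a
  XtX <- Matrix::crossprod(X)
  XtZ <- Matrix::crossprod(X, Z)
  ZtZ <- Matrix::crossprod(Z) + Kl
  if (is.null(W)) {
    lhs <- rbind(cbind(XtX, XtZ), cbind(Matrix::t(XtZ), ZtZ))
    rhs <- c(as.numeric(Matrix::crossprod(X, y)),
             as.numeric(Matrix::crossprod(Z, y)))
  } else {
    lambda_h <- vc$sigma_e2 / vc$sigma_h2
    XtW <- Matrix::crossprod(X, W)
    ZtW <- Matrix::crossprod(Z, W)
    WtW <- Matrix::crossprod(W) +
      Matrix::Diagonal(ncol(W)) * lambda_h
    lhs <- rbind(cbind(XtX, XtZ, XtW),
                 cbind(Matrix::t(XtZ), ZtZ, ZtW),
                 cbind(Matrix::t(XtW), Matrix::t(ZtW), WtW))
    rhs <- c(as.numeric(Matrix::crossprod(X, y)),
             as.numeric(Matrix::crossprod(Z, y)),
             as.numeric(Matrix::crossprod(W, y)))
  }
  structure(
    list(lhs = lhs, rhs = rhs,
         fixed_names = fixed_names, animal_ids = ids,
         herd_levels = if (herd_model == "random") herd_levels else NULL,
         herd_model = herd_model, vc = vc, n_records = n,
         dense = !methods::is(kernel_inverse, "sparseMatrix"),
         X = X),
    class = "mme_system")
}

# Shared construction of the record-level design matrices: intercept (plus
# herd dummies with the first level dropped under a fixed herd), the animal
# incidence Z over the kernel ids, and the herd incidence W under a random
# herd.
build_design <- function(y, animal, herd, ids, vc,
                         herd_model = c("none", "fixed", "random")) {
  herd_model <- match.arg(herd_model)
  stopifnot(inherits(vc, "variance_components"), is.numeric(y))
  n <- length(y)
  stopifnot(length(animal) == n)
  if (herd_model != "none" && (is.null(herd) || length(herd) != n)) {
    abort("`herd` is required (one value per record) for this herd model")
  }
  if (herd_model == "random" && vc$sigma_h2 <= 0) {
    abort("a random herd effect requires `sigma_h2` > 0")
  }
  ju <- match(as.character(animal), ids)
  if (anyNA(ju)) abort("some records refer to animals absent from the kernel")
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = ju, x = 1,
                            dims = c(n, length(ids)))
  X <- Matrix::Matrix(1, nrow = n, ncol = 1, sparse = TRUE)
  fixed_names <- "(Intercept)"
  herd_levels <- if (!is.null(herd)) sort(unique(herd)) else NULL
  if (herd_model == "fixed") {
    keep <- herd_levels[-1]                      # reference coding
    if (length(keep)) {
      jh <- match(herd, keep)
      obs <- !is.na(jh)
      Xh <- Matrix::sparseMatrix(i = which(obs), j = jh[obs], x = 1,
                                 dims = c(n, length(keep)))
      X <- cbind(X, Xh)
      fixed_names <- c(fixed_names, paste0("herd:", keep))
    }
  }
  W <- NULL
  if (herd_model == "random") {
    W <- Matrix::sparseMatrix(i = seq_len(n), j = match(herd, herd_levels),
                              x = 1, dims = c(n, length(herd_levels)))
  }
  list(X = X, Z = Z, W = W, ju = ju, fixed_names = fixed_names,
       herd_levels = if (herd_model == "random") herd_levels else NULL)
}

#' @export
print.mme_system <- function(x, ...) {
  cat("<mme_system> ", nrow(x$lhs), " equations (", length(x$fixed_names),
      " fixed, ", length(x$animal_ids), " animal",
      if (!is.null(x$herd_levels)) paste0(", ", length(x$herd_levels),
                                          " herd"),
      "); herd model: ", x$herd_model, "\n", sep = "")
  invisible(x)
}

#' Solve the mixed-model equations
#'
#' Direct factorization of the assembled system: sparse LU/Cholesky via the
#' Matrix package when the kernel inverse is sparse (pedigree BLUP), dense
#' LAPACK otherwise (genomic BLUP).  The solution is invariant to the
#' ordering of records.  A relative residual above 1e-8 triggers a warning;
#' a singular system triggers an error that names the collinear fixed-effect
#' columns when the fixed block is the cause.
#'
#' @param system An [build_mme()] system.
#' @return A `blup_fit`: list with tibbles `b` (`term`, `estimate`), `u`
#'   (`id`, `ebv`) covering every animal in the kernel, and `h` (`herd_id`,
#'   `effect`; random-herd models only), plus bookkeeping fields.
#' @export
solve_mme <- function(system) {
  stopifnot(inherits(system, "mme_system"))
  lhs <- if (system$dense) as.matrix(system$lhs) else system$lhs
  sol <- tryCatch(
    as.numeric(solve(lhs, system$rhs)),
    error = function(e) {
      r <- qr(as.matrix(Matrix::crossprod(system$X)))
      if (r$rank < ncol(system$X)) {
        bad <- system$fixed_names[r$pivot[(r$rank + 1):ncol(system$X)]]
        abort(paste0("fixed-effect block is singular; collinear columns: ",
                     paste(bad, collapse = ", ")))
      }
      abort(paste0("mixed-model equations could not be solved: ",
                   conditionMessage(e)))
    })
  rel_res <- sqrt(sum((as.numeric(system$lhs %*% sol) - system$rhs)^2)) /
    max(sqrt(sum(system$rhs^2)), .Machine$double.eps)
  if (rel_res > 1e-8) {
    warning("MME solution has relative residual ", format(rel_res))
  }
  nf <- length(system$fixed_names)
  nu <- length(system$animal_ids)
  b <- tibble(term = system$fixed_names, estimate = sol[seq_len(nf)])
  u <- tibble(id = system$animal_ids, ebv = sol[nf + seq_len(nu)])
  h <- NULL
  if (!is.null(system$herd_levels)) {
    h <- tibble(herd_id = system$herd_levels,
                effect = sol[nf + nu + seq_along(system$herd_levels)])
  }
  structure(list(b = b, u = u, h = h, herd_model = system$herd_model,
                 vc = system$vc, n_records = system$n_records,
                 rel_residual = rel_res),
            class = "blup_fit")
}

#' Run a genetic evaluation
#'
#' One-call interface tying kernel construction and solving together for a
#' training set: pedigree BLUP assembles and solves the sparse mixed-model
#' equations with the A-inverse over the supplied pedigree (breeding values
#' are returned for every pedigree animal, phenotyped or not); genomic BLUP
#' uses the VanRaden G over the genotyped training cows through the
#' numerically stable covariance-matrix route ([solve_blup_gls()]).
#' Variance components are inputs, never estimated.
#'
#' @param training A [make_training_set()] tibble, or any tibble with
#'   columns `id`, `herd_id`, `phenotype`.
#' @param vc A [variance_components()] object.
#' @param method `"pblup"` or `"gblup"`.
#' @param herd_model `"none"`, `"fixed"` or `"random"`.
#' @param pedigree Topologically ordered pedigree tibble (`id`, `sire`,
#'   `dam`), required for `"pblup"`; e.g. [recent_pedigree()].
#' @param genotypes SNP dosage matrix of the training cows (rownames =
#'   ids), required for `"gblup"`; e.g. [snp_genotypes()].
#' @return A `blup_fit` (see [solve_mme()]) with attribute `method`.
#' @export
fit_blup <- function(training, vc, method = c("pblup", "gblup"),
                     herd_model = c("none", "fixed", "random"),
                     pedigree = NULL, genotypes = NULL) {
  method <- match.arg(method)
  herd_model <- match.arg(herd_model)
  stopifnot(all(c("id", "phenotype") %in% names(training)))
  if (method == "pblup") {
    if (is.null(pedigree)) abort("`pedigree` is required for pblup")
    sys <- build_mme(y = training$phenotype, animal = training$id,
                     herd = training$herd_id,
                     kernel_inverse = nrm_inverse(pedigree),
                     vc = vc, herd_model = herd_model)
    fit <- solve_mme(sys)
  } else {
    if (is.null(genotypes)) abort("`genotypes` is required for gblup")
    fit <- solve_blup_gls(y = training$phenotype, animal = training$id,
                          herd = training$herd_id, kernel = grm(genotypes),
                          vc = vc, herd_model = herd_model)
  }
  attr(fit, "method") <- method
  fit
}

#' Solve BLUP through the phenotypic covariance matrix
#'
#' The mixed-model solution in its generalized-least-squares form:
#' `V = sigma_a2 * Z K Z' + sigma_h2 * W W' + sigma_e2 * I`, fixed effects
#' by GLS, then `u = sigma_a2 * K Z' V^-1 (y - X b)` and, under a random
#' herd, `h = sigma_h2 * W' V^-1 (y - X b)`.  This route takes the
#' relationship kernel itself rather than its inverse, so it remains
#' numerically stable when K is singular or nearly so — the usual situation
#' for a genomic relationship matrix among strongly related animals —
#' because `V` is kept well away from singularity by the residual variance.
#' It is algebraically identical to solving the mixed-model equations.
#'
#' @inheritParams build_mme
#' @param kernel Dense relationship kernel (e.g. [grm()] output) with
#'   animal ids as dimnames.
#' @return A `blup_fit` (see [solve_mme()]).
#' @export
solve_blup_gls <- function(y, animal, herd = NULL, kernel, vc,
                           herd_model = c("none", "fixed", "random")) {
  herd_model <- match.arg(herd_model)
  ids <- colnames(kernel)
  if (is.null(ids)) abort("`kernel` must carry animal ids as dimnames")
  d <- build_design(y, animal, herd, ids, vc, herd_model)
  n <- length(y)
  K <- unclass(kernel)

  ZK <- as.matrix(d$Z %*% K)               # records x animals
  V <- vc$sigma_a2 * as.matrix(d$Z %*% t(ZK))
  if (herd_model == "random") {
    V <- V + vc$sigma_h2 * as.matrix(Matrix::tcrossprod(d$W))
  }
  diag(V) <- diag(V) + vc$sigma_e2
  cV <- chol(V)
  chol_solve <- function(M) {
    backsolve(cV, backsolve(cV, as.matrix(M), transpose = TRUE))
  }

  Xd <- as.matrix(d$X)
  ViX <- chol_solve(Xd)
  XtViX <- crossprod(Xd, ViX)
  b <- tryCatch(
    drop(solve(XtViX, crossprod(ViX, y))),
    error = function(e) {
      r <- qr(XtViX)
      if (r$rank < ncol(Xd)) {
        bad <- d$fixed_names[r$pivot[(r$rank + 1):ncol(Xd)]]
        abort(paste0("fixed-effect block is singular; collinear columns: ",
                     paste(bad, collapse = ", ")))
      }
      abort(paste0("GLS fixed-effect system could not be solved: ",
                   conditionMessage(e)))
    })
  resid <- y - drop(Xd %*% b)
  Vir <- drop(chol_solve(resid))
  u <- vc$sigma_a2 * drop(crossprod(ZK, Vir))
  h <- NULL
  if (herd_model == "random") {
    h <- tibble(herd_id = d$herd_levels,
                effect = vc$sigma_h2 *
                  as.numeric(Matrix::crossprod(d$W, Vir)))
  }
  rel_res <- sqrt(sum((V %*% Vir - resid)^2)) /
    max(sqrt(sum(resid^2)), .Machine$double.eps)
  structure(list(b = tibble(term = d$fixed_names, estimate = b),
                 u = tibble(id = ids, ebv = u), h = h,
                 herd_model = herd_model, vc = vc, n_records = n,
                 rel_residual = rel_res),
            class = "blup_fit")
}

#' Invert a genomic relationship matrix
#'
#' Cholesky-based inverse of G for use as the `kernel_inverse` of
#' [build_mme()].  If the factorization fails, `ridge` is added to the
#' diagonal once (and logged via `message()`).  Note that [fit_blup()]
#' deliberately avoids this inverse for genomic models — see
#' [solve_blup_gls()] — because G can be ill-conditioned even when its
#' Cholesky factorization succeeds; this helper is for well-conditioned
#' kernels and for cross-checks.
#'
#' @param G A [grm()] matrix (or any symmetric positive-definite kernel
#'   with dimnames).
#' @param ridge Diagonal stabilizer used only on factorization failure.
#' @return The dense inverse, dimnames preserved.
#' @export
grm_inverse <- function(G, ridge = 1e-8) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) {
    message("G is not positive definite; adding ", ridge, " to the diagonal")
    ch <- chol(unclass(G) + diag(ridge, nrow(G)))
  }
  Ginv <- chol2inv(ch)
  dimnames(Ginv) <- dimnames(G)
  Ginv
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("<blup_fit> ", attr(x, "method") %||% "blup", ", herd ",
      x$herd_model, ": ", x$n_records, " records, ", nrow(x$u),
      " breeding values\n", sep = "")
  invisible(x)
}

#' Tidy a BLUP fit
#'
#' @param x A `blup_fit`.
#' @param ... Unused.
#' @return A tibble with columns `effect` (`"fixed"`, `"animal"`,
#'   `"herd"`), `term` and `estimate`.
#' @export
tidy.blup_fit <- function(x, ...) {
  out <- dplyr::bind_rows(
    dplyr::mutate(x$b, effect = "fixed"),
    tibble(term = as.character(x$u$id), estimate = x$u$ebv,
           effect = "animal"))
  if (!is.null(x$h)) {
    out <- dplyr::bind_rows(
      out, tibble(term = as.character(x$h$herd_id), estimate = x$h$effect,
                  effect = "herd"))
  }
  dplyr::select(out, "effect", "term", "estimate")
}

#' Glance at a BLUP fit
#'
#' @inheritParams tidy.blup_fit
#' @return A one-row tibble summarising the model.
#' @export
glance.blup_fit <- function(x, ...) {
  tibble(method = attr(x, "method") %||% NA_character_,
         herd_model = x$herd_model,
         n_records = x$n_records,
         n_animals = nrow(x$u),
         n_herds = if (is.null(x$h)) NA_integer_ else nrow(x$h),
         lambda_a = x$vc$sigma_e2 / x$vc$sigma_a2,
         lambda_h = x$vc$sigma_e2 / x$vc$sigma_h2,
         rel_residual = x$rel_residual)
}
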
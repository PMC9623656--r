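#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A by the recursive tabular
#' method, including inbreeding: for animal i with parents s and d (in
#' topological order), `a_ij = (a_js + a_jd) / 2` for j < i and
#' `a_ii = 1 + a_sd / 2`.  Unknown parents (coded 0 or `NA`) contribute
#' nothing.
#'
#' @param pedigree Tibble or data frame with columns `id`, `sire`, `dam`,
#'   topologically ordered (parents before offspring).
#' @return A symmetric matrix with dimnames equal to the animal ids, of
#'   class `relationship_matrix` with attribute `flavor = "pedigree"`.
#' @export
#' @examples
#' ped <- tibble::tibble(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
#' nrm(ped)   # parent-offspring relationship 0.5
nrm <- function(pedigree) {
  p <- check_pedigree(pedigree)
  n <- nrow(p)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p$sire[i]
    d <- p$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (s > 0L) A[s, j] else 0
      row_d <- if (d > 0L) A[d, j] else 0
      A[i, j] <- A[j, i] <- (row_s + row_d) / 2
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  dimnames(A) <- list(p$id, p$id)
  structure(A, class = c("relationship_matrix", "matrix", "array"),
            flavor = "pedigree")
}

#' Inbreeding coefficients (Meuwissen-Luo algorithm)
#'
#' Computes F for every animal in a topologically ordered pedigree by
#' tracing each animal's ancestors with the L-matrix decomposition of A,
#' without ever forming A.
#'
#' @inheritParams nrm
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(pedigree) {
  p <- check_pedigree(pedigree)
  n <- nrow(p)
  FF <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- p$sire[i]
    d <- p$dam[i]
    D[i] <- mendelian_variance(s, d, FF)
    if (s == 0L || d == 0L) {
      FF[i] <- 0
      next
    }
    # a_ii = sum over ancestors j of L_ij^2 * D_j, accumulated youngest-first
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * D[j]
      sj <- p$sire[j]
      dj <- p$dam[j]
      if (sj > 0L) L[sj] <- L[sj] + L[j] / 2
      if (dj > 0L) L[dj] <- L[dj] + L[j] / 2
    }
    FF[i] <- aii - 1
  }
  setNames(FF, p$id)
}

# Mendelian sampling variance d_i given parent codes and inbreeding so far.
mendelian_variance <- function(s, d, FF) {
  if (s > 0L && d > 0L) {
    0.5 - 0.25 * (FF[s] + FF[d])
  } else if (s > 0L) {
    0.75 - 0.25 * FF[s]
  } else if (d > 0L) {
    0.75 - 0.25 * FF[d]
  } else {
    1
  }
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules with
#' inbreeding accounted for via the Meuwissen-Luo algorithm; only the
#' diagonal and parent-offspring / parent-parent cross terms are non-zero,
#' which is what makes pedigree BLUP feasible on large pedigrees.
#'
#' @inheritParams nrm
#' @return A sparse symmetric `Matrix::dgCMatrix` with dimnames equal to
#'   the animal ids and attribute `inbreeding`.
#' @export
nrm_inverse <- function(pedigree) {
  p <- check_pedigree(pedigree)
  n <- nrow(p)
  FF <- inbreeding(pedigree)
  D <- vapply(seq_len(n),
              function(i) mendelian_variance(p$sire[i], p$dam[i], FF),
              numeric(1))
  tri <- vector("list", n)
  for (i in seq_len(n)) {
    s <- p$sire[i]
    d <- p$dam[i]
    a <- 1 / D[i]
    par <- c(s, d)
    par <- par[par > 0L]
    ti <- list(c(i, i, a))
    for (q in par) {
      ti <- c(ti, list(c(i, q, -a / 2), c(q, i, -a / 2), c(q, q, a / 4)))
    }
    if (length(par) == 2L) {
      ti <- c(ti, list(c(par[1], par[2], a / 4), c(par[2], par[1], a / 4)))
    }
    tri[[i]] <- do.call(rbind, ti)
  }
  tri <- do.call(rbind, tri)
  Ainv <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                               dims = c(n, n),
                               dimnames = list(p$id, p$id))
  attr(Ainv, "inbreeding") <- FF
  Ainv
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers the dosage matrix column-wise by twice the observed allele
#' frequency and scales the cross-product by `2 * sum(p * (1 - p))` over the
#' polymorphic markers: `G = M M' / (2 sum p(1-p))`, with allele frequencies
#' estimated in the genotyped animals themselves.  Monomorphic markers carry
#' no information and are excluded.
#'
#' @param dosages Integer/numeric matrix of SNP dosages in \{0, 1, 2\}
#'   (animals x markers), rownames taken as animal ids.
#' @return A symmetric matrix of class `relationship_matrix` with attribute
#'   `flavor = "genomic"`.
#' @export
#' @examples
#' grm(matrix(c(0, 1, 2), ncol = 1))   # the 3-animal single-locus case
grm <- function(dosages) {
  stopifnot(is.matrix(dosages), nrow(dosages) >= 2)
  p <- colMeans(dosages) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("all markers are monomorphic; G is undefined")
  M <- sweep(dosages[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(M) / denom
  ids <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  dimnames(G) <- list(ids, ids)
  structure(G, class = c("relationship_matrix", "matrix", "array"),
            flavor = "genomic")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("<relationship_matrix> ", attr(x, "flavor"), ", ", nrow(x), " x ",
      ncol(x), "; mean diagonal ", round(mean(diag(x)), 4), "\n", sep = "")
  invisible(x)
}

# Validate and recode a pedigree to consecutive integer positions.
# Returns tibble with id (original labels) and sire/dam as row positions
# (0 = unknown).  Errors on unordered or cyclic pedigrees.
check_pedigree <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  id <- pedigree$id
  if (anyDuplicated(id)) abort("duplicated animal ids in pedigree")
  pos <- seq_along(id)
  names(pos) <- as.character(id)
  code <- function(par) {
    par[is.na(par)] <- 0
    chr <- as.character(par)
    out <- unname(pos[chr])
    out[chr == "0"] <- 0L
    if (anyNA(out)) {
      abort("pedigree references parents that are not listed as animals")
    }
    out
  }
  sire <- code(pedigree$sire)
  dam <- code(pedigree$dam)
  bad <- which(sire >= pos | dam >= pos)
  if (length(bad)) {
    abort(paste0("pedigree is not topologically ordered (or cyclic) at id ",
                 id[bad[1]], "; parents must precede offspring"))
  }
  tibble(id = id, sire = as.integer(sire), dam = as.integer(dam))
}
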
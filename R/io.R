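#' Read and write pedigree files
#'
#' Three-column CSV (`id`, `sire`, `dam`) with 0 meaning unknown, the usual
#' exchange format for animal-breeding pedigrees.
#'
#' @param pedigree Tibble with `id`, `sire`, `dam`.
#' @param path File path.
#' @return `read_pedigree_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  out <- dplyr::mutate(pedigree[, c("id", "sire", "dam")],
                       sire = dplyr::coalesce(.data$sire, 0L),
                       dam = dplyr::coalesce(.data$dam, 0L))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_integer(), sire = readr::col_integer(),
    dam = readr::col_integer()))
}

#' Read and write phenotype files
#'
#' CSV with one record per animal: `id`, `sire`, `dam`, `sex`,
#' `generation`, `herd_id`, `phenotype`, `tbv` (columns absent from the
#' input tibble are skipped).
#'
#' @param records A tibble, e.g. a [make_training_set()].
#' @param path File path.
#' @export
write_phenotypes_csv <- function(records, path) {
  keep <- intersect(c("id", "sire", "dam", "sex", "generation", "herd_id",
                      "phenotype", "tbv"), names(records))
  readr::write_csv(as_tibble(records)[, keep], path)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols())
}

#' Read and write genotype dosage tables
#'
#' A PLINK-raw-style table: an `id` column followed by one 0/1/2 dosage
#' column per SNP.
#'
#' @param dosages Dosage matrix with rownames as ids.
#' @param path File path.
#' @export
write_dosages_csv <- function(dosages, path) {
  df <- as_tibble(as.data.frame(dosages))
  names(df) <- paste0("snp", seq_len(ncol(df)))
  df <- dplyr::mutate(df,
                      id = rownames(dosages) %||%
                        as.character(seq_len(nrow(dosages))),
                      .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_dosages_csv
#' @export
read_dosages_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Export founder haplotypes as a phased VCF
#'
#' Writes a minimal VCFv4.2 with phased GT fields, one diploid founder per
#' sample column.  Genetic positions (Morgans) are mapped to integer
#' coordinates at 1e6 per Morgan.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path (plain text).
#' @param sites Optional site indices to export (default: all).
#' @export
write_founder_vcf <- function(panel, path, sites = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  sites <- sites %||% panel$site_map$site
  sm <- panel$site_map[sites, ]
  a <- panel$alleles[, sites, drop = FALSE]
  odd <- seq(1L, nrow(a), by = 2L)
  gt <- matrix(paste0(a[odd, , drop = FALSE], "|",
                      a[odd + 1L, , drop = FALSE]),
               nrow = length(odd))
  samples <- paste0("F", seq_len(panel$n_founders))
  header <- c("##fileformat=VCFv4.2",
              "##source=smallherd",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sm)), function(j) {
    paste(c(sm$chr[j], as.integer(round(sm$pos[j] * 1e6)) + 1L,
            paste0("site", sm$site[j]), "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses the vcfR package to parse a (possibly user-supplied) VCF and
#' returns the 0/1/2 dosage matrix of the biallelic records.
#'
#' @param path VCF path.
#' @return Integer dosage matrix, animals in rows.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF genotypes requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(0L, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  for (j in seq_len(nrow(gt))) {
    g <- gt[j, ]
    dos[, j] <- vapply(strsplit(g, "[|/]"),
                       function(x) sum(as.integer(x)), integer(1))
  }
  dos
}

#' Export a genetic map
#'
#' Three-column text map: chromosome, site id, position in Morgans.
#'
#' @param panel A `haplotype_panel`.
#' @param path File path.
#' @export
write_genetic_map <- function(panel, path) {
  readr::write_tsv(panel$site_map[, c("chr", "site", "pos")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Export a relationship matrix in long format
#'
#' Labeled coordinate triplets (`id_i`, `id_j`, `value`), writing only
#' structurally non-zero entries for sparse inputs.
#'
#' @param mat A relationship matrix (dense) or sparse `Matrix` (e.g. an
#'   A-inverse).
#' @param path File path.
#' @export
write_relationship_long <- function(mat, path) {
  if (methods::is(mat, "sparseMatrix")) {
    tr <- Matrix::summary(mat)
    df <- tibble(id_i = rownames(mat)[tr$i], id_j = colnames(mat)[tr$j],
                 value = tr$x)
  } else {
    df <- tibble(id_i = rep(rownames(mat), times = ncol(mat)),
                 id_j = rep(colnames(mat), each = nrow(mat)),
                 value = as.vector(unclass(mat)))
  }
  readr::write_csv(df, path)
  invisible(path)
}
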
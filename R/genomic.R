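#' SNP genotype container
#'
#' @param dosages numeric matrix, animals in rows (rownames = animal labels),
#'   SNPs in columns (colnames = SNP names); entries 0/1/2 with `NA` for
#'   missing calls.
#' @param map data frame with columns `snp`, `chrom`, `pos` matching the
#'   dosage columns.
#' @return Object of class `genotype_data` with elements `dosages`, `map`,
#'   `qc_log` (empty until [qc_genotypes()] is run) and `imputed` flag.
#' @export
genotype_data <- function(dosages, map) {
  dosages <- as.matrix(dosages)
  map <- as_tibble(map)
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)))
  if (ncol(dosages) != nrow(map)) {
    abort(sprintf("%d dosage columns but %d SNPs in map", ncol(dosages), nrow(map)))
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp
  if (!identical(colnames(dosages), as.character(map$snp))) {
    abort("dosage column names disagree with the SNP map")
  }
  if (nrow(dosages) > 0 && is.null(rownames(dosages))) {
    abort("dosage rows must be named by animal")
  }
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad) > 0) abort("dosages must be coded 0/1/2 or NA")
  structure(
    list(dosages = dosages, map = map, qc_log = NULL, imputed = FALSE),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf(
    "<genotype_data> %d animals x %d SNPs (%s)\n",
    nrow(x$dosages), ncol(x$dosages),
    if (is.null(x$qc_log)) "raw" else "post-QC"
  ))
  invisible(x)
}

#' Read a whitespace-delimited genotype matrix plus SNP map
#'
#' The genotype file holds one row per animal with the animal id in the first
#' column and 0/1/2 dosages after it (`NA` for missing); `transposed = TRUE`
#' accepts the common SNP-per-row variant. The map file is a CSV
#' `snp,chrom,pos`.
#'
#' @param path genotype matrix path.
#' @param map_path SNP map path.
#' @param transposed set `TRUE` if rows are SNPs and columns animals.
#' @return A [genotype_data()] object.
#' @export
read_genotypes <- function(path, map_path, transposed = FALSE) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE, comment.char = "#")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (transposed) {
    m <- t(m)
    tmp <- ids
    ids <- colnames(raw)[-1]
    colnames(m) <- tmp
  }
  rownames(m) <- ids
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("snp", "chrom", "pos") %in% names(map))) {
    abort(sprintf("malformed SNP map header in '%s' (line 1): need snp,chrom,pos", map_path))
  }
  genotype_data(m[, as.character(map$snp), drop = FALSE], map)
}

is_autosome_label <- function(chrom) {
  suppressWarnings(!is.na(as.integer(as.character(chrom))))
}

#' Genotype quality control
#'
#' Removes SNPs failing any of: per-SNP call rate below `callrate_min`,
#' non-autosomal placement, or minor allele frequency below `maf_min`.
#' Filters are applied in that order (call rate, autosome, MAF), with MAF
#' computed on the SNPs that survive the earlier filters, and each removal is
#' logged with its (first) reason. Remaining missing dosages are mean-imputed
#' to twice the observed allele frequency of the SNP. Optionally animals with
#' per-animal call rate below `animal_callrate_min` are dropped first
#' (disabled by default).
#'
#' @param g a [genotype_data()] object.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param callrate_min minimum per-SNP call rate (default 0.95).
#' @param animal_callrate_min optional per-animal call-rate threshold; `NULL`
#'   (default) disables the animal filter.
#' @return A `genotype_data` with failing SNPs removed, missing dosages
#'   imputed, and a `qc_log` tibble (`snp`, `status`, `reason`).
#' @export
qc_genotypes <- function(g, maf_min = 0.05, callrate_min = 0.95,
                         animal_callrate_min = NULL) {
  stopifnot(inherits(g, "genotype_data"))
  M <- g$dosages
  if (!is.null(animal_callrate_min)) {
    acr <- rowMeans(!is.na(M))
    M <- M[acr >= animal_callrate_min, , drop = FALSE]
  }
  snp <- colnames(M)
  reason <- rep(NA_character_, ncol(M))
  cr <- colMeans(!is.na(M))
  reason[cr < callrate_min] <- "call_rate"
  auto <- is_autosome_label(g$map$chrom)
  reason[is.na(reason) & !auto] <- "non_autosomal"
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  reason[is.na(reason) & maf < maf_min] <- "maf"
  keep <- is.na(reason)
  if (!any(keep)) abort("no SNPs passed quality control")
  Mk <- M[, keep, drop = FALSE]
  pk <- p[keep]
  for (j in which(colSums(is.na(Mk)) > 0)) {
    Mk[is.na(Mk[, j]), j] <- 2 * pk[j]
  }
  out <- g
  out$dosages <- Mk
  out$map <- g$map[keep, , drop = FALSE]
  out$qc_log <- tibble(
    snp = snp,
    status = ifelse(keep, "pass", "fail"),
    reason = ifelse(keep, NA_character_, reason)
  )
  out$imputed <- TRUE
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum_k p_k (1 - p_k))` with `Z = M - 2p`, where `M` are
#' the (QC'd, imputed) dosages and `p` the observed allele frequencies of the
#' genotyped set.
#'
#' @param g a QC'd [genotype_data()].
#' @return Dense symmetric matrix with animal dimnames, attribute
#'   `kind = "G"`.
#' @export
build_G_vanraden1 <- function(g) {
  stopifnot(inherits(g, "genotype_data"))
  M <- g$dosages
  if (nrow(M) < 2 || ncol(M) < 2) abort("need at least 2 animals and 2 SNPs")
  p <- colMeans(M) / 2
  if (any(p <= 0 | p >= 1)) {
    abort(sprintf(
      "monomorphic SNPs present (should have been removed by QC): %s",
      paste(utils::head(colnames(M)[p <= 0 | p >= 1], 5), collapse = ", ")
    ))
  }
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  structure((G + t(G)) / 2, kind = "G")
}

#' Blend G with the pedigree block A22
#'
#' `G_blend = w G + (1 - w) A22`, the standard device to guarantee a
#' non-singular genomic relationship matrix before inversion.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship block over the same animals, same order.
#' @param weight weight on G, strictly inside (0, 1); default 0.95.
#' @return Blended matrix, attribute `kind = "Gblend"`.
#' @export
blend_G <- function(G, A22, weight = 0.95) {
  if (!(weight > 0 && weight < 1)) abort("blend weight must be strictly between 0 and 1")
  if (!all(dim(G) == dim(A22))) abort("G and A22 dimensions disagree")
  structure(weight * as.matrix(G) + (1 - weight) * as.matrix(A22), kind = "Gblend")
}

#' Single-step H-inverse
#'
#' `H^-1 = A^-1 + [[0, 0], [0, G^-1 - A22^-1]]`: the pedigree inverse
#' everywhere, with the genotyped-by-genotyped block corrected by the
#' difference between the inverse (blended) genomic matrix and the inverse of
#' the genotyped pedigree block.
#'
#' @param Ainv sparse inverse numerator relationship matrix over the full
#'   pedigree ([build_A_inverse()]).
#' @param G blended genomic relationship matrix over the genotyped animals
#'   (inverted internally), with animal labels as dimnames.
#' @param A22 pedigree relationship block over the same animals
#'   ([build_A()] with `subset`), inverted internally.
#' @return Sparse symmetric matrix, attribute `kind = "Hinv"` and attribute
#'   `genotyped` holding the genotyped animal labels. With an empty genotyped
#'   set this is exactly `Ainv`.
#' @export
build_H_inverse <- function(Ainv, G = NULL, A22 = NULL) {
  n <- nrow(Ainv)
  if (is.null(G) || nrow(G) == 0) {
    return(structure(Ainv, kind = "Hinv", genotyped = character(0)))
  }
  ids <- rownames(G)
  if (is.null(ids)) abort("G must carry animal labels as dimnames")
  gi <- match(ids, rownames(Ainv))
  if (anyNA(gi)) {
    abort(paste0(
      "genotyped animals absent from the pedigree: ",
      paste(utils::head(ids[is.na(gi)], 10), collapse = ", ")
    ))
  }
  if (!all(dim(G) == dim(A22))) abort("G and A22 dimensions disagree")
  Ginv <- solve(as.matrix(G))
  A22inv <- solve(as.matrix(A22))
  corr <- Ginv - A22inv
  ng <- length(gi)
  Corr <- Matrix::sparseMatrix(
    i = rep(gi, each = ng), j = rep(gi, times = ng),
    x = as.numeric(t(corr)), dims = c(n, n), dimnames = dimnames(Ainv)
  )
  H <- Matrix::forceSymmetric(Ainv + Corr)
  structure(H, kind = "Hinv", genotyped = ids)
}

#' Write the QC report
#' @param g a QC'd [genotype_data()].
#' @param path CSV output path (`snp,status,reason`).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(g, path) {
  if (is.null(g$qc_log)) abort("run qc_genotypes() first")
  utils::write.csv(g$qc_log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
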
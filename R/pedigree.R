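#' Construct a validated, renumbered pedigree
#'
#' Takes a data frame of animal/sire/dam labels (plus optional `hatch_week`
#' and `sex`), validates it (no duplicate animals, no animal its own ancestor,
#' parents not missing from the animal column unless unknown) and renumbers
#' it topologically so that parents always precede offspring. Original labels
#' are preserved.
#'
#' @param df data frame with columns `animal`, `sire`, `dam`; `0`, `""` or
#'   `NA` denote an unknown parent. Optional columns `hatch_week` and `sex`
#'   are carried through.
#' @return A tibble of class `pedigree_tbl`, ordered so parents precede
#'   offspring, with columns `id`, `sire_id`, `dam_id` (integer indices into
#'   the renumbered pedigree, `NA` for unknown), `animal` (original label),
#'   `generation` (topological rank, founders = 1), and any carried columns.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   animal = c("s1", "d1", "kid"), sire = c(0, 0, "s1"), dam = c(0, 0, "d1")
#' ))
#' ped$generation
#' @export
as_pedigree <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  lab <- as.character(df$animal)
  if (anyDuplicated(lab)) {
    abort(paste0(
      "duplicate animal ids: ",
      paste(unique(lab[duplicated(lab)]), collapse = ", ")
    ))
  }
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("0", "")] <- NA_character_
    x
  }
  sire <- clean(df$sire)
  dam <- clean(df$dam)
  missing_par <- setdiff(stats::na.omit(c(sire, dam)), lab)
  if (length(missing_par) > 0) {
    abort(paste0(
      "parents missing from the animal column: ",
      paste(utils::head(missing_par, 10), collapse = ", ")
    ))
  }
  n <- length(lab)
  si <- match(sire, lab)
  di <- match(dam, lab)
  if (any(si == seq_len(n), na.rm = TRUE) || any(di == seq_len(n), na.rm = TRUE)) {
    bad <- lab[which(si == seq_len(n) | di == seq_len(n))]
    abort(paste0("animal listed as its own parent: ", paste(bad, collapse = ", ")))
  }
  # Kahn topological sort; also detects cycles and yields generation ranks
  gen <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  level <- 0L
  while (any(remaining)) {
    level <- level + 1L
    ready <- remaining &
      (is.na(si) | !remaining[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | !remaining[ifelse(is.na(di), 1L, di)])
    ready[!remaining] <- FALSE
    if (!any(ready)) {
      cyc <- lab[remaining]
      abort(paste0(
        "pedigree contains a cycle among: ",
        paste(utils::head(cyc, 10), collapse = " -> ")
      ))
    }
    gen[ready] <- level
    remaining[ready] <- FALSE
  }
  ord <- order(gen, seq_len(n))
  newpos <- match(seq_len(n), ord)
  out <- tibble(
    id = seq_len(n),
    sire_id = newpos[si][ord],
    dam_id = newpos[di][ord],
    animal = lab[ord],
    generation = gen[ord]
  )
  extra <- setdiff(names(df), c("animal", "sire", "dam"))
  for (col in extra) out[[col]] <- df[[col]][ord]
  class(out) <- c("pedigree_tbl", class(out))
  out
}

#' Read a pedigree CSV
#'
#' Expects header `animal,sire,dam[,hatch_week,...]`; `0` or blank encodes an
#' unknown parent. Rows may appear in any order; the result is renumbered so
#' parents precede offspring.
#'
#' @param path CSV file path.
#' @return A [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("animal", "sire", "dam") %in% names(df))) {
    abort(sprintf(
      "malformed pedigree header in '%s' (line 1): need animal,sire,dam",
      path
    ))
  }
  as_pedigree(df)
}

#' Inbreeding coefficients
#'
#' Computes `F_i = A_ii - 1` for every animal using the Meuwissen-Luo
#' algorithm (no dense relationship matrix is formed). Founders have `F = 0`.
#'
#' @param ped a [as_pedigree()] tibble.
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree_tbl"))
  f <- inbreeding_cpp(
    ifelse(is.na(ped$sire_id), 0L, ped$sire_id),
    ifelse(is.na(ped$dam_id), 0L, ped$dam_id)
  )
  setNames(f, ped$animal)
}

#' Numerator relationship matrix A (or a genotyped-subset block)
#'
#' Builds the pedigree numerator relationship matrix by the tabular method:
#' `a_jj = 1 + 0.5 a_{s(j),d(j)}` and `a_ij = 0.5 (a_{i,s(j)} + a_{i,d(j)})`.
#' When `subset` is given, A is computed over the full pedigree and then
#' sliced, which is how the genotyped block `A22` of single-step evaluation
#' must be obtained.
#'
#' @param ped a [as_pedigree()] tibble.
#' @param subset optional character vector of animal labels (or integer ids)
#'   selecting a block such as the genotyped animals.
#' @return Dense symmetric matrix with animal labels as dimnames; attribute
#'   `kind` is `"A"` or `"A22"`.
#' @export
build_A <- function(ped, subset = NULL) {
  stopifnot(inherits(ped, "pedigree_tbl"))
  n <- nrow(ped)
  if (n > 8000) {
    abort("dense tabular A is limited to pedigrees of at most 8000 animals")
  }
  A <- tabular_A_cpp(
    ifelse(is.na(ped$sire_id), 0L, ped$sire_id),
    ifelse(is.na(ped$dam_id), 0L, ped$dam_id)
  )
  dimnames(A) <- list(ped$animal, ped$animal)
  if (is.null(subset)) {
    return(structure(A, kind = "A"))
  }
  if (length(subset) == 0) {
    return(structure(matrix(0, 0, 0), kind = "A22"))
  }
  idx <- if (is.numeric(subset)) as.integer(subset) else match(as.character(subset), ped$animal)
  if (anyNA(idx) || any(idx < 1 | idx > n)) {
    abort("subset contains animals absent from the pedigree")
  }
  structure(A[idx, idx, drop = FALSE], kind = "A22")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `alpha_i = 1/d_i` times the `{1, -1/2, -1/2}` outer-product pattern over
#' (animal, sire, dam), where the Mendelian-sampling variance is
#' `d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_known` with one, and `1` for founders.
#'
#' @param ped a [as_pedigree()] tibble.
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`) with animal labels;
#'   attribute `kind = "Ainv"`. Nonzeros are confined to
#'   (individual, parent, mate) triples.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree_tbl"))
  n <- nrow(ped)
  F <- unname(inbreeding(ped))
  s <- ped$sire_id
  d <- ped$dam_id
  Fs <- ifelse(is.na(s), NA_real_, F[ifelse(is.na(s), 1L, s)])
  Fd <- ifelse(is.na(d), NA_real_, F[ifelse(is.na(d), 1L, d)])
  di <- ifelse(!is.na(s) & !is.na(d), 0.5 - 0.25 * (Fs + Fd),
    ifelse(!is.na(s), 0.75 - 0.25 * Fs,
      ifelse(!is.na(d), 0.75 - 0.25 * Fd, 1)
    )
  )
  alpha <- 1 / di
  ii <- seq_len(n)
  trip_i <- c(ii)
  trip_j <- c(ii)
  trip_x <- c(alpha)
  add <- function(i, j, x) {
    trip_i <<- c(trip_i, i)
    trip_j <<- c(trip_j, j)
    trip_x <<- c(trip_x, x)
  }
  hs <- !is.na(s)
  hd <- !is.na(d)
  add(ii[hs], s[hs], -alpha[hs] / 2)
  add(s[hs], ii[hs], -alpha[hs] / 2)
  add(ii[hd], d[hd], -alpha[hd] / 2)
  add(d[hd], ii[hd], -alpha[hd] / 2)
  add(s[hs], s[hs], alpha[hs] / 4)
  add(d[hd], d[hd], alpha[hd] / 4)
  both <- hs & hd
  add(s[both], d[both], alpha[both] / 4)
  add(d[both], s[both], alpha[both] / 4)
  Ainv <- Matrix::sparseMatrix(
    i = trip_i, j = trip_j, x = trip_x, dims = c(n, n),
    dimnames = list(ped$animal, ped$animal)
  )
  structure(Matrix::forceSymmetric(Ainv), kind = "Ainv")
}

#' @export
print.pedigree_tbl <- function(x, ...) {
  cat(sprintf(
    "<pedigree_tbl> %d animals, %d founders, %d generation levels\n",
    nrow(x), sum(is.na(x$sire_id) & is.na(x$dam_id)), max(x$generation)
  ))
  NextMethod()
}

#' Export a relationship matrix in coordinate format
#'
#' Writes nonzero entries as `i,j,value` rows under a header comment naming
#' the matrix kind, together with a sidecar id map (`index,animal`).
#'
#' @param m matrix (dense or sparse) with animal dimnames.
#' @param path output path for the coordinate file; the id map is written to
#'   `paste0(path, ".ids")`.
#' @param kind label recorded in the header (defaults to the `kind` attribute).
#' @return `path`, invisibly.
#' @export
write_relmatrix <- function(m, path, kind = attr(m, "kind") %||% "rel") {
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@x != 0
  df <- data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, value = tm@x[keep])
  df <- df[order(df$i, df$j), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s n=%d ids=%s", kind, nrow(m), basename(paste0(path, ".ids"))), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(index = seq_len(nrow(m)), animal = rownames(m) %||% seq_len(nrow(m))),
    paste0(path, ".ids"),
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
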
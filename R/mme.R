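#' Build random-regression design matrices
#'
#' Constructs the incidence matrices of the weekly egg-production model
#' `y = Xb + Qa + Zp + e`. Fixed effects are the hatch-week-by-week-of-lay
#' interaction (all cells present in the data), the week-of-lay-by-AFE-class
#' interaction (first AFE class dropped within each week as reference), and
#' one body-weight regression slope per week of lay (body weight centered).
#' `Q` places the record's Legendre covariate row in the animal's coefficient
#' block; `Z` does the same over hens with records.
#'
#' @param pheno phenotype tibble with columns `animal`, `week`, `eggs`,
#'   `afe_class`, `hatch_week`, `body_weight` (at most one record per
#'   animal-week).
#' @param ped the [as_pedigree()] tibble the animals belong to.
#' @param basis a [legendre_design()] basis covering the weeks present.
#' @param res a [residual_spec()] defining the residual periods.
#' @return Object of class `rr_design`: record table, sparse `X`, `Q`, `Z`,
#'   fixed-effect column map, hen index, and the centering constant.
#' @export
build_design <- function(pheno, ped, basis = legendre_design(), res = NULL) {
  pheno <- as_tibble(pheno)
  need <- c("animal", "week", "eggs", "afe_class", "hatch_week", "body_weight")
  stopifnot(all(need %in% names(pheno)))
  aid <- match(as.character(pheno$animal), ped$animal)
  if (anyNA(aid)) {
    abort(paste0(
      "records for animals absent from the pedigree: ",
      paste(utils::head(unique(pheno$animal[is.na(aid)]), 10), collapse = ", ")
    ))
  }
  wk <- as.integer(pheno$week)
  if (any(!wk %in% basis$weeks)) abort("record weeks outside the basis grid")
  if (anyDuplicated(paste(aid, wk))) abort("more than one record per animal-week")
  if (anyNA(pheno$eggs)) abort("egg counts must not be missing")

  afe_levels <- sort(unique(as.character(pheno$afe_class)))
  hw_levels <- sort(unique(as.character(pheno$hatch_week)))
  nrec <- nrow(pheno)

  hw_cell <- paste(pheno$hatch_week, wk, sep = ":")
  hw_cells <- sort(unique(hw_cell))
  hw_idx <- match(hw_cell, hw_cells)

  # reference AFE class (first level) carries no coefficient, per week
  afe_chr <- as.character(pheno$afe_class)
  is_ref <- afe_chr == afe_levels[1]
  afe_cell <- ifelse(is_ref, NA_character_, paste(afe_chr, wk, sep = ":"))
  afe_cells <- sort(unique(afe_cell[!is.na(afe_cell)]))
  afe_idx <- match(afe_cell, afe_cells)

  bw_center <- mean(pheno$body_weight)
  bwc <- pheno$body_weight - bw_center
  slope_weeks <- sort(unique(wk))
  slope_idx <- match(wk, slope_weeks)

  n_hw <- length(hw_cells)
  n_afe <- length(afe_cells)
  n_sl <- length(slope_weeks)
  rows <- seq_len(nrec)
  has_afe <- !is.na(afe_idx)
  X <- Matrix::sparseMatrix(
    i = c(rows, rows[has_afe], rows),
    j = c(hw_idx, n_hw + afe_idx[has_afe], n_hw + n_afe + slope_idx),
    x = c(rep(1, nrec), rep(1, sum(has_afe)), bwc),
    dims = c(nrec, n_hw + n_afe + n_sl)
  )
  fixed_map <- tibble(
    term = c(
      rep("hatchweek_week", n_hw), rep("week_afe", n_afe),
      rep("bodyweight_slope", n_sl)
    ),
    level = c(hw_cells, afe_cells, paste0("week", slope_weeks))
  )

  q <- basis$order + 1
  wrow <- match(wk, basis$weeks)
  Phi <- basis$Phi
  N <- nrow(ped)
  hens <- sort(unique(aid))
  hen_of <- match(aid, hens)
  Q <- Matrix::sparseMatrix(
    i = rep(rows, each = q),
    j = as.integer(t(outer((aid - 1) * q, seq_len(q), `+`))),
    x = as.numeric(t(Phi[wrow, , drop = FALSE])),
    dims = c(nrec, N * q)
  )
  Z <- Matrix::sparseMatrix(
    i = rep(rows, each = q),
    j = as.integer(t(outer((hen_of - 1) * q, seq_len(q), `+`))),
    x = as.numeric(t(Phi[wrow, , drop = FALSE])),
    dims = c(nrec, length(hens) * q)
  )

  rec <- tibble(
    animal_id = aid, hen = hen_of, week = wk, y = as.numeric(pheno$eggs),
    hw_level = hw_idx, afe_level = afe_idx, bw = bwc
  )
  if (!is.null(res)) {
    period_of_week <- purrr::map_int(
      basis$weeks,
      function(w) which(res$week_lo <= w & w <= res$week_hi)
    )
    rec$period <- period_of_week[match(wk, basis$weeks)]
  }
  structure(
    list(
      rec = rec, X = X, Q = Q, Z = Z, fixed_map = fixed_map,
      hens = hens, basis = basis, bw_center = bw_center,
      afe_levels = afe_levels, hw_levels = hw_levels, res = res,
      n_animals = N, animal_labels = ped$animal
    ),
    class = "rr_design"
  )
}

#' Assemble the mixed-model equations
#'
#' Forms `W' R^-1 W + blockdiag(0, Kinv x C^-1, I x P^-1)` and the matching
#' right-hand side, where `W = [X Q Z]`, `R` holds the period residual
#' variance of each record's week, and `Kinv` is either the pedigree inverse
#' (`A^-1`, RR-PBLUP) or the single-step inverse (`H^-1`, RR-ssGBLUP).
#'
#' @param design an [build_design()] object (built with its `res`).
#' @param Kinv sparse relationship inverse over the full pedigree.
#' @param C,P coefficient covariance matrices of the additive and permanent
#'   environmental effects (must be positive definite).
#' @param res a [residual_spec()]; defaults to the one used in the design.
#' @return Object of class `mme_system` with `LHS`, `RHS` and index maps.
#' @export
assemble_mme <- function(design, Kinv, C, P, res = design$res) {
  stopifnot(inherits(design, "rr_design"))
  if (is.null(res)) abort("a residual_spec is required")
  assert_pd(as.matrix(C), "C (additive coefficient covariance)")
  assert_pd(as.matrix(P), "P (permanent environmental coefficient covariance)")
  q <- design$basis$order + 1
  N <- design$n_animals
  if (nrow(Kinv) != N) {
    abort(sprintf("Kinv is %dx%d but the pedigree has %d animals", nrow(Kinv), ncol(Kinv), N))
  }
  nh <- length(design$hens)
  rvar <- residual_by_week(res, design$basis$weeks)
  w <- 1 / rvar[match(design$rec$week, design$basis$weeks)]
  W <- cbind(design$X, design$Q, design$Z)
  Rinv <- Matrix::Diagonal(x = w)
  LHS <- Matrix::forceSymmetric(Matrix::crossprod(W, Rinv %*% W))
  RHS <- as.numeric(Matrix::crossprod(W, w * design$rec$y))
  Cinv <- solve(as.matrix(C))
  Pinv <- solve(as.matrix(P))
  nf <- ncol(design$X)
  prior <- Matrix::bdiag(
    Matrix::Matrix(0, nf, nf, sparse = TRUE),
    Matrix::kronecker(Kinv, Matrix::Matrix(Cinv, sparse = TRUE)),
    Matrix::kronecker(Matrix::Diagonal(nh), Matrix::Matrix(Pinv, sparse = TRUE))
  )
  structure(
    list(
      LHS = Matrix::forceSymmetric(LHS + prior), RHS = RHS,
      n_fixed = nf, n_animals = N, q = q, hens = design$hens,
      fixed_map = design$fixed_map, basis = design$basis,
      animal_labels = design$animal_labels,
      kind = attr(Kinv, "kind") %||% "Kinv"
    ),
    class = "mme_system"
  )
}

#' @export
print.mme_system <- function(x, ...) {
  cat(sprintf(
    "<mme_system> %d equations (%d fixed, %d animals x %d, %d hens x %d), relationship %s\n",
    length(x$RHS), x$n_fixed, x$n_animals, x$q, length(x$hens), x$q, x$kind
  ))
  invisible(x)
}

# preconditioned conjugate gradients with block-Jacobi preconditioner
pcg_solve <- function(A, b, block_starts, block_sizes, tol = 1e-10, maxit = 5000) {
  n <- length(b)
  # build sparse inverse of the diagonal blocks
  ti <- tj <- tx <- vector("list", length(block_starts))
  Adg <- A
  for (k in seq_along(block_starts)) {
    idx <- block_starts[k] + seq_len(block_sizes[k]) - 1L
    blk <- as.matrix(Adg[idx, idx, drop = FALSE])
    bi <- solve(blk)
    ti[[k]] <- rep(idx, each = length(idx))
    tj[[k]] <- rep(idx, times = length(idx))
    tx[[k]] <- as.numeric(bi)
  }
  Minv <- Matrix::sparseMatrix(
    i = unlist(ti), j = unlist(tj), x = unlist(tx), dims = c(n, n)
  )
  x <- numeric(n)
  r <- b - as.numeric(A %*% x)
  z <- as.numeric(Minv %*% r)
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / bn
    hist <- c(hist, rel)
    if (rel < tol) {
      return(list(x = x, iterations = it, relres = rel, history = hist))
    }
    z <- as.numeric(Minv %*% r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  abort(sprintf(
    "PCG did not converge in %d iterations (final relative residual %.2e; history tail: %s)",
    maxit, rel, paste(signif(utils::tail(hist, 5), 3), collapse = ", ")
  ))
}

#' Solve the mixed-model equations
#'
#' @param sys an [assemble_mme()] system.
#' @param method `"direct"` (sparse Cholesky, default for systems up to 20k
#'   unknowns) or `"pcg"` (preconditioned conjugate gradients with a
#'   block-Jacobi preconditioner over the fixed scalars and the 4x4 animal /
#'   hen coefficient blocks).
#' @param tol relative-residual tolerance for PCG.
#' @param maxit PCG iteration cap.
#' @return Object of class `rr_solution`: `fixed` tibble, `alpha` (animals x
#'   coefficients, rownames = animal labels), `pe` (hens x coefficients),
#'   relative residual achieved, and the system's metadata.
#' @export
solve_mme <- function(sys, method = NULL, tol = 1e-10, maxit = 5000) {
  stopifnot(inherits(sys, "mme_system"))
  n <- length(sys$RHS)
  method <- method %||% if (n <= 20000) "direct" else "pcg"
  method <- match.arg(method, c("direct", "pcg"))
  if (method == "direct") {
    ch <- Matrix::Cholesky(sys$LHS, LDL = FALSE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(ch, sys$RHS))
    its <- NA_integer_
  } else {
    q <- sys$q
    nf <- sys$n_fixed
    nblk <- nf + sys$n_animals + length(sys$hens)
    starts <- c(seq_len(nf), nf + (seq_len(sys$n_animals) - 1L) * q + 1L,
      nf + sys$n_animals * q + (seq_len(length(sys$hens)) - 1L) * q + 1L)
    sizes <- c(rep(1L, nf), rep(q, sys$n_animals + length(sys$hens)))
    res <- pcg_solve(sys$LHS, sys$RHS, starts, sizes, tol = tol, maxit = maxit)
    sol <- res$x
    its <- res$iterations
  }
  relres <- sqrt(sum((as.numeric(sys$LHS %*% sol) - sys$RHS)^2)) / sqrt(sum(sys$RHS^2))
  q <- sys$q
  nf <- sys$n_fixed
  N <- sys$n_animals
  alpha <- matrix(sol[nf + seq_len(N * q)], N, q, byrow = TRUE)
  rownames(alpha) <- sys$animal_labels
  colnames(alpha) <- paste0("phi", seq_len(q) - 1)
  pe <- matrix(sol[nf + N * q + seq_len(length(sys$hens) * q)], length(sys$hens), q, byrow = TRUE)
  rownames(pe) <- sys$animal_labels[sys$hens]
  colnames(pe) <- colnames(alpha)
  structure(
    list(
      fixed = dplyr::mutate(sys$fixed_map, estimate = sol[seq_len(nf)]),
      alpha = alpha, pe = pe, relres = relres, method = method,
      iterations = its, basis = sys$basis, kind = sys$kind
    ),
    class = "rr_solution"
  )
}

#' Fit a random-regression evaluation (RR-PBLUP or RR-ssGBLUP)
#'
#' Tidy front end tying the pipeline together: builds the design, the
#' relationship inverse (pedigree `A^-1`, or single-step `H^-1` when a QC'd
#' genotype set is supplied), assembles and solves the mixed-model equations,
#' and attaches weekly trajectory parameters.
#'
#' @param pheno phenotype tibble (see [build_design()]).
#' @param ped [as_pedigree()] tibble.
#' @param C,P positive-definite coefficient covariance matrices.
#' @param res a [residual_spec()].
#' @param genotypes optional QC'd [genotype_data()]; when given, the fit is
#'   RR-ssGBLUP with VanRaden method-1 G blended as
#'   `blend_weight * G + (1 - blend_weight) * A22`.
#' @param basis Legendre basis (default order 3 on weeks 1..24).
#' @param blend_weight weight on G in the blend (default 0.95).
#' @param method solver passed to [solve_mme()].
#' @return Object of class `rr_fit` with the design, solution, relationship
#'   kind, trajectory parameters and inputs.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n_generations = 3, n_dams = 20), seed = 1)
#' pars <- turkey_reference_params()
#' fit <- fit_rr(sim$pheno, sim$ped, pars$C_pd, pars$P_pd, pars$residual)
#' glance(fit)
#' }
#' @export
fit_rr <- function(pheno, ped, C, P, res, genotypes = NULL,
                   basis = legendre_design(), blend_weight = 0.95,
                   method = NULL) {
  design <- build_design(pheno, ped, basis, res)
  if (is.null(genotypes)) {
    Kinv <- build_A_inverse(ped)
    label <- "RR-PBLUP"
  } else {
    stopifnot(inherits(genotypes, "genotype_data"))
    if (!isTRUE(genotypes$imputed)) {
      abort("genotypes must pass qc_genotypes() before a single-step fit")
    }
    ids <- rownames(genotypes$dosages)
    Ainv <- build_A_inverse(ped)
    A22 <- build_A(ped, subset = ids)
    G <- build_G_vanraden1(genotypes)
    Gb <- blend_G(G, A22, blend_weight)
    Kinv <- build_H_inverse(Ainv, Gb, A22)
    label <- "RR-ssGBLUP"
  }
  sys <- assemble_mme(design, Kinv, C, P, res)
  sol <- solve_mme(sys, method = method)
  structure(
    list(
      design = design, solution = sol, method_label = label,
      trajectory = trajectory_parameters(
        cov_function(C, basis, "additive"),
        cov_function(P, basis, "pe"), res
      ),
      C = C, P = P, res = res, basis = basis,
      sire_id = ped$sire_id, dam_id = ped$dam_id,
      genotyped = if (is.null(genotypes)) character(0) else rownames(genotypes$dosages)
    ),
    class = "rr_fit"
  )
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf(
    "<rr_fit> %s: %d records, %d hens, %d animals in pedigree, %d genotyped\n",
    x$method_label, nrow(x$design$rec), length(x$design$hens),
    x$design$n_animals, length(x$genotyped)
  ))
  cat(sprintf("solver %s, relative residual %.2e\n", x$solution$method, x$solution$relres))
  invisible(x)
}

#' Weekly EBV trajectories, cumulative EBV and persistency
#'
#' Maps each animal's additive coefficient solutions through the Legendre
#' basis: weekly `EBV(t) = phi(t)' alpha`, cumulative EBV is the sum over the
#' week grid, and persistency is the peak-to-late-week slope
#' (see [persistency()]).
#'
#' @param fit an [fit_rr()] object (or an `rr_solution`).
#' @param peak_week,end_week,divisor persistency definition (defaults: weeks
#'   3 and 18, divisor 16).
#' @return A `breeding_values` tibble: `animal`, `genotyped`, one `wk<t>`
#'   column per week, `cumulative`, `persistency`.
#' @export
ebv_trajectory <- function(fit, peak_week = 3, end_week = 18, divisor = 16) {
  sol <- if (inherits(fit, "rr_fit")) fit$solution else fit
  basis <- sol$basis
  ebv <- sol$alpha %*% t(basis$Phi)
  colnames(ebv) <- paste0("wk", basis$weeks)
  out <- as_tibble(ebv)
  out <- dplyr::mutate(out,
    animal = rownames(sol$alpha),
    genotyped = if (inherits(fit, "rr_fit")) rownames(sol$alpha) %in% fit$genotyped else NA,
    .before = 1
  )
  out$cumulative <- unname(rowSums(ebv))
  out$persistency <- unname(apply(ebv, 1, function(v) {
    persistency(setNames(v, basis$weeks), peak_week, end_week, divisor)
  }))
  class(out) <- c("breeding_values", class(out))
  out
}

#' Persistency slope of a weekly trajectory
#'
#' `(value(peak_week) - value(end_week)) / divisor`; a smaller slope means a
#' more persistent layer. The conventional summary uses peak week 3, end week
#' 18, and divisor 16.
#'
#' @param values numeric vector of weekly values named by week.
#' @param peak_week,end_week weeks to difference (must differ).
#' @param divisor scale divisor (default 16).
#' @return The slope (a single number).
#' @examples
#' persistency(c(`3` = 5.30, `18` = 3.91)) # 0.0869
#' @export
persistency <- function(values, peak_week = 3, end_week = 18, divisor = 16) {
  if (peak_week == end_week) abort("peak and end weeks must differ")
  nm <- names(values)
  if (is.null(nm)) abort("values must be named by week")
  vp <- values[match(as.character(peak_week), nm)]
  ve <- values[match(as.character(end_week), nm)]
  if (anyNA(c(vp, ve))) abort("peak/end week not present in values")
  unname((vp - ve) / divisor)
}

#' @method tidy rr_fit
#' @export
tidy.rr_fit <- function(x, effects = c("ebv", "fixed", "pe"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(x$solution$fixed)
  }
  if (effects == "pe") {
    m <- x$solution$pe
    return(dplyr::mutate(as_tibble(m), animal = rownames(m), .before = 1))
  }
  ebv <- ebv_trajectory(x)
  tidyr::pivot_longer(
    dplyr::select(ebv, "animal", "genotyped", dplyr::starts_with("wk")),
    dplyr::starts_with("wk"),
    names_to = "week", names_prefix = "wk", names_transform = as.integer,
    values_to = "ebv"
  )
}

#' @method glance rr_fit
#' @export
glance.rr_fit <- function(x, ...) {
  tibble(
    method = x$method_label,
    n_records = nrow(x$design$rec),
    n_hens = length(x$design$hens),
    n_animals = x$design$n_animals,
    n_genotyped = length(x$genotyped),
    n_fixed = ncol(x$design$X),
    solver = x$solution$method,
    relres = x$solution$relres
  )
}

#' @method augment rr_fit
#' @export
augment.rr_fit <- function(x, ...) {
  rec <- x$design$rec
  fitted_fixed <- as.numeric(x$design$X %*% x$solution$fixed$estimate)
  wrow <- match(rec$week, x$basis$weeks)
  Phi <- x$basis$Phi
  g <- rowSums(Phi[wrow, , drop = FALSE] * x$solution$alpha[rec$animal_id, , drop = FALSE])
  hen_rows <- match(rec$animal_id, x$design$hens)
  pe <- rowSums(Phi[wrow, , drop = FALSE] * x$solution$pe[hen_rows, , drop = FALSE])
  dplyr::mutate(rec,
    animal = x$design$animal_labels[rec$animal_id],
    .fitted = fitted_fixed + g + pe,
    .resid = rec$y - (fitted_fixed + g + pe)
  )
}
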
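#' Normalized Legendre basis over weeks of lay
#'
#' Builds the matrix of normalized Legendre polynomial covariates used by the
#' random-regression model. Week `t` is mapped linearly onto the standardized
#' time axis so that the first week corresponds to `x = -1` and the last to
#' `x = +1`; the k-th covariate is `sqrt((2k+1)/2) * P_k(x)` with `P_k` the
#' standard Legendre polynomial, so the columns are orthonormal under the
#' continuous inner product on `[-1, 1]`.
#'
#' @param order highest polynomial order `k` (an order-3 basis has 4
#'   covariates, the default used for 24-week egg-production trajectories).
#' @param weeks integer grid of weeks of lay (default `1:24`).
#' @return An object of class `legendre_basis`: a list with elements `order`,
#'   `weeks`, `x` (standardized time) and `Phi`, the `length(weeks) x
#'   (order+1)` covariate matrix.
#' @examples
#' basis <- legendre_design(order = 3, weeks = 1:24)
#' basis$Phi[13, ] # covariates for week 13
#' @export
legendre_design <- function(order = 3, weeks = 1:24) {
  stopifnot(order >= 0, length(weeks) >= 1)
  weeks <- as.integer(weeks)
  if (length(weeks) < 2 && order > 0) {
    abort("a single-week grid only supports order 0")
  }
  x <- if (length(weeks) == 1) 0 else {
    -1 + 2 * (weeks - min(weeks)) / (max(weeks) - min(weeks))
  }
  P <- matrix(0, length(x), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      # Bonnet recurrence: k P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  Phi <- sweep(P, 2, sqrt((2 * (0:order) + 1) / 2), "*")
  dimnames(Phi) <- list(paste0("week", weeks), paste0("phi", 0:order))
  structure(
    list(order = order, weeks = weeks, x = x, Phi = Phi),
    class = "legendre_basis"
  )
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat(sprintf(
    "<legendre_basis> order %d over weeks %d..%d (%d covariates)\n",
    x$order, min(x$weeks), max(x$weeks), x$order + 1
  ))
  invisible(x)
}

#' Covariance function of random-regression coefficients
#'
#' Pairs a symmetric coefficient (co)variance matrix (additive genetic `C` or
#' permanent environmental `P`) with the Legendre basis that defines its
#' trajectory expansion.
#'
#' @param coeff symmetric `(order+1) x (order+1)` matrix of coefficient
#'   (co)variances.
#' @param basis a [legendre_design()] basis of matching order.
#' @param label one of `"additive"` or `"pe"`.
#' @return An object of class `cov_function`.
#' @export
cov_function <- function(coeff, basis = legendre_design(), label = c("additive", "pe")) {
  label <- match.arg(label)
  coeff <- as.matrix(coeff)
  stopifnot(nrow(coeff) == ncol(coeff))
  if (nrow(coeff) != basis$order + 1) {
    abort(sprintf(
      "coefficient matrix is %dx%d but basis order %d needs %d",
      nrow(coeff), ncol(coeff), basis$order, basis$order + 1
    ))
  }
  if (max(abs(coeff - t(coeff))) > 1e-8) abort("coefficient matrix must be symmetric")
  coeff <- (coeff + t(coeff)) / 2
  structure(list(coeff = coeff, basis = basis, label = label), class = "cov_function")
}

#' Expand a coefficient covariance matrix to weekly (co)variances
#'
#' Computes `Phi %*% coeff %*% t(Phi)`: the week-by-week (co)variance matrix
#' implied by the coefficient covariance of a random-regression term.
#'
#' @param x a [cov_function()], or a plain symmetric coefficient matrix.
#' @param basis basis to use when `x` is a plain matrix.
#' @return A symmetric `length(weeks) x length(weeks)` matrix with week
#'   dimnames; its rank is at most `order + 1`.
#' @examples
#' basis <- legendre_design()
#' K <- expand_covariance(diag(4), basis)
#' all.equal(diag(K), rowSums(basis$Phi^2), check.names = FALSE)
#' @export
expand_covariance <- function(x, basis = legendre_design()) {
  cf <- if (inherits(x, "cov_function")) x else cov_function(x, basis)
  Phi <- cf$basis$Phi
  K <- Phi %*% cf$coeff %*% t(Phi)
  dimnames(K) <- list(rownames(Phi), rownames(Phi))
  (K + t(K)) / 2
}

#' Heterogeneous residual variance specification
#'
#' Residual variance of weekly egg counts is modelled as constant within
#' contiguous periods of the trajectory. The default four periods and
#' variances are the reference estimates for a commercial turkey female line
#' (see [turkey_reference_params()]).
#'
#' @param periods a data frame with columns `week_lo`, `week_hi`, `var_e`;
#'   periods must be contiguous, non-overlapping, and cover the week grid.
#' @param weeks the week grid the periods must cover.
#' @return A tibble of class `residual_spec`.
#' @export
residual_spec <- function(periods, weeks = 1:24) {
  p <- as_tibble(periods)
  stopifnot(all(c("week_lo", "week_hi", "var_e") %in% names(p)))
  p <- dplyr::arrange(p, .data$week_lo)
  if (any(p$var_e <= 0)) abort("residual variances must be positive")
  covered <- unlist(purrr::map2(p$week_lo, p$week_hi, seq))
  if (!identical(sort(covered), sort(as.integer(weeks)))) {
    abort("residual periods must tile the week grid exactly (contiguous, exhaustive, non-overlapping)")
  }
  structure(p, class = c("residual_spec", class(p)))
}

#' Per-week residual variances from a residual specification
#' @param res a [residual_spec()].
#' @param weeks weeks to look up.
#' @return Numeric vector of residual variances, one per week.
#' @export
residual_by_week <- function(res, weeks = 1:24) {
  idx <- purrr::map_int(as.integer(weeks), function(w) {
    j <- which(res$week_lo <= w & w <= res$week_hi)
    if (length(j) != 1) abort(sprintf("week %d not covered by residual spec", w))
    j
  })
  setNames(res$var_e[idx], paste0("week", weeks))
}

#' Weekly variances, heritabilities and correlation matrices of a trajectory
#'
#' Combines the basis expansions of the additive-genetic and
#' permanent-environmental coefficient covariances with the period residual
#' variances into per-week variance components, heritabilities, and genetic /
#' phenotypic correlation matrices. Residuals are independent across weeks, so
#' between-week phenotypic covariance is the genetic plus the permanent
#' environmental covariance; the residual variance enters the within-week
#' phenotypic variance only.
#'
#' @param add,pe additive and permanent-environmental [cov_function()]s (or
#'   plain coefficient matrices interpreted on `basis`).
#' @param res a [residual_spec()].
#' @param basis basis used when `add`/`pe` are plain matrices.
#' @return An object of class `rregg_trajectory`: list with `by_week` (tibble:
#'   week, var_a, var_pe, var_e, var_p, h2), `cor_g`, `cor_p` (week-by-week
#'   correlation matrices), and the expansions `K_a`, `K_pe`.
#' @examples
#' pars <- turkey_reference_params()
#' tr <- trajectory_parameters(pars$C, pars$P, pars$residual)
#' tr$by_week[c(1, 13, 18), ]
#' @export
trajectory_parameters <- function(add, pe, res, basis = legendre_design()) {
  K_a <- expand_covariance(add, basis)
  K_pe <- expand_covariance(pe, basis)
  weeks <- if (inherits(add, "cov_function")) add$basis$weeks else basis$weeks
  var_e <- unname(residual_by_week(res, weeks))
  var_a <- diag(K_a)
  var_pe <- diag(K_pe)
  var_p <- var_a + var_pe + var_e
  if (any(var_p <= 0)) abort("total phenotypic variance must be positive at every week")
  K_p <- K_a + K_pe
  diag(K_p) <- var_p
  structure(
    list(
      by_week = tibble(
        week = as.integer(weeks),
        var_a = unname(var_a), var_pe = unname(var_pe), var_e = var_e,
        var_p = unname(var_p), h2 = unname(var_a / var_p)
      ),
      cor_g = pmin(pmax(stats::cov2cor(K_a), -1), 1),
      cor_p = pmin(pmax(stats::cov2cor(K_p), -1), 1),
      K_a = K_a, K_pe = K_pe, K_p = K_p
    ),
    class = "rregg_trajectory"
  )
}

#' @export
print.rregg_trajectory <- function(x, ...) {
  cat("<rregg_trajectory> weekly variance components\n")
  print(x$by_week, n = 6)
  cat(sprintf(
    "h2 range %.2f-%.2f; genetic correlations %.2f-%.2f\n",
    min(x$by_week$h2), max(x$by_week$h2),
    min(x$cor_g[upper.tri(x$cor_g)]), max(x$cor_g[upper.tri(x$cor_g)])
  ))
  invisible(x)
}

#' @method tidy rregg_trajectory
#' @export
tidy.rregg_trajectory <- function(x, ...) x$by_week

#' Fit a reduced-order covariance function to a weekly covariance matrix
#'
#' Least-squares projection of a week-by-week covariance matrix onto the
#' Legendre basis of the requested order:
#' `coeff = (Phi'Phi)^-1 Phi' K Phi (Phi'Phi)^-1`. Goodness of fit is reported
#' as `1 - ||K - Phi coeff Phi'||_F / ||K||_F` (relative Frobenius criterion).
#'
#' @param K symmetric weekly covariance matrix.
#' @param order order of the fitted covariance function.
#' @param weeks week grid matching the rows of `K`.
#' @return List of class `cov_function_fit` with `coeff`, `basis`,
#'   `goodness_of_fit` and the fitted matrix `K_hat`.
#' @export
fit_covariance_function <- function(K, order = 3, weeks = 1:24) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K), nrow(K) == length(weeks))
  if (order + 1 > length(weeks)) abort("order + 1 must not exceed the number of weeks")
  basis <- legendre_design(order, weeks)
  Phi <- basis$Phi
  PtP <- crossprod(Phi)
  if (rcond(PtP) < 1e-12) abort("rank-deficient basis on this week grid")
  proj <- solve(PtP, t(Phi))
  coeff <- proj %*% K %*% t(proj)
  coeff <- (coeff + t(coeff)) / 2
  K_hat <- Phi %*% coeff %*% t(Phi)
  gof <- 1 - norm(K - K_hat, "F") / norm(K, "F")
  structure(
    list(coeff = coeff, basis = basis, goodness_of_fit = gof, K_hat = K_hat),
    class = "cov_function_fit"
  )
}

#' @export
print.cov_function_fit <- function(x, ...) {
  cat(sprintf(
    "<cov_function_fit> order %d, goodness of fit %.4f\n",
    x$basis$order, x$goodness_of_fit
  ))
  invisible(x)
}

#' Variance and correlation of summed weekly genetic values
#'
#' For subsets of weeks, the variance of the summed trajectory value is the
#' bilinear form `1' K 1` over the subset block, and the covariance between
#' two partial sums is the corresponding rectangular block sum. Used, e.g., to
#' relate 16-week to 24-week cumulative egg production.
#'
#' @param K weekly covariance matrix (rows/cols indexed by `weeks`).
#' @param subset_a,subset_b week subsets (positions in `weeks`).
#' @param weeks week labels of `K`'s rows.
#' @return Tibble with `var_a`, `var_b`, `cov_ab`, `cor_ab`.
#' @export
partial_sum_stats <- function(K, subset_a, subset_b = subset_a, weeks = 1:24) {
  if (length(subset_a) == 0 || length(subset_b) == 0) abort("week subsets must be non-empty")
  ia <- match(subset_a, weeks)
  ib <- match(subset_b, weeks)
  if (anyNA(ia) || anyNA(ib)) abort("subset weeks must be on the matrix grid")
  va <- sum(K[ia, ia])
  vb <- sum(K[ib, ib])
  cab <- sum(K[ia, ib])
  tibble(var_a = va, var_b = vb, cov_ab = cab, cor_ab = cab / sqrt(va * vb))
}
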
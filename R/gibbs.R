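#' Gibbs chain configuration
#'
#' Defaults follow the standard long-chain protocol for random-regression
#' variance components: 200,000 rounds, 20,000 burn-in, every 50th sample
#' saved. Tests and desk-scale runs use shorter chains via these arguments.
#'
#' @param rounds total Gibbs rounds.
#' @param burn_in rounds discarded before saving (must be `< rounds`).
#' @param thin save every `thin`-th post-burn-in sample (`>= 1`).
#' @param seed RNG seed for the chain.
#' @return A `chain_config` list; `n_saved(cfg)` gives the stored sample count.
#' @export
chain_config <- function(rounds = 200000, burn_in = 20000, thin = 50, seed = 1) {
  stopifnot(burn_in < rounds, thin >= 1)
  structure(
    list(
      rounds = as.integer(rounds), burn_in = as.integer(burn_in),
      thin = as.integer(thin), seed = as.integer(seed)
    ),
    class = "chain_config"
  )
}

#' Stored sample count implied by a chain configuration
#' @param cfg a [chain_config()].
#' @return `floor((rounds - burn_in) / thin)`.
#' @export
n_saved <- function(cfg) {
  (cfg$rounds - cfg$burn_in) %/% cfg$thin
}

tri_names <- function(prefix, q) {
  idx <- which(upper.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  sprintf("%s%d%d", prefix, idx[, "row"], idx[, "col"])
}

tri_to_matrix <- function(v, q) {
  m <- matrix(0, q, q)
  m[upper.tri(m, diag = TRUE)] <- NA
  idx <- which(upper.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    m[idx[k, 1], idx[k, 2]] <- m[idx[k, 2], idx[k, 1]] <- v[k]
  }
  m
}

#' Bayesian estimation of random-regression variance components
#'
#' Gibbs sampler for the coefficient covariance matrices `C` (additive,
#' relationship-structured) and `P` (permanent environmental) and the period
#' residual variances of the weekly egg-production model. Location effects
#' are drawn from Gaussian full conditionals (blocked per animal over the
#' basis coefficients); `C` and `P` from inverse-Wishart full conditionals
#' with near-flat priors (identity scale, df = dim + 2); each residual
#' variance from a scaled inverse chi-square with a flat (df = -2) prior.
#'
#' @param pheno,ped,res,basis model inputs as in [fit_rr()]; only the period
#'   boundaries of `res` are used (the variances are estimated).
#' @param genotypes optional QC'd [genotype_data()] for a single-step
#'   (H-inverse) chain; default uses the pedigree inverse.
#' @param chain a [chain_config()].
#' @param blend_weight blend weight for G when genotypes are supplied.
#' @param start optional list with start values `C`, `P`, `r`.
#' @return Object of class `rregg_chain`: `draws` (tibble, one row per saved
#'   sample), chain metadata, and the model dimensions.
#' @export
run_gibbs <- function(pheno, ped, res, genotypes = NULL,
                      basis = legendre_design(), chain = chain_config(),
                      blend_weight = 0.95, start = NULL) {
  design <- build_design(pheno, ped, basis, res)
  if (is.null(genotypes)) {
    Kinv <- build_A_inverse(ped)
  } else {
    ids <- rownames(genotypes$dosages)
    Ainv <- build_A_inverse(ped)
    A22 <- build_A(ped, subset = ids)
    Gb <- blend_G(build_G_vanraden1(genotypes), A22, blend_weight)
    Kinv <- build_H_inverse(Ainv, Gb, A22)
  }
  q <- basis$order + 1
  np <- nrow(res)
  rec <- design$rec
  start <- start %||% list()
  Cstart <- start$C %||% diag(0.2, q)
  Pstart <- start$P %||% diag(0.2, q)
  rstart <- start$r %||% rep(max(stats::var(rec$y), 1e-2) / 2, np)
  hen_animal <- design$hens

  set.seed(chain$seed)
  out <- gibbs_rr_cpp(
    y = rec$y,
    week = match(rec$week, basis$weeks) - 1L,
    period = rec$period - 1L,
    hw = rec$hw_level - 1L,
    afe = ifelse(is.na(rec$afe_level), -1L, rec$afe_level - 1L),
    bw = rec$bw,
    hen = rec$hen - 1L,
    hen_animal = hen_animal - 1L,
    Phi = basis$Phi,
    Kinv = as(as(Kinv, "generalMatrix"), "CsparseMatrix"),
    C0 = diag(q), dfC = q + 2,
    P0 = diag(q), dfP = q + 2,
    res_df0 = -2,
    n_hw = max(rec$hw_level), n_afe = max(c(rec$afe_level, 0L), na.rm = TRUE),
    nperiod = np,
    Cstart = Cstart, Pstart = Pstart, rstart = rstart,
    rounds = chain$rounds, burnin = chain$burn_in, thin = chain$thin
  )
  draws <- as_tibble(cbind(
    setNames(as.data.frame(out$C), tri_names("C", q)),
    setNames(as.data.frame(out$P), tri_names("P", q)),
    setNames(as.data.frame(out$residual), paste0("r", seq_len(np)))
  ))
  draws <- dplyr::mutate(draws, sample = dplyr::row_number(), .before = 1)
  structure(
    list(
      draws = draws, config = chain, q = q, n_periods = np,
      basis = basis, res_periods = dplyr::select(res, "week_lo", "week_hi"),
      pd_rejections = out$pd_rejections,
      relationship = attr(Kinv, "kind") %||% "Ainv",
      n_animals = nrow(ped), n_hens = length(hen_animal)
    ),
    class = "rregg_chain"
  )
}

#' @export
print.rregg_chain <- function(x, ...) {
  cat(sprintf(
    "<rregg_chain> %d saved samples (%d rounds, %d burn-in, thin %d), relationship %s\n",
    nrow(x$draws), x$config$rounds, x$config$burn_in, x$config$thin, x$relationship
  ))
  if (x$pd_rejections > 0) {
    cat(sprintf("%d jittered Cholesky retries during sampling\n", x$pd_rejections))
  }
  invisible(x)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted samples containing
#' `prob` of them.
#'
#' @param x numeric sample vector.
#' @param prob interval mass (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) abort("no finite samples")
  k <- min(n, max(1L, ceiling(prob * n)))
  if (k == n) {
    return(c(lower = x[1], upper = x[n]))
  }
  widths <- x[k:n] - x[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Autocorrelation-based effective sample size
#'
#' `n / (1 + 2 sum rho_k)` with the autocorrelation sum truncated at the
#' first non-positive lag.
#'
#' @param x numeric sample vector.
#' @return Effective sample size (capped at `length(x)`).
#' @export
ess_autocorr <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) {
    return(as.numeric(n))
  }
  rho <- as.numeric(acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf)[-1]
  cut <- which(rho <= 0)
  if (length(cut) > 0) rho <- rho[seq_len(cut[1] - 1)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Posterior summaries of a Gibbs chain
#'
#' @param chain an [run_gibbs()] chain (or any tibble of draws with a
#'   `sample` column).
#' @param prob HPD interval mass.
#' @return Tibble: `parameter`, `mean`, `sd`, `hpd_lo`, `hpd_hi`, `ess`.
#' @export
posterior_summary <- function(chain, prob = 0.95) {
  draws <- if (inherits(chain, "rregg_chain")) chain$draws else as_tibble(chain)
  if (nrow(draws) < 100) abort("need at least 100 saved samples for summaries")
  pars <- setdiff(names(draws), "sample")
  purrr::map_dfr(pars, function(pn) {
    v <- draws[[pn]]
    h <- hpd_interval(v, prob)
    tibble(
      parameter = pn, mean = mean(v), sd = stats::sd(v),
      hpd_lo = unname(h[1]), hpd_hi = unname(h[2]), ess = ess_autocorr(v)
    )
  })
}

#' Posterior mean matrices of a chain
#' @param chain an [run_gibbs()] chain.
#' @return List with `C`, `P` (symmetric matrices) and `residual` (vector).
#' @export
posterior_means <- function(chain) {
  stopifnot(inherits(chain, "rregg_chain"))
  q <- chain$q
  d <- chain$draws
  cm <- colMeans(dplyr::select(d, dplyr::starts_with("C")))
  pm <- colMeans(dplyr::select(d, dplyr::starts_with("P")))
  rm_ <- colMeans(dplyr::select(d, dplyr::matches("^r[0-9]+$")))
  list(C = tri_to_matrix(cm, q), P = tri_to_matrix(pm, q), residual = unname(rm_))
}

#' Per-week posterior trajectory summaries
#'
#' Expands every saved (C, P, residual) sample through the Legendre basis and
#' summarizes the weekly additive and permanent environmental variances and
#' heritability with posterior means and HPD intervals.
#'
#' @param chain an [run_gibbs()] chain.
#' @param prob HPD mass.
#' @return Tibble: week, posterior mean and HPD bounds of `var_a`, `var_pe`,
#'   `h2`.
#' @export
trajectory_posterior <- function(chain, prob = 0.95) {
  stopifnot(inherits(chain, "rregg_chain"))
  q <- chain$q
  basis <- chain$basis
  Phi <- basis$Phi
  d <- chain$draws
  Cc <- as.matrix(dplyr::select(d, dplyr::starts_with("C")))
  Pc <- as.matrix(dplyr::select(d, dplyr::starts_with("P")))
  Rc <- as.matrix(dplyr::select(d, dplyr::matches("^r[0-9]+$")))
  res_weeks <- purrr::map_int(basis$weeks, function(w) {
    which(chain$res_periods$week_lo <= w & w <= chain$res_periods$week_hi)
  })
  nw <- length(basis$weeks)
  ns <- nrow(d)
  va <- vp <- h2 <- matrix(0, ns, nw)
  for (s in seq_len(ns)) {
    Cm <- tri_to_matrix(Cc[s, ], q)
    Pm <- tri_to_matrix(Pc[s, ], q)
    da <- rowSums((Phi %*% Cm) * Phi)
    dp <- rowSums((Phi %*% Pm) * Phi)
    de <- Rc[s, res_weeks]
    va[s, ] <- da
    vp[s, ] <- dp
    h2[s, ] <- da / (da + dp + de)
  }
  purrr::map_dfr(seq_len(nw), function(w) {
    ha <- hpd_interval(va[, w], prob)
    hp <- hpd_interval(vp[, w], prob)
    hh <- hpd_interval(h2[, w], prob)
    tibble(
      week = basis$weeks[w],
      var_a = mean(va[, w]), var_a_lo = unname(ha[1]), var_a_hi = unname(ha[2]),
      var_pe = mean(vp[, w]), var_pe_lo = unname(hp[1]), var_pe_hi = unname(hp[2]),
      h2 = mean(h2[, w]), h2_lo = unname(hh[1]), h2_hi = unname(hh[2])
    )
  })
}

#' Chain diagnostics
#'
#' @param chain an [run_gibbs()] chain.
#' @param trace_dir optional directory; when given, per-parameter trace CSVs
#'   (`sample,value`) are written there.
#' @return Tibble of per-parameter effective sample sizes.
#' @export
diagnostics <- function(chain, trace_dir = NULL) {
  draws <- if (inherits(chain, "rregg_chain")) chain$draws else as_tibble(chain)
  pars <- setdiff(names(draws), "sample")
  out <- purrr::map_dfr(pars, function(pn) {
    tibble(parameter = pn, n = nrow(draws), ess = ess_autocorr(draws[[pn]]))
  })
  if (!is.null(trace_dir)) {
    dir.create(trace_dir, showWarnings = FALSE, recursive = TRUE)
    for (pn in pars) {
      utils::write.csv(
        data.frame(sample = draws$sample, value = draws[[pn]]),
        file.path(trace_dir, paste0("trace_", pn, ".csv")),
        row.names = FALSE
      )
    }
  }
  out
}

#' @method tidy rregg_chain
#' @export
tidy.rregg_chain <- function(x, ...) posterior_summary(x, ...)

#' @method glance rregg_chain
#' @export
glance.rregg_chain <- function(x, ...) {
  dg <- diagnostics(x)
  tibble(
    rounds = x$config$rounds, burn_in = x$config$burn_in, thin = x$config$thin,
    n_saved = nrow(x$draws), relationship = x$relationship,
    min_ess = min(dg$ess), pd_rejections = x$pd_rejections
  )
}
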
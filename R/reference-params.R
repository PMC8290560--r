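#' Reference variance components for turkey weekly egg production
#'
#' Posterior-mean variance-component estimates reported for 24-week egg
#' production in a commercial turkey female line under an order-3
#' random-regression model: the 4x4 coefficient covariance matrices of the
#' additive genetic (`C`) and permanent environmental (`P`) effects, the four
#' heterogeneous residual-variance periods, and the weekly descriptive
#' statistics (hen counts, means, standard deviations) of the same population.
#' These values calibrate the simulator defaults and anchor the package's
#' consistency checks.
#'
#' `C` as published (rounded to two decimals) has one slightly negative
#' eigenvalue; `C_pd` and `P_pd` are bent copies ([bend_matrix()]) for uses
#' that require positive definiteness (simulation, mixed-model priors).
#'
#' @return A list with elements `C`, `P`, `C_pd`, `P_pd` (4x4 matrices),
#'   `residual` (a [residual_spec()]), and `weekly_phenotypes` (tibble: week,
#'   n, mean, sd).
#' @examples
#' pars <- turkey_reference_params()
#' diag(expand_covariance(pars$C))[13] # weekly genetic variance, week 13
#' @export
turkey_reference_params <- function() {
  C <- matrix(c(
    0.62, 0.06, -0.08, -0.01,
    0.06, 0.04, -0.02, -0.02,
    -0.08, -0.02, 0.02, 0.00,
    -0.01, -0.02, 0.00, 0.01
  ), 4, 4, byrow = TRUE)
  P <- matrix(c(
    0.73, -0.03, -0.12, 0.04,
    -0.03, 0.18, -0.01, -0.06,
    -0.12, -0.01, 0.09, -0.01,
    0.04, -0.06, -0.01, 0.05
  ), 4, 4, byrow = TRUE)
  dimnames(C) <- dimnames(P) <- list(paste0("phi", 0:3), paste0("phi", 0:3))
  residual <- residual_spec(tibble(
    week_lo = c(1L, 5L, 13L, 18L),
    week_hi = c(4L, 12L, 17L, 24L),
    var_e = c(1.33, 1.38, 1.21, 1.10)
  ))
  weekly_phenotypes <- tibble(
    week = 1:24,
    n = c(
      7422L, 7351L, 7332L, 7310L, 7296L, 7284L, 7259L, 7231L, 7205L, 7184L,
      7132L, 7055L, 7022L, 6972L, 6937L, 6883L, 6823L, 6683L, 6592L, 6427L,
      6081L, 5719L, 5101L, 3478L
    ),
    mean = c(
      5.21, 5.26, 5.30, 5.22, 5.16, 5.06, 4.94, 4.85, 4.77, 4.71, 4.58, 4.50,
      4.38, 4.29, 4.16, 4.09, 3.98, 3.91, 3.88, 3.84, 3.82, 3.82, 3.73, 3.53
    ),
    sd = c(
      1.34, 1.47, 1.48, 1.49, 1.51, 1.53, 1.53, 1.54, 1.52, 1.51, 1.50, 1.49,
      1.47, 1.47, 1.45, 1.44, 1.44, 1.43, 1.41, 1.40, 1.37, 1.35, 1.30, 1.30
    )
  )
  list(
    C = C, P = P,
    C_pd = bend_matrix(C), P_pd = bend_matrix(P),
    residual = residual,
    weekly_phenotypes = weekly_phenotypes
  )
}
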
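small_fit_inputs <- function(n_founders = 6, n_offspring = 24, seed = 101,
                             weeks = 1:24) {
  ped <- as_pedigree(random_pedigree_df(n_founders, n_offspring, seed = seed))
  ped$hatch_week <- rep(c(1, 2), length.out = nrow(ped))
  set.seed(seed)
  pheno <- toy_pheno(ped, weeks = weeks, hens = ped$animal[seq(2, nrow(ped), by = 2)])
  list(ped = ped, pheno = pheno)
}

test_that("design matrices have the prescribed structure", {
  inp <- small_fit_inputs()
  b <- legendre_design()
  d <- build_design(inp$pheno, inp$ped, b, ref_pars$residual)
  # one hen's 24 records occupy exactly 4 columns of Q
  hen1 <- d$hens[1]
  rows <- which(d$rec$animal_id == hen1)
  expect_equal(length(rows), 24)
  block <- d$Q[rows, , drop = FALSE]
  expect_equal(sum(Matrix::colSums(abs(block)) > 0), 4)
  expect_equal(
    which(Matrix::colSums(abs(block)) > 0),
    (hen1 - 1) * 4 + 1:4
  )
  # Q rows are the basis covariates of the record's week
  expect_equal(
    as.numeric(block[1, (hen1 - 1) * 4 + 1:4]),
    unname(b$Phi[match(d$rec$week[rows[1]], b$weeks), ])
  )
  # X cross-products match a hand cross-tabulation on a tiny table
  ped3 <- as_pedigree(data.frame(
    animal = c("h1", "h2", "h3"), sire = "0", dam = "0",
    hatch_week = c(1, 1, 2)
  ))
  ph <- tibble::tibble(
    animal = rep(c("h1", "h2", "h3"), each = 4),
    week = rep(1:4, 3),
    eggs = rnorm(12, 5, 1),
    afe_class = rep(c("29-31", "32-34", "29-31"), each = 4),
    hatch_week = rep(c(1, 1, 2), each = 4),
    body_weight = rep(c(10, 11, 12), each = 4)
  )
  d3 <- build_design(ph, ped3, legendre_design(3, 1:4), ref_pars$residual)
  XtX <- as.matrix(Matrix::crossprod(d3$X))
  hw_cols <- which(d3$fixed_map$term == "hatchweek_week")
  counts <- table(paste(ph$hatch_week, ph$week, sep = ":"))
  expect_equal(
    unname(diag(XtX)[hw_cols]),
    unname(as.numeric(counts[d3$fixed_map$level[hw_cols]]))
  )
  # two hens sharing hatch week and AFE class: X rows differ only in the
  # body-weight column
  ph2 <- dplyr::mutate(ph, hatch_week = 1)
  d4 <- build_design(ph2, ped3, legendre_design(3, 1:4), ref_pars$residual)
  r1 <- which(d4$rec$animal_id == 1 & d4$rec$week == 2)
  r2 <- which(d4$rec$animal_id == 3 & d4$rec$week == 2)
  diff_cols <- which(as.numeric(d4$X[r1, ]) != as.numeric(d4$X[r2, ]))
  expect_equal(unname(d4$fixed_map$term[diff_cols]), "bodyweight_slope")
  expect_error(
    build_design(dplyr::mutate(ph, animal = "ghost"), ped3, legendre_design(3, 1:4)),
    "absent"
  )
  expect_error(
    build_design(ph[c(1, 1), ], ped3, legendre_design(3, 1:4)),
    "one record per animal-week"
  )
})

test_that("assembly demands positive-definite coefficient covariances", {
  inp <- small_fit_inputs()
  d <- build_design(inp$pheno, inp$ped, legendre_design(), ref_pars$residual)
  Ainv <- build_A_inverse(inp$ped)
  badC <- diag(4)
  badC[1, 1] <- -1
  expect_error(
    assemble_mme(d, Ainv, badC, ref_pars$P_pd),
    "positive definite.*eigenvalues"
  )
  sys <- assemble_mme(d, Ainv, ref_pars$C_pd, ref_pars$P_pd)
  expect_equal(
    length(sys$RHS),
    ncol(d$X) + 4 * nrow(inp$ped) + 4 * length(d$hens)
  )
})

test_that("a single record shrinks exactly by the trajectory variance ratio", {
  ped <- as_pedigree(data.frame(animal = "h", sire = "0", dam = "0", hatch_week = 1))
  ph <- tibble::tibble(
    animal = "h", week = 10L, eggs = 2.5, afe_class = "29-31",
    hatch_week = 1, body_weight = 10
  )
  d <- build_design(ph, ped, legendre_design(), ref_pars$residual)
  # strip the fixed effects so the record informs the random terms directly
  d$X <- d$X[, integer(0), drop = FALSE]
  d$fixed_map <- d$fixed_map[integer(0), ]
  C <- ref_pars$C_pd
  P <- ref_pars$P_pd
  sys <- assemble_mme(d, build_A_inverse(ped), C, P)
  sol <- solve_mme(sys)
  phi <- legendre_design()$Phi[10, ]
  vy <- c(phi %*% C %*% phi + phi %*% P %*% phi) + 1.38 # week 10 residual
  expect_equal(c(phi %*% sol$alpha[1, ]), c(phi %*% C %*% phi) / vy * 2.5,
    tolerance = 1e-8
  )
  expect_equal(c(phi %*% sol$pe[1, ]), c(phi %*% P %*% phi) / vy * 2.5,
    tolerance = 1e-8
  )
})

test_that("MME solutions match a dense GLS oracle", {
  inp <- small_fit_inputs(n_founders = 10, n_offspring = 35, seed = 17, weeks = 1:8)
  basis <- legendre_design(3, 1:8)
  res <- residual_spec(
    tibble::tibble(week_lo = c(1, 5), week_hi = c(4, 8), var_e = c(1.3, 1.1)),
    1:8
  )
  C <- ref_pars$C_pd
  P <- ref_pars$P_pd
  d <- build_design(inp$pheno, inp$ped, basis, res)
  sys <- assemble_mme(d, build_A_inverse(inp$ped), C, P, res)
  sol <- solve_mme(sys)
  # normal equations satisfied
  expect_lt(sol$relres, 1e-8)
  # dense GLS: V = Q (A x C) Q' + Z (I x P) Z' + R
  A <- build_A(inp$ped)
  Qd <- as.matrix(d$Q)
  Zd <- as.matrix(d$Z)
  Xd <- as.matrix(d$X)
  rv <- residual_by_week(res, basis$weeks)
  Rd <- diag(unname(rv[match(d$rec$week, basis$weeks)]))
  V <- Qd %*% kronecker(A, C) %*% t(Qd) +
    Zd %*% kronecker(diag(length(d$hens)), P) %*% t(Zd) + Rd
  Vi <- solve(V)
  y <- d$rec$y
  bhat <- solve(t(Xd) %*% Vi %*% Xd, t(Xd) %*% Vi %*% y)
  ahat <- kronecker(A, C) %*% t(Qd) %*% Vi %*% (y - Xd %*% bhat)
  expect_equal(sol$fixed$estimate, as.numeric(bhat), tolerance = 1e-6)
  expect_equal(as.numeric(t(sol$alpha)), as.numeric(ahat), tolerance = 1e-6)
})

test_that("direct and PCG solvers agree", {
  inp <- small_fit_inputs(seed = 23)
  d <- build_design(inp$pheno, inp$ped, legendre_design(), ref_pars$residual)
  sys <- assemble_mme(d, build_A_inverse(inp$ped), ref_pars$C_pd, ref_pars$P_pd)
  s1 <- solve_mme(sys, method = "direct")
  s2 <- solve_mme(sys, method = "pcg", tol = 1e-12)
  expect_lt(max(abs(s1$alpha - s2$alpha)), 1e-6)
  expect_lt(max(abs(s1$fixed$estimate - s2$fixed$estimate)), 1e-6)
  expect_error(solve_mme(sys, method = "pcg", maxit = 2), "did not converge")
})

test_that("single-step with G = A22 reproduces the pedigree fit exactly", {
  inp <- small_fit_inputs(seed = 29)
  ped <- inp$ped
  d <- build_design(inp$pheno, ped, legendre_design(), ref_pars$residual)
  Ainv <- build_A_inverse(ped)
  sub <- ped$animal[seq(5, nrow(ped), by = 3)]
  A22 <- build_A(ped, subset = sub)
  Hinv <- build_H_inverse(Ainv, G = A22, A22 = A22)
  solA <- solve_mme(assemble_mme(d, Ainv, ref_pars$C_pd, ref_pars$P_pd))
  solH <- solve_mme(assemble_mme(d, Hinv, ref_pars$C_pd, ref_pars$P_pd))
  expect_lt(max(abs(solA$alpha - solH$alpha)), 1e-8)
})

test_that("EBVs are invariant to a constant shift of all body weights", {
  inp <- small_fit_inputs(seed = 37)
  f1 <- fit_rr(inp$pheno, inp$ped, ref_pars$C_pd, ref_pars$P_pd, ref_pars$residual)
  ph2 <- dplyr::mutate(inp$pheno, body_weight = body_weight + 3.7)
  f2 <- fit_rr(ph2, inp$ped, ref_pars$C_pd, ref_pars$P_pd, ref_pars$residual)
  expect_lt(max(abs(f1$solution$alpha - f2$solution$alpha)), 1e-8)
})

test_that("EBV trajectories, cumulative values and persistency are consistent", {
  basis <- legendre_design()
  sol <- structure(
    list(
      alpha = rbind(
        zero = c(0, 0, 0, 0),
        const = c(1, 0, 0, 0),
        mix = c(0.3, -0.2, 0.1, 0.05)
      ),
      pe = matrix(0, 0, 4), basis = basis,
      fixed = tibble::tibble(term = character(), level = character(), estimate = numeric()),
      relres = 0, method = "direct", iterations = NA, kind = "Ainv"
    ),
    class = "rr_solution"
  )
  bv <- ebv_trajectory(sol)
  expect_equal(unname(unlist(bv[1, paste0("wk", 1:24)])), rep(0, 24))
  expect_equal(bv$persistency[1], 0)
  expect_equal(
    unname(unlist(bv[2, paste0("wk", 1:24)])),
    rep(sqrt(0.5), 24),
    tolerance = 1e-12
  )
  expect_equal(bv$cumulative[3], sum(unlist(bv[3, paste0("wk", 1:24)])))
  # doubling the trajectory doubles the slope
  v <- setNames(as.numeric(bv[3, paste0("wk", 1:24)]), 1:24)
  expect_equal(persistency(2 * v), 2 * persistency(v))
  # reference weekly means, weeks 3 and 18: (5.30 - 3.91) / 16
  means <- setNames(ref_pars$weekly_phenotypes$mean, 1:24)
  expect_equal(persistency(means), (5.30 - 3.91) / 16)
  expect_equal(persistency(means), 0.086875)
  expect_error(persistency(means, 5, 5), "must differ")
})
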
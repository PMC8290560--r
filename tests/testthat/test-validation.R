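test_that("age-based split takes the youngest floor(n * fraction) deterministically", {
  ped <- as_pedigree(data.frame(
    animal = paste0("h", 1:100), sire = "0", dam = "0",
    hatch_week = rep(1:10, each = 10)
  ))
  ph <- tibble::tibble(animal = paste0("h", 1:100))
  sp <- split_by_age(ph, ped, 0.1)
  expect_length(sp$validation, 10)
  expect_true(all(ped$hatch_week[match(sp$validation, ped$animal)] == 10))
  # all hens in one hatch week: id tie-break still returns exactly the quota
  ped1 <- as_pedigree(data.frame(
    animal = paste0("h", 1:100), sire = "0", dam = "0", hatch_week = 1
  ))
  sp1 <- split_by_age(ph, ped1, 0.1)
  expect_length(sp1$validation, 10)
  expect_identical(sp1$validation, split_by_age(ph, ped1, 0.1)$validation)
  # cohort-scale arithmetic: 7422 hens at 10% -> 742
  expect_equal(floor(7422 * 0.10), 742)
  expect_error(split_by_age(ph, ped, 1.5), "fraction")
})

fake_fit <- function(fixed, afe_levels, bw_center = 0) {
  structure(
    list(
      solution = list(fixed = fixed),
      design = list(afe_levels = afe_levels, bw_center = bw_center)
    ),
    class = "rr_fit"
  )
}

test_that("fixed-effect correction matches hand-computed cell arithmetic", {
  fixed <- tibble::tibble(
    term = c(
      "hatchweek_week", "hatchweek_week", "week_afe",
      "bodyweight_slope", "bodyweight_slope"
    ),
    level = c("1:1", "2:1", "32-34:1", "week1", "week2"),
    estimate = c(4.0, 5.0, 0.5, 0.2, 0.0)
  )
  fit <- fake_fit(fixed, afe_levels = c("29-31", "32-34"), bw_center = 10)
  ph <- tibble::tibble(
    animal = c("a", "b", "c"),
    week = 1L,
    eggs = c(6, 6, 6),
    afe_class = c("29-31", "32-34", "29-31"),
    hatch_week = c(1, 1, 2),
    body_weight = c(10, 11, 10)
  )
  ys <- corrected_phenotypes(ph, fit)
  expect_equal(ys$ystar, c(6 - 4, 6 - 4 - 0.5 - 0.2, 6 - 5))
  # zero solutions leave phenotypes untouched
  fit0 <- fake_fit(dplyr::mutate(fixed, estimate = 0), c("29-31", "32-34"), 10)
  expect_equal(corrected_phenotypes(ph, fit0)$ystar, ph$eggs)
  # adding a constant to all records of one cell is absorbed by that cell's mean
  ph_shift <- dplyr::mutate(ph, eggs = ifelse(hatch_week == 1, eggs + 2, eggs))
  fit_shift <- fake_fit(
    dplyr::mutate(fixed, estimate = estimate + 2 * (level == "1:1")),
    c("29-31", "32-34"), 10
  )
  expect_equal(
    corrected_phenotypes(ph_shift, fit_shift)$ystar[c(1, 2)],
    ys$ystar[c(1, 2)]
  )
  # unseen level dropped with a warning
  ph_new <- dplyr::mutate(ph, hatch_week = c(1, 1, 9))
  expect_warning(out <- corrected_phenotypes(ph_new, fit), "unseen")
  expect_equal(nrow(out), 2)
})

test_that("correlation accuracy is the correlation scaled by sqrt(h2)", {
  set.seed(8)
  n <- 60
  ebv <- tibble::tibble(
    animal = paste0("v", 1:n), week = 1L, ebv = rnorm(n)
  )
  ys <- tibble::tibble(
    animal = paste0("v", 1:n), week = 1L, y = 0,
    ystar = 0.3 * ebv$ebv + rnorm(n)
  )
  acc <- correlation_accuracy(ebv, ys, c(`1` = 0.16))
  expect_equal(acc$accuracy, cor(ebv$ebv, ys$ystar) / 0.4)
  # arithmetic anchor: r = 0.2 with h2 = 0.16 gives accuracy 0.5
  expect_equal(0.2 / sqrt(0.16), 0.5)
  # accuracy invariant to a constant shift of the week's EBVs
  acc2 <- correlation_accuracy(dplyr::mutate(ebv, ebv = ebv + 100), ys, c(`1` = 0.16))
  expect_equal(acc2$accuracy, acc$accuracy)
  # constant EBVs: undefined, reported missing
  acc3 <- correlation_accuracy(dplyr::mutate(ebv, ebv = 1), ys, c(`1` = 0.16))
  expect_true(is.na(acc3$accuracy))
  # too few animals: missing
  acc4 <- correlation_accuracy(ebv[1:2, ], ys[1:2, ], c(`1` = 0.16))
  expect_true(is.na(acc4$accuracy))
})

fake_rr_fit <- function(ped, alpha, hens, basis = legendre_design()) {
  structure(
    list(
      design = list(
        n_animals = nrow(ped), hens = hens, animal_labels = ped$animal
      ),
      solution = list(alpha = alpha),
      basis = basis,
      sire_id = ped$sire_id, dam_id = ped$dam_id
    ),
    class = "rr_fit"
  )
}

test_that("Mendelian-sampling predictions follow the parent-average identity", {
  ped <- as_pedigree(data.frame(
    animal = c("s", "d", "k1", "k2"),
    sire = c("0", "0", "s", "s"), dam = c("0", "0", "d", "d")
  ))
  # flat weekly EBVs: parents 2, offspring 3 (phi0 = sqrt(1/2))
  alpha <- rbind(
    s = c(2, 0, 0, 0), d = c(2, 0, 0, 0),
    k1 = c(3, 0, 0, 0), k2 = c(3, 0, 0, 0)
  ) / sqrt(0.5)
  fit <- fake_rr_fit(ped, alpha, hens = 3:4)
  ms <- mendelian_sampling(fit)
  # eligible: k1, k2 only (records + both parents)
  expect_setequal(unique(ms$animal), c("k1", "k2"))
  expect_equal(unique(round(ms$ms, 10)), 1) # 3 - 0.5*(2+2) = 1
  # full sibs with identical EBVs give identical ms
  expect_equal(
    dplyr::filter(ms, animal == "k1")$ms,
    dplyr::filter(ms, animal == "k2")$ms
  )
  # offspring equal to parent average: ms = 0
  alpha0 <- alpha
  alpha0[3:4, ] <- alpha[1, , drop = FALSE][rep(1, 2), ]
  ms0 <- mendelian_sampling(fake_rr_fit(ped, alpha0, hens = 3:4))
  expect_equal(unique(round(ms0$ms, 12)), 0)
  expect_error(
    mendelian_sampling(fake_rr_fit(ped, alpha, hens = 1:2)),
    "no animals"
  )
})

test_that("the nu ratio is variance over half the additive variance", {
  ms <- tidyr::expand_grid(animal = paste0("a", 1:40), week = 1:2)
  ms$ms <- 0
  out <- ms_variance_ratio(ms, c(`1` = 0.4, `2` = 0.5))
  expect_equal(out$nu, c(0, 0))
  # construct ms values with variance exactly half the additive variance
  set.seed(3)
  v <- rnorm(40)
  v <- (v - mean(v)) / sd(v) * sqrt(0.5 * 0.4)
  ms2 <- dplyr::mutate(ms, ms = rep(v, each = 2))
  out2 <- ms_variance_ratio(ms2, c(`1` = 0.4, `2` = 0.4))
  expect_equal(out2$nu, c(1, 1), tolerance = 1e-12)
  # fewer than min_n animals: missing
  out3 <- ms_variance_ratio(ms2[ms2$animal %in% paste0("a", 1:5), ], c(`1` = 0.4, `2` = 0.4))
  expect_true(all(is.na(out3$nu)))
})

test_that("nu computed from true breeding values approaches one", {
  # pedigree-flow architecture: Mendelian-sampling deviations have variance
  # d_i * C exactly, so the plug-in-truth ratio is 1 up to sampling noise
  cfg <- sim_config(
    n_generations = 4, n_sires = 8, n_dams = 150, progeny_per_dam = 6,
    n_snp = 100, genotyped_fraction = 0.3, genetic_architecture = "pedigree"
  )
  sim <- simulate_dataset(cfg, seed = 44)
  truth <- sim$truth$g_weekly
  eligible <- sim$ped$animal[
    !is.na(sim$ped$sire_id) & !is.na(sim$ped$dam_id) &
      sim$ped$animal %in% unique(sim$pheno$animal)
  ]
  ms_true <- tibble::tibble(
    animal = rep(eligible, each = 24),
    week = rep(1:24, length(eligible)),
    ms = as.numeric(t(
      truth[eligible, ] -
        0.5 * (truth[sim$ped$animal[sim$ped$sire_id[match(eligible, sim$ped$animal)]], ] +
          truth[sim$ped$animal[sim$ped$dam_id[match(eligible, sim$ped$animal)]], ])
    ))
  )
  va <- diag(expand_covariance(sim$truth$C_true))
  nu <- suppressWarnings(ms_variance_ratio(ms_true, setNames(va, 1:24)))
  # plug-in truth: Var(ms_i) = d_i * sigma2_a with d_i = 0.5 - 0.25(F_s+F_d),
  # so E[nu] = mean(2 d_i) = 1 - 0.5 (mean parental F); Monte-Carlo noise
  # shrinks with the ~1350 eligible trios
  F <- inbreeding(sim$ped)
  ei <- match(eligible, sim$ped$animal)
  expected <- mean(1 - 0.5 * (F[sim$ped$sire_id[ei]] + F[sim$ped$dam_id[ei]]))
  expect_true(all(nu$nu > expected - 0.2 & nu$nu < expected + 0.2))
  expect_equal(mean(nu$nu), expected, tolerance = 0.1)
})
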
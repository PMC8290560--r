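test_that("pedigree simulation produces the configured counts deterministically", {
  cfg <- sim_config(
    n_generations = 3, n_sires = 2, n_dams = 8, progeny_per_dam = 4,
    n_snp = 50
  )
  ped <- simulate_pedigree(cfg, seed = 1)
  expect_equal(nrow(ped), 10 + 2 * 32) # founders + 32 progeny per later generation
  expect_equal(sum(is.na(ped$sire_id) & is.na(ped$dam_id)), 10)
  expect_equal(max(ped$generation), 3)
  expect_identical(ped, simulate_pedigree(cfg, seed = 1))
  expect_false(identical(ped, simulate_pedigree(cfg, seed = 2)))
  one <- simulate_pedigree(sim_config(n_generations = 1, n_dams = 5, n_snp = 10), seed = 1)
  expect_true(all(is.na(one$sire_id)))
})

test_that("gene dropping respects Mendelian transmission", {
  cfg <- sim_config(
    n_generations = 3, n_sires = 3, n_dams = 12, progeny_per_dam = 3,
    n_snp = 150, genotyped_fraction = 0.5, missing_rate = 0
  )
  ped <- simulate_pedigree(cfg, seed = 5)
  g <- simulate_genotypes(ped, cfg, seed = 5)
  D <- attr(g, "full_dosages")
  off <- which(!is.na(ped$sire_id) & !is.na(ped$dam_id))
  for (i in off[1:20]) {
    s <- D[ped$sire_id[i], ]
    d <- D[ped$dam_id[i], ]
    o <- D[i, ]
    # both parents homozygous 0 -> offspring 0; both 2 -> offspring 2
    expect_true(all(o[s == 0 & d == 0] == 0))
    expect_true(all(o[s == 2 & d == 2] == 2))
    # offspring dosage bounded by what the parents can transmit
    expect_true(all(o >= (s == 2) + (d == 2)))
    expect_true(all(o <= (s > 0) + (d > 0)))
  }
  # realized founder frequency close to the drawn frequency (binomial bound)
  p <- attr(g, "founder_freq")
  founders <- which(is.na(ped$sire_id) & is.na(ped$dam_id))
  phat <- colMeans(D[founders, ]) / 2
  se <- sqrt(p * (1 - p) / (2 * length(founders)))
  expect_gt(mean(abs(phat - p) < 3 * se + 1e-9), 0.95)
})

test_that("QC recovers the planted failure classes", {
  cfg <- sim_config(
    n_generations = 3, n_sires = 4, n_dams = 30, progeny_per_dam = 4,
    n_snp = 500, genotyped_fraction = 0.6
  )
  sim <- simulate_dataset(cfg, seed = 12)
  planted <- attr(sim$genotypes, "planted")
  qc <- qc_genotypes(sim$genotypes)
  failed <- qc$qc_log$snp[qc$qc_log$status == "fail"]
  # every planted sex-chromosome SNP is removed
  expect_true(all(planted$snp[planted$sex_chrom] %in% failed))
  # planted low-MAF SNPs are removed; founder frequencies near the 0.04
  # planting bound can drift across the 0.05 cut in a finite population
  expect_gt(mean(planted$snp[planted$low_maf] %in% failed), 0.75)
  # most planted high-missingness SNPs fail call rate (10% loss vs 5% cut)
  expect_gt(mean(planted$snp[planted$high_missing] %in% failed), 0.8)
  # all retained SNPs are autosomal with adequate MAF and call rate
  expect_true(all(is_clean <- !qc$map$chrom %in% "Z"))
  p <- colMeans(qc$dosages) / 2
  expect_true(all(pmin(p, 1 - p) >= 0.045)) # imputation can nudge MAF slightly
})

test_that("trait generation matches the target covariance structure", {
  # founder coefficient covariance converges to C_true
  cfg <- sim_config(
    n_generations = 1, n_sires = 100, n_dams = 2400, n_snp = 400,
    genotyped_fraction = 0.05
  )
  sim <- simulate_dataset(cfg, seed = 31)
  founders <- sim$ped$animal
  emp <- cov(sim$truth$alpha[founders, ])
  C <- cfg$C_true
  nf <- length(founders)
  se <- sqrt((outer(diag(C), diag(C)) + C^2) / nf)
  expect_true(all(abs(emp - C) < 3 * se + 0.01))
  # parent-offspring coefficient covariance is half the founder covariance
  cfg2 <- sim_config(
    n_generations = 2, n_sires = 30, n_dams = 600, progeny_per_dam = 2,
    n_snp = 400, genotyped_fraction = 0.05
  )
  sim2 <- simulate_dataset(cfg2, seed = 32)
  off <- which(!is.na(sim2$ped$dam_id))
  po <- cov(
    sim2$truth$alpha[off, ],
    sim2$truth$alpha[sim2$ped$dam_id[off], ]
  )
  expect_true(all(abs(po - 0.5 * C) < 3 * sqrt((outer(diag(C), diag(C)) + C^2) / length(off)) + 0.01))
  # weekly genetic variance of the truth matches the expanded target
  va_emp <- apply(sim$truth$g_weekly[founders, ], 2, var)
  va_target <- diag(expand_covariance(C))
  expect_lt(max(abs(va_emp - va_target) / va_target), 0.10)
})

test_that("null genetics leaves only residual variance within fixed cells", {
  cfg <- sim_config(
    n_generations = 2, n_sires = 4, n_dams = 40, progeny_per_dam = 6,
    n_snp = 100, C_true = diag(1e-8, 4), P_true = diag(1e-8, 4),
    hatch_weeks_per_gen = 1, missing_week_rate = 0, bw_slope_sd = 0
  )
  sim <- simulate_dataset(cfg, seed = 41)
  cells <- dplyr::group_by(sim$pheno, .data$hatch_week, .data$week, .data$afe_class)
  vs <- dplyr::summarise(cells, v = var(.data$eggs), n = dplyr::n(), .groups = "drop")
  vs <- dplyr::filter(vs, n >= 30)
  rv <- residual_by_week(ref_pars$residual, 1:24)
  vs$target <- unname(rv[vs$week])
  # each cell variance within its chi-square 99% band around the period value
  lo <- qchisq(0.005, vs$n - 1) / (vs$n - 1)
  hi <- qchisq(0.995, vs$n - 1) / (vs$n - 1)
  inside <- vs$v / vs$target > lo & vs$v / vs$target < hi
  expect_gt(mean(inside), 0.95)
})

test_that("dataset writing round-trips and is reproducible", {
  cfg <- sim_config(
    n_generations = 2, n_sires = 2, n_dams = 8, progeny_per_dam = 3,
    n_snp = 40, genotyped_fraction = 0.5
  )
  sim <- simulate_dataset(cfg, seed = 77)
  d1 <- withr::local_tempdir()
  write_dataset(sim, d1)
  back <- read_dataset(d1)
  expect_equal(nrow(back$ped), nrow(sim$ped))
  expect_equal(back$ped$animal, sim$ped$animal)
  expect_equal(back$pheno$eggs, sim$pheno$eggs, tolerance = 1e-12)
  expect_equal(
    unname(back$genotypes$dosages),
    unname(sim$genotypes$dosages)
  )
  expect_equal(nrow(back$truth_alpha), nrow(sim$ped))
  # regenerating under the same seed gives identical files
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg, seed = 77), d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f)),
      label = f
    )
  }
})
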
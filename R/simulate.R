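#' Simulation configuration
#'
#' Defines the synthetic turkey population: discrete-generation pedigree,
#' SNP panel with planted QC failures, and 24-week egg-production records
#' generated under exactly the random-regression model the package fits.
#' The generating coefficient covariances default to the reference estimates
#' for a commercial turkey female line ([turkey_reference_params()], bent to
#' positive definiteness), the residual periods to the reference four-period
#' structure, and the fixed-effect mean curve to the reference weekly means.
#'
#' @param n_generations discrete generations (default 8).
#' @param n_sires,n_dams breeding males/females per generation.
#' @param progeny_per_dam progeny per dam.
#' @param hatch_weeks_per_gen hatch-week contemporary groups per generation.
#' @param genotyped_fraction fraction of pedigree animals genotyped, youngest
#'   first (default 0.30).
#' @param n_snp SNP panel size (default 2000).
#' @param n_chromosomes autosome count; one additional sex chromosome ("Z")
#'   is always simulated to exercise QC (default 10).
#' @param frac_low_maf,frac_high_missing fractions of SNPs planted with
#'   founder MAF below 0.05 and with elevated missingness (default 0.05 each).
#' @param missing_rate baseline genotype missing rate (default 0.01).
#' @param high_missing_rate missing rate of the planted high-missingness SNPs
#'   (default 0.10).
#' @param C_true,P_true generating coefficient covariances (positive
#'   definite).
#' @param residual generating [residual_spec()].
#' @param afe_probs probabilities of the three age-at-first-egg classes
#'   `29-31`, `32-34`, `>34`.
#' @param bw_mean,bw_sd body weight at start of lay (kg).
#' @param bw_slope_sd SD of the per-week body-weight regression slopes.
#' @param hw_effect_sd SD of hatch-week-by-week fixed deviations around the
#'   mean curve.
#' @param afe_effect_sd SD of week-by-AFE fixed effects (reference class 0).
#' @param missing_week_rate probability a hen-week record is missing.
#' @param order Legendre order of the generating trajectories.
#' @param genetic_architecture `"markers"` (default): additive coefficient
#'   vectors are sums of per-SNP effects over the autosomal simulated loci,
#'   `alpha_i = (d_i - 2p)' U` with `U ~ MVN(0, C_true / (2 sum p q))`, so
#'   genomic relationships carry real information about Mendelian sampling
#'   while founder variance, parent-offspring covariance and
#'   Mendelian-sampling variance still follow `C_true` exactly in
#'   expectation. `"pedigree"`: coefficients flow through the pedigree only
#'   (founders `MVN(0, C_true)`, descendants parent average plus
#'   `MVN(0, d_i C_true)`), independent of the markers.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_generations = 8, n_sires = 12, n_dams = 110,
                       progeny_per_dam = 4, hatch_weeks_per_gen = 2,
                       genotyped_fraction = 0.30,
                       n_snp = 2000, n_chromosomes = 10,
                       frac_low_maf = 0.05, frac_high_missing = 0.05,
                       missing_rate = 0.01, high_missing_rate = 0.10,
                       C_true = NULL, P_true = NULL, residual = NULL,
                       afe_probs = c(0.3, 0.5, 0.2),
                       bw_mean = 10.5, bw_sd = 0.8, bw_slope_sd = 0.05,
                       hw_effect_sd = 0.3, afe_effect_sd = 0.2,
                       missing_week_rate = 0.03, order = 3,
                       genetic_architecture = c("markers", "pedigree")) {
  genetic_architecture <- match.arg(genetic_architecture)
  pars <- turkey_reference_params()
  C_true <- C_true %||% pars$C_pd
  P_true <- P_true %||% pars$P_pd
  residual <- residual %||% pars$residual
  if (n_sires < 1 || n_dams < 1) abort("need at least one sire and one dam per generation")
  stopifnot(abs(sum(afe_probs) - 1) < 1e-8)
  assert_pd(C_true, "C_true")
  assert_pd(P_true, "P_true")
  cfg <- as.list(environment())
  cfg$pars <- NULL
  structure(cfg, class = "sim_config")
}

#' Simulate a discrete-generation pedigree
#'
#' Founders form generation 1; each later generation draws its sires and
#' dams from the previous generation (random mating, no selfing) and every
#' dam produces `progeny_per_dam` offspring of random sex. Hatch weeks are
#' assigned within generation.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return A [as_pedigree()] tibble with `hatch_week` and `sex` columns.
#' @export
simulate_pedigree <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(seed, "pedigree"))
  rows <- list()
  next_id <- 1L
  make_ids <- function(n) {
    ids <- sprintf("T%05d", next_id + seq_len(n) - 1L)
    next_id <<- next_id + n
    ids
  }
  sires <- make_ids(cfg$n_sires)
  dams <- make_ids(cfg$n_dams)
  hw0 <- sample(seq_len(cfg$hatch_weeks_per_gen), cfg$n_sires + cfg$n_dams, replace = TRUE)
  rows[[1]] <- tibble(
    animal = c(sires, dams), sire = "0", dam = "0",
    sex = c(rep("M", cfg$n_sires), rep("F", cfg$n_dams)),
    generation_born = 1L,
    hatch_week = hw0
  )
  if (cfg$n_generations > 1) {
    for (g in 2:cfg$n_generations) {
      mate_sire <- sample(sires, cfg$n_dams, replace = TRUE)
      n_off <- cfg$n_dams * cfg$progeny_per_dam
      off <- make_ids(n_off)
      sex <- sample(c("M", "F"), n_off, replace = TRUE)
      rows[[g]] <- tibble(
        animal = off,
        sire = rep(mate_sire, each = cfg$progeny_per_dam),
        dam = rep(dams, each = cfg$progeny_per_dam),
        sex = sex,
        generation_born = g,
        hatch_week = (g - 1L) * cfg$hatch_weeks_per_gen +
          sample(seq_len(cfg$hatch_weeks_per_gen), n_off, replace = TRUE)
      )
      males <- rows[[g]]$animal[sex == "M"]
      females <- rows[[g]]$animal[sex == "F"]
      if (length(males) < cfg$n_sires || length(females) < cfg$n_dams) {
        abort("too few progeny to supply the next generation's parents; increase progeny_per_dam")
      }
      sires <- sample(males, cfg$n_sires)
      dams <- sample(females, cfg$n_dams)
    }
  }
  as_pedigree(dplyr::bind_rows(rows))
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder dosages are binomial draws at allele frequencies ~ U(0.05, 0.5);
#' descendants receive one allele per parent (unlinked loci, recombination
#' plays no role because the analysis uses relationships only). Planted QC
#' challenges: a fraction of SNPs with founder MAF below the QC threshold, a
#' fraction with elevated missingness, and SNPs on the sex chromosome "Z".
#' Only the genotyped subset (youngest `genotyped_fraction` of the pedigree)
#' is returned.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg the [sim_config()].
#' @param seed RNG seed.
#' @return A raw (pre-QC) [genotype_data()] plus attribute `planted`
#'   (tibble of the planted failure classes).
#' @export
simulate_genotypes <- function(ped, cfg, seed = 1) {
  set.seed(derive_seed(seed, "genotypes"))
  n <- nrow(ped)
  m <- cfg$n_snp
  n_low <- round(cfg$frac_low_maf * m)
  n_miss <- round(cfg$frac_high_missing * m)
  p <- runif(m, 0.05, 0.5)
  low_idx <- sample(m, n_low)
  p[low_idx] <- runif(n_low, 0.005, 0.04)
  chrom <- sample(as.character(seq_len(cfg$n_chromosomes)), m, replace = TRUE)
  sex_idx <- sample(setdiff(seq_len(m), low_idx), max(1, round(m / (cfg$n_chromosomes + 1))))
  chrom[sex_idx] <- "Z"
  miss_idx <- sample(setdiff(seq_len(m), c(low_idx, sex_idx)), n_miss)
  miss_rate <- rep(cfg$missing_rate, m)
  miss_rate[miss_idx] <- cfg$high_missing_rate

  D <- matrix(0L, n, m)
  founder <- is.na(ped$sire_id) & is.na(ped$dam_id)
  nf <- sum(founder)
  D[founder, ] <- matrix(rbinom(nf * m, 2L, rep(p, each = nf)), nf, m)
  for (i in which(!founder)) {
    s <- ped$sire_id[i]
    d <- ped$dam_id[i]
    gs <- if (is.na(s)) rbinom(m, 1L, p) else rbinom(m, 1L, D[s, ] / 2)
    gd <- if (is.na(d)) rbinom(m, 1L, p) else rbinom(m, 1L, D[d, ] / 2)
    D[i, ] <- gs + gd
  }
  ng <- round(cfg$genotyped_fraction * n)
  gen_idx <- utils::tail(seq_len(n), ng) # youngest animals (pedigree is age-ordered)
  Dg <- D[gen_idx, , drop = FALSE]
  mode(Dg) <- "numeric"
  miss <- matrix(rbinom(length(Dg), 1L, rep(miss_rate, each = nrow(Dg))) == 1L, nrow(Dg), m)
  Dg[miss] <- NA_real_
  rownames(Dg) <- ped$animal[gen_idx]
  snp <- sprintf("snp%05d", seq_len(m))
  colnames(Dg) <- snp
  g <- genotype_data(Dg, tibble(
    snp = snp, chrom = chrom,
    pos = as.integer(seq_len(m) * 1000)
  ))
  rownames(D) <- ped$animal
  colnames(D) <- snp
  attr(g, "full_dosages") <- D
  attr(g, "founder_freq") <- p
  attr(g, "planted") <- tibble(
    snp = snp,
    low_maf = seq_len(m) %in% low_idx,
    high_missing = seq_len(m) %in% miss_idx,
    sex_chrom = seq_len(m) %in% sex_idx
  )
  g
}

rmvn <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(rnorm(n * ncol(Sigma)), n) %*% L
}

#' Simulate 24-week egg-production trajectories
#'
#' Additive coefficient vectors follow the pedigree: founders are
#' `MVN(0, C_true)`; a descendant receives the parent average plus a
#' Mendelian-sampling deviation `MVN(0, d_i C_true)` with
#' `d_i = 0.5 - 0.25 (F_s + F_d)`. Hens (all females) get permanent
#' environmental coefficients `MVN(0, P_true)` and weekly records
#' `y = (HxW) + (WxAFE) + b_t * bw + phi(t)'alpha + phi(t)'pe + e` with
#' period-heterogeneous residuals. Fixed-effect level values are drawn once
#' per dataset around the reference weekly mean curve and stored in the
#' truth record.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg the [sim_config()].
#' @param seed RNG seed.
#' @param genotypes the [simulate_genotypes()] result (with its full-pedigree
#'   dosage attribute); required for the `"markers"` architecture.
#' @return List: `pheno` (record tibble), `truth` (list with `alpha`, `pe`
#'   matrices, per-animal weekly genetic values `g_weekly`, the generating
#'   parameters, and the drawn fixed-effect tables).
#' @export
simulate_trajectories <- function(ped, cfg, seed = 1, genotypes = NULL) {
  set.seed(derive_seed(seed, "trajectories"))
  basis <- legendre_design(cfg$order, 1:24)
  q <- cfg$order + 1
  n <- nrow(ped)
  if (cfg$genetic_architecture == "markers") {
    if (is.null(genotypes) || is.null(attr(genotypes, "full_dosages"))) {
      abort("the 'markers' architecture needs the simulated genotypes (full-pedigree dosages)")
    }
    D <- attr(genotypes, "full_dosages")
    p <- attr(genotypes, "founder_freq")
    causal <- is_autosome_label(genotypes$map$chrom)
    Z <- sweep(D[, causal, drop = FALSE], 2, 2 * p[causal])
    denom <- 2 * sum(p[causal] * (1 - p[causal]))
    U <- matrix(rnorm(sum(causal) * q), ncol = q) %*% chol(cfg$C_true / denom)
    alpha <- Z %*% U
  } else {
    F <- unname(inbreeding(ped))
    alpha <- matrix(0, n, q)
    Lc <- chol(cfg$C_true)
    for (i in seq_len(n)) {
      s <- ped$sire_id[i]
      d <- ped$dam_id[i]
      pa <- numeric(q)
      di <- 1
      if (!is.na(s) && !is.na(d)) {
        pa <- 0.5 * (alpha[s, ] + alpha[d, ])
        di <- 0.5 - 0.25 * (F[s] + F[d])
      } else if (!is.na(s)) {
        pa <- 0.5 * alpha[s, ]
        di <- 0.75 - 0.25 * F[s]
      } else if (!is.na(d)) {
        pa <- 0.5 * alpha[d, ]
        di <- 0.75 - 0.25 * F[d]
      }
      alpha[i, ] <- pa + sqrt(di) * (rnorm(q) %*% Lc)
    }
  }
  rownames(alpha) <- ped$animal

  hens <- which(ped$sex == "F")
  nh <- length(hens)
  pe <- rmvn(nh, cfg$P_true)
  rownames(pe) <- ped$animal[hens]

  pars <- turkey_reference_params()
  mu_week <- pars$weekly_phenotypes$mean
  hw_levels <- sort(unique(ped$hatch_week))
  hw_eff <- matrix(rnorm(length(hw_levels) * 24, 0, cfg$hw_effect_sd),
    length(hw_levels), 24,
    dimnames = list(hw_levels, NULL)
  )
  afe_classes <- c("29-31", "32-34", ">34")
  afe_eff <- rbind(0, matrix(rnorm(2 * 24, 0, cfg$afe_effect_sd), 2, 24))
  rownames(afe_eff) <- afe_classes
  b_slope <- rnorm(24, 0, cfg$bw_slope_sd)

  afe <- sample(afe_classes, nh, replace = TRUE, prob = cfg$afe_probs)
  bw <- rnorm(nh, cfg$bw_mean, cfg$bw_sd)
  res_week <- residual_by_week(cfg$residual, 1:24)

  keep <- matrix(runif(nh * 24) >= cfg$missing_week_rate, nh, 24)
  hen_rows <- rep(seq_len(nh), each = 24)
  week <- rep(1:24, times = nh)
  ok <- keep[cbind(hen_rows, week)]
  hen_rows <- hen_rows[ok]
  week <- week[ok]
  hen_ped <- hens[hen_rows]
  hwm <- match(ped$hatch_week[hen_ped], hw_levels)
  g_val <- rowSums(basis$Phi[week, , drop = FALSE] * alpha[hen_ped, , drop = FALSE])
  pe_val <- rowSums(basis$Phi[week, , drop = FALSE] * pe[hen_rows, , drop = FALSE])
  y <- mu_week[week] + hw_eff[cbind(hwm, week)] + afe_eff[cbind(match(afe[hen_rows], afe_classes), week)] +
    b_slope[week] * (bw[hen_rows] - cfg$bw_mean) +
    g_val + pe_val + rnorm(length(week), 0, sqrt(res_week[week]))
  pheno <- tibble(
    animal = ped$animal[hen_ped],
    week = week,
    eggs = unname(y),
    afe_class = afe[hen_rows],
    hatch_week = ped$hatch_week[hen_ped],
    body_weight = bw[hen_rows]
  )
  g_weekly <- alpha %*% t(basis$Phi)
  colnames(g_weekly) <- paste0("wk", 1:24)
  list(
    pheno = pheno,
    truth = list(
      alpha = alpha, pe = pe, g_weekly = g_weekly,
      C_true = cfg$C_true, P_true = cfg$P_true, residual = cfg$residual,
      hw_eff = hw_eff, afe_eff = afe_eff, b_slope = b_slope, mu_week = mu_week
    )
  )
}

#' Simulate a complete dataset
#'
#' Pedigree, genotypes and phenotypes in one call, with the generating truth
#' retained for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; all stages derive their own stream from it.
#' @return Object of class `rregg_sim`: `ped`, `genotypes` (raw, pre-QC),
#'   `pheno`, `truth`, `cfg`, `seed`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1) {
  ped <- simulate_pedigree(cfg, seed)
  genotypes <- simulate_genotypes(ped, cfg, seed)
  tr <- simulate_trajectories(ped, cfg, seed, genotypes = genotypes)
  structure(
    list(
      ped = ped, genotypes = genotypes, pheno = tr$pheno,
      truth = tr$truth, cfg = cfg, seed = seed
    ),
    class = "rregg_sim"
  )
}

#' @export
print.rregg_sim <- function(x, ...) {
  cat(sprintf(
    "<rregg_sim> %d animals (%d hens with records), %d genotyped, %d records, seed %d\n",
    nrow(x$ped), length(unique(x$pheno$animal)), nrow(x$genotypes$dosages),
    nrow(x$pheno), x$seed
  ))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `pedigree.csv`, `phenotypes.csv`, `genotypes.txt` (animal id +
#' dosages), `snp_map.csv`, `truth_alpha.csv` and `config.yaml` under `dir`.
#'
#' @param sim an [simulate_dataset()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped_out <- tibble(
    animal = sim$ped$animal,
    sire = ifelse(is.na(sim$ped$sire_id), "0", sim$ped$animal[sim$ped$sire_id]),
    dam = ifelse(is.na(sim$ped$dam_id), "0", sim$ped$animal[sim$ped$dam_id]),
    hatch_week = sim$ped$hatch_week,
    sex = sim$ped$sex
  )
  utils::write.csv(ped_out, file.path(dir, "pedigree.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$pheno, file.path(dir, "phenotypes.csv"), row.names = FALSE, quote = FALSE)
  g <- sim$genotypes
  gm <- data.frame(
    animal = rownames(g$dosages) %||% character(0), g$dosages,
    check.names = FALSE
  )
  utils::write.table(gm, file.path(dir, "genotypes.txt"), row.names = FALSE, quote = FALSE)
  utils::write.csv(g$map, file.path(dir, "snp_map.csv"), row.names = FALSE, quote = FALSE)
  al <- data.frame(animal = rownames(sim$truth$alpha), sim$truth$alpha, check.names = FALSE)
  colnames(al) <- c("animal", paste0("alpha", seq_len(ncol(sim$truth$alpha)) - 1))
  utils::write.csv(al, file.path(dir, "truth_alpha.csv"), row.names = FALSE, quote = FALSE)
  cfg <- sim$cfg
  cfg_out <- purrr::map(cfg, function(v) if (is.matrix(v)) as.numeric(v) else if (inherits(v, "data.frame")) as.list(v) else v)
  cfg_out$seed <- sim$seed
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @return List with `ped`, `pheno`, `genotypes`, `truth_alpha`.
#' @export
read_dataset <- function(dir) {
  list(
    ped = read_pedigree(file.path(dir, "pedigree.csv")),
    pheno = as_tibble(utils::read.csv(file.path(dir, "phenotypes.csv"))),
    genotypes = read_genotypes(
      file.path(dir, "genotypes.txt"),
      file.path(dir, "snp_map.csv")
    ),
    truth_alpha = as_tibble(utils::read.csv(file.path(dir, "truth_alpha.csv")))
  )
}
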
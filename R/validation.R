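#' Forward-validation split by age
#'
#' Assigns approximately the youngest `fraction` of the hens with records to
#' the validation group (their phenotypes are masked when training). Youth is
#' judged by hatch week (numerically when possible), with ties broken by
#' pedigree id so the split is deterministic.
#'
#' @param pheno phenotype tibble (`animal` column).
#' @param ped [as_pedigree()] tibble with a `hatch_week` column.
#' @param fraction validation fraction in (0, 1); default 0.10. The group
#'   size is `floor(n_hens * fraction)`.
#' @return List with character vectors `reference` and `validation` (animal
#'   labels).
#' @export
split_by_age <- function(pheno, ped, fraction = 0.10) {
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be in (0, 1)")
  hens <- unique(as.character(pheno$animal))
  idx <- match(hens, ped$animal)
  if (anyNA(idx)) abort("phenotyped animals missing from the pedigree")
  hwn <- suppressWarnings(as.numeric(as.character(ped$hatch_week[idx])))
  if (anyNA(hwn)) hwn <- as.numeric(factor(as.character(ped$hatch_week[idx])))
  ord <- order(-hwn, -idx) # youngest first: latest hatch week, then latest id
  nv <- floor(length(hens) * fraction)
  val <- hens[ord[seq_len(nv)]]
  list(reference = setdiff(hens, val), validation = val)
}

#' Phenotypes corrected for fixed effects
#'
#' `y* = y - X b_hat` using the fixed-effect solutions of a reference-data
#' fit: the record's hatch-week-by-week mean, its week-by-AFE effect (zero
#' for the reference class) and the body-weight term, centered with the
#' reference fit's centering constant. Records whose fixed level was unseen
#' in the reference fit are dropped with a warning.
#'
#' @param pheno phenotype tibble for the records to correct.
#' @param fit the reference [fit_rr()].
#' @return Tibble `animal`, `week`, `y`, `ystar`.
#' @export
corrected_phenotypes <- function(pheno, fit) {
  stopifnot(inherits(fit, "rr_fit"))
  fx <- fit$solution$fixed
  get_est <- function(term, level) {
    m <- fx$estimate[fx$term == term][match(level, fx$level[fx$term == term])]
    m
  }
  wk <- as.integer(pheno$week)
  hw_lev <- paste(pheno$hatch_week, wk, sep = ":")
  b_hw <- get_est("hatchweek_week", hw_lev)
  afe_chr <- as.character(pheno$afe_class)
  is_ref <- afe_chr == fit$design$afe_levels[1]
  afe_lev <- paste(afe_chr, wk, sep = ":")
  b_afe <- ifelse(is_ref, 0, get_est("week_afe", afe_lev))
  b_sl <- get_est("bodyweight_slope", paste0("week", wk))
  keep <- !is.na(b_hw) & !is.na(b_afe) & !is.na(b_sl)
  if (!all(keep)) {
    warn(sprintf(
      "%d record(s) dropped: fixed-effect level unseen in the reference fit",
      sum(!keep)
    ))
  }
  xb <- b_hw + b_afe + b_sl * (pheno$body_weight - fit$design$bw_center)
  tibble(
    animal = as.character(pheno$animal)[keep],
    week = wk[keep],
    y = as.numeric(pheno$eggs)[keep],
    ystar = as.numeric(pheno$eggs)[keep] - xb[keep]
  )
}

#' Correlation-based weekly prediction accuracy
#'
#' `acc(t) = cor(EBV_t, y*_t) / sqrt(h2_t)` over the validation animals with
#' a week-`t` record: the Pearson correlation between (G)EBV and phenotypes
#' corrected for fixed effects, scaled by the square root of the weekly
#' heritability.
#'
#' @param ebv long EBV tibble (`animal`, `week`, `ebv`), e.g.
#'   `tidy(fit)`, from the masked (reference) fit.
#' @param ystar corrected phenotypes of the validation animals
#'   ([corrected_phenotypes()]).
#' @param h2 per-week heritabilities: a numeric vector indexed by week, or a
#'   trajectory tibble with `week` and `h2` columns.
#' @param min_n weeks with fewer validation animals than this are reported
#'   as `NA` (default 3).
#' @return Tibble `week`, `n`, `r`, `accuracy`.
#' @export
correlation_accuracy <- function(ebv, ystar, h2, min_n = 3) {
  if (is.data.frame(h2)) h2 <- setNames(h2$h2, h2$week)
  joined <- dplyr::inner_join(ystar, ebv, by = c("animal", "week"))
  dplyr::group_by(joined, .data$week) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= min_n && stats::sd(.data$ebv) > 0 && stats::sd(.data$ystar) > 0) {
        cor(.data$ebv, .data$ystar)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      h2 = unname(h2[as.character(.data$week)]),
      accuracy = ifelse(.data$h2 > 0, .data$r / sqrt(.data$h2), NA_real_)
    )
}

#' Predicted Mendelian-sampling effects
#'
#' `ms_i(t) = EBV_i(t) - 0.5 (EBV_sire(t) + EBV_dam(t))` on the weekly EBV
#' scale, for eligible animals: those with at least one record and both
#' parents known.
#'
#' @param fit an [fit_rr()] object.
#' @return Long tibble `animal`, `week`, `ms` over eligible animals.
#' @export
mendelian_sampling <- function(fit) {
  stopifnot(inherits(fit, "rr_fit"))
  design <- fit$design
  alpha <- fit$solution$alpha
  ped_ids <- seq_len(design$n_animals)
  has_rec <- ped_ids %in% design$hens
  sire <- fit$sire_id
  dam <- fit$dam_id
  eligible <- which(has_rec & !is.na(sire) & !is.na(dam))
  if (length(eligible) == 0) abort("no animals with records and both parents known")
  Phi <- fit$basis$Phi
  ms_alpha <- alpha[eligible, , drop = FALSE] -
    0.5 * (alpha[sire[eligible], , drop = FALSE] + alpha[dam[eligible], , drop = FALSE])
  ms <- ms_alpha %*% t(Phi)
  colnames(ms) <- fit$basis$weeks
  as_tibble(ms) |>
    dplyr::mutate(animal = design$animal_labels[eligible], .before = 1) |>
    tidyr::pivot_longer(-"animal",
      names_to = "week",
      names_transform = as.integer, values_to = "ms"
    )
}

#' Mendelian-sampling variance ratio
#'
#' `nu(t) = Var(ms(t)) / (0.5 * sigma2_a(t))`: the empirical variance
#' (denominator n-1) of the predicted Mendelian-sampling effects at week `t`
#' over one half of the weekly additive genetic variance from the model's
#' expanded coefficient covariance. Approaches 1 as predictions become
#' perfectly accurate; values slightly above 1 trigger a warning.
#'
#' @param ms long tibble from [mendelian_sampling()] (or any `animal`,
#'   `week`, `ms` table, e.g. built from true breeding values).
#' @param var_a per-week additive variances: numeric vector indexed by week
#'   or a trajectory tibble with `week`, `var_a`.
#' @param min_n minimum eligible animals per week (default 10).
#' @return Tibble `week`, `n`, `nu`.
#' @export
ms_variance_ratio <- function(ms, var_a, min_n = 10) {
  if (is.data.frame(var_a)) var_a <- setNames(var_a$var_a, var_a$week)
  out <- dplyr::group_by(ms, .data$week) |>
    dplyr::summarise(n = dplyr::n(), v = stats::var(.data$ms), .groups = "drop") |>
    dplyr::mutate(
      sigma2_a = unname(var_a[as.character(.data$week)]),
      nu = ifelse(.data$n >= min_n & .data$sigma2_a > 0,
        .data$v / (0.5 * .data$sigma2_a), NA_real_
      )
    ) |>
    dplyr::select("week", "n", "nu")
  if (any(out$nu > 1.05, na.rm = TRUE)) {
    warn("nu exceeds 1.05 at some weeks; predictions more variable than the Mendelian-sampling expectation")
  }
  out
}

#' Forward validation of RR-PBLUP and/or RR-ssGBLUP
#'
#' Orchestrates the two accuracy statistics: (1) the correlation-based
#' accuracy on an age-based validation split (phenotypes of the youngest
#' hens masked when training, then corrected for the reference fit's fixed
#' effects), and (2) the Mendelian-sampling variance ratio computed from a
#' fit to all data (no partition needed). The heritability in the accuracy
#' denominator is the weekly h2 implied by the supplied (C, P, residual)
#' parameters, one scale for all methods.
#'
#' @param pheno,ped,C,P,res,basis,blend_weight as in [fit_rr()].
#' @param genotypes optional QC'd genotypes; when supplied both RR-PBLUP and
#'   RR-ssGBLUP are validated, otherwise RR-PBLUP only.
#' @param fraction validation fraction (default 0.10).
#' @return Object of class `rregg_validation`: tibble `week`, `method`,
#'   `acc_corr`, `nu`, `n_validation`, `n_trios`, with the split stored as an
#'   attribute.
#' @export
validate_accuracy <- function(pheno, ped, C, P, res, genotypes = NULL,
                              fraction = 0.10, basis = legendre_design(),
                              blend_weight = 0.95) {
  split <- split_by_age(pheno, ped, fraction)
  ref_pheno <- dplyr::filter(pheno, as.character(.data$animal) %in% split$reference)
  val_pheno <- dplyr::filter(pheno, as.character(.data$animal) %in% split$validation)
  traj <- trajectory_parameters(
    cov_function(C, basis, "additive"), cov_function(P, basis, "pe"), res
  )
  methods <- if (is.null(genotypes)) list(`RR-PBLUP` = NULL) else {
    list(`RR-PBLUP` = NULL, `RR-ssGBLUP` = genotypes)
  }
  out <- purrr::imap_dfr(methods, function(g, label) {
    fit_ref <- fit_rr(ref_pheno, ped, C, P, res,
      genotypes = g, basis = basis, blend_weight = blend_weight
    )
    ys <- corrected_phenotypes(val_pheno, fit_ref)
    acc <- correlation_accuracy(tidy(fit_ref), ys, traj$by_week)
    fit_all <- fit_rr(pheno, ped, C, P, res,
      genotypes = g, basis = basis, blend_weight = blend_weight
    )
    ms <- mendelian_sampling(fit_all)
    nu <- ms_variance_ratio(ms, traj$by_week)
    dplyr::left_join(acc, nu, by = "week") |>
      dplyr::transmute(
        week = .data$week, method = label, acc_corr = .data$accuracy,
        nu = .data$nu, n_validation = .data$n.x, n_trios = .data$n.y
      )
  })
  structure(out, class = c("rregg_validation", class(out)), split = split)
}
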
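#' Run configuration for the full pipeline
#'
#' A single structured configuration drives every stage: simulation (or input
#' paths), model settings, chain settings and validation. Defaults mirror the
#' reference analysis settings: order-3 Legendre basis, 0.95 G blend, MAF
#' 0.05, call rate 0.95, validation fraction 0.10, and the reference
#' four-period residual structure.
#'
#' @param out_dir output directory for all artifacts.
#' @param sim a [sim_config()] (used by the `simulate` stage).
#' @param seed master seed.
#' @param order basis order.
#' @param blend_weight G blend weight.
#' @param maf_min,callrate_min genotype QC thresholds.
#' @param validation_fraction forward-validation fraction.
#' @param chain a [chain_config()] for the `gibbs` stage.
#' @param C,P,residual model parameters used by the fitting stages (defaults:
#'   reference estimates, bent for positive definiteness).
#' @return A `run_config` list with a stable `hash`.
#' @export
run_config <- function(out_dir, sim = sim_config(), seed = 1, order = 3,
                       blend_weight = 0.95, maf_min = 0.05, callrate_min = 0.95,
                       validation_fraction = 0.10,
                       chain = chain_config(
                         rounds = 20000, burn_in = 2000,
                         thin = 10, seed = seed
                       ),
                       C = NULL, P = NULL, residual = NULL) {
  pars <- turkey_reference_params()
  cfg <- list(
    out_dir = out_dir, sim = sim, seed = as.integer(seed), order = order,
    blend_weight = blend_weight, maf_min = maf_min, callrate_min = callrate_min,
    validation_fraction = validation_fraction, chain = chain,
    C = C %||% pars$C_pd, P = P %||% pars$P_pd,
    residual = residual %||% pars$residual
  )
  cfg$hash <- digest::digest(cfg[setdiff(names(cfg), "out_dir")], algo = "xxhash32")
  structure(cfg, class = "run_config")
}

write_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", cfg$hash, cfg$seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

artifact_hash <- function(path) {
  l1 <- readLines(path, n = 1)
  if (!grepl("^# config_hash=", l1)) {
    return(NA_character_)
  }
  sub("^# config_hash=([0-9a-f]+).*", "\\1", l1)
}

require_artifact <- function(path, stage_needed) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact '%s': run stage '%s' first", basename(path), stage_needed))
  }
  invisible(path)
}

#' Execute pipeline stages
#'
#' Runs the requested stages in order against `cfg$out_dir`:
#' `simulate` (writes the dataset), `qc` (genotype quality control),
#' `fit-pblup` / `fit-ssgblup` (solve the mixed-model equations and export
#' fixed solutions and EBV trajectories), `gibbs` (variance-component chain
#' and posterior summaries), `validate` (both accuracy statistics) and
#' `report` (summary tables). Every CSV artifact carries the configuration
#' hash; stages refuse inputs with a different hash.
#'
#' @param cfg a [run_config()].
#' @param stages character vector of stage names.
#' @return Invisibly, a named list of the in-memory results per stage.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "qc", "fit-pblup", "validate", "report")) {
  stopifnot(inherits(cfg, "run_config"))
  known <- c("simulate", "qc", "fit-pblup", "fit-ssgblup", "gibbs", "validate", "report")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(cfg$out_dir, "data")
  basis <- legendre_design(cfg$order, 1:24)
  results <- list()
  state <- new.env(parent = emptyenv())

  load_data <- function() {
    if (is.null(state$data)) {
      require_artifact(file.path(data_dir, "pedigree.csv"), "simulate")
      state$data <- read_dataset(data_dir)
    }
    state$data
  }
  load_qc <- function() {
    if (is.null(state$qc)) {
      require_artifact(file.path(cfg$out_dir, "qc_report.csv"), "qc")
      d <- load_data()
      state$qc <- qc_genotypes(d$genotypes, cfg$maf_min, cfg$callrate_min)
    }
    state$qc
  }
  check_hash <- function(path) {
    h <- artifact_hash(path)
    if (!is.na(h) && h != cfg$hash) {
      abort(sprintf(
        "artifact '%s' was produced under config %s but this run is %s; refusing to mix",
        basename(path), h, cfg$hash
      ))
    }
  }

  for (stage in stages) {
    if (stage == "simulate") {
      sim <- simulate_dataset(cfg$sim, cfg$seed)
      write_dataset(sim, data_dir)
      state$data <- list(
        ped = sim$ped, pheno = sim$pheno,
        genotypes = sim$genotypes,
        truth_alpha = as_tibble(data.frame(
          animal = rownames(sim$truth$alpha),
          sim$truth$alpha
        ))
      )
      results$simulate <- sim
    } else if (stage == "qc") {
      d <- load_data()
      g <- qc_genotypes(d$genotypes, cfg$maf_min, cfg$callrate_min)
      write_artifact(g$qc_log, file.path(cfg$out_dir, "qc_report.csv"), cfg)
      state$qc <- g
      results$qc <- g
    } else if (stage %in% c("fit-pblup", "fit-ssgblup")) {
      d <- load_data()
      g <- NULL
      if (stage == "fit-ssgblup") {
        if (nrow(d$genotypes$dosages) == 0) {
          abort("fit-ssgblup requires genotypes; none are present in the dataset")
        }
        g <- load_qc()
      }
      fit <- fit_rr(d$pheno, d$ped, cfg$C, cfg$P, cfg$residual,
        genotypes = g, basis = basis, blend_weight = cfg$blend_weight
      )
      tag <- if (stage == "fit-pblup") "pblup" else "ssgblup"
      write_artifact(
        fit$solution$fixed,
        file.path(cfg$out_dir, sprintf("solutions_fixed_%s.csv", tag)), cfg
      )
      write_artifact(
        ebv_trajectory(fit),
        file.path(cfg$out_dir, sprintf("ebv_%s.csv", tag)), cfg
      )
      state[[stage]] <- fit
      results[[stage]] <- fit
    } else if (stage == "gibbs") {
      d <- load_data()
      chain <- run_gibbs(d$pheno, d$ped, cfg$residual,
        basis = basis, chain = cfg$chain
      )
      dr <- chain$draws
      write_artifact(
        dr[c("sample", grep("^C", names(dr), value = TRUE))],
        file.path(cfg$out_dir, "chain_C.csv"), cfg
      )
      write_artifact(
        dr[c("sample", grep("^P", names(dr), value = TRUE))],
        file.path(cfg$out_dir, "chain_P.csv"), cfg
      )
      write_artifact(
        dr[c("sample", grep("^r[0-9]+$", names(dr), value = TRUE))],
        file.path(cfg$out_dir, "chain_res.csv"), cfg
      )
      write_artifact(posterior_summary(chain), file.path(cfg$out_dir, "posterior_summary.csv"), cfg)
      state$gibbs <- chain
      results$gibbs <- chain
    } else if (stage == "validate") {
      d <- load_data()
      g <- if (nrow(d$genotypes$dosages) > 0) load_qc() else NULL
      v <- validate_accuracy(d$pheno, d$ped, cfg$C, cfg$P, cfg$residual,
        genotypes = g, fraction = cfg$validation_fraction,
        basis = basis, blend_weight = cfg$blend_weight
      )
      write_artifact(v, file.path(cfg$out_dir, "accuracy_by_week.csv"), cfg)
      results$validate <- v
    } else if (stage == "report") {
      d <- load_data()
      for (f in list.files(cfg$out_dir, pattern = "\\.csv$", full.names = TRUE)) check_hash(f)
      desc <- descriptive_table(d$pheno)
      traj <- trajectory_parameters(
        cov_function(cfg$C, basis, "additive"),
        cov_function(cfg$P, basis, "pe"), cfg$residual
      )
      write_artifact(desc, file.path(cfg$out_dir, "report_descriptive.csv"), cfg)
      write_artifact(traj$by_week, file.path(cfg$out_dir, "report_trajectory.csv"), cfg)
      write_artifact(as_tibble(cfg$residual), file.path(cfg$out_dir, "report_residual.csv"), cfg)
      ctab <- correlation_table(traj)
      write_artifact(
        dplyr::mutate(as_tibble(ctab), week = rownames(ctab), .before = 1),
        file.path(cfg$out_dir, "report_correlations.csv"), cfg
      )
      results$report <- list(
        descriptive = desc, trajectory = traj$by_week,
        correlations = ctab
      )
    }
  }
  invisible(results)
}

#' Weekly descriptive statistics
#'
#' @param pheno phenotype tibble.
#' @return Tibble `week`, `n`, `mean`, `sd`, `cv` (CV in percent,
#'   `sd/mean*100`).
#' @export
descriptive_table <- function(pheno) {
  dplyr::group_by(as_tibble(pheno), week = as.integer(.data$week)) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$eggs), sd = stats::sd(.data$eggs),
      .groups = "drop"
    ) |>
    dplyr::mutate(cv = .data$sd / .data$mean * 100)
}

#' Selected-week correlation table
#'
#' Square table over selected weeks with heritabilities on the diagonal,
#' genetic correlations above it and phenotypic correlations below it.
#'
#' @param traj an [trajectory_parameters()] object.
#' @param weeks weeks to show (default 1, 4, 8, 12, 16, 20, 24).
#' @return Numeric matrix with `week<w>` dimnames.
#' @export
correlation_table <- function(traj, weeks = c(1, 4, 8, 12, 16, 20, 24)) {
  idx <- match(weeks, traj$by_week$week)
  if (anyNA(idx)) abort("requested weeks outside the trajectory grid")
  k <- length(idx)
  out <- matrix(NA_real_, k, k, dimnames = list(paste0("week", weeks), paste0("week", weeks)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- if (i == j) {
        traj$by_week$h2[idx[i]]
      } else if (i < j) {
        traj$cor_g[idx[i], idx[j]]
      } else {
        traj$cor_p[idx[i], idx[j]]
      }
    }
  }
  out
}
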
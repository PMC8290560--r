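# Independent oracles used across tests: deliberately naive pure-R
# implementations, kept separate from the package internals they check.

# tabular numerator relationship matrix by direct recursion
oracle_tabular_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- sire[j]
    d <- dam[j]
    if (j > 1) {
      for (i in seq_len(j - 1)) {
        a <- 0
        if (s > 0) a <- a + 0.5 * A[i, s]
        if (d > 0) a <- a + 0.5 * A[i, d]
        A[i, j] <- A[j, i] <- a
      }
    }
    A[j, j] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  A
}

# random multi-generation pedigree as a plain data frame
random_pedigree_df <- function(n_founders = 10, n_offspring = 40, seed = 1) {
  set.seed(seed)
  n <- n_founders + n_offspring
  sire <- dam <- integer(n)
  for (i in (n_founders + 1):n) {
    pars <- sample(seq_len(i - 1), 2)
    sire[i] <- pars[1]
    dam[i] <- pars[2]
  }
  data.frame(
    animal = paste0("a", seq_len(n)),
    sire = ifelse(sire == 0, "0", paste0("a", sire)),
    dam = ifelse(dam == 0, "0", paste0("a", dam)),
    hatch_week = rep(1, n)
  )
}

# naive double-loop VanRaden method-1 G
oracle_G <- function(M) {
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p)
  n <- nrow(M)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- sum(Z[i, ] * Z[j, ])
    }
  }
  G / (2 * sum(p * (1 - p)))
}

# small phenotype table on a given pedigree: one record per hen-week, AFE
# class and body weight deterministic in the hen index, stochastic egg counts
# under the caller's seed
toy_pheno <- function(ped, weeks = 1:24, hens = NULL) {
  is_f <- if ("sex" %in% names(ped)) ped$sex == "F" else rep(TRUE, nrow(ped))
  hens <- hens %||% ped$animal[is_f]
  grid <- expand.grid(animal = hens, week = weeks, stringsAsFactors = FALSE)
  hidx <- match(grid$animal, hens)
  tibble::tibble(
    animal = grid$animal,
    week = as.integer(grid$week),
    eggs = rnorm(nrow(grid), 5, 1.5),
    afe_class = c("29-31", "32-34", ">34")[hidx %% 3 + 1],
    hatch_week = ped$hatch_week[match(grid$animal, ped$animal)],
    body_weight = 10 + (hidx %% 5) / 5
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_pars <- rregg::turkey_reference_params()
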
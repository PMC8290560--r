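make_geno <- function(M, chrom = NULL) {
  m <- ncol(M)
  rownames(M) <- paste0("an", seq_len(nrow(M)))
  colnames(M) <- paste0("s", seq_len(m))
  genotype_data(M, tibble::tibble(
    snp = colnames(M), chrom = chrom %||% rep("1", m), pos = seq_len(m)
  ))
}

test_that("QC removes SNPs for the right reasons, in order, and imputes the rest", {
  set.seed(1)
  n <- 200
  M <- cbind(
    rbinom(n, 2, 0.04), # low MAF
    rbinom(n, 2, 0.3), # fails call rate (below)
    rbinom(n, 2, 0.4), # sex chromosome
    rbinom(n, 2, 0.3), # clean
    rbinom(n, 2, 0.5) # clean with some missing
  )
  M[1:12, 2] <- NA # call rate 94%
  M[1:4, 5] <- NA # call rate 98%: retained, imputed
  g <- make_geno(M, chrom = c("1", "2", "Z", "3", "4"))
  qc <- qc_genotypes(g)
  expect_equal(qc$qc_log$reason, c("maf", "call_rate", "non_autosomal", NA, NA))
  expect_equal(ncol(qc$dosages), 2)
  # imputation fills missing with twice the observed allele frequency
  p5 <- mean(M[-(1:4), 5]) / 2
  expect_equal(unname(qc$dosages[1, "s5"]), 2 * p5)
  expect_false(anyNA(qc$dosages))
  # removed + retained = input, reasons partition removals
  expect_equal(sum(qc$qc_log$status == "pass") + sum(qc$qc_log$status == "fail"), 5)
  expect_error(qc_genotypes(make_geno(cbind(rbinom(50, 2, 0.01)))), "no SNPs")
})

test_that("MAF exactly at the threshold is retained, just below is removed", {
  M <- rbind(
    matrix(2, 1, 2),
    matrix(0, 19, 2)
  ) # p = 0.05 both columns
  M2 <- M
  M2[1, 2] <- 1 # p = 0.025 in column 2
  expect_equal(sum(qc_genotypes(make_geno(M2), maf_min = 0.05)$qc_log$status == "fail"), 1)
  expect_equal(qc_genotypes(make_geno(M), maf_min = 0.05)$qc_log$status, c("pass", "pass"))
})

test_that("VanRaden method-1 G matches hand and brute-force evaluation", {
  # p = (0.5, 0.5): Z rows (-1, 1) and (1, -1), denominator 2 sum pq = 1
  g2 <- make_geno(matrix(c(0, 2, 2, 0), 2))
  G <- build_G_vanraden1(g2)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  set.seed(11)
  M <- matrix(rbinom(20 * 100, 2, runif(100, 0.1, 0.9)[rep(1:100, each = 20)]), 20, 100)
  keep <- apply(M, 2, function(x) length(unique(x)) > 1)
  M <- M[, keep]
  g <- make_geno(M)
  expect_lt(max(abs(build_G_vanraden1(g) - oracle_G(M))), 1e-10)
  # G symmetric PSD up to numerical floor
  ev <- eigen(build_G_vanraden1(g), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # monomorphic SNP triggers the error path
  Mm <- cbind(M, 0)
  expect_error(build_G_vanraden1(make_geno(Mm)), "monomorphic")
})

test_that("blending restores invertibility and respects its bounds", {
  set.seed(2)
  base <- matrix(rbinom(10 * 60, 2, 0.4), 10, 60)
  M <- rbind(base, base[1, , drop = FALSE]) # duplicate animal: singular G
  rownames(M) <- paste0("an", seq_len(nrow(M)))
  g <- make_geno(M)
  G <- build_G_vanraden1(g)
  expect_lt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  ped <- as_pedigree(data.frame(
    animal = rownames(M), sire = "0", dam = "0"
  ))
  A22 <- build_A(ped, subset = rownames(M))
  Gb <- blend_G(G, A22, 0.95)
  expect_gt(min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values), 0)
  # fixed point: blending G with itself returns it
  expect_equal(unname(blend_G(A22, A22, 0.95)), unname(A22), ignore_attr = TRUE)
  expect_error(blend_G(G, A22, 1.0), "strictly between")
  expect_error(blend_G(G, A22[1:5, 1:5], 0.95), "dimensions")
})

test_that("H-inverse reduces to A-inverse in the degenerate cases", {
  ped <- as_pedigree(random_pedigree_df(8, 40, seed = 21))
  Ainv <- build_A_inverse(ped)
  H0 <- build_H_inverse(Ainv) # no genotyped animals
  expect_equal(as.matrix(H0), as.matrix(Ainv))
  sub <- ped$animal[30:45]
  A22 <- build_A(ped, subset = sub)
  Hnull <- build_H_inverse(Ainv, G = A22, A22 = A22) # G == A22
  expect_lt(max(abs(as.matrix(Hnull) - as.matrix(Ainv))), 1e-8)
  expect_error(
    build_H_inverse(Ainv, G = structure(A22, dimnames = list(
      c("ghost", sub[-1]), c("ghost", sub[-1])
    )), A22 = A22),
    "absent from the pedigree"
  )
})

test_that("H-inverse equals the inverse of the assembled H matrix", {
  ped <- as_pedigree(random_pedigree_df(6, 24, seed = 31))
  n <- nrow(ped)
  sub <- ped$animal[21:30] # 10 genotyped
  set.seed(31)
  M <- matrix(rbinom(10 * 80, 2, 0.4), 10, 80)
  rownames(M) <- sub
  colnames(M) <- paste0("s", 1:80)
  g <- genotype_data(M, tibble::tibble(snp = colnames(M), chrom = "1", pos = 1:80))
  Gb <- blend_G(build_G_vanraden1(qc_genotypes(g)), build_A(ped, subset = sub), 0.95)
  Ainv <- build_A_inverse(ped)
  Hinv <- build_H_inverse(Ainv, Gb, build_A(ped, subset = sub))
  # dense oracle: build H itself from its partitioned definition and invert
  A <- build_A(ped)
  gi <- match(sub, ped$animal)
  ni <- setdiff(seq_len(n), gi)
  A22 <- A[gi, gi]
  A22i <- solve(A22)
  H <- A
  H[gi, gi] <- Gb
  H[ni, gi] <- A[ni, gi] %*% A22i %*% Gb
  H[gi, ni] <- t(H[ni, gi])
  H[ni, ni] <- A[ni, ni] - A[ni, gi] %*% A22i %*% (A22 - Gb) %*% A22i %*% A[gi, ni]
  expect_lt(max(abs(as.matrix(Hinv) - solve(H))), 1e-8)
})

test_that("genotype files round-trip in both orientations", {
  set.seed(7)
  M <- matrix(rbinom(12, 2, 0.5), 3, 4)
  rownames(M) <- paste0("an", 1:3)
  colnames(M) <- paste0("s", 1:4)
  map <- data.frame(snp = colnames(M), chrom = "1", pos = 1:4)
  d <- withr::local_tempdir()
  write.csv(map, file.path(d, "map.csv"), row.names = FALSE, quote = FALSE)
  write.table(data.frame(animal = rownames(M), M, check.names = FALSE),
    file.path(d, "g.txt"),
    row.names = FALSE, quote = FALSE
  )
  g <- read_genotypes(file.path(d, "g.txt"), file.path(d, "map.csv"))
  expect_equal(g$dosages, M)
  # SNP-per-row variant via the transposed flag
  write.table(
    data.frame(snp = colnames(M), t(M), check.names = FALSE),
    file.path(d, "gt.txt"),
    row.names = FALSE, quote = FALSE
  )
  gt <- read_genotypes(file.path(d, "gt.txt"), file.path(d, "map.csv"),
    transposed = TRUE
  )
  expect_equal(gt$dosages, M)
})
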
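test_that("GRM matches hand standardization on the two-individual case", {
  g <- make_genotypes(matrix(c(0L, 2L), 2, 1), ids = c("a", "b"))
  grm <- compute_grm(g)
  # p = 0.5, so (x - 1)/sqrt(0.5): individual scores -sqrt(2), +sqrt(2)
  expect_equal(grm$values, matrix(c(2, -2, -2, 2), 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(grm$kind, "G")
})

test_that("GRM equals the brute-force double-loop oracle", {
  set.seed(42)
  counts <- matrix(rbinom(5 * 4, 2, 0.4), 5, 4)
  counts[1, 1] <- 2L  # guard against a monomorphic column
  grm <- compute_grm(make_genotypes(counts))
  expect_lt(max(abs(grm$values - grm_oracle(counts))), 1e-12)
  # and with missingness (pairwise-complete averaging)
  counts_na <- counts
  counts_na[2, 3] <- NA
  counts_na[4, 1] <- NA
  grm_na <- compute_grm(make_genotypes(counts_na))
  expect_lt(max(abs(grm_na$values - grm_oracle(counts_na))), 1e-12)
  expect_equal(grm_na$pair_counts[2, 4], 2)  # two shared missing columns
})

test_that("identical genotype rows give identical GRM rows", {
  set.seed(7)
  counts <- matrix(rbinom(4 * 30, 2, 0.3), 4, 30)
  counts[2, ] <- counts[1, ]
  counts[4, ] <- 1L  # keeps every column polymorphic (0 < p < 1)
  grm <- compute_grm(make_genotypes(counts))
  expect_equal(grm$values[1, ], grm$values[2, ],
               ignore_attr = TRUE)
})

test_that("monomorphic SNPs and all-missing pairs are rejected", {
  counts <- matrix(c(0L, 0L, 0L, 1L, 2L, 1L), 3, 2)
  expect_error(compute_grm(make_genotypes(counts)), "monomorphic.*snp1")
  counts2 <- matrix(rbinom(9, 2, 0.5), 3, 3)
  counts2[1, 2] <- 2L; counts2[1, ] <- NA  # row 1 all missing
  expect_error(compute_grm(make_genotypes(counts2)), "missing|monomorphic")
})

test_that("ERM matches the outer-product case and the double-loop oracle", {
  e1 <- compute_erm(matrix(c(1, -1), 2, 1, dimnames = list(c("a", "b"), "PC1")))
  expect_equal(e1$values, matrix(c(1, -1, -1, 1), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
  # k identical PCs average to the k = 1 matrix
  s <- matrix(rnorm(6), 6, 1)
  expect_equal(compute_erm(cbind(s, s, s))$values, compute_erm(s)$values)
  set.seed(11)
  scores <- matrix(rnorm(18), 6, 3)
  expect_lt(max(abs(compute_erm(scores)$values - erm_oracle(scores))), 1e-12)
  expect_error(compute_erm(cbind(s, 0)), "zero-variance")
})

test_that("hadamard product: identity mask, arithmetic, PSD, id checks", {
  ids <- c("a", "b")
  g <- relmat(matrix(c(1, 0.5, 0.5, 1), 2), ids, "G")
  e <- relmat(matrix(c(1, -0.2, -0.2, 1), 2), ids, "E")
  h <- hadamard(g, e)
  expect_equal(unname(h$values), matrix(c(1, -0.1, -0.1, 1), 2))
  expect_equal(h$kind, "GxE")
  # commutative, symmetric
  expect_equal(hadamard(e, g)$values, h$values)
  # identity mask
  i8 <- relmat(diag(8), sprintf("s%d", 1:8), "G")
  m8 <- relmat(random_kernel(8, seed = 3), sprintf("s%d", 1:8), "E")
  expect_equal(unname(hadamard(i8, m8)$values), diag(diag(m8$values)))
  # Schur product of PSD kernels stays PSD
  k1 <- relmat(random_kernel(8, seed = 1), sprintf("s%d", 1:8), "G")
  k2 <- relmat(random_kernel(8, seed = 2), sprintf("s%d", 1:8), "E")
  expect_gt(min(eigen(hadamard(k1, k2)$values, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-10)
  # id mismatch is named
  e_bad <- relmat(e$values, c("a", "z"), "E")
  expect_error(hadamard(g, e_bad), "position 2")
})

test_that("filter_unrelated removes the minimum necessary individuals", {
  ids <- sprintf("s%d", 1:6)
  # identity: nothing to remove
  expect_equal(filter_unrelated(relmat(diag(6), ids, "G"), 0.05), ids)
  # one related pair: exactly one member dropped
  A <- diag(6); A[1, 2] <- A[2, 1] <- 0.5
  expect_length(filter_unrelated(relmat(A, ids, "G"), 0.05), 5)
  # 3-clique at 0.3: two removals, matching the brute-force maximum
  # independent set over all subsets
  B <- diag(6)
  B[1, 2] <- B[2, 1] <- B[1, 3] <- B[3, 1] <- B[2, 3] <- B[3, 2] <- 0.3
  kept <- filter_unrelated(relmat(B, ids, "G"), 0.05)
  expect_length(kept, 4)
  best <- 0
  for (size in 6:1) {
    combos <- utils::combn(6, size)
    for (ci in seq_len(ncol(combos))) {
      sub <- B[combos[, ci], combos[, ci], drop = FALSE]
      if (all(sub[upper.tri(sub)] < 0.05)) { best <- size; break }
    }
    if (best > 0) break
  }
  expect_equal(length(kept), best)
  # post-hoc guarantee on a random relatedness structure
  set.seed(5)
  C <- diag(10)
  C[upper.tri(C)] <- sample(c(0, 0.1), 45, replace = TRUE, prob = c(.8, .2))
  C <- C + t(C) - diag(diag(C))
  kept2 <- filter_unrelated(relmat(C, sprintf("x%d", 1:10), "G"), 0.05)
  sub <- C[match(kept2, sprintf("x%d", 1:10)),
           match(kept2, sprintf("x%d", 1:10))]
  expect_true(all(sub[upper.tri(sub)] < 0.05))
})

test_that("grm_pcs separates population blocks and matches a dense solver", {
  ids <- sprintf("s%d", 1:6)
  blockA <- matrix(0.8, 3, 3); blockB <- matrix(0.8, 3, 3)
  G <- rbind(cbind(blockA, matrix(-0.5, 3, 3)),
             cbind(matrix(-0.5, 3, 3), blockB))
  diag(G) <- 1
  pcs <- grm_pcs(relmat(G, ids, "G"), k = 3)
  expect_true(all(sign(pcs$scores[1:3, 1]) == sign(pcs$scores[1, 1])))
  expect_true(all(sign(pcs$scores[4:6, 1]) == -sign(pcs$scores[1, 1])))
  expect_true(all(diff(pcs$values) <= 1e-12))
  # eigenpairs match an independent dense decomposition of the centered
  # matrix (columns up to sign, which the convention then fixes)
  M <- random_kernel(6, seed = 9)
  H <- diag(6) - matrix(1 / 6, 6, 6)
  ref <- eigen(H %*% M %*% H, symmetric = TRUE)
  got <- grm_pcs(relmat(M, ids, "G"), k = 6)
  expect_equal(got$values, ref$values, tolerance = 1e-10)
  for (j in 1:5)  # last eigenvalue of a centered matrix is ~0, skip
    expect_lt(min(max(abs(got$scores[, j] - ref$vectors[, j])),
                  max(abs(got$scores[, j] + ref$vectors[, j]))), 1e-10)
  expect_error(grm_pcs(relmat(M, ids, "G"), k = 7), "exceeds")
})

test_that("precorrection removes nothing when there is nothing to remove", {
  set.seed(21)
  n <- 150
  G <- random_kernel(n, rank = 400, seed = 22)
  ids <- sprintf("s%d", seq_len(n))
  covar <- data.frame(age = rnorm(n))
  # heritability-0 trait: residuals ~ the covariate-residualized original
  y0 <- rnorm(n) + 0.3 * covar$age
  pc0 <- matrix(y0, dimnames = list(ids, "PC1"))
  out <- precorrect_pcs(pc0, relmat(G, ids, "G"), covariates = covar)
  y0_resid <- residuals(lm(y0 ~ covar$age))
  expect_gt(cor(out[, 1], y0_resid), 0.99)
  expect_lt(abs(mean(out[, 1])), 1e-8)
})
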
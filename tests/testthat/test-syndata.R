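test_that("config validation enforces the generative invariants", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "monomorphic")
  expect_error(sim_config(var_g = 0.5, var_e = 0.5, var_gxe = 0.5,
                          var_resid = 0.5), "sum to 1")
  expect_error(sim_config(trauma_h2 = 1), "trauma_h2")
  expect_error(sim_config(n_causal_trauma = 10, n_snps = 5), "exceeds")
  expect_error(sim_config(n_clusters = 50, n_individuals = 10), "exceeds")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(sex_gxe_ratio = -1), "positive")
})

test_that("genotypes are HWE draws at the configured frequencies", {
  cfg <- sim_config(n_individuals = 4, n_snps = 10,
                    maf_range = c(0.5, 0.5), n_causal_trauma = 5,
                    n_trauma_items = 3, n_clusters = 1, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$counts), c(4L, 10L))
  expect_true(all(g$counts %in% 0:2))
  # column means / 2 estimate p = 0.5 within binomial error (8 draws)
  expect_true(all(abs(g$allele_freqs - 0.5) <= 3 * sqrt(0.25 / 8)))
  # determinism
  g2 <- simulate_genotypes(cfg)
  expect_identical(g$counts, g2$counts)
})

test_that("sib pairs realize GRM relatedness near the pedigree 0.5", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 5000,
                    sib_pair_fraction = 1, n_causal_trauma = 100, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_equal(nrow(g$sib_pairs), 500L)
  grm <- compute_grm(g)
  vals <- grm$values[g$sib_pairs]
  expect_lt(abs(mean(vals) - 0.5), 3 * sd(vals) / sqrt(length(vals)))
  # non-sib pairs stay near 0
  expect_lt(abs(mean(grm$values[cbind(g$sib_pairs[, 1],
                                      rev(g$sib_pairs[, 2]))])), 0.02)
})

test_that("latent trauma heritability behaves at the null and target", {
  # h2 = 0: HE estimate within 2 SE of zero
  cfg0 <- sim_config(n_individuals = 800, n_snps = 1500, trauma_h2 = 0,
                     n_causal_trauma = 150, seed = 4)
  g0 <- simulate_genotypes(cfg0)
  tr0 <- simulate_trauma(g0, cfg0)
  he0 <- he_univariate(tr0$latent, compute_grm(g0))
  expect_lt(abs(he0$h2), 2 * he0$se)
  # realized variance decomposition of the latent is exact by scaling
  cfg <- sim_config(n_individuals = 500, n_snps = 1000, trauma_h2 = 0.17,
                    n_causal_trauma = 100, seed = 5)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trauma(g, cfg)
  expect_equal(var(tr$latent), 1, tolerance = 1e-10)
})

test_that("single-factor items put PC1 first and items track the latent", {
  cfg <- sim_config(n_individuals = 600, n_snps = 800, n_trauma_items = 6,
                    n_causal_trauma = 100, seed = 6)
  g <- simulate_genotypes(cfg)
  tr <- simulate_trauma(g, cfg)
  expect_true(all(tr$items %in% 0:1))
  pcs <- compute_trauma_pcs(tr$items)
  expect_gt(pcs$explained_share[1], max(pcs$explained_share[-1]))
  expect_gt(abs(cor(pcs$scores[, 1], tr$latent)), 0.6)
})

test_that("phenotype variance fractions are realized exactly", {
  cfg <- sim_config(n_individuals = 400, n_snps = 600,
                    n_causal_trauma = 80, seed = 7)
  cc <- simulate_cohort(cfg)
  tr <- cc$cohort$truth
  expect_equal(var(tr$g), 0.16, tolerance = 1e-10)
  expect_equal(var(tr$e), 0.18, tolerance = 1e-10)
  expect_equal(var(tr$gxe), 0.20, tolerance = 1e-10)
  expect_equal(var(tr$resid), 0.46, tolerance = 1e-10)
  expect_equal(tr$liability,
               tr$fixed + tr$g + tr$e + tr$gxe + tr$resid)
  # interaction draws are uncorrelated with main effects
  expect_lt(abs(cor(tr$gxe, tr$g)), 3 / sqrt(400))
  expect_lt(abs(cor(tr$gxe, tr$e)), 3 / sqrt(400))
})

test_that("noise-only phenotype has residual-scale variance", {
  cfg <- sim_config(n_individuals = 500, n_snps = 400,
                    var_g = 0, var_e = 0, var_gxe = 0, var_resid = 1,
                    n_causal_trauma = 50, seed = 8)
  cc <- simulate_cohort(cfg)
  y_res <- residuals(lm(cc$cohort$phenotype ~ age + sex + batch,
                        data = cc$cohort$covariates))
  expect_lt(abs(var(y_res) - 1), 3 * sqrt(2 / 500))
})

test_that("liability thresholding hits the prevalence exactly", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 400, prevalence = 0.28,
                    n_causal_trauma = 50, seed = 9)
  cc <- simulate_cohort(cfg)
  expect_true(all(cc$cohort$phenotype %in% 0:1))
  # empirical-quantile threshold: case share exact up to rounding
  expect_lt(abs(mean(cc$cohort$phenotype) - 0.28),
            1.5 / 1000 + 3 * sqrt(0.28 * 0.72 / 1000))
  # reproducible case count under the same seed
  cc2 <- simulate_cohort(cfg)
  expect_identical(cc$cohort$phenotype, cc2$cohort$phenotype)
})

test_that("sex-specific interaction variance follows the configured ratio", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 400,
                    n_causal_trauma = 50, sex_gxe_ratio = 5, seed = 10)
  cc <- simulate_cohort(cfg)
  tr <- cc$cohort$truth
  male <- cc$cohort$sex == "M"
  ratio <- var(tr$gxe[male]) / var(tr$gxe[!male])
  expect_gt(ratio, 3)
  expect_lt(ratio, 7)
})

test_that("strata partition is near-equal, degenerate k works, reproducible", {
  cfg <- sim_config(n_individuals = 100, n_snps = 10, n_clusters = 5,
                    n_causal_trauma = 5, n_trauma_items = 2, seed = 11)
  s <- assign_strata(cfg)
  expect_true(all(table(s$cluster) == 20))
  cfg99 <- sim_config(n_individuals = 99, n_snps = 10, n_clusters = 5,
                      n_causal_trauma = 5, n_trauma_items = 2, seed = 11)
  expect_true(all(abs(table(assign_strata(cfg99)$cluster) - 99 / 5) <= 1))
  cfg1 <- sim_config(n_individuals = 50, n_snps = 10, n_clusters = 1,
                     n_causal_trauma = 5, n_trauma_items = 2, seed = 11)
  expect_equal(unique(assign_strata(cfg1)$cluster), 1L)
  expect_identical(assign_strata(cfg)$cluster, assign_strata(cfg)$cluster)
  # sex composition near the 52% female target
  expect_lt(abs(mean(assign_strata(cfg)$sex == "F") - 0.52), 0.2)
})
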
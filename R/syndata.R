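#' Simulation configuration for a synthetic biobank-style cohort
#'
#' Collects the generative quantities of the four-component mixed model
#' `y = Xb + g + e + gxe + resid`: cohort and marker dimensions, the
#' heritable latent trauma exposure, the four variance fractions, the
#' genetic correlation between exposure and outcome, the liability-scale
#' prevalence for binary traits, cluster/sex strata and the sex contrast
#' in interaction variance.
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of biallelic SNPs (drawn in Hardy-Weinberg
#'   equilibrium).
#' @param maf_range Length-2 numeric, minor-allele-frequency range in
#'   (0, 0.5]. The lower bound must be strictly positive: monomorphic
#'   SNPs cannot be standardized into a relationship matrix.
#' @param sib_pair_fraction Fraction of individuals arranged in full-sib
#'   pairs (gene-dropped through simulated parents).
#' @param n_trauma_items Number of binary questionnaire items generated
#'   from the latent exposure.
#' @param trauma_h2 SNP heritability of the latent trauma exposure, in
#'   `[0, 1)`.
#' @param n_causal_trauma Number of SNPs with a causal effect on the
#'   latent exposure.
#' @param var_g,var_e,var_gxe,var_resid Variance fractions of the additive
#'   genetic, environmental (exposure), interaction and residual
#'   components; must sum to 1.
#' @param rg_trauma_pheno Genetic correlation between the latent exposure
#'   and the phenotype's additive genetic value, in `[-1, 1]`.
#' @param prevalence Optional population prevalence in (0, 1); when set
#'   the phenotype is dichotomized at the matching liability threshold.
#' @param n_clusters Number of (simulated) geographic clusters.
#' @param sex_gxe_ratio Male:female ratio of interaction variance; 1 means
#'   no sex contrast.
#' @param seed Integer seed; the same config reproduces the cohort
#'   bit-identically.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 2000L,
                       n_snps = 5000L,
                       maf_range = c(0.05, 0.5),
                       sib_pair_fraction = 0,
                       n_trauma_items = 12L,
                       trauma_h2 = 0.17,
                       n_causal_trauma = 500L,
                       var_g = 0.16,
                       var_e = 0.18,
                       var_gxe = 0.20,
                       var_resid = 0.46,
                       rg_trauma_pheno = 0.6,
                       prevalence = NULL,
                       n_clusters = 5L,
                       sex_gxe_ratio = 1,
                       seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals", min = 2L)
  n_snps <- check_count(n_snps, "n_snps", min = 1L)
  stopifnot(length(maf_range) == 2L, is.numeric(maf_range))
  if (maf_range[1] <= 0)
    stop("maf_range lower bound must be > 0: frequency-0 SNPs are ",
         "monomorphic and cannot enter a GRM", call. = FALSE)
  if (maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be increasing within (0, 0.5]", call. = FALSE)
  check_proportion(sib_pair_fraction, "sib_pair_fraction")
  if (trauma_h2 < 0 || trauma_h2 >= 1)
    stop("trauma_h2 must lie in [0, 1)", call. = FALSE)
  n_trauma_items <- check_count(n_trauma_items, "n_trauma_items", min = 1L)
  n_causal_trauma <- check_count(n_causal_trauma, "n_causal_trauma", min = 1L)
  if (n_causal_trauma > n_snps)
    stop("n_causal_trauma exceeds n_snps", call. = FALSE)
  for (v in c("var_g", "var_e", "var_gxe", "var_resid"))
    check_proportion(get(v), v)
  tot <- var_g + var_e + var_gxe + var_resid
  if (abs(tot - 1) > 1e-12)
    stop(sprintf("variance fractions must sum to 1 (got %.15f)", tot),
         call. = FALSE)
  if (abs(rg_trauma_pheno) > 1)
    stop("rg_trauma_pheno must lie in [-1, 1]", call. = FALSE)
  if (!is.null(prevalence))
    check_proportion(prevalence, "prevalence", open_left = TRUE,
                     open_right = TRUE)
  n_clusters <- check_count(n_clusters, "n_clusters", min = 1L)
  if (n_clusters > n_individuals)
    stop("n_clusters exceeds n_individuals", call. = FALSE)
  if (!is.numeric(sex_gxe_ratio) || sex_gxe_ratio <= 0)
    stop("sex_gxe_ratio must be a positive scalar", call. = FALSE)
  structure(list(
    n_individuals = n_individuals, n_snps = n_snps, maf_range = maf_range,
    sib_pair_fraction = sib_pair_fraction, n_trauma_items = n_trauma_items,
    trauma_h2 = trauma_h2, n_causal_trauma = n_causal_trauma,
    var_g = var_g, var_e = var_e, var_gxe = var_gxe, var_resid = var_resid,
    rg_trauma_pheno = rg_trauma_pheno, prevalence = prevalence,
    n_clusters = n_clusters, sex_gxe_ratio = sex_gxe_ratio,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d individuals, m = %d SNPs (MAF %.2f-%.2f), %d%% in sib pairs\n",
              x$n_individuals, x$n_snps, x$maf_range[1], x$maf_range[2],
              round(100 * x$sib_pair_fraction)))
  cat(sprintf("  trauma: %d items, latent h2 = %.3f (%d causal SNPs)\n",
              x$n_trauma_items, x$trauma_h2, x$n_causal_trauma))
  cat(sprintf("  variance fractions G/E/GxE/resid = %.2f/%.2f/%.2f/%.2f, rg = %.2f\n",
              x$var_g, x$var_e, x$var_gxe, x$var_resid, x$rg_trauma_pheno))
  cat(sprintf("  prevalence = %s, clusters = %d, male:female GxE ratio = %g, seed = %d\n",
              if (is.null(x$prevalence)) "none (quantitative)"
              else format(x$prevalence), x$n_clusters, x$sex_gxe_ratio,
              x$seed))
  invisible(x)
}

#' Simulate biallelic genotypes with optional full-sib pairs
#'
#' Unrelated individuals receive independent `binomial(2, p)` genotypes
#' with `p` uniform over `maf_range` (Hardy-Weinberg equilibrium).
#' Sib pairs are gene-dropped: two parents are simulated per pair and
#' each child inherits one allele from each parent, so realized
#' relatedness is genuine (expected GRM entry 0.5) rather than a
#' perturbation of the matrix.
#'
#' @param config A [sim_config()].
#' @return An object of class `genotypes`: list with `counts` (n x m
#'   integer matrix of 0/1/2), `sample_ids`, `snp_ids`, `allele_freqs`
#'   (in-sample counted-allele frequencies) and `sib_pairs` (2-column
#'   matrix of row indices, possibly empty).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  set.seed(child_seed(config$seed, "genotypes"))
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  n_pairs <- floor(config$sib_pair_fraction * n / 2)
  n_sib <- 2L * n_pairs
  counts <- matrix(0L, n, m)
  if (n_sib < n) {
    counts[(n_sib + 1L):n, ] <- matrix(
      stats::rbinom((n - n_sib) * m, 2L, rep(p, each = n - n_sib)),
      n - n_sib, m)
  }
  if (n_pairs > 0) {
    # gene dropping: each parental genotype transmits one allele per SNP
    transmit <- function(parent)
      matrix(stats::rbinom(length(parent), 1L, parent / 2), nrow(parent))
    pa <- matrix(stats::rbinom(n_pairs * m, 2L, rep(p, each = n_pairs)),
                 n_pairs, m)
    mo <- matrix(stats::rbinom(n_pairs * m, 2L, rep(p, each = n_pairs)),
                 n_pairs, m)
    counts[seq_len(n_pairs) * 2L - 1L, ] <- transmit(pa) + transmit(mo)
    counts[seq_len(n_pairs) * 2L, ]      <- transmit(pa) + transmit(mo)
  }
  sib_pairs <- if (n_pairs > 0)
    cbind(seq_len(n_pairs) * 2L - 1L, seq_len(n_pairs) * 2L)
  else matrix(integer(0), 0, 2)

  ids <- sprintf("id%0*d", nchar(n), seq_len(n))
  structure(list(
    counts = counts,
    sample_ids = ids,
    snp_ids = sprintf("snp%0*d", nchar(m), seq_len(m)),
    allele_freqs = colMeans(counts) / 2,
    sib_pairs = sib_pairs), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs, %d sib pairs\n",
              nrow(x$counts), ncol(x$counts), nrow(x$sib_pairs)))
  invisible(x)
}

#' Simulate a heritable latent trauma exposure and questionnaire items
#'
#' The latent exposure is `L = g_L + noise` where `g_L` is a weighted sum
#' of `n_causal_trauma` standardized genotypes scaled to sample variance
#' `trauma_h2`, and the noise brings the total variance to 1. Each of the
#' `n_trauma_items` binary items is a thresholded noisy copy of `L`
#' (loading `sqrt(0.5)` on the standardized exposure), with item
#' endorsement rates spread over 0.15-0.5 to mimic heterogeneous
#' questionnaire prevalences.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param config The matching [sim_config()].
#' @return List with `items` (n x p 0/1 matrix with item ids), `latent`
#'   (the true exposure, variance 1), `causal_idx` and `causal_beta`
#'   (the SNP effects, for constructing genetically correlated traits).
#' @export
simulate_trauma <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotypes"), inherits(config, "sim_config"))
  n <- nrow(genotypes$counts)
  set.seed(child_seed(config$seed, "trauma"))
  m <- ncol(genotypes$counts)
  idx <- sort(sample.int(m, config$n_causal_trauma))
  Z <- scale(genotypes$counts[, idx, drop = FALSE])
  beta <- stats::rnorm(config$n_causal_trauma)
  g_raw <- drop(Z %*% beta)
  g_l <- scale_to_var(g_raw, config$trauma_h2)
  # orthogonalize the noise against the genetic part so the realized
  # latent variance is exactly 1 and realized h2 exactly trauma_h2
  noise <- stats::rnorm(n)
  if (config$trauma_h2 > 0) noise <- stats::lm.fit(cbind(1, g_l), noise)$residuals
  latent <- g_l + scale_to_var(noise, 1 - config$trauma_h2)

  p_items <- config$n_trauma_items
  lat_std <- drop(scale(latent))
  rates <- seq(0.15, 0.5, length.out = p_items)
  items <- matrix(0L, n, p_items)
  for (j in seq_len(p_items)) {
    item_liab <- sqrt(0.5) * lat_std + sqrt(0.5) * stats::rnorm(n)
    items[, j] <- as.integer(item_liab > stats::quantile(item_liab,
                                                         1 - rates[j]))
  }
  colnames(items) <- sprintf("item%02d", seq_len(p_items))
  rownames(items) <- genotypes$sample_ids
  list(items = items, latent = latent, causal_idx = idx, causal_beta = beta)
}

#' Assign cluster and sex labels
#'
#' Clusters form a near-equal-size random partition (sizes differ by at
#' most 1); sex is Bernoulli with P(female) = 0.52, matching the cohort
#' composition the design emulates.
#'
#' @param config A [sim_config()].
#' @return List with `cluster` (integer labels 1..k) and `sex`
#'   (factor with levels "F", "M").
#' @export
assign_strata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  k <- config$n_clusters
  set.seed(child_seed(config$seed, "strata"))
  cluster <- sample(rep_len(seq_len(k), n))
  sex <- factor(ifelse(stats::runif(n) < 0.52, "F", "M"),
                levels = c("F", "M"))
  list(cluster = cluster, sex = sex)
}

# Draw a mean-zero vector with covariance proportional to a PSD kernel,
# via eigendecomposition with negative eigenvalues clipped at 0, then
# rescaled to an exact sample variance. The clip total is attached so
# callers can diagnose badly conditioned Hadamard kernels.
draw_from_kernel <- function(kernel, target_var, tol = 1e-8) {
  n <- nrow(kernel)
  if (target_var == 0) return(structure(rep(0, n), clipped = 0))
  eg <- eigen(kernel, symmetric = TRUE)
  neg <- eg$values < 0
  clipped <- -sum(eg$values[neg])
  if (clipped > tol * sum(abs(eg$values)))
    stop(sprintf(paste0("kernel is not positive semidefinite beyond the ",
                        "jitter tolerance (clipped eigenvalue mass %.3g)"),
                 clipped), call. = FALSE)
  vals <- pmax(eg$values, 0)
  x <- drop(eg$vectors %*% (sqrt(vals) * stats::rnorm(n)))
  structure(scale_to_var(x, target_var), clipped = clipped)
}

#' Simulate a phenotype under the four-component interaction model
#'
#' Generates `y = Xb + g + e + gxe + resid` with realized sample variances
#' matching the configured fractions exactly:
#' * `g` multivariate normal with covariance proportional to the GRM,
#'   with a fraction `rg_trauma_pheno^2` of its variance driven by the
#'   trauma-causal SNP effects so that the genetic correlation between
#'   exposure and outcome equals `rg_trauma_pheno` in expectation;
#' * `e` the scaled standardized latent exposure;
#' * `gxe` multivariate normal with covariance proportional to the
#'   Hadamard product of the GRM and the exposure relationship matrix
#'   (eigendecomposed, negative eigenvalues clipped at zero), with
#'   per-sex variance scaled so the male:female ratio equals
#'   `sex_gxe_ratio` while the overall fraction stays `var_gxe`;
#' * fixed effects: small contributions of a continuous age-like
#'   covariate, sex and a binary batch indicator.
#'
#' When `prevalence` is set, the phenotype is the indicator of liability
#' exceeding its empirical `(1 - prevalence)` quantile, so the realized
#' case fraction is exact up to integer rounding.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param trauma A [simulate_trauma()] result (its `latent` and causal
#'   effects are used).
#' @param config The matching [sim_config()].
#' @param grm Optional precomputed [compute_grm()] of `genotypes`
#'   (recomputed if missing).
#' @param erm Optional precomputed exposure relationship matrix used for
#'   the interaction kernel; defaults to the rank-1 kernel of the
#'   standardized latent exposure.
#' @param e_mode `"latent"` (default): `e` is the scaled standardized
#'   latent exposure, so the exposure effect is exactly the rank-1
#'   direction of the true factor. `"kernel"`: `e` is drawn multivariate
#'   normal with covariance proportional to `erm` — the well-specified
#'   regime in which the kernels later used for fitting are exactly the
#'   generative ones (used by the pipeline's recovery benchmarks).
#' @param strata Optional [assign_strata()] result (generated if missing).
#' @return List of class `cohort` with elements `phenotype` (vector; 0/1
#'   if dichotomized), `liability`, `covariates` (data.frame: age, sex,
#'   batch), `truth` (data.frame of the realized g/e/gxe/resid/fixed
#'   values), `cluster`, `sex`, `threshold`, `prevalence` and `config`.
#' @export
simulate_phenotype <- function(genotypes, trauma, config, grm = NULL,
                               erm = NULL, e_mode = c("latent", "kernel"),
                               strata = NULL) {
  stopifnot(inherits(genotypes, "genotypes"), inherits(config, "sim_config"))
  e_mode <- match.arg(e_mode)
  if (e_mode == "kernel" && is.null(erm))
    stop("e_mode = 'kernel' requires an erm", call. = FALSE)
  n <- nrow(genotypes$counts)
  if (is.null(grm)) grm <- compute_grm(genotypes)
  if (is.null(strata)) strata <- assign_strata(config)
  lat_std <- drop(scale(trauma$latent))
  if (is.null(erm)) {
    erm_values <- tcrossprod(lat_std)
  } else {
    erm_values <- erm$values
  }
  set.seed(child_seed(config$seed, "phenotype"))

  # genetic value: shared part through the trauma-causal effects gives the
  # target genetic correlation; orthogonal polygenic part tops it up
  rg <- config$rg_trauma_pheno
  Zc <- scale(genotypes$counts[, trauma$causal_idx, drop = FALSE])
  g_shared <- drop(Zc %*% trauma$causal_beta)
  # Z w / sqrt(m) has covariance Z Z' / m = G exactly, at O(nm) cost
  Zall <- scale(genotypes$counts)
  g_indep <- drop(Zall %*% stats::rnorm(ncol(Zall))) / sqrt(ncol(Zall))
  g <- if (config$var_g > 0) {
    scale_to_var(rg * drop(scale(g_shared)) +
                   sqrt(max(0, 1 - rg^2)) * drop(scale(g_indep)),
                 config$var_g)
  } else rep(0, n)

  e <- if (e_mode == "latent") scale_to_var(lat_std, config$var_e)
       else draw_from_kernel(erm_values, config$var_e)

  gxe <- rep(0, n)
  if (config$var_gxe > 0) {
    kernel <- grm$values * erm_values
    gxe_raw <- draw_from_kernel(kernel, 1)
    r <- config$sex_gxe_ratio
    male <- strata$sex == "M"
    # per-sex scale factors with overall sample variance var_gxe preserved
    w <- ifelse(male, sqrt(2 * r / (1 + r)), sqrt(2 / (1 + r)))
    gxe <- scale_to_var(w * gxe_raw, config$var_gxe)
  }

  resid <- scale_to_var(stats::rnorm(n), config$var_resid)

  age <- stats::rnorm(n, 56, 7)
  batch <- stats::rbinom(n, 1L, 0.5)
  sex_num <- as.integer(strata$sex == "M")
  fixed <- 0.1 * drop(scale(age)) + 0.05 * sex_num + 0.05 * batch
  liability <- fixed + g + e + gxe + resid

  if (is.null(config$prevalence)) {
    phenotype <- liability
    threshold <- NA_real_
  } else {
    threshold <- stats::quantile(liability, 1 - config$prevalence,
                                 names = FALSE)
    phenotype <- as.integer(liability > threshold)
  }

  truth <- data.frame(sample_id = genotypes$sample_ids, g = g, e = e,
                      gxe = gxe, resid = resid, fixed = fixed,
                      liability = liability)
  structure(list(
    phenotype = phenotype, liability = liability,
    covariates = data.frame(age = age, sex = sex_num, batch = batch),
    truth = truth, cluster = strata$cluster, sex = strata$sex,
    threshold = threshold, prevalence = config$prevalence,
    sample_ids = genotypes$sample_ids, config = config), class = "cohort")
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_trauma()], [assign_strata()] and [simulate_phenotype()] and
#' returning all pieces, including the GRM.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `trauma`, `grm`, `cohort`.
#' @export
simulate_cohort <- function(config) {
  genotypes <- simulate_genotypes(config)
  trauma <- simulate_trauma(genotypes, config)
  grm <- compute_grm(genotypes)
  strata <- assign_strata(config)
  cohort <- simulate_phenotype(genotypes, trauma, config, grm = grm,
                               strata = strata)
  list(genotypes = genotypes, trauma = trauma, grm = grm, cohort = cohort)
}
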
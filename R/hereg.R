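# Moment-based Haseman-Elston estimation. The slope of pairwise trait
# products on pairwise relatedness estimates the genetic (co)variance on
# the standardized scale. Diagonal entries are excluded; covariates are
# residualized out of each trait first (moment estimators assume
# mean-zero traits). Delete-1 jackknife SEs are computed by O(n) sum
# downdates per left-out individual, so exact leave-one-out costs O(n^2)
# overall; a delete-block mode is provided for very large n.

# Residualize on an intercept + covariates and scale to unit variance.
residualize_std <- function(y, covariates = NULL) {
  X <- build_design(length(y), covariates)
  r <- stats::lm.fit(X, y)$residuals
  drop(scale(r))
}

# Pair-sum machinery shared by the HE estimators. For the regression of
# pairwise products on off-diagonal G over the M = n(n-1)/2 pairs, all
# required sums and their per-individual downdates (sums over the pairs
# that involve i) are linear-algebra aggregates of the zero-diagonal GRM
# and the trait vectors, so exact delete-1 costs O(n) per individual.
he_sums <- function(A, y1, y2) {
  n <- length(y1)
  Ay1 <- drop(A %*% y1)
  Ay2 <- if (identical(y1, y2)) Ay1 else drop(A %*% y2)
  T1 <- sum(y1); T2 <- sum(y2)
  list(
    n = n,
    M = n * (n - 1) / 2,
    Sx  = sum(A) / 2,
    Sxx = sum(A^2) / 2,
    Sp  = (T1 * T2 - sum(y1 * y2)) / 2,
    Sxp = (sum(y1 * Ay2) + sum(y2 * Ay1)) / 4,
    dM  = rep(n - 1, n),
    dSx  = rowSums(A),
    dSxx = rowSums(A^2),
    dSp  = (y1 * (T2 - y2) + y2 * (T1 - y1)) / 2,
    dSxp = (y1 * Ay2 + y2 * Ay1) / 2
  )
}

# Least-squares slope (with intercept) from the pair sums.
he_slope <- function(s) {
  num <- s$Sxp - s$Sx * s$Sp / s$M
  den <- s$Sxx - s$Sx^2 / s$M
  num / den
}

# Slope recomputed with one individual (or an index block) removed.
he_slope_without <- function(s, idx, A, y1, y2) {
  if (length(idx) == 1L) {
    M   <- s$M - s$dM[idx]
    Sx  <- s$Sx - s$dSx[idx]
    Sxx <- s$Sxx - s$dSxx[idx]
    Sp  <- s$Sp - s$dSp[idx]
    Sxp <- s$Sxp - s$dSxp[idx]
  } else {
    # block removal: pair sums within the block were subtracted twice
    Ab <- A[idx, idx, drop = FALSE]
    y1b <- y1[idx]; y2b <- y2[idx]
    nb <- length(idx)
    M   <- s$M - sum(s$dM[idx]) + nb * (nb - 1) / 2
    Sx  <- s$Sx - sum(s$dSx[idx]) + sum(Ab) / 2
    Sxx <- s$Sxx - sum(s$dSxx[idx]) + sum(Ab^2) / 2
    Sp  <- s$Sp - sum(s$dSp[idx]) +
      (sum(y1b) * sum(y2b) - sum(y1b * y2b)) / 2
    Sxp <- s$Sxp - sum(s$dSxp[idx]) +
      (sum(y1b * drop(Ab %*% y2b)) + sum(y2b * drop(Ab %*% y1b))) / 4
  }
  (Sxp - Sx * Sp / M) / (Sxx - Sx^2 / M)
}

#' Univariate Haseman-Elston regression
#'
#' Regresses pairwise products `y_j * y_k` (covariate-residualized,
#' unit-variance trait) on the off-diagonal GRM entries over all j < k
#' pairs; the slope estimates the SNP heritability on the standardized
#' observed scale.
#'
#' @param y Trait vector.
#' @param grm A [relmat()] (or plain symmetric matrix) aligned to `y`.
#' @param covariates Optional covariate matrix/data.frame.
#' @param jackknife `"delete1"` (exact leave-one-individual-out),
#'   `"block"` (delete-block, for very large n), or `"none"`.
#' @param n_blocks Number of blocks for `jackknife = "block"`.
#' @param max_exact_n Above this n, `"delete1"` falls back to `"block"`
#'   (mode recorded in the result).
#' @return List: `h2`, `se`, `n_used`, `jackknife` (mode actually used).
#' @export
he_univariate <- function(y, grm, covariates = NULL,
                          jackknife = c("delete1", "block", "none"),
                          n_blocks = 100L, max_exact_n = 5000L) {
  jackknife <- match.arg(jackknife)
  A <- if (inherits(grm, "relmat")) grm$values else as.matrix(grm)
  keep <- !is.na(y)
  y <- y[keep]
  A <- A[keep, keep, drop = FALSE]
  if (!is.null(covariates))
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  n <- length(y)
  if (n < 3) stop("need at least 3 non-missing observations", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant trait", call. = FALSE)
  ys <- residualize_std(y, covariates)
  diag(A) <- 0
  s <- he_sums(A, ys, ys)
  h2 <- he_slope(s)
  se <- NA_real_
  if (jackknife != "none") {
    mode <- if (jackknife == "delete1" && n <= max_exact_n) "delete1"
            else "block"
    theta <- jk_estimates(mode, n, n_blocks,
                          function(idx) he_slope_without(s, idx, A, ys, ys))
    se <- jk_se(theta)
    jackknife <- mode
  }
  list(h2 = h2, se = se, n_used = n, jackknife = jackknife)
}

#' Bivariate Haseman-Elston regression and genetic correlation
#'
#' Cross-trait regression of symmetrized products
#' `(y1_j y2_k + y1_k y2_j) / 2` on off-diagonal GRM entries estimates
#' the genetic covariance; the genetic correlation is
#' `rg = cov_g / sqrt(h2_1 * h2_2)` with both heritabilities from
#' [he_univariate()] on the same (complete-case) sample. The jackknife
#' SE of rg re-derives the full ratio with each individual left out.
#'
#' @param y1,y2 Two trait vectors on the same id-aligned sample
#'   (individuals missing either trait are dropped).
#' @param grm A [relmat()] or plain symmetric matrix.
#' @param covariates Optional covariate matrix/data.frame.
#' @param jackknife,n_blocks,max_exact_n As in [he_univariate()].
#' @param clip_rg Clip rg into `[-1, 1]` (clipping recorded in
#'   `clipped`).
#' @return Object of class `hefit`: `h2_trait1`, `h2_trait2`,
#'   `genetic_covariance`, `rg`, `se_rg`, `n_used`, `status`
#'   (`"ok"` or `"undefined_h2"`), `clipped`, `jackknife`.
#' @export
he_bivariate <- function(y1, y2, grm, covariates = NULL,
                         jackknife = c("delete1", "block", "none"),
                         n_blocks = 100L, max_exact_n = 5000L,
                         clip_rg = TRUE) {
  jackknife <- match.arg(jackknife)
  A <- if (inherits(grm, "relmat")) grm$values else as.matrix(grm)
  keep <- !is.na(y1) & !is.na(y2)
  y1 <- y1[keep]; y2 <- y2[keep]
  A <- A[keep, keep, drop = FALSE]
  if (!is.null(covariates))
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  n <- length(y1)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  z1 <- residualize_std(y1, covariates)
  z2 <- residualize_std(y2, covariates)
  diag(A) <- 0
  s11 <- he_sums(A, z1, z1)
  s22 <- he_sums(A, z2, z2)
  s12 <- he_sums(A, z1, z2)
  h2_1 <- he_slope(s11)
  h2_2 <- he_slope(s22)
  covg <- he_slope(s12)

  rg_from <- function(h1, h2, cg) {
    if (h1 <= 0 || h2 <= 0) return(NA_real_)
    cg / sqrt(h1 * h2)
  }
  rg <- rg_from(h2_1, h2_2, covg)
  status <- if (is.na(rg)) "undefined_h2" else "ok"
  clipped <- FALSE
  if (!is.na(rg) && clip_rg && abs(rg) > 1) {
    rg <- sign(rg)
    clipped <- TRUE
  }

  se_rg <- NA_real_
  if (jackknife != "none" && status == "ok") {
    mode <- if (jackknife == "delete1" && n <= max_exact_n) "delete1"
            else "block"
    theta <- jk_estimates(mode, n, n_blocks, function(idx)
      rg_from(he_slope_without(s11, idx, A, z1, z1),
              he_slope_without(s22, idx, A, z2, z2),
              he_slope_without(s12, idx, A, z1, z2)))
    if (anyNA(theta)) {
      status <- "jackknife_undefined"
    } else {
      se_rg <- jk_se(theta)
    }
    jackknife <- mode
  }
  structure(list(h2_trait1 = h2_1, h2_trait2 = h2_2,
                 genetic_covariance = covg, rg = rg, se_rg = se_rg,
                 n_used = n, status = status, clipped = clipped,
                 jackknife = jackknife), class = "hefit")
}

#' @export
print.hefit <- function(x, ...) {
  cat(sprintf("Haseman-Elston bivariate fit (n = %d, %s jackknife)\n",
              x$n_used, x$jackknife))
  cat(sprintf("  h2: %.4f / %.4f, genetic covariance %.4f\n",
              x$h2_trait1, x$h2_trait2, x$genetic_covariance))
  cat(sprintf("  rg = %.4f (SE %.4f)%s [%s]\n", x$rg, x$se_rg,
              if (x$clipped) " [clipped]" else "", x$status))
  invisible(x)
}

# Leave-out estimates for delete-1 or delete-block resampling.
jk_estimates <- function(mode, n, n_blocks, leave_out_fn) {
  if (mode == "delete1") {
    vapply(seq_len(n), function(i) leave_out_fn(i), numeric(1))
  } else {
    blocks <- split(seq_len(n), rep_len(seq_len(min(n_blocks, n)), n))
    vapply(blocks, leave_out_fn, numeric(1))
  }
}

jk_se <- function(theta) {
  g <- length(theta)
  sqrt((g - 1) / g * sum((theta - mean(theta))^2))
}

#' Jackknife standard error of an arbitrary estimator
#'
#' Delete-1 (exact, for n up to `max_exact_n`) or delete-block jackknife:
#' `SE^2 = ((g-1)/g) * sum_b (theta_(b) - mean(theta))^2` over the g
#' leave-out estimates.
#'
#' @param estimator Function taking a vector of retained indices and
#'   returning a scalar estimate.
#' @param n Sample size.
#' @param max_exact_n Above this n the delete-block mode is used.
#' @param n_blocks Number of blocks in delete-block mode.
#' @return List: `se`, `mode` (`"delete1"` or `"block"`), `estimates`
#'   (the leave-out values).
#' @export
jackknife_se <- function(estimator, n, max_exact_n = 2000L,
                         n_blocks = 100L) {
  n <- check_count(n, "n", min = 3L)
  mode <- if (n <= max_exact_n) "delete1" else "block"
  theta <- if (mode == "delete1") {
    vapply(seq_len(n), function(i) estimator(setdiff(seq_len(n), i)),
           numeric(1))
  } else {
    blocks <- split(seq_len(n), rep_len(seq_len(n_blocks), n))
    vapply(blocks, function(b) estimator(setdiff(seq_len(n), b)),
           numeric(1))
  }
  list(se = jk_se(theta), mode = mode, estimates = theta)
}
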
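#' Relationship matrix constructor
#'
#' Lightweight container shared by the genomic (G), environmental (E) and
#' interaction (GxE) similarity matrices: a symmetric value matrix, the
#' sample ids in matrix order, a kind tag, and (for GRMs) the per-pair
#' count of markers entering each average.
#'
#' @param values n x n symmetric numeric matrix.
#' @param sample_ids Character vector of unique ids, length n.
#' @param kind One of `"G"`, `"E"`, `"GxE"`.
#' @param pair_counts Optional n x n matrix of per-pair marker counts.
#' @return Object of class `relmat`.
#' @export
relmat <- function(values, sample_ids, kind = c("G", "E", "GxE"),
                   pair_counts = NULL) {
  kind <- match.arg(kind)
  check_symmetric(values, "values")
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match matrix dimension", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique", call. = FALSE)
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 kind = kind, pair_counts = pair_counts),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  n <- nrow(x$values)
  od <- x$values[upper.tri(x$values)]
  cat(sprintf("%s relationship matrix: %d x %d\n", x$kind, n, n))
  cat(sprintf("  diagonal mean %.4f; off-diagonal mean %.2e, range [%.3f, %.3f]\n",
              mean(diag(x$values)), mean(od), min(od), max(od)))
  invisible(x)
}

#' Genomic relationship matrix (GRM) from genotype counts
#'
#' The standard GREML estimator: for individuals j, k and SNP i with
#' counted-allele frequency `p_i`,
#' `A_jk = mean_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`,
#' averaged over the SNPs non-missing in both individuals
#' (pairwise-complete, with the per-pair divisor recorded in
#' `pair_counts`). Allele frequencies are estimated in-sample.
#'
#' @param genotypes A `genotypes` object (see [simulate_genotypes()]) or a
#'   plain n x m matrix of 0/1/2 counts (NA = missing) with row/column
#'   names as ids.
#' @return A [relmat()] of kind `"G"`.
#' @export
compute_grm <- function(genotypes) {
  if (inherits(genotypes, "genotypes")) {
    counts <- genotypes$counts
    sample_ids <- genotypes$sample_ids
    snp_ids <- genotypes$snp_ids
  } else {
    counts <- as.matrix(genotypes)
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- sprintf("id%d", seq_len(nrow(counts)))
    snp_ids <- colnames(counts)
    if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(ncol(counts)))
  }
  storage.mode(counts) <- "double"
  p <- colMeans(counts, na.rm = TRUE) / 2
  mono <- which(p <= 0 | p >= 1 | !is.finite(p))
  if (length(mono))
    stop("monomorphic (or all-missing) SNP(s) cannot be standardized: ",
         paste(utils::head(snp_ids[mono], 5), collapse = ", "),
         if (length(mono) > 5) ", ..." else "", call. = FALSE)

  Z <- sweep(counts, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  miss <- is.na(Z)
  if (any(miss)) {
    Z[miss] <- 0
    obs <- 1 - miss
    storage.mode(obs) <- "double"
    pair_n <- tcrossprod(obs)
    zero <- pair_n == 0
    if (any(zero)) {
      bad <- which(zero, arr.ind = TRUE)[1, ]
      stop(sprintf("pair (%s, %s) shares no non-missing SNP",
                   sample_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
    }
  } else {
    pair_n <- matrix(ncol(counts), nrow(counts), nrow(counts))
  }
  values <- tcrossprod(Z) / pair_n
  values <- (values + t(values)) / 2
  relmat(values, sample_ids, kind = "G", pair_counts = pair_n)
}

#' Environmental relationship matrix (ERM) from exposure principal
#' components
#'
#' Each PC column is standardized to mean 0 and unit mean square, and
#' the similarity is the cross-product averaged over the k components:
#' `E_jk = mean_c z_cj z_ck`. This is the standardized-variable analogue
#' of the GRM; the diagonal mean is exactly 1.
#'
#' @param pcs A `trauma_pcs` object (see [compute_trauma_pcs()]) or a
#'   plain n x k score matrix with row names as ids.
#' @return A [relmat()] of kind `"E"`.
#' @export
compute_erm <- function(pcs) {
  scores <- if (inherits(pcs, "trauma_pcs")) pcs$scores else as.matrix(pcs)
  if (ncol(scores) < 1) stop("need at least one PC column", call. = FALSE)
  if (anyNA(scores)) stop("missing PC scores are not supported", call. = FALSE)
  ids <- rownames(scores)
  if (is.null(ids)) ids <- sprintf("id%d", seq_len(nrow(scores)))
  # population-style standardization (divide by sqrt(mean square)) so the
  # diagonal mean is exactly 1
  Zc <- sweep(scores, 2, colMeans(scores))
  ms <- sqrt(colMeans(Zc^2))
  if (any(ms == 0))
    stop("zero-variance PC column(s): ",
         paste(which(ms == 0), collapse = ", "), call. = FALSE)
  Zs <- sweep(Zc, 2, ms, `/`)
  values <- tcrossprod(Zs) / ncol(Zs)
  values <- (values + t(values)) / 2
  relmat(values, ids, kind = "E")
}

#' Hadamard (cell-by-cell) product of two relationship matrices
#'
#' The covariance kernel of genome-by-environment interaction effects.
#' By the Schur product theorem the product of two PSD kernels is PSD
#' (up to floating-point error).
#'
#' @param g,e Two [relmat()] objects with identical id ordering.
#' @return A [relmat()] of kind `"GxE"`.
#' @export
hadamard <- function(g, e) {
  stopifnot(inherits(g, "relmat"), inherits(e, "relmat"))
  if (!identical(g$sample_ids, e$sample_ids)) {
    bad <- which(g$sample_ids != e$sample_ids)[1]
    stop(sprintf("id ordering differs (first mismatch at position %d: '%s' vs '%s')",
                 bad, g$sample_ids[bad], e$sample_ids[bad]), call. = FALSE)
  }
  relmat(g$values * e$values, g$sample_ids, kind = "GxE")
}

#' Select a subset with all pairwise relatedness below a threshold
#'
#' Greedy max-degree removal: repeatedly drop the individual involved in
#' the most off-diagonal entries at or above the threshold (ties broken by
#' id order) until none remain. The returned set is verified post hoc:
#' every retained off-diagonal is strictly below the threshold.
#'
#' @param grm A [relmat()].
#' @param threshold Relatedness cutoff (e.g. 0.05); pairs at or above it
#'   are considered related.
#' @return Character vector of retained sample ids (possibly empty).
#' @export
filter_unrelated <- function(grm, threshold = 0.05) {
  stopifnot(inherits(grm, "relmat"), threshold > 0)
  A <- grm$values
  diag(A) <- 0
  related <- A >= threshold
  keep <- rep(TRUE, nrow(A))
  repeat {
    deg <- rowSums(related[keep, keep, drop = FALSE])
    if (!length(deg) || max(deg) == 0) break
    drop_local <- which.max(deg)  # which.max takes the first = id order
    keep[which(keep)[drop_local]] <- FALSE
  }
  ids <- grm$sample_ids[keep]
  sub <- A[keep, keep, drop = FALSE]
  stopifnot(all(sub[upper.tri(sub)] < threshold))
  ids
}

#' Principal components of a genomic relationship matrix
#'
#' Top-k eigenvectors of the double-centered GRM, ordered by descending
#' eigenvalue, used as ancestry covariates in the mixed models. The sign
#' of each eigenvector is fixed so its largest-magnitude loading is
#' positive, making output deterministic across linear-algebra backends.
#'
#' @param grm A [relmat()].
#' @param k Number of components.
#' @return List with `scores` (n x k, ids as row names) and `values`
#'   (the k eigenvalues, non-increasing).
#' @export
grm_pcs <- function(grm, k = 15L) {
  stopifnot(inherits(grm, "relmat"))
  n <- nrow(grm$values)
  k <- check_count(k, "k")
  if (k > n) stop("k exceeds the sample size", call. = FALSE)
  A <- grm$values
  A <- sweep(A, 1, rowMeans(A))
  A <- sweep(A, 2, colMeans(A))
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  vec <- fix_signs(vec)
  rownames(vec) <- grm$sample_ids
  colnames(vec) <- sprintf("PC%d", seq_len(k))
  list(scores = vec, values = eg$values[seq_len(k)])
}

# Deterministic eigenvector sign convention: largest-|loading| entry
# positive (first such entry on ties).
fix_signs <- function(vectors) {
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vectors
}

#' Remove the genetic component from exposure principal components
#'
#' For each PC, fits the single-kernel mixed model with the PC as outcome
#' and the GRM as random-effect covariance (plus optional fixed
#' covariates), and returns the residual
#' `observed - fixed-effect fit - BLUP of the genetic value`. In
#' mixed-model practice this is what "regressing a trait on G" means:
#' the genetic random effect, not a column regression, is removed.
#'
#' @param pcs A `trauma_pcs` object or plain score matrix.
#' @param grm A [relmat()] aligned to the same samples.
#' @param covariates Optional numeric matrix/data.frame of fixed
#'   covariates (an intercept is always included).
#' @param ... Passed to [fit_reml()].
#' @return The input with scores replaced by residualized scores (class
#'   preserved for `trauma_pcs` input).
#' @export
precorrect_pcs <- function(pcs, grm, covariates = NULL, ...) {
  stopifnot(inherits(grm, "relmat"))
  is_tp <- inherits(pcs, "trauma_pcs")
  scores <- if (is_tp) pcs$scores else as.matrix(pcs)
  if (!is.null(rownames(scores)) &&
      !identical(rownames(scores), grm$sample_ids))
    stop("PC score ids do not match GRM ids", call. = FALSE)
  n <- nrow(scores)
  X <- build_design(n, covariates)
  out <- scores
  for (j in seq_len(ncol(scores))) {
    fit <- tryCatch(
      fit_reml(scores[, j], X, list(G = grm$values), ...),
      error = function(e) stop(sprintf("REML failed for PC %d: %s", j,
                                       conditionMessage(e)), call. = FALSE))
    out[, j] <- reml_residuals(fit)
  }
  if (is_tp) {
    pcs$scores <- out
    pcs$precorrected <- TRUE
    pcs
  } else out
}

# Intercept + optional covariates as a full-rank design matrix.
build_design <- function(n, covariates = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}
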
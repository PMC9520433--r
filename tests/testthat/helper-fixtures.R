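# Small fixtures built in code. Sizes are kept desk-scale; anything
# statistically demanding lives in test-acceptance.R.

# Plain genotype count matrix with ids, wrapped as a genotypes object.
make_genotypes <- function(counts, ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  n <- nrow(counts); m <- ncol(counts)
  structure(list(counts = counts,
                 sample_ids = ids %||% sprintf("id%d", seq_len(n)),
                 snp_ids = sprintf("snp%d", seq_len(m)),
                 allele_freqs = colMeans(counts, na.rm = TRUE) / 2,
                 sib_pairs = matrix(integer(0), 0, 2)),
            class = "genotypes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force GRM: the O(n^2 m) double loop the fast path must equal.
grm_oracle <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts); m <- ncol(counts)
  p <- colMeans(counts, na.rm = TRUE) / 2
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (i in seq_len(m)) {
      xj <- counts[j, i]; xk <- counts[k, i]
      if (!is.na(xj) && !is.na(xk)) {
        acc <- acc + (xj - 2 * p[i]) * (xk - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
        cnt <- cnt + 1
      }
    }
    A[j, k] <- acc / cnt
  }
  A
}

# Brute-force ERM on standardized (population-sd) PC scores.
erm_oracle <- function(scores) {
  Z <- apply(scores, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  n <- nrow(Z); k <- ncol(Z)
  E <- matrix(0, n, n)
  for (j in seq_len(n)) for (l in seq_len(n))
    E[j, l] <- sum(Z[j, ] * Z[l, ]) / k
  E
}

# Restricted log-likelihood evaluated directly from its definition
# (dense solves, no reuse) -- the independent oracle for AI-REML.
reml_loglik_oracle <- function(sigma2, y, X, kernels) {
  n <- length(y); p <- ncol(X)
  V <- diag(sigma2[length(sigma2)], n)
  for (i in seq_along(kernels)) V <- V + sigma2[i] * kernels[[i]]
  ld <- determinant(V, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  Vi <- solve(V)
  S <- t(X) %*% Vi %*% X
  lds <- determinant(S, logarithm = TRUE)
  if (lds$sign <= 0) return(-Inf)
  P <- Vi - Vi %*% X %*% solve(S) %*% t(X) %*% Vi
  -0.5 * ((n - p) * log(2 * pi) + as.numeric(ld$modulus) +
            as.numeric(lds$modulus) + drop(t(y) %*% P %*% y))
}

# Haseman-Elston slope by explicit pair enumeration (with intercept).
he_slope_oracle <- function(y1, y2, A) {
  n <- length(y1)
  xs <- ys <- numeric(0)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    xs <- c(xs, A[j, k])
    ys <- c(ys, (y1[j] * y2[k] + y1[k] * y2[j]) / 2)
  }
  unname(stats::coef(stats::lm(ys ~ xs))[2])
}

# A small well-conditioned random PSD kernel with unit-ish diagonal.
random_kernel <- function(n, rank = n, seed = 1) {
  set.seed(seed)
  B <- matrix(rnorm(n * rank), n, rank)
  K <- tcrossprod(B) / rank
  (K + t(K)) / 2
}
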
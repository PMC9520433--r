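# Multi-kernel REML: V = sum_i sigma2_i K_i + sigma2_resid I, maximized
# over the restricted likelihood with EM warm-up iterations followed by
# average-information (AI) updates, zero-boundary clamping, and standard
# errors from the inverse AI matrix at the optimum. Per-iteration cost is
# one n x n Cholesky inversion; traces tr(P K) use the identity
# tr(Vinv K) = sum(Vinv * K) so no further O(n^3) products are needed.

#' Fit a variance-component mixed model by AI-REML
#'
#' Maximizes the restricted log-likelihood of
#' `y ~ N(X beta, sum_i sigma2_i K_i + sigma2_resid I)` over the
#' non-negative variance components. The first `n_em` iterations are
#' expectation-maximization updates (robust to poor starting values),
#' after which average-information (quasi-Newton) updates with
#' step-halving take over. Components driven negative are clamped at the
#' zero boundary and the update re-solved over the free components; a
#' clamped component whose gradient turns positive is released.
#'
#' @param y Numeric outcome vector (no missing values).
#' @param X Fixed-effect design matrix (full column rank; an intercept
#'   column is NOT added automatically).
#' @param kernels Named list of n x n symmetric covariance kernels. The
#'   residual identity kernel is implicit and always included.
#' @param max_iter Maximum iterations (default 200).
#' @param tol_loglik Relative log-likelihood change declaring convergence.
#' @param tol_par Maximum relative parameter change (relative to the
#'   phenotypic variance) declaring convergence.
#' @param n_em Number of EM warm-up iterations.
#' @param start Optional numeric vector of starting values, length
#'   `length(kernels) + 1` (residual last); default: equal split of the
#'   sample variance of `y`.
#' @param se Compute standard errors (inverse AI at the optimum).
#' @return Object of class `vcfit`: `sigma2` (named; residual last),
#'   `se`, `proportions` and `prop_se` (delta method), `loglik`
#'   (restricted, at the optimum), `beta` (GLS fixed effects), `n_iter`,
#'   `converged`, `ai_cov` (sampling covariance of `sigma2`), `Py`
#'   (projected data, for BLUP residuals), `boundary` (logical, clamped
#'   components), `n`, `trajectory` (per-iteration log-likelihoods).
#' @export
fit_reml <- function(y, X, kernels, max_iter = 200L, tol_loglik = 1e-8,
                     tol_par = 1e-6, n_em = 3L, start = NULL, se = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing values in y", call. = FALSE)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X rows do not match length(y)", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("X is not of full column rank", call. = FALSE)
  if (!length(kernels) || is.null(names(kernels)) ||
      any(!nzchar(names(kernels))))
    stop("kernels must be a non-empty named list", call. = FALSE)
  kernels <- lapply(kernels, function(K) {
    K <- if (inherits(K, "relmat")) K$values else as.matrix(K)
    check_symmetric(K, "kernel", tol = 1e-8)
    if (nrow(K) != n) stop("kernel dimension does not match y", call. = FALSE)
    K
  })
  c_k <- length(kernels)
  if (n <= ncol(X))
    stop("sample too small for the requested model", call. = FALSE)

  varP <- stats::var(y)
  sigma2 <- if (is.null(start)) rep(varP / (c_k + 1), c_k + 1)
            else {
              stopifnot(length(start) == c_k + 1)
              pmax(as.numeric(start), 0)
            }
  floor_res <- 1e-8 * varP

  # One likelihood evaluation: returns loglik pieces reused by the update.
  eval_state <- function(sig) {
    V <- diag(max(sig[c_k + 1], floor_res), n)
    for (i in seq_len(c_k)) if (sig[i] != 0) V <- V + sig[i] * kernels[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    A <- Vinv %*% X
    S <- crossprod(X, A)
    chS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(chS)) return(NULL)
    Sinv <- chol2inv(chS)
    Vy <- Vinv %*% y
    XtVy <- crossprod(X, Vy)
    beta <- drop(Sinv %*% XtVy)
    Py <- drop(Vy - A %*% (Sinv %*% XtVy))
    yPy <- sum(y * Py)
    ll <- -0.5 * ((n - ncol(X)) * log(2 * pi) +
                    2 * sum(log(diag(ch))) + 2 * sum(log(diag(chS))) + yPy)
    list(Vinv = Vinv, A = A, Sinv = Sinv, Py = Py, beta = beta, loglik = ll)
  }

  st <- eval_state(sigma2)
  if (is.null(st)) stop("initial V not positive definite", call. = FALSE)
  trajectory <- st$loglik
  boundary <- rep(FALSE, c_k + 1)
  converged <- FALSE
  iter <- 0L
  AI <- NULL

  for (iter in seq_len(max_iter)) {
    Vinv <- st$Vinv; A <- st$A; Sinv <- st$Sinv; Py <- st$Py

    # gradients and the AI matrix (all O(n^2) given Vinv)
    W <- matrix(0, n, c_k + 1)
    trPK <- q <- numeric(c_k + 1)
    for (i in seq_len(c_k)) {
      Ki <- kernels[[i]]
      trPK[i] <- sum(Vinv * Ki) - sum(Sinv * (crossprod(A, Ki %*% A)))
      W[, i] <- Ki %*% Py
    }
    trPK[c_k + 1] <- sum(diag(Vinv)) - sum(Sinv * crossprod(A))
    W[, c_k + 1] <- Py
    q <- drop(crossprod(W, Py))
    score <- -0.5 * (trPK - q)

    VW <- Vinv %*% W
    U <- VW - A %*% (Sinv %*% crossprod(X, VW))
    AI <- 0.5 * crossprod(W, U)

    # active set: clamped components stay unless their gradient is positive
    boundary <- boundary & (score <= 0)
    free <- which(!boundary)

    if (iter <= n_em) {
      prop <- sigma2 + sigma2^2 * (q - trPK) / n
    } else {
      prop <- sigma2
      delta <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                        error = function(e) NULL)
      if (is.null(delta)) delta <- score[free] / pmax(diag(AI)[free], 1e-12)
      prop[free] <- sigma2[free] + delta
    }
    prop[boundary] <- 0

    # step-halving toward the current point on failure or loglik decrease
    accepted <- FALSE
    for (half in 0:10) {
      cand <- sigma2 + (prop - sigma2) / 2^half
      cand[cand < 0] <- 0
      cand[c_k + 1] <- max(cand[c_k + 1], floor_res)
      st_new <- eval_state(cand)
      if (!is.null(st_new) && st_new$loglik >= st$loglik - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { # cannot improve: treat as converged at current point
      converged <- TRUE
      break
    }
    boundary <- cand == 0
    boundary[c_k + 1] <- FALSE
    d_ll <- st_new$loglik - st$loglik
    d_par <- max(abs(cand - sigma2)) / varP
    sigma2 <- cand
    st <- st_new
    trajectory <- c(trajectory, st$loglik)
    if (iter > n_em &&
        abs(d_ll) < tol_loglik * max(1, abs(st$loglik)) &&
        d_par < tol_par) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop(sprintf(paste0("AI-REML did not converge in %d iterations ",
                        "(last loglik %.6f; trajectory range [%.6f, %.6f])"),
                 max_iter, st$loglik, min(trajectory), max(trajectory)),
         call. = FALSE)

  # final AI and SEs at the optimum
  Vinv <- st$Vinv; A <- st$A; Sinv <- st$Sinv; Py <- st$Py
  W <- matrix(0, n, c_k + 1)
  for (i in seq_len(c_k)) W[, i] <- kernels[[i]] %*% Py
  W[, c_k + 1] <- Py
  VW <- Vinv %*% W
  U <- VW - A %*% (Sinv %*% crossprod(X, VW))
  AI <- 0.5 * crossprod(W, U)
  ai_cov <- se_vec <- NULL
  if (se) {
    ai_cov <- tryCatch(solve(AI), error = function(e)
      matrix(NA_real_, c_k + 1, c_k + 1))
    se_vec <- sqrt(pmax(diag(ai_cov), 0))
  }

  comp_names <- c(names(kernels), "residual")
  names(sigma2) <- comp_names
  total <- sum(sigma2)
  props <- sigma2 / total
  prop_se <- rep(NA_real_, c_k + 1)
  if (se && all(is.finite(ai_cov))) {
    for (i in seq_along(sigma2)) {
      grad <- -sigma2[i] / total^2
      g <- rep(grad, c_k + 1)
      g[i] <- g[i] + 1 / total
      prop_se[i] <- sqrt(max(0, drop(t(g) %*% ai_cov %*% g)))
    }
  }
  if (se) names(se_vec) <- comp_names
  names(props) <- names(prop_se) <- comp_names
  if (!is.null(ai_cov)) dimnames(ai_cov) <- list(comp_names, comp_names)

  structure(list(sigma2 = sigma2, se = se_vec, proportions = props,
                 prop_se = prop_se, loglik = st$loglik, beta = st$beta,
                 n_iter = iter, converged = converged, ai_cov = ai_cov,
                 Py = st$Py, boundary = boundary, n = n, X = X,
                 kernel_names = names(kernels), trajectory = trajectory),
            class = "vcfit")
}

#' @export
print.vcfit <- function(x, ...) {
  cat(sprintf("AI-REML fit: n = %d, %d iterations, logL = %.4f\n",
              x$n, x$n_iter, x$loglik))
  tab <- data.frame(component = names(x$sigma2),
                    sigma2 = round(x$sigma2, 5),
                    se = round(x$se %||% NA_real_, 5),
                    proportion = round(x$proportions, 4),
                    prop_se = round(x$prop_se, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

# Residuals after removing fixed effects and the BLUPs of all modelled
# random effects. Identity: y - X beta - sum_i sigma2_i K_i P y equals
# sigma2_resid * P y.
reml_residuals <- function(fit) {
  stopifnot(inherits(fit, "vcfit"))
  fit$sigma2[["residual"]] * fit$Py
}

#' Likelihood-ratio test between nested variance-component fits
#'
#' Because variance components are tested on the boundary of the
#' parameter space, the null reference for one extra component is a
#' 50:50 mixture of a point mass at zero and chi-square(1); for d extra
#' components the binomial mixture `sum_j C(d,j) 2^-d chi2(j)` is used.
#'
#' @param fit_full,fit_reduced Two [fit_reml()] fits on the same data;
#'   the reduced fit's kernel set must be a strict subset of the full
#'   fit's.
#' @return List of class `lrt_result`: `statistic` (clipped at 0), `df`
#'   (number of constrained components), `p_value`.
#' @export
lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "vcfit"), inherits(fit_reduced, "vcfit"))
  if (fit_full$n != fit_reduced$n)
    stop("fits are on different sample sizes", call. = FALSE)
  kf <- fit_full$kernel_names
  kr <- fit_reduced$kernel_names
  if (!all(kr %in% kf) || length(kr) >= length(kf))
    stop("models are not strictly nested (reduced kernels must be a ",
         "proper subset of the full kernels)", call. = FALSE)
  df <- length(kf) - length(kr)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  if (stat == 0) {
    p <- 1
  } else {
    weights <- stats::dbinom(0:df, df, 0.5)
    tails <- c(0, vapply(seq_len(df), function(j)
      stats::pchisq(stat, j, lower.tail = FALSE), numeric(1)))
    p <- sum(weights * tails)
  }
  structure(list(statistic = stat, df = df, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT (boundary mixture): statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Convert an observed-scale variance proportion to the liability scale
#'
#' The liability-threshold transformation with ascertainment correction:
#' `h2_lia = h2_obs * K^2 (1-K)^2 / (z^2 P (1-P))`, where K is the
#' population prevalence, P the case proportion in the analyzed sample,
#' and z the standard normal density at the (1-K) quantile. With P = K
#' (the default, matching a population sample) this reduces to
#' `h2_obs * K (1-K) / z^2`.
#'
#' @param h2_obs Observed-scale (0/1) variance proportion, >= 0.
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion in (0, 1); defaults to `K`.
#' @return Liability-scale proportion.
#' @export
observed_to_liability <- function(h2_obs, K, P = K) {
  if (any(h2_obs < 0)) stop("h2_obs must be >= 0", call. = FALSE)
  check_proportion(K, "K", open_left = TRUE, open_right = TRUE)
  check_proportion(P, "P", open_left = TRUE, open_right = TRUE)
  z <- stats::dnorm(stats::qnorm(1 - K))
  h2_obs * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}

#' Variance proportions of a converged fit
#'
#' Each component's share of the total variance, with first-order
#' delta-method standard errors from the AI sampling covariance. When a
#' prevalence is supplied, liability-scale proportions are appended for
#' every non-residual component.
#'
#' @param fit A converged [fit_reml()].
#' @param prevalence Optional population prevalence K for a binary
#'   outcome analyzed on the 0/1 scale.
#' @param case_prop Optional sample case proportion P; defaults to `K`.
#' @return Data frame: component, sigma2, se, proportion, prop_se and
#'   (when `prevalence` is set) liability, liability_se.
#' @export
variance_proportions <- function(fit, prevalence = NULL, case_prop = NULL) {
  stopifnot(inherits(fit, "vcfit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (sum(fit$sigma2) <= 0) stop("zero total variance", call. = FALSE)
  out <- data.frame(component = names(fit$sigma2),
                    sigma2 = unname(fit$sigma2),
                    se = unname(fit$se %||% rep(NA_real_, length(fit$sigma2))),
                    proportion = unname(fit$proportions),
                    prop_se = unname(fit$prop_se))
  if (!is.null(prevalence)) {
    P <- case_prop %||% prevalence
    fac <- observed_to_liability(1, prevalence, P)
    is_res <- out$component == "residual"
    out$liability <- ifelse(is_res, NA_real_, out$proportion * fac)
    out$liability_se <- ifelse(is_res, NA_real_, out$prop_se * fac)
  }
  out
}

#' Fit one of the four standard interaction models
#'
#' Model 1 uses kernel set {G}; model 2 {E}; model 3 {G, E}; model 4
#' {G, E, GxE} — the GxE kernel is formed as the Hadamard product of G
#' and E when not supplied.
#'
#' @param y Outcome vector.
#' @param covariates Optional covariate matrix/data.frame (intercept
#'   added; rank-deficient columns dropped).
#' @param G,E [relmat()] objects (E required for models 2-4).
#' @param model Integer 1-4.
#' @param ... Passed to [fit_reml()].
#' @return A `vcfit` (kernel names G/E/GxE as appropriate).
#' @export
fit_mlm <- function(y, covariates = NULL, G = NULL, E = NULL, model = 4L,
                    ...) {
  model <- check_count(model, "model")
  if (!model %in% 1:4) stop("model must be 1, 2, 3 or 4", call. = FALSE)
  kernels <- switch(model,
    `1` = list(G = G),
    `2` = list(E = E),
    `3` = list(G = G, E = E),
    `4` = list(G = G, E = E, GxE = hadamard(G, E)))
  if (any(vapply(kernels, is.null, logical(1))))
    stop("model ", model, " needs kernels: ",
         paste(names(kernels), collapse = ", "), call. = FALSE)
  X <- build_design(length(y), covariates)
  fit_reml(y, X, kernels, ...)
}
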
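#' Inverse-variance meta-analysis of per-stratum estimates
#'
#' Pools k independent estimates with standard errors by inverse-variance
#' weighting. `"fixed"` uses weights `1/se^2`. `"random_DL"` adds the
#' DerSimonian-Laird moment estimate of between-study variance,
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and
#' reweights by `1/(se^2 + tau2)`. `"random_REML"` estimates `tau2` by
#' maximizing the restricted likelihood of the random-effects model
#' (scalar optimization). Heterogeneity is summarized by Cochran's Q and
#' `I2 = max(0, (Q - (k-1))/Q)`.
#'
#' @param estimates Numeric vector of per-stratum estimates.
#' @param ses Matching standard errors, all > 0.
#' @param method `"fixed"`, `"random_DL"` or `"random_REML"`.
#' @return Object of class `meta_result`: `estimate`, `se`, `ci_lower`,
#'   `ci_upper` (normal 95%), `Q`, `tau2`, `I2`, `method`, `k_studies`,
#'   `weights` (normalized).
#' @export
meta_pool <- function(estimates, ses,
                      method = c("random_REML", "fixed", "random_DL")) {
  method <- match.arg(method)
  if (length(estimates) != length(ses))
    stop("estimates and ses differ in length", call. = FALSE)
  k <- length(estimates)
  if (k < 2) stop("need at least 2 strata to pool", call. = FALSE)
  if (!all(is.finite(estimates)) || !all(is.finite(ses)))
    stop("non-finite estimate or SE", call. = FALSE)
  if (any(ses <= 0)) stop("all SEs must be > 0", call. = FALSE)

  w_fixed <- 1 / ses^2
  mu_fixed <- sum(w_fixed * estimates) / sum(w_fixed)
  Q <- sum(w_fixed * (estimates - mu_fixed)^2)

  tau2 <- 0
  if (method == "random_DL") {
    denom <- sum(w_fixed) - sum(w_fixed^2) / sum(w_fixed)
    tau2 <- max(0, (Q - (k - 1)) / denom)
  } else if (method == "random_REML") {
    nll <- function(t2) {
      w <- 1 / (ses^2 + t2)
      mu <- sum(w * estimates) / sum(w)
      0.5 * (sum(log(ses^2 + t2)) + log(sum(w)) +
               sum(w * (estimates - mu)^2))
    }
    upper <- max(stats::var(estimates), max(ses^2)) * 10 + 1e-12
    opt <- stats::optimize(nll, c(0, upper), tol = 1e-12)
    tau2 <- if (nll(0) <= opt$objective) 0 else opt$minimum
  }
  w <- 1 / (ses^2 + tau2)
  mu <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(estimate = mu, se = se,
                 ci_lower = mu - stats::qnorm(0.975) * se,
                 ci_upper = mu + stats::qnorm(0.975) * se,
                 Q = Q, tau2 = tau2, I2 = I2, method = method,
                 k_studies = k, weights = w / sum(w)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis (%s, k = %d): %.4f (SE %.4f, 95%% CI %.4f-%.4f)\n",
              x$method, x$k_studies, x$estimate, x$se, x$ci_lower,
              x$ci_upper))
  cat(sprintf("  Q = %.3f, tau2 = %.5f, I2 = %.1f%%\n", x$Q, x$tau2,
              100 * x$I2))
  invisible(x)
}

#' Pool a tidy per-stratum estimate table
#'
#' Groups a long table of per-stratum estimates by component (and any
#' additional keys) and pools each group with [meta_pool()], returning a
#' forest-plot-ready table: every input stratum row followed by the
#' pooled row per group.
#'
#' @param table Data frame with at least `stratum`, `component`,
#'   `estimate`, `se` columns.
#' @param method Pooling method passed to [meta_pool()] (no default in
#'   pipeline output contexts; state it explicitly).
#' @param by Grouping columns (default `"component"`).
#' @return Data frame with the input rows (`row_type = "stratum"`) and
#'   one `row_type = "pooled"` row per group carrying Q, tau2, I2.
#' @export
meta_pool_table <- function(table, method, by = "component") {
  stopifnot(all(c("stratum", "estimate", "se", by) %in% names(table)))
  groups <- split(table, table[by], drop = TRUE)
  out <- lapply(groups, function(g) {
    g$row_type <- "stratum"
    g$Q <- g$tau2 <- g$I2 <- NA_real_
    pooled <- g[1, , drop = FALSE]
    pooled$stratum <- "pooled"
    pooled$row_type <- "pooled"
    m <- meta_pool(g$estimate, g$se, method = method)
    pooled$estimate <- m$estimate
    pooled$se <- m$se
    pooled$Q <- m$Q; pooled$tau2 <- m$tau2; pooled$I2 <- m$I2
    rbind(g, pooled)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
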
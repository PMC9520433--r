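test_that("all-identity kernels collapse to the iid sample variance", {
  # REML of an iid normal equals the unbiased (n-1) variance; extra
  # identity kernels may split the total but must preserve it
  y <- c(1, 2, 3)
  X <- matrix(1, 3, 1)
  f1 <- fit_reml(y, X, list(I = diag(3)), n_em = 10)
  expect_equal(sum(f1$sigma2), 1, tolerance = 1e-6)
  set.seed(30)
  y2 <- rnorm(40, mean = 2)
  X2 <- matrix(1, 40, 1)
  f2 <- fit_reml(y2, X2, list(I1 = diag(40), I2 = diag(40)))
  expect_equal(sum(f2$sigma2), var(y2), tolerance = 1e-6)
})

test_that("restricted likelihood is invariant to kernel ordering", {
  set.seed(31)
  n <- 80
  G <- random_kernel(n, rank = 200, seed = 31)
  E <- random_kernel(n, rank = 5, seed = 32)
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  f_ge <- fit_reml(y, X, list(G = G, E = E))
  f_eg <- fit_reml(y, X, list(E = E, G = G))
  expect_lt(abs(f_ge$loglik - f_eg$loglik), 1e-9)
  expect_equal(f_ge$sigma2[["G"]], f_eg$sigma2[["G"]], tolerance = 1e-5)
})

test_that("AI-REML optimum matches a derivative-free oracle at n = 60", {
  set.seed(33)
  n <- 60
  G <- random_kernel(n, rank = 150, seed = 33)
  E <- random_kernel(n, rank = 4, seed = 34)
  kernels <- list(G = G, E = E)
  X <- cbind(1, rnorm(n))
  for (rep in 1:3) {
    g <- drop(chol(G + 1e-8 * diag(n)) %*% rnorm(n)) * sqrt(0.4)
    y <- g + rnorm(n, sd = sqrt(0.6)) + 0.5 * X[, 2]
    fit <- fit_reml(y, X, kernels)
    # independent route: direct Nelder-Mead maximization of the
    # restricted likelihood evaluated from its definition
    nll <- function(par) -reml_loglik_oracle(exp(par), y, X, kernels)
    best <- Inf
    for (s in list(log(rep(var(y) / 3, 3)),
                   log(c(0.4, 0.1, 0.6)),
                   log(pmax(fit$sigma2, 1e-6)))) {
      o <- optim(s, nll, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_gte(fit$loglik + 1e-6, -best)
    expect_lt(abs(fit$loglik - (-best)), 1e-6)
  }
})

test_that("boundary components are clamped at zero without failing", {
  set.seed(35)
  n <- 120
  G <- random_kernel(n, rank = 300, seed = 35)
  y <- rnorm(n)  # no genetic signal at all
  X <- matrix(1, n, 1)
  f <- fit_reml(y, X, list(G = G))
  expect_true(f$converged)
  expect_gte(f$sigma2[["G"]], 0)
  expect_equal(sum(f$proportions), 1, tolerance = 1e-10)
})

test_that("input validation: rank-deficient X, bad kernels, tiny n", {
  y <- rnorm(20)
  X_bad <- cbind(1, 1)  # rank 1, duplicated columns
  expect_error(fit_reml(y, matrix(X_bad[rep(1, 20), ], 20, 2),
                        list(I = diag(20))), "full column rank")
  expect_error(fit_reml(y, matrix(1, 20, 1),
                        list(K = matrix(rnorm(400), 20, 20))),
               "not symmetric")
  expect_error(fit_reml(rnorm(4), diag(4),
                        list(A = diag(4), B = diag(4))), "too small")
})

test_that("LRT boundary convention: zero statistic, half-chi-square tail", {
  fake_fit <- function(loglik, kernel_names, n = 100) {
    structure(list(loglik = loglik, kernel_names = kernel_names, n = n),
              class = "vcfit")
  }
  t0 <- lrt(fake_fit(-50, c("G", "E")), fake_fit(-50, "G"))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # statistic 2.706 on one boundary component: p = 0.5 * P(chi2_1 > 2.706)
  t1 <- lrt(fake_fit(-50 + 2.706 / 2, c("G", "E")), fake_fit(-50, "G"))
  expect_equal(t1$p_value, 0.5 * pchisq(2.706, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(t1$p_value, 0.05, tolerance = 1e-3)
  # non-nested rejected
  expect_error(lrt(fake_fit(-49, c("G", "E")), fake_fit(-50, "GxE")),
               "nested")
  expect_error(lrt(fake_fit(-49, c("G")), fake_fit(-50, c("G", "E"))),
               "nested")
})

test_that("liability conversion closed forms", {
  # K = P = 0.5: z = dnorm(0) = 1/sqrt(2*pi), factor = pi/2
  expect_equal(observed_to_liability(0.1, 0.5), 0.1 * pi / 2,
               tolerance = 1e-10)
  expect_equal(observed_to_liability(0, 0.3, 0.4), 0)
  # K = P = 0.28, frozen from the normal quantile/density closed form:
  # z = dnorm(qnorm(0.72)) = 0.336623345; K(1-K)/z^2 = 1.779106988
  expect_equal(observed_to_liability(0.2, 0.28), 0.2 * 1.779106988,
               tolerance = 1e-8)
  expect_error(observed_to_liability(0.1, 0), "K")
  expect_error(observed_to_liability(0.1, 0.5, 1), "P")
  # monotone in |K - 0.5|, minimized at K = 0.5
  ks <- c(0.16, 0.20, 0.28, 0.5)
  fac <- observed_to_liability(1, 0.5)
  for (k in ks) expect_gte(observed_to_liability(1, k), fac - 1e-12)
  expect_true(all(diff(sapply(c(0.16, 0.20, 0.28),
                              function(k) observed_to_liability(1, k))) < 0))
})

test_that("variance proportions: equal split, normalization, liability", {
  set.seed(36)
  n <- 100
  f <- fit_reml(rnorm(n), matrix(1, n, 1),
                list(A = diag(n), B = diag(n)))
  vp <- variance_proportions(f)
  expect_equal(sum(vp$proportion), 1, tolerance = 1e-10)
  vpl <- variance_proportions(f, prevalence = 0.28)
  fac <- observed_to_liability(1, 0.28)
  expect_equal(vpl$liability[1], vpl$proportion[1] * fac)
  expect_true(is.na(vpl$liability[vpl$component == "residual"]))
})

test_that("delta-method proportion SEs agree with a parametric bootstrap", {
  set.seed(37)
  n <- 400
  G <- random_kernel(n, rank = 1000, seed = 37)
  X <- matrix(1, n, 1)
  cG <- chol(G + 1e-8 * diag(n))
  sim_y <- function() drop(crossprod(cG, rnorm(n))) * sqrt(0.4) +
    rnorm(n, sd = sqrt(0.6))
  fit <- fit_reml(sim_y(), X, list(G = G))
  boots <- replicate(150, {
    f <- fit_reml(sim_y(), X, list(G = G), se = FALSE)
    f$proportions[["G"]]
  })
  expect_lt(abs(fit$prop_se[["G"]] - sd(boots)) / sd(boots), 0.25)
})
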
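test_that("fit_linear solves the normal equations", {
  # exact interpolation: y = 2 z
  f0 <- fit_linear(cbind(z = 1:10), 2 * (1:10))
  expect_equal(unname(coef(f0)), c(0, 2), tolerance = 1e-10)
  expect_equal(f0$residual_sd, sqrt(1e-6 * var(2 * (1:10))))  # floored

  # hand-solved three-point fit
  f <- fit_linear(cbind(z = c(0, 1, 2)), c(1, 2, 2))
  expect_equal(unname(coef(f)), c(7 / 6, 1 / 2), tolerance = 1e-12)
  expect_equal(unname(predict(f, cbind(c(0, 1, 2)))),
               c(7 / 6, 5 / 3, 13 / 6), tolerance = 1e-12)

  # closed-form Gaussian likelihood and BIC with q = p + 2
  rss <- sum((c(1, 2, 2) - c(7 / 6, 5 / 3, 13 / 6))^2)
  s2 <- rss / 3
  ll <- -3 / 2 * (log(2 * pi * s2) + 1)
  expect_equal(f$log_likelihood, ll, tolerance = 1e-12)
  expect_equal(BIC(f), -2 * ll + 3 * log(3), tolerance = 1e-12)

  # unit weights change nothing
  fw <- fit_linear(cbind(z = c(0, 1, 2)), c(1, 2, 2), weights = rep(1, 3))
  expect_equal(coef(fw), coef(f), tolerance = 1e-12)
})

test_that("fit_linear rejects singular designs", {
  z <- rnorm(20)
  expect_error(fit_linear(cbind(z, 2 * z), rnorm(20)), "singular")
})

test_that("single-component EM reproduces ordinary least squares", {
  set.seed(2)
  Z <- matrix(rnorm(200 * 3), 200, 3)
  y <- drop(Z %*% c(1, -2, 0.5)) + rnorm(200)
  ols <- fit_linear(Z, y)
  em <- mixlm(Z, y, K = 1, n_starts = 1, seed = 1)
  expect_equal(unname(em$coefficients[1, ]), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(em$residual_sds[1], ols$residual_sd, tolerance = 1e-8)
})

test_that("EM recovers planted well-separated components", {
  d <- planted_mixture(2000, seed = 3)
  fit <- mixlm(d$Z, d$y, K = 2, n_starts = 5, seed = 4)
  slopes <- sort(fit$coefficients[, "z"])
  expect_equal(slopes, c(-2, 2), tolerance = 0.1, ignore_attr = TRUE)
  # sharp posteriors for nearly all subjects
  expect_gt(mean(apply(fit$posterior, 1, max) > 0.95), 0.9)
  # modal labels agree with truth up to permutation
  lab <- modal_assignment(fit)
  agree <- max(mean((lab == 1) == (d$lab == 1)),
               mean((lab == 2) == (d$lab == 1)))
  expect_gt(agree, 0.95)
  # nesting: two components fit at least as well as one
  one <- mixlm(d$Z, d$y, K = 1, n_starts = 1, seed = 1)
  expect_gte(fit$log_likelihood, one$log_likelihood - 1e-8)
  expect_lt(fit$bic, one$bic)
})

test_that("EM log-likelihood is monotone within a start", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(80:250, 1)
    Z <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n, drop(Z %*% c(1, -1)) * rbinom(n, 1, 0.5), 0.7)
    fit <- mixlm(Z, y, K = 2, n_starts = 2, max_iter = 200,
                 seed = 100 + i)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("frozen-responsibility M-step equals per-label OLS exactly", {
  d <- planted_mixture(400, seed = 5)
  tau <- cbind(d$lab, 1 - d$lab)
  m <- mixlm_mstep(d$Z, d$y, tau)
  for (k in 1:2) {
    idx <- if (k == 1) d$lab == 1 else d$lab == 0
    ols <- fit_linear(d$Z[idx, , drop = FALSE], d$y[idx])
    expect_equal(unname(m$coefficients[k, ]), unname(coef(ols)),
                 tolerance = 1e-12)
    expect_equal(m$residual_sds[k], ols$residual_sd, tolerance = 1e-12)
  }
  expect_equal(m$mixing_weights, c(mean(d$lab), 1 - mean(d$lab)),
               tolerance = 1e-12)
})

test_that("mixture BIC uses K(p+2)-1 free parameters", {
  d <- planted_mixture(500, seed = 6)
  fit <- mixlm(d$Z, d$y, K = 2, n_starts = 3, seed = 7)
  q <- 2 * (1 + 2) - 1  # p = 1
  expect_equal(attr(logLik(fit), "df"), q)
  expect_equal(fit$bic, -2 * fit$log_likelihood + q * log(fit$n),
               tolerance = 1e-10)
  expect_equal(BIC(fit), fit$bic, tolerance = 1e-10)
})

test_that("relative entropy follows the normalized-entropy formula", {
  expect_equal(relative_entropy(matrix(0.5, 4, 2)), 0)
  expect_equal(relative_entropy(rbind(c(1, 0), c(0, 1), c(1, 0))), 1)
  tau <- matrix(rep(c(0.9, 0.1), each = 6), 6, 2)
  expect_equal(relative_entropy(tau),
               1 - (-0.9 * log(0.9) - 0.1 * log(0.1)) / log(2),
               tolerance = 1e-10)
  # permutation invariance
  set.seed(8)
  t2 <- matrix(runif(30), 10, 3)
  t2 <- t2 / rowSums(t2)
  expect_equal(relative_entropy(t2), relative_entropy(t2[, c(2, 3, 1)]),
               tolerance = 1e-12)
  expect_error(relative_entropy(matrix(c(0.7, 0.7, 0.4, 0.2), 2, 2)),
               "sum to 1")
})

test_that("informative component is the one with largest mean |slope|", {
  sl <- clinical_slopes()
  expect_equal(informative_component(sl, warn = FALSE), 2L)
  expect_equal(mean(abs(sl["V", ])), 0.1943, tolerance = 1e-10)
  expect_equal(mean(abs(sl["I", ])), 0.0473, tolerance = 1e-10)
  # identical components: lowest index plus a near-tie warning
  expect_warning(idx <- informative_component(rbind(sl["V", ], sl["V", ])),
                 "near-tie")
  expect_equal(idx, 1L)
  # sign-flipped copy ties on absolute magnitude
  expect_warning(informative_component(rbind(sl["V", ], -sl["V", ])),
                 "near-tie")
})

test_that("modal assignment is argmax with informative tie-break", {
  tau <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(modal_assignment(tau), c(1L, 1L, 2L))
  expect_equal(modal_assignment(tau, informative = 2L), c(1L, 2L, 2L))
})

test_that("EM is scale-equivariant in the response", {
  # component labels are arbitrary, so align by slope before comparing
  d <- planted_mixture(500, seed = 9)
  f1 <- mixlm(d$Z, d$y, K = 2, n_starts = 3, seed = 10)
  f2 <- mixlm(d$Z, 10 * d$y, K = 2, n_starts = 3, seed = 10)
  o1 <- order(f1$coefficients[, "z"])
  o2 <- order(f2$coefficients[, "z"])
  expect_equal(f2$coefficients[o2, ], 10 * f1$coefficients[o1, ],
               tolerance = 1e-4)
  expect_equal(f2$residual_sds[o2], 10 * f1$residual_sds[o1],
               tolerance = 1e-4)
  # stopping points differ in the last iterations (the log-likelihood
  # scale shifts by n log c), so posteriors agree absolutely, not in ulps
  expect_lt(max(abs(f2$posterior[, o2] - f1$posterior[, o1])), 1e-4)
})

test_that("formula interface matches the matrix interface", {
  d <- planted_mixture(300, seed = 12)
  df <- data.frame(y = d$y, z = d$Z[, "z"])
  f1 <- mixlm(y ~ z, df, K = 2, n_starts = 3, seed = 13)
  f2 <- mixlm(d$Z, d$y, K = 2, n_starts = 3, seed = 13)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-10)
  expect_equal(unname(f1$coefficients), unname(f2$coefficients),
               tolerance = 1e-10)
  # predict on new data through the formula terms
  nd <- data.frame(z = c(-1, 0, 1))
  pr <- predict(f1, nd, component = f1$informative)
  expect_length(pr, 3)
})

test_that("simulate() draws from the fitted mixture", {
  d <- planted_mixture(500, seed = 14)
  fit <- mixlm(d$Z, d$y, K = 2, n_starts = 3, seed = 15)
  sims <- simulate(fit, nsim = 2, seed = 16)
  expect_equal(dim(sims), c(500, 2))
  # a refit on simulated data finds slopes of similar magnitude
  refit <- mixlm(d$Z, sims[[1]], K = 2, n_starts = 3, seed = 17)
  expect_equal(sort(abs(refit$coefficients[, "z"])), c(2, 2),
               tolerance = 0.25, ignore_attr = TRUE)
})
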
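test_that("ROC AUC handles the canonical cases", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1), ci = FALSE)$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), ci = FALSE)$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1), ci = FALSE)$auc, 0)
  # equal weights reduce to the unweighted statistic
  set.seed(1)
  s <- rnorm(100); y <- rbinom(100, 1, 0.5)
  expect_equal(roc_auc(s, y, weights = rep(3, 100), ci = FALSE)$auc,
               roc_auc(s, y, ci = FALSE)$auc, tolerance = 1e-12)
  expect_error(roc_auc(s, rep(1, 100), ci = FALSE), "class")
})

test_that("weighted and unweighted AUC agree with pair-count oracles", {
  set.seed(2)
  for (i in 1:30) {
    inst <- random_tied_instance(sample(10:80, 1))
    if (length(unique(inst$y)) < 2) next
    expect_equal(roc_auc(inst$score, inst$y, ci = FALSE)$auc,
                 oracle_auc(inst$score, inst$y), tolerance = 1e-12)
    expect_equal(roc_auc(inst$score, inst$y, weights = inst$w,
                         ci = FALSE)$auc,
                 oracle_auc(inst$score, inst$y, inst$w), tolerance = 1e-12)
  }
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- rnorm(150); y <- rbinom(150, 1, 0.4)
  ours <- roc_auc(s, y)
  ref <- pROC::roc(y, s, direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # DeLong variance agreement
  expect_equal(ours$se^2, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-10)
})

test_that("hand-computed weighted AUC on six subjects", {
  score <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.05)
  y <- c(0, 0, 1, 1, 0, 1)
  w <- c(2, 1, 1, 1, 1, 2)
  expect_equal(roc_auc(score, y, weights = w, ci = FALSE)$auc,
               oracle_auc(score, y, w), tolerance = 1e-12)
})

test_that("paired AUC test: identity, power, and reference agreement", {
  set.seed(4)
  y <- rbinom(300, 1, 0.5)
  s1 <- y + rnorm(300, 0, 0.7)
  expect_equal(auc_test_paired(s1, s1, y)$p_value, 1)
  s2 <- rnorm(300)
  strong <- auc_test_paired(y + rnorm(300, 0, 0.2), s2, y)
  expect_lt(strong$p_value, 0.001)
  skip_if_not_installed("pROC")
  ours <- auc_test_paired(s1, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s1, direction = "<", quiet = TRUE),
                        pROC::roc(y, s2, direction = "<", quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("Spearman rho and its oracle agree, ties included", {
  expect_equal(spearman_rho(1:5, c(3, 1, 2, 5, 4))$rho, 0.6,
               tolerance = 1e-12)
  expect_equal(spearman_rho(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_rho(1:6, -(1:6)^3)$rho, -1)
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), "constant")
  set.seed(5)
  for (i in 1:20) {
    inst <- random_tied_instance(sample(5:50, 1))
    expect_equal(spearman_rho(inst$score, inst$T_)$rho,
                 oracle_spearman(inst$score, inst$T_), tolerance = 1e-12)
  }
})

test_that("Spearman permutation test: identity and power", {
  set.seed(6)
  T_ <- rnorm(300)
  s1 <- T_ + rnorm(300, 0, 0.01)  # rank-preserving copy
  s2 <- rnorm(300)
  expect_equal(spearman_perm_test(s1, s1, T_, n_perm = 200,
                                  seed = 1)$p_value, 1)
  pw <- spearman_perm_test(s1, s2, T_, n_perm = 999, seed = 2)
  expect_lte(pw$p_value, 0.01)
  expect_error(spearman_perm_test(rep(1, 10), rnorm(10), rnorm(10),
                                  n_perm = 100), "constant")
  expect_error(spearman_perm_test(rnorm(10), rnorm(10), rnorm(10),
                                  n_perm = 10), "n_perm")
})

test_that("propensity weights recover known observation models", {
  set.seed(7)
  # observation independent of covariates: all weights near 1
  Z <- matrix(rnorm(50000 * 2), 50000, 2)
  obs <- runif(50000) < 0.6
  pw <- propensity_weights(Z, obs)
  expect_true(all(abs(pw$weights[obs] - 1) < 0.05))
  expect_true(all(pw$weights[!obs] == 0))
  # single binary covariate with observation odds 3:1 vs 1:1
  zb <- rbinom(50000, 1, 0.5)
  pobs <- ifelse(zb == 1, 0.75, 0.5)
  obs2 <- runif(50000) < pobs
  pw2 <- propensity_weights(cbind(zb), obs2)
  expect_lt(abs(pw2$coefficients[2] - log(3)), 0.05)
  expect_error(propensity_weights(Z, rep(TRUE, 50000)), "observed")
})

test_that("propensity weighting detects separation", {
  z <- c(rep(0, 30), rep(1, 30))
  obs <- z == 1
  expect_error(propensity_weights(cbind(z), obs), "separation")
})

test_that("AUC sweep reduces to roc_auc and flags empty classes", {
  set.seed(8)
  T_ <- rnorm(400, 0, 50)
  s1 <- T_ / 50 + rnorm(400, 0, 0.5)
  s2 <- rnorm(400)
  sw <- auc_sweep(s1, s2, T_, cutoffs = 20, n_boot = 0)
  y <- as.integer(T_ > 20)
  expect_equal(sw$auc1, roc_auc(s1, y, ci = FALSE)$auc, tolerance = 1e-12)
  expect_equal(sw$auc2, roc_auc(s2, y, ci = FALSE)$auc, tolerance = 1e-12)
  # identical scores give an identically-zero difference curve
  sw0 <- auc_sweep(s1, s1, T_, cutoffs = seq(5, 25, 5), n_boot = 0)
  expect_true(all(sw0$difference == 0))
  # a cutoff beyond the data range is undefined, not dropped
  sw2 <- auc_sweep(s1, s2, T_, cutoffs = c(20, 1e6), n_boot = 0)
  expect_equal(sw2$defined, c(TRUE, FALSE))
  expect_true(is.na(sw2$auc1[2]))
  expect_error(auc_sweep(s1, s2, T_, cutoffs = c(1e6, 2e6)), "range")
})

test_that("sweep bootstrap intervals bracket the point difference", {
  set.seed(9)
  T_ <- rnorm(300, 0, 50)
  s1 <- T_ / 50 + rnorm(300, 0, 0.3)
  s2 <- rnorm(300)
  sw <- auc_sweep(s1, s2, T_, cutoffs = c(10, 20), n_boot = 200, seed = 10)
  expect_true(all(sw$ci_lower <= sw$difference + 1e-12))
  expect_true(all(sw$ci_upper >= sw$difference - 1e-12))
  # strongly informative score: difference significantly positive
  expect_true(all(sw$ci_lower > 0))
})

test_that("discrimination report restricts to observed targets", {
  set.seed(10)
  n <- 300
  T_ <- rnorm(n, 0, 50)
  scores <- data.frame(a = T_ / 50 + rnorm(n, 0, 0.4), b = rnorm(n))
  obs <- runif(n) < 0.7
  rep_ <- discrimination_report(scores, T_, observed = obs, cutoff = 20,
                                n_perm = 200, seed = 11)
  expect_equal(rep_$n_effective, sum(obs))
  expect_true(all(rep_$auc[, "estimate"] >= 0 & rep_$auc[, "estimate"] <= 1))
  expect_lt(rep_$auc_p_values["a", "b"], 0.01)
  expect_lt(rep_$rho_p_values["a", "b"], 0.01)
})
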
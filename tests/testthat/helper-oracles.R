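# Brute-force oracles and small data builders shared across tests.

# Weighted Mann-Whitney AUC by exhaustive pair enumeration (ties = 1/2).
oracle_auc <- function(score, y, w = rep(1, length(score))) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  num <- 0
  den <- 0
  for (i in pos) for (j in neg) {
    pw <- w[i] * w[j]
    num <- num + pw * ((score[i] > score[j]) + 0.5 * (score[i] == score[j]))
    den <- den + pw
  }
  num / den
}

# Spearman's rho as Pearson correlation of midranks, by hand.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Concordance probability P(R_i < R_j | T_i < T_j) by exhaustive pairs.
oracle_concordance <- function(R, T_) {
  num <- 0
  den <- 0
  n <- length(R)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (T_[i] == T_[j]) next
    lo <- if (T_[i] < T_[j]) i else j
    hi <- if (T_[i] < T_[j]) j else i
    num <- num + (R[lo] < R[hi]) + 0.5 * (R[lo] == R[hi])
    den <- den + 1
  }
  num / den
}

# Two planted, well-separated regression components: slopes +2 / -2 on a
# single covariate, intercepts +3 / -3 (so the component means do not cross
# inside the covariate's mass), residual SD 0.5, equal mixing.
planted_mixture <- function(n = 2000, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  lab <- rbinom(n, 1, 0.5)
  y <- ifelse(lab == 1, 3 + 2 * z, -3 - 2 * z) + rnorm(n, 0, 0.5)
  list(Z = cbind(z = z), y = y, lab = lab)
}

# Random metric instance with ties (integer-valued scores and outcomes).
random_tied_instance <- function(n) {
  list(score = sample(seq_len(max(3L, n %/% 4L)), n, replace = TRUE),
       y = rbinom(n, 1, 0.4),
       w = sample(1:4, n, replace = TRUE),
       T_ = sample(seq_len(max(3L, n %/% 5L)), n, replace = TRUE))
}

# Slope matrix printed for the clinical two-component fit (attenuated
# component first, informative second), on standardized covariates.
clinical_slopes <- function() {
  rbind(
    I = c(0.047, -0.041, -0.015, 0.063, 0.110, -0.063, 0.060, 0.072,
          -0.002, 0),
    V = c(0.25, -0.147, -0.134, 0.213, 0.388, -0.253, 0.206, 0.193,
          -0.109, 0.05))
}
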
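## Discrimination metrics: (weighted) ROC AUC with placement-value
## inference, paired AUC comparison, Spearman's rho with a permutation
## comparison, inverse-probability-of-observation weights, and the
## cutoff-sweep of propensity-weighted AUC differences.

check_binary <- function(outcome) {
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  if (!all(outcome %in% c(0, 1)))
    stop("'outcome' must be binary (0/1, logical, or a two-level factor)")
  as.integer(outcome)
}

## Weighted Mann-Whitney AUC, exact for ties, O(n log n): ascending score
## groups accumulate the negative-class weight strictly below each group.
weighted_auc_stat <- function(score, y, w) {
  o <- order(score)
  s <- score[o]; yy <- y[o]; ww <- w[o]
  grp <- cumsum(c(1L, as.integer(diff(s) != 0)))
  posw <- rowsum(ww * yy, grp)
  negw <- rowsum(ww * (1 - yy), grp)
  below <- cumsum(negw) - negw
  tot_pos <- sum(posw); tot_neg <- sum(negw)
  if (tot_pos <= 0 || tot_neg <= 0)
    stop("both outcome classes must have positive (weighted) mass")
  sum(posw * below + 0.5 * posw * negw) / (tot_pos * tot_neg)
}

## Placement values: V10[i] = fraction of negatives below positive i
## (ties 1/2); V01[j] = fraction of positives below negative j.
placement_values <- function(score, y) {
  pos <- score[y == 1L]; neg <- score[y == 0L]
  m <- length(pos); q <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  V10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / q
  V01 <- (r_all[m + seq_len(q)] - rank(neg, ties.method = "average")) / m
  list(V10 = V10, V01 = V01, m = m, q = q)
}

#' ROC area under the curve, optionally weighted
#'
#' Mann-Whitney estimate of the probability that a random positive subject
#' scores above a random negative one (ties counted 1/2). With weights the
#' statistic is the weighted pair sum
#' `sum_(i in pos, j in neg) w_i w_j [1(R_i > R_j) + 1/2 1(R_i = R_j)]`
#' divided by the total weighted pair mass. Confidence intervals use the
#' asymptotic placement-value (DeLong) variance when unweighted, and a
#' class-stratified bootstrap when weighted.
#'
#' @param score Numeric risk score vector.
#' @param outcome Binary outcome (0/1, logical, or two-level factor;
#'   positive class = 1 / `TRUE` / second level).
#' @param weights Optional nonnegative subject weights.
#' @param ci Compute a confidence interval?
#' @param conf_level Confidence level.
#' @param n_boot Bootstrap replicates for the weighted-case CI.
#' @param seed Optional seed for the bootstrap.
#' @return List with `auc`, `ci` (length-2 or `NULL`), `se` (unweighted
#'   case), `n_pos`, `n_neg`, `method`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
roc_auc <- function(score, outcome, weights = NULL, ci = TRUE,
                    conf_level = 0.95, n_boot = 2000, seed = NULL) {
  y <- check_binary(outcome)
  n <- length(score)
  if (length(y) != n) stop("'score' and 'outcome' must have equal length")
  weighted <- !is.null(weights)
  w <- if (weighted) as.numeric(weights) else rep(1, n)
  if (length(w) != n || any(w < 0)) stop("invalid 'weights'")
  auc <- weighted_auc_stat(score, y, w)
  out <- list(auc = auc, ci = NULL, se = NULL,
              n_pos = sum(y == 1L), n_neg = sum(y == 0L),
              method = if (weighted) "weighted" else "unweighted")
  if (!ci) return(out)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (!weighted) {
    pl <- placement_values(score, y)
    v <- stats::var(pl$V10) / pl$m + stats::var(pl$V01) / pl$q
    out$se <- sqrt(max(v, 0))
    out$ci <- pmin(pmax(auc + c(-1, 1) * z * out$se, 0), 1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx_pos <- which(y == 1L); idx_neg <- which(y == 0L)
    boots <- replicate(n_boot, {
      ii <- c(sample(idx_pos, replace = TRUE),
              sample(idx_neg, replace = TRUE))
      weighted_auc_stat(score[ii], y[ii], w[ii])
    })
    out$ci <- unname(stats::quantile(boots,
                                     c((1 - conf_level) / 2,
                                       1 - (1 - conf_level) / 2)))
  }
  out
}

#' Paired comparison of two correlated AUCs
#'
#' Two-sided test of equality of the AUCs of two risk scores measured on
#' the same subjects against the same binary outcome, using the
#' placement-value (structural-components) variance of the AUC difference.
#' When every placement variance is zero (degenerate scores) the test falls
#' back to a class-stratified paired bootstrap of the difference.
#'
#' @param score1,score2 Risk scores on the same subjects.
#' @param outcome Binary outcome.
#' @param n_boot Bootstrap replicates for the fallback.
#' @param seed Optional seed for the fallback bootstrap.
#' @return List with `auc1`, `auc2`, `difference`, `statistic` (z),
#'   `p_value`, `method`.
#' @export
auc_test_paired <- function(score1, score2, outcome, n_boot = 2000,
                            seed = NULL) {
  y <- check_binary(outcome)
  n <- length(y)
  if (length(score1) != n || length(score2) != n)
    stop("scores and outcome must have equal length")
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("both outcome classes must be present")
  p1 <- placement_values(score1, y)
  p2 <- placement_values(score2, y)
  auc1 <- mean(p1$V10); auc2 <- mean(p2$V10)
  diff <- auc1 - auc2
  S10 <- stats::cov(cbind(p1$V10, p2$V10))
  S01 <- stats::cov(cbind(p1$V01, p2$V01))
  v <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / p1$m +
       (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / p1$q
  if (v > 0) {
    z <- diff / sqrt(v)
    return(list(auc1 = auc1, auc2 = auc2, difference = diff,
                statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                method = "placement-value"))
  }
  if (diff == 0)
    return(list(auc1 = auc1, auc2 = auc2, difference = 0,
                statistic = 0, p_value = 1, method = "degenerate"))
  ## degenerate placements but unequal AUCs: paired stratified bootstrap
  if (!is.null(seed)) set.seed(seed)
  idx_pos <- which(y == 1L); idx_neg <- which(y == 0L)
  boots <- replicate(n_boot, {
    ii <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
    weighted_auc_stat(score1[ii], y[ii], rep(1, length(ii))) -
      weighted_auc_stat(score2[ii], y[ii], rep(1, length(ii)))
  })
  se <- stats::sd(boots)
  z <- if (se > 0) diff / se else Inf * sign(diff)
  list(auc1 = auc1, auc2 = auc2, difference = diff, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)), method = "paired-bootstrap")
}

#' Spearman's rank correlation with a Fisher-z interval
#'
#' Pearson correlation of midranks, with the usual Fisher-z confidence
#' interval (standard error `1 / sqrt(n - 3)`).
#'
#' @param x,y Paired numeric vectors, `n >= 3`, neither constant.
#' @param conf_level Confidence level.
#' @return List with `rho`, `ci`, `n`.
#' @export
spearman_rho <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman's rho undefined for a constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  ci <- if (n > 3L && abs(rho) < 1) {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    tanh(z + c(-1, 1) * q * se)
  } else {
    c(-1, 1)
  }
  list(rho = rho, ci = ci, n = n)
}

#' Permutation comparison of two dependent Spearman correlations
#'
#' Tests whether two risk scores, measured on the same subjects, correlate
#' equally (in Spearman's rho) with the same target. The observed statistic
#' is `d = rho(score1, target) - rho(score2, target)`. The null
#' distribution is built by independently swapping the score pair
#' `(score1_i, score2_i)` with probability 1/2 for every subject in each
#' permutation — exchangeability of the two scores given the target. The
#' two-sided p-value carries the add-one correction
#' `(1 + #(|d*| >= |d|)) / (n_perm + 1)`.
#'
#' @param score1,score2 Paired risk scores.
#' @param target Target outcome vector.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional seed.
#' @return List with `difference`, `rho1`, `rho2`, `p_value`, `n_perm`.
#' @export
spearman_perm_test <- function(score1, score2, target, n_perm = 1000,
                               seed = NULL) {
  n <- length(target)
  if (length(score1) != n || length(score2) != n)
    stop("scores and target must have equal length")
  if (n_perm < 100L) stop("'n_perm' must be at least 100")
  if (stats::sd(score1) == 0 || stats::sd(score2) == 0 ||
      stats::sd(target) == 0)
    stop("degenerate constant input")
  if (!is.null(seed)) set.seed(seed)
  rT <- rank(target, ties.method = "average")
  rho_of <- function(v) stats::cor(rank(v, ties.method = "average"), rT)
  rho1 <- rho_of(score1); rho2 <- rho_of(score2)
  d_obs <- rho1 - rho2
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, score2, score1)
    bb <- ifelse(swap, score1, score2)
    d <- rho_of(a) - rho_of(bb)
    if (abs(d) >= abs(d_obs)) exceed <- exceed + 1L
  }
  list(difference = d_obs, rho1 = rho1, rho2 = rho2,
       p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Inverse-probability-of-observation weights
#'
#' Fits a logistic propensity model for whether the target outcome was
#' observed, given covariates, and converts it to evaluation weights.
#' The default (`type = "inverse"`) gives observed subjects weight
#' `1 / p_hat` — inverse probability of observation, the standard
#' missing-data correction — clipped at the 99th percentile and normalized
#' to mean 1 over observed subjects; unobserved subjects get weight 0.
#' `type = "propensity"` instead uses the fitted propensity itself as the
#' weight (normalized the same way), the literal "propensity score as a
#' weight" reading.
#'
#' @param Z Covariate matrix.
#' @param observed Logical vector: was the target recorded?
#' @param type `"inverse"` or `"propensity"`.
#' @param clip_quantile Upper quantile at which observed weights are capped.
#' @return An object of class `"propensity_model"`: list with `weights`
#'   (length n, zero where unobserved), `fitted` propensities,
#'   `coefficients`, `n_observed`, `type`.
#' @export
propensity_weights <- function(Z, observed, type = c("inverse", "propensity"),
                               clip_quantile = 0.99) {
  type <- match.arg(type)
  Z <- as.matrix(Z)
  observed <- as.logical(observed)
  n <- nrow(Z)
  if (length(observed) != n) stop("'observed' and 'Z' are not conformable")
  if (all(observed)) stop("all subjects observed: no missingness to model")
  if (!any(observed)) stop("no subjects observed")
  if (n <= ncol(Z) + 1L) stop("need n > p + 1")
  fit <- suppressWarnings(
    stats::glm.fit(cbind("(Intercept)" = 1, Z), as.numeric(observed),
                   family = stats::binomial()))
  p_hat <- fit$fitted.values
  eps <- 1e-8
  if (!fit$converged || any(p_hat < eps | p_hat > 1 - eps))
    stop("propensity model shows (near-)perfect separation; ",
         "consider penalizing or removing offending covariates")
  w <- numeric(n)
  w_obs <- if (type == "inverse") 1 / p_hat[observed] else p_hat[observed]
  cap <- stats::quantile(w_obs, clip_quantile)
  w_obs <- pmin(w_obs, cap)
  w[observed] <- w_obs / mean(w_obs)
  structure(
    list(weights = w, fitted = p_hat, coefficients = fit$coefficients,
         n_observed = sum(observed), type = type),
    class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Observation propensity model (", x$n_observed, " of ",
      length(x$fitted), " observed; ", x$type, " weighting)\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Weighted AUC difference across target cutoffs
#'
#' For every cutoff `c` in the grid, dichotomizes the target at `c`
#' (positive class `target > c` for `direction = "greater"`), computes the
#' weighted AUC of two competing risk scores, their difference, and a
#' class-stratified bootstrap confidence interval for the difference
#' (pointwise). Cutoffs at which a class has no weighted mass are reported
#' as undefined rather than dropped.
#'
#' @param score1,score2 Competing risk scores on the same subjects.
#' @param target Continuous target outcome.
#' @param weights Subject weights (e.g. from [propensity_weights()]);
#'   default equal weights.
#' @param cutoffs Numeric grid of cutoffs (default 5 to 25 by 1, the
#'   clinically plausible range of meaningful eGFR decline).
#' @param direction `"greater"`: positive class is `target > cutoff`;
#'   `"less"` flips it.
#' @param n_boot Bootstrap replicates for the difference CI (0 skips CIs).
#' @param conf_level Confidence level.
#' @param seed Optional seed.
#' @return A data frame of class `"auc_sweep"`: columns `cutoff`, `auc1`,
#'   `auc2`, `difference`, `ci_lower`, `ci_upper`, `defined`; the weight
#'   summary is attached as attribute `"weights_summary"`.
#' @export
auc_sweep <- function(score1, score2, target, weights = NULL,
                      cutoffs = 5:25, direction = c("greater", "less"),
                      n_boot = 2000, conf_level = 0.95, seed = NULL) {
  direction <- match.arg(direction)
  n <- length(target)
  if (length(score1) != n || length(score2) != n)
    stop("scores and target must have equal length")
  if (length(cutoffs) < 1L) stop("empty cutoff grid")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0)) stop("invalid 'weights'")
  keep <- w > 0
  if (!any(keep)) stop("all weights are zero")
  s1 <- score1[keep]; s2 <- score2[keep]; tt <- target[keep]; ww <- w[keep]
  if (all(cutoffs >= max(tt)) || all(cutoffs <= min(tt)))
    stop("cutoff grid lies entirely outside the data range")
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - conf_level) / 2
  rows <- lapply(cutoffs, function(cc) {
    y <- if (direction == "greater") as.integer(tt > cc)
         else as.integer(tt < cc)
    if (sum(ww[y == 1L]) <= 0 || sum(ww[y == 0L]) <= 0)
      return(data.frame(cutoff = cc, auc1 = NA_real_, auc2 = NA_real_,
                        difference = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, defined = FALSE))
    a1 <- weighted_auc_stat(s1, y, ww)
    a2 <- weighted_auc_stat(s2, y, ww)
    lo <- hi <- NA_real_
    if (n_boot > 0L) {
      ip <- which(y == 1L); iq <- which(y == 0L)
      boots <- replicate(n_boot, {
        ii <- c(sample(ip, replace = TRUE), sample(iq, replace = TRUE))
        weighted_auc_stat(s1[ii], y[ii], ww[ii]) -
          weighted_auc_stat(s2[ii], y[ii], ww[ii])
      })
      qs <- stats::quantile(boots, c(alpha, 1 - alpha))
      lo <- qs[[1L]]; hi <- qs[[2L]]
    }
    data.frame(cutoff = cc, auc1 = a1, auc2 = a2, difference = a1 - a2,
               ci_lower = lo, ci_upper = hi, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "weights_summary") <- summary(ww)
  class(out) <- c("auc_sweep", "data.frame")
  out
}

#' @export
plot.auc_sweep <- function(x, ...) {
  ok <- x$defined
  graphics::plot(x$cutoff[ok], x$difference[ok], type = "b", pch = 16,
                 xlab = "target cutoff", ylab = "AUC difference (score1 - score2)",
                 ...)
  if (!all(is.na(x$ci_lower))) {
    graphics::arrows(x$cutoff[ok], x$ci_lower[ok], x$cutoff[ok],
                     x$ci_upper[ok], angle = 90, code = 3, length = 0.03,
                     col = "grey50")
  }
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Full discrimination report for a set of risk scores
#'
#' Evaluates each candidate risk score against the target outcome on the
#' observed-target subjects: AUC (target dichotomized at `cutoff`) with its
#' interval, Spearman's rho with its interval, and all pairwise score
#' comparisons (placement-value AUC test, permutation rho test).
#'
#' @param scores Named list / data frame of risk score vectors (e.g. a
#'   [risk_score_set()]).
#' @param target Continuous target outcome.
#' @param observed Logical mask of observed targets (default: non-missing).
#' @param cutoff Dichotomization cutoff for the AUC (default 20).
#' @param direction Passed to the dichotomization, see [auc_sweep()].
#' @param n_perm Permutations for the rho comparisons.
#' @param conf_level Confidence level.
#' @param seed Optional seed.
#' @return Object of class `"discrimination_report"`: `auc` and `rho`
#'   tables (estimate, lower, upper per score), square matrices
#'   `auc_p_values` and `rho_p_values`, and `n_effective`.
#' @export
discrimination_report <- function(scores, target, observed = NULL,
                                  cutoff = 20,
                                  direction = c("greater", "less"),
                                  n_perm = 1000, conf_level = 0.95,
                                  seed = NULL) {
  direction <- match.arg(direction)
  sc <- as.data.frame(scores)
  if (is.null(observed)) observed <- !is.na(target)
  sc <- sc[observed, , drop = FALSE]
  tt <- target[observed]
  n_eff <- length(tt)
  y <- if (direction == "greater") as.integer(tt > cutoff)
       else as.integer(tt < cutoff)
  if (!is.null(seed)) set.seed(seed)
  nm <- names(sc)
  auc_tab <- t(vapply(sc, function(s) {
    r <- roc_auc(s, y, conf_level = conf_level)
    c(estimate = r$auc, lower = r$ci[1L], upper = r$ci[2L])
  }, numeric(3)))
  rho_tab <- t(vapply(sc, function(s) {
    r <- spearman_rho(s, tt, conf_level = conf_level)
    c(estimate = r$rho, lower = r$ci[1L], upper = r$ci[2L])
  }, numeric(3)))
  k <- length(nm)
  auc_p <- rho_p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      auc_p[i, j] <- auc_p[j, i] <-
        auc_test_paired(sc[[i]], sc[[j]], y)$p_value
      rho_p[i, j] <- rho_p[j, i] <-
        spearman_perm_test(sc[[i]], sc[[j]], tt, n_perm = n_perm)$p_value
    }
  }
  structure(list(auc = auc_tab, rho = rho_tab,
                 auc_p_values = auc_p, rho_p_values = rho_p,
                 cutoff = cutoff, n_effective = n_eff),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, digits = 3, ...) {
  cat("Discrimination report (n_effective =", x$n_effective,
      "; AUC cutoff =", x$cutoff, ")\n\nAUC:\n")
  print(round(x$auc, digits))
  cat("\nSpearman's rho:\n")
  print(round(x$rho, digits))
  cat("\nPaired AUC-difference p-values:\n")
  print(signif(x$auc_p_values, 2))
  cat("\nPermutation rho-difference p-values:\n")
  print(signif(x$rho_p_values, 2))
  invisible(x)
}
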
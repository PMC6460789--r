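## Core estimator: K-component mixture of Gaussian linear regressions with
## unconstrained component variances, fitted by EM with random restarts.

variance_floor_sd <- function(y) {
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) return(1e-12)
  sqrt(1e-6 * vy)
}

#' Weighted Gaussian linear fit
#'
#' Least-squares fit of `y` on covariates `Z` with an intercept, optionally
#' weighted. This is both the pooled comparator model and the M-step
#' workhorse of [mixlm()]. The residual SD is the (weighted) root mean
#' squared residual — the Gaussian maximum-likelihood scale, not the
#' degrees-of-freedom-corrected one — floored at `sqrt(1e-6 * var(y))` so a
#' perfectly interpolating fit cannot produce an infinite log-likelihood.
#'
#' @param Z Numeric covariate matrix (without an intercept column).
#' @param y Numeric response vector.
#' @param weights Optional nonnegative weights, not all zero.
#' @return An object of class `"linfit"`: list with `coefficients`
#'   (intercept first), `residual_sd`, `fitted`, `n`, `p`, and
#'   `log_likelihood` (weighted Gaussian log-likelihood at the MLE scale).
#' @examples
#' f <- fit_linear(cbind(z = c(0, 1, 2)), c(1, 2, 2))
#' coef(f)  # intercept 7/6, slope 1/2
#' @export
fit_linear <- function(Z, y, weights = NULL) {
  Z <- as.matrix(Z)
  n <- length(y)
  if (nrow(Z) != n) stop("'Z' and 'y' are not conformable")
  X <- cbind("(Intercept)" = 1, Z)
  if (n <= ncol(X)) stop("need n > p + 1 observations")
  if (is.null(weights)) {
    fit <- stats::lm.fit(X, y)
    w <- rep(1, n)
  } else {
    if (length(weights) != n) stop("'weights' must have length n")
    if (any(weights < 0)) stop("'weights' must be nonnegative")
    if (sum(weights) <= 0) stop("'weights' must not be all zero")
    fit <- stats::lm.wfit(X, y, weights)
    w <- weights
  }
  if (fit$rank < ncol(X))
    stop("singular design: covariates are linearly dependent")
  res <- y - drop(X %*% fit$coefficients)
  sigma <- sqrt(sum(w * res^2) / sum(w))
  sigma <- max(sigma, variance_floor_sd(y))
  ll <- sum(w * stats::dnorm(y, drop(X %*% fit$coefficients), sigma, log = TRUE))
  structure(
    list(coefficients = fit$coefficients,
         residual_sd = sigma,
         fitted = drop(X %*% fit$coefficients),
         residuals = res,
         n = n, p = ncol(Z),
         log_likelihood = ll),
    class = "linfit")
}

#' @export
print.linfit <- function(x, digits = 4, ...) {
  cat("Gaussian linear fit (n =", x$n, ")\n")
  print(round(x$coefficients, digits))
  cat("residual SD:", signif(x$residual_sd, digits),
      "| log-likelihood:", signif(x$log_likelihood, 6),
      "| BIC:", signif(stats::BIC(x), 6), "\n")
  invisible(x)
}

#' @export
coef.linfit <- function(object, ...) object$coefficients

#' @export
logLik.linfit <- function(object, ...) {
  ## free parameters: p slopes + intercept + residual variance
  structure(object$log_likelihood, df = object$p + 2, nobs = object$n,
            class = "logLik")
}

#' @export
predict.linfit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  X <- cbind(1, as.matrix(newdata))
  if (ncol(X) != length(object$coefficients))
    stop("'newdata' has the wrong number of columns")
  drop(X %*% object$coefficients)
}

#' @export
residuals.linfit <- function(object, ...) object$residuals

## One M-step of the EM algorithm with given responsibilities: each
## component is refitted by responsibility-weighted least squares and the
## mixing weights become the mean responsibilities. Exposed so the frozen-
## responsibility fit can be checked against per-label OLS.

#' M-step of the regression-mixture EM
#'
#' Refits every mixture component by responsibility-weighted least squares
#' and recomputes the mixing weights as mean responsibilities. With
#' responsibilities frozen at 0/1 labels this reproduces per-label ordinary
#' least squares exactly.
#'
#' @param Z Covariate matrix (no intercept column).
#' @param y Response vector.
#' @param responsibilities `n x K` matrix of nonnegative row-normalized
#'   responsibilities.
#' @return List with `coefficients` (`K x (p+1)`, intercept first),
#'   `residual_sds` (length `K`) and `mixing_weights`.
#' @export
mixlm_mstep <- function(Z, y, responsibilities) {
  Z <- as.matrix(Z)
  tau <- as.matrix(responsibilities)
  K <- ncol(tau)
  X <- cbind("(Intercept)" = 1, Z)
  d <- ncol(X)
  coefs <- matrix(NA_real_, K, d, dimnames = list(NULL, colnames(X)))
  sds <- numeric(K)
  floor_sd <- variance_floor_sd(y)
  for (k in seq_len(K)) {
    wk <- tau[, k]
    if (sum(wk) < d + 1) stop("degenerate component: responsibility mass too small")
    fit <- stats::lm.wfit(X, y, wk)
    if (anyNA(fit$coefficients)) stop("degenerate component: rank-deficient weighted fit")
    coefs[k, ] <- fit$coefficients
    res <- y - drop(X %*% fit$coefficients)
    sds[k] <- max(sqrt(sum(wk * res^2) / sum(wk)), floor_sd)
  }
  list(coefficients = coefs, residual_sds = sds,
       mixing_weights = colMeans(tau))
}

em_estep <- function(X, y, coefs, sds, pi_) {
  K <- length(pi_)
  logd <- matrix(0, length(y), K)
  for (k in seq_len(K))
    logd[, k] <- stats::dnorm(y, drop(X %*% coefs[k, ]), sds[k], log = TRUE) +
      log(pi_[k])
  m <- apply(logd, 1L, max)
  lse <- m + log(rowSums(exp(logd - m)))
  list(loglik = sum(lse), tau = exp(logd - lse))
}

run_one_start <- function(X, y, K, tol, max_iter, floor_sd) {
  n <- length(y); d <- ncol(X)
  ## per-row symmetric Dirichlet(1) initialization of the responsibilities
  tau <- matrix(stats::rexp(n * K), n, K)
  tau <- tau / rowSums(tau)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  coefs <- NULL; sds <- NULL; pi_ <- NULL
  for (iter in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      wk <- tau[, k]
      if (sum(wk) < d + 1) return(list(degenerate = TRUE))
      fit <- stats::lm.wfit(X, y, wk)
      if (anyNA(fit$coefficients)) return(list(degenerate = TRUE))
      res <- y - drop(X %*% fit$coefficients)
      s2 <- sum(wk * res^2) / sum(wk)
      if (s2 < floor_sd^2) return(list(degenerate = TRUE))
      if (k == 1L) {
        coefs <- matrix(NA_real_, K, d, dimnames = list(NULL, colnames(X)))
        sds <- numeric(K)
      }
      coefs[k, ] <- fit$coefficients
      sds[k] <- sqrt(s2)
    }
    pi_ <- colMeans(tau)
    e <- em_estep(X, y, coefs, sds, pi_)
    tau <- e$tau
    trace <- c(trace, e$loglik)
    if (is.finite(ll_prev) &&
        (e$loglik - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      break
    }
    ll_prev <- e$loglik
  }
  list(degenerate = FALSE, loglik = trace[length(trace)], trace = trace,
       tau = tau, coefficients = coefs, residual_sds = sds,
       mixing_weights = pi_, n_iterations = length(trace),
       converged = converged)
}

#' Fit a mixture of linear regressions by EM
#'
#' Fits a `K`-component mixture of Gaussian linear regressions with
#' component-specific (unconstrained) residual variances. Starting from
#' per-row Dirichlet(1) random responsibilities, the algorithm alternates a
#' responsibility-weighted least-squares M-step with an E-step that turns
#' prior membership probabilities and component likelihoods into posterior
#' responsibilities, until the relative change in the observed-data
#' log-likelihood drops below `tol`. The best of `n_starts` random
#' initializations is retained. A start in which a component's
#' responsibility mass drops below `p + 2` effective observations, or its
#' residual variance hits the floor `1e-6 * var(y)`, is discarded as
#' degenerate and redrawn (up to three times `n_starts` attempts in total).
#'
#' No identifiability constraint is imposed during fitting; component labels
#' are arbitrary and the informative component is identified post hoc with
#' [informative_component()].
#'
#' @param x Covariate matrix (default method) or a model formula.
#' @param y Response vector (default method).
#' @param data Data frame for the formula method.
#' @param K Number of mixture components (>= 1; `K = 1` reduces to
#'   [fit_linear()]).
#' @param n_starts Number of random initializations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Optional integer seed making the fit reproducible.
#' @param ... Passed between methods.
#' @return An object of class `"mixlm"`: list with `coefficients`
#'   (`K x (p+1)` matrix, intercept first), `residual_sds`,
#'   `mixing_weights`, `posterior` (`n x K`), `log_likelihood`, `bic`,
#'   `relative_entropy`, `n_iterations`, `converged`, `n_starts_used`,
#'   `loglik_trace` (of the best start), `informative` (index from
#'   [informative_component()], `K >= 2` only) and bookkeeping fields.
#' @examples
#' set.seed(1)
#' z <- rnorm(300)
#' grp <- rbinom(300, 1, 0.5)
#' y <- ifelse(grp == 1, 3 + 2 * z, -3 - 2 * z) + rnorm(300, 0, 0.5)
#' fit <- mixlm(cbind(z = z), y, K = 2, n_starts = 5, seed = 1)
#' coef(fit)
#' @export
mixlm <- function(x, ...) UseMethod("mixlm")

#' @rdname mixlm
#' @export
mixlm.formula <- function(x, data, K = 2, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (colnames(X)[1L] != "(Intercept)")
    stop("the model must include an intercept")
  fit <- mixlm.default(X[, -1L, drop = FALSE], y, K = K, ...)
  fit$terms <- attr(mf, "terms")
  fit$call <- match.call()
  fit
}

#' @rdname mixlm
#' @export
mixlm.default <- function(x, y, K = 2, n_starts = 20, tol = 1e-8,
                          max_iter = 500, seed = NULL, ...) {
  Z <- as.matrix(x)
  n <- length(y)
  if (nrow(Z) != n) stop("'x' and 'y' are not conformable")
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1")
  d <- ncol(Z) + 1L
  if (n <= K * (d + 1L)) stop("need n > K * (p + 2) observations")
  if (!is.null(seed)) set.seed(seed)
  X <- cbind("(Intercept)" = 1, Z)
  floor_sd <- variance_floor_sd(y)

  best <- NULL
  n_used <- 0L
  attempts <- 0L
  max_attempts <- 3L * n_starts
  while (n_used < n_starts && attempts < max_attempts) {
    attempts <- attempts + 1L
    res <- run_one_start(X, y, K, tol, max_iter, floor_sd)
    if (isTRUE(res$degenerate)) next
    n_used <- n_used + 1L
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("all EM starts degenerate; reduce K or supply more data")

  tau <- best$tau
  colnames(best$coefficients) <- colnames(X)
  q <- K * (d + 1L) - 1L  # per component: p slopes + intercept + variance; plus K-1 weights
  out <- structure(
    list(K = K,
         coefficients = best$coefficients,
         residual_sds = best$residual_sds,
         mixing_weights = best$mixing_weights,
         posterior = tau,
         log_likelihood = best$loglik,
         bic = -2 * best$loglik + q * log(n),
         relative_entropy = if (K >= 2L) relative_entropy(tau) else NA_real_,
         n_iterations = best$n_iterations,
         converged = best$converged,
         n_starts_used = n_used,
         loglik_trace = best$trace,
         n = n, p = ncol(Z), df = q,
         X = X, y = y,
         seed = seed,
         call = match.call()),
    class = "mixlm")
  if (K >= 2L)
    out$informative <- informative_component(out, warn = FALSE)
  out
}

#' Relative entropy of a posterior classification
#'
#' One minus the mean posterior entropy normalized by its maximum `ln K`:
#' `1 - sum(-tau * log(tau)) / (n * log(K))`, with `0 * log(0)` taken as 0.
#' Values near 1 indicate well-separated components (posteriors near 0/1);
#' 0 indicates maximal classification uncertainty.
#'
#' @param posteriors `n x K` posterior probability matrix (rows sum to 1),
#'   `K >= 2`, or a fitted `"mixlm"` object.
#' @return A scalar in `[0, 1]`.
#' @export
relative_entropy <- function(posteriors) {
  if (inherits(posteriors, "mixlm")) posteriors <- posteriors$posterior
  tau <- as.matrix(posteriors)
  K <- ncol(tau)
  if (K < 2L) stop("relative entropy requires K >= 2 components")
  if (any(tau < -1e-12) || any(tau > 1 + 1e-12))
    stop("posterior entries must lie in [0, 1]")
  if (any(abs(rowSums(tau) - 1) > 1e-6))
    stop("posterior rows must sum to 1")
  h <- -tau * log(tau)
  h[tau == 0] <- 0
  1 - sum(h) / (nrow(tau) * log(K))
}

#' Identify the informative mixture component
#'
#' Selects, post hoc, the component whose covariate effects are largest: the
#' one maximizing the mean absolute slope (intercept excluded). Intended for
#' fits on standardized covariates, where slope magnitudes are comparable.
#' A diagnostic warning is emitted when the top two components are within
#' 10% relative of each other, since the selection is then fragile (ties are
#' broken toward the lowest index).
#'
#' @param fit A fitted `"mixlm"` object, or a `K x p` matrix of slopes
#'   (one row per component, no intercept column).
#' @param warn Emit the near-tie warning?
#' @return Integer component index.
#' @export
informative_component <- function(fit, warn = TRUE) {
  slopes <- if (inherits(fit, "mixlm")) {
    if (fit$K < 2L) stop("informative component requires K >= 2")
    fit$coefficients[, -1L, drop = FALSE]
  } else {
    as.matrix(fit)
  }
  score <- rowMeans(abs(slopes))
  idx <- which.max(score)
  ord <- sort(score, decreasing = TRUE)
  if (warn && length(ord) >= 2L && ord[1L] > 0 &&
      (ord[1L] - ord[2L]) / ord[1L] < 0.1)
    warning("near-tie: top two components differ by < 10% in mean |slope|; ",
            "informative-component selection may be unstable")
  as.integer(idx)
}

#' Modal component assignment
#'
#' Assigns each subject to the component with the largest posterior
#' probability. Exact ties are broken toward the informative component when
#' its index is supplied (or known to the fit), otherwise toward the lowest
#' index.
#'
#' @param posteriors `n x K` posterior matrix or a fitted `"mixlm"`.
#' @param informative Optional component index used to break ties.
#' @return Integer vector of component indices, length `n`.
#' @export
modal_assignment <- function(posteriors, informative = NULL) {
  if (inherits(posteriors, "mixlm")) {
    if (is.null(informative)) informative <- posteriors$informative
    posteriors <- posteriors$posterior
  }
  tau <- as.matrix(posteriors)
  lab <- max.col(tau, ties.method = "first")
  if (!is.null(informative)) {
    mx <- tau[cbind(seq_len(nrow(tau)), rep(informative, nrow(tau)))]
    tied <- mx == apply(tau, 1L, max)
    lab[tied] <- informative
  }
  lab
}
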
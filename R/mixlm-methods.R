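#' @export
print.mixlm <- function(x, digits = 4, ...) {
  cat("Mixture of linear regressions (K =", x$K, ", n =", x$n, ")\n")
  cat("mixing weights:",
      paste(formatC(x$mixing_weights, digits = 3, format = "f"),
            collapse = ", "), "\n")
  cat("log-likelihood:", signif(x$log_likelihood, 7),
      "| BIC:", signif(x$bic, 7), "\n")
  if (x$K >= 2L)
    cat("relative entropy:", signif(x$relative_entropy, 4),
        "| informative component:", x$informative, "\n")
  invisible(x)
}

#' @export
coef.mixlm <- function(object, ...) object$coefficients

#' @export
logLik.mixlm <- function(object, ...) {
  structure(object$log_likelihood, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.mixlm <- function(object, ...) {
  ## posterior-weighted mixture mean
  preds <- component_predictions(object)
  rowSums(preds * object$posterior)
}

#' @export
residuals.mixlm <- function(object, ...) {
  if (is.null(object$y)) stop("fit does not carry the response; refit storing data")
  object$y - fitted(object)
}

#' Predict from a regression-mixture fit
#'
#' Returns the linear predictor of a single mixture component for every
#' subject (not only modally assigned ones). The default component is the
#' post hoc informative one, which is the mixture's risk score; an explicit
#' component index or `"all"` (matrix of all component predictors) may be
#' requested instead.
#'
#' @param object A fitted `"mixlm"`.
#' @param newdata Covariate matrix (or data frame for formula fits). When
#'   omitted, the training covariates are required to have been stored.
#' @param component `"informative"`, `"all"`, or an integer index.
#' @param ... Unused.
#' @return Numeric vector of risk scores, or an `n x K` matrix for
#'   `component = "all"`.
#' @export
predict.mixlm <- function(object, newdata = NULL,
                          component = "informative", ...) {
  X <- mixlm_design(object, newdata)
  if (identical(component, "all"))
    return(X %*% t(object$coefficients))
  k <- if (identical(component, "informative")) {
    if (is.null(object$informative))
      stop("no informative component recorded (K = 1?)")
    object$informative
  } else {
    component <- as.integer(component)
    if (is.na(component) || component < 1L || component > object$K)
      stop("invalid component index")
    component
  }
  drop(X %*% object$coefficients[k, ])
}

mixlm_design <- function(object, newdata) {
  if (is.null(newdata)) {
    if (is.null(object$X)) stop("supply 'newdata' (training design not stored)")
    return(object$X)
  }
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    return(stats::model.matrix(tt, stats::model.frame(tt, newdata)))
  }
  X <- cbind(1, as.matrix(newdata))
  if (ncol(X) != ncol(object$coefficients))
    stop("'newdata' has the wrong number of columns")
  X
}

component_predictions <- function(object) {
  if (is.null(object$X)) stop("training design not stored")
  object$X %*% t(object$coefficients)
}

#' @export
summary.mixlm <- function(object, ...) {
  structure(list(fit = object,
                 modal = tabulate(modal_assignment(object), object$K)),
            class = "summary.mixlm")
}

#' @export
print.summary.mixlm <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f)
  cat("\nComponent coefficients (rows = components):\n")
  print(round(f$coefficients, digits))
  cat("residual SDs:",
      paste(signif(f$residual_sds, digits), collapse = ", "), "\n")
  cat("modal assignment counts:", paste(x$modal, collapse = ", "), "\n")
  cat("EM: ", f$n_iterations, " iterations, converged = ", f$converged,
      ", starts used = ", f$n_starts_used, "\n", sep = "")
  invisible(x)
}

#' Simulate responses from a fitted regression mixture
#'
#' Draws component membership from the fitted mixing weights and responses
#' from the corresponding component's Gaussian linear model, at the stored
#' training design.
#'
#' @param object A fitted `"mixlm"` carrying its training design.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses.
#' @export
simulate.mixlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  preds <- component_predictions(object)
  n <- nrow(preds)
  out <- replicate(nsim, {
    k <- sample.int(object$K, n, replace = TRUE,
                    prob = object$mixing_weights)
    stats::rnorm(n, preds[cbind(seq_len(n), k)], object$residual_sds[k])
  })
  as.data.frame(out)
}

#' Diagnostic plot for a regression-mixture fit
#'
#' Left: histogram of the posterior probability of the informative
#' component (a well-separated fit piles mass near 0 and 1). Right:
#' response against the informative component's linear predictor, coloured
#' by modal assignment.
#'
#' @param x A fitted `"mixlm"` carrying its training data.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mixlm <- function(x, ...) {
  if (x$K < 2L) stop("plot method requires K >= 2")
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  k <- x$informative
  graphics::hist(x$posterior[, k], breaks = 20, main = "Posterior P(informative)",
                 xlab = "posterior probability", col = "grey80")
  if (!is.null(x$X) && !is.null(x$y)) {
    score <- drop(x$X %*% x$coefficients[k, ])
    lab <- modal_assignment(x)
    graphics::plot(score, x$y, col = ifelse(lab == k, "firebrick", "grey50"),
                   xlab = "informative-component prediction", ylab = "response",
                   main = "Response vs risk score", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
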
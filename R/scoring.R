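## Risk scores and surrogate-screening criteria.
##
## A risk score is any one-dimensional per-subject summary meant to order
## subjects by disease disposition. The pooled linear model's score is its
## prediction; the mixture's score is the informative component's
## prediction; the raw surrogate itself serves as comparator.

#' Assemble a set of candidate risk scores
#'
#' Builds the standard three-way comparison: the raw surrogate value, the
#' pooled linear model's prediction, and the mixture's informative-component
#' prediction, for the same subjects.
#'
#' @param Z Covariate matrix.
#' @param S Surrogate outcome vector (the `raw_surrogate` score).
#' @param linear_fit A `"linfit"` from [fit_linear()].
#' @param mixture_fit A `"mixlm"` from [mixlm()].
#' @param component Mixture component used for the score: `"informative"`
#'   or an index (see [predict.mixlm()]).
#' @return A data frame of class `"risk_score_set"` with columns
#'   `raw_surrogate`, `linear`, `mixture_V`; the provenance (component
#'   index used) is attached as attribute `"provenance"`.
#' @export
risk_score_set <- function(Z, S, linear_fit, mixture_fit,
                           component = "informative") {
  Z <- as.matrix(Z)
  if (length(S) != nrow(Z)) stop("'S' and 'Z' are not conformable")
  k <- if (identical(component, "informative")) mixture_fit$informative
       else as.integer(component)
  out <- data.frame(
    raw_surrogate = as.numeric(S),
    linear = predict(linear_fit, Z),
    mixture_V = predict(mixture_fit, Z, component = k))
  attr(out, "provenance") <- list(mixture_component = k,
                                  K = mixture_fit$K)
  class(out) <- c("risk_score_set", "data.frame")
  out
}

#' Concordance probability of a risk score
#'
#' Estimates `P(R_i < R_j | T_i < T_j)`, the probability that the risk
#' score orders a random pair of subjects the same way as the target
#' outcome — the minimal requirement for a discriminating score (it must
#' exceed 1/2). Estimated by the pairwise concordance (Somers-type)
#' estimator: over all pairs with `T_i != T_j`, the fraction ordered
#' concordantly, counting score ties as 1/2; target-tied pairs are
#' excluded. For binary 0/1 targets this equals the ROC AUC exactly.
#'
#' @param R Risk score vector.
#' @param T_ Target outcome vector, same length.
#' @param method `"pairs"` (exhaustive O(n^2) enumeration), `"rank"`
#'   (O(n log n) via [survival::concordance()]), or `"auto"` (pairs up to
#'   n = 2000, rank beyond). Both paths agree exactly, including ties.
#' @return Concordance probability in `[0, 1]`.
#' @examples
#' concordance_probability(c(1, 2, 3), c(10, 20, 30))  # 1
#' @export
concordance_probability <- function(R, T_, method = c("auto", "pairs", "rank")) {
  method <- match.arg(method)
  n <- length(R)
  if (length(T_) != n) stop("'R' and 'T_' must have equal length")
  if (n < 2L) stop("need at least two subjects")
  if (all(T_ == T_[1L]))
    stop("concordance undefined: all target values are equal")
  if (method == "auto") method <- if (n <= 2000L) "pairs" else "rank"
  if (method == "pairs") {
    lt <- outer(T_, T_, "<")           # [i, j]: T_i < T_j
    conc <- outer(R, R, "<") + 0.5 * outer(R, R, "==")
    sum(conc[lt]) / sum(lt)
  } else {
    cf <- survival::concordance(T_ ~ R)
    ## survival counts (concordant + ties.x/2) / comparable on T
    unname(cf$concordance)
  }
}

#' Screen covariate-surrogate and covariate-target association
#'
#' Diagnostic screen of the two prerequisites for surrogate-based risk
#' scoring: the covariates must carry information about the surrogate
#' (`f(S|Z) != f(S)`) and about the target (`f(T|Z) != f(T)`).
#' Operationalized as the overall F-test of the linear regression of each
#' outcome on all covariates, together with per-covariate marginal
#' correlations. The target is screened on observed rows only. This is a
#' screening report, not a gate.
#'
#' @param Z Covariate matrix.
#' @param S Surrogate vector.
#' @param T_ Target vector.
#' @param observed_T Logical mask of observed targets (default: non-missing
#'   entries of `T_`).
#' @return An object of class `"association_screen"`: per-outcome list with
#'   `f_statistic`, `df`, `p_value`, `marginal_cor`, and `n`.
#' @export
association_screen <- function(Z, S, T_, observed_T = NULL) {
  Z <- as.matrix(Z)
  if (is.null(observed_T)) observed_T <- !is.na(T_)
  screen_one <- function(y, X, label) {
    n <- length(y)
    if (n <= ncol(X) + 1L)
      stop("insufficient observations to screen ", label,
           " (need n > p + 1)")
    fit <- stats::lm(y ~ X)
    fs <- summary(fit)$fstatistic
    list(outcome = label,
         n = n,
         f_statistic = unname(fs[1L]),
         df = unname(fs[2:3]),
         p_value = unname(stats::pf(fs[1L], fs[2L], fs[3L],
                                    lower.tail = FALSE)),
         marginal_cor = drop(stats::cor(X, y)))
  }
  if (!any(observed_T)) stop("no observed target values to screen")
  out <- list(
    surrogate = screen_one(S, Z, "surrogate"),
    target = screen_one(T_[observed_T], Z[observed_T, , drop = FALSE],
                        "target"))
  class(out) <- "association_screen"
  out
}

#' @export
print.association_screen <- function(x, ...) {
  for (s in x) {
    cat(sprintf("%s ~ Z: F(%d, %d) = %.3f, p = %.3g (n = %d)\n",
                s$outcome, s$df[1L], s$df[2L], s$f_statistic, s$p_value,
                s$n))
  }
  invisible(x)
}
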
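#' Covariate specification for the synthetic cohort generator
#'
#' Describes the joint distribution of the baseline covariate matrix `Z`.
#' The default emulates a perioperative cardiac-surgery cohort with ten
#' predictors of acute kidney injury: eight continuous traits (age, body mass
#' index, baseline haemoglobin, intraoperative urine output, intraoperative
#' fluids, baseline eGFR, maximum intraoperative lactate, length of surgery)
#' and two binary ones (diabetes, emergency surgery). Continuous covariates
#' are generated on a standardized scale; binary covariates are Bernoulli
#' with the stated marginal proportions. Dependence is exchangeable: every
#' pair of latent Gaussian variables shares correlation `correlation`
#' (binary columns are obtained by thresholding their latent variable at the
#' quantile matching the target proportion).
#'
#' @param p_continuous Number of continuous covariates.
#' @param p_binary Number of binary covariates.
#' @param binary_props Marginal success proportions, one per binary
#'   covariate; each must lie strictly inside (0, 1). Defaults are the
#'   cohort proportions of diabetes (1765/4737) and emergency surgery
#'   (315/4737).
#' @param correlation Exchangeable latent correlation in `[0, 1)`.
#' @param standardize If `TRUE`, continuous columns are sample-standardized
#'   to mean 0, SD 1.
#' @return An object of class `"covariate_spec"`.
#' @seealso [generate_covariates()], [simulate_cohort()]
#' @export
covariate_spec <- function(p_continuous = 8L,
                           p_binary = 2L,
                           binary_props = c(1765, 315) / 4737,
                           correlation = 0.2,
                           standardize = TRUE) {
  p_continuous <- as.integer(p_continuous)
  p_binary <- as.integer(p_binary)
  if (p_continuous < 0L || p_binary < 0L || p_continuous + p_binary < 1L)
    stop("need at least one covariate")
  if (p_binary > 0L) {
    if (length(binary_props) != p_binary)
      stop("'binary_props' must have length ", p_binary)
    if (any(binary_props <= 0 | binary_props >= 1))
      stop("binary proportions must lie strictly in (0, 1)")
  } else {
    binary_props <- numeric(0)
  }
  if (correlation < 0 || correlation >= 1)
    stop("'correlation' must lie in [0, 1)")
  structure(
    list(p_continuous = p_continuous, p_binary = p_binary,
         binary_props = as.numeric(binary_props),
         correlation = correlation, standardize = isTRUE(standardize)),
    class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat("Covariate specification:", x$p_continuous, "continuous +",
      x$p_binary, "binary covariates\n")
  if (x$p_binary > 0L)
    cat("  binary proportions:",
        paste(formatC(x$binary_props, digits = 3, format = "f"),
              collapse = ", "), "\n")
  cat("  exchangeable latent correlation:", x$correlation,
      "| standardize continuous:", x$standardize, "\n")
  invisible(x)
}

n_covariates <- function(spec) spec$p_continuous + spec$p_binary

#' Generate a covariate matrix
#'
#' Draws `n` rows from the covariate model described by a
#' [covariate_spec()]. The exchangeable correlation is induced through a
#' one-factor construction: each latent column is
#' `sqrt(rho) * W0 + sqrt(1 - rho) * E_j` with independent standard normal
#' `W0`, `E_j`. Binary columns threshold their latent variable so the
#' marginal success probability is exact.
#'
#' @param n Number of subjects (>= 1).
#' @param spec A [covariate_spec()].
#' @param seed Optional integer seed; identical calls with identical seeds
#'   return identical matrices.
#' @return An `n x p` numeric matrix with columns `z1..zp` (continuous
#'   first, then binary 0/1 columns).
#' @export
generate_covariates <- function(n, spec = covariate_spec(), seed = NULL) {
  if (!inherits(spec, "covariate_spec")) stop("'spec' must be a covariate_spec")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  p <- n_covariates(spec)
  rho <- spec$correlation
  latent <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    w0 <- stats::rnorm(n)
    latent <- sqrt(rho) * w0 + sqrt(1 - rho) * latent
  }
  Z <- latent
  if (spec$p_binary > 0L) {
    for (j in seq_len(spec$p_binary)) {
      col <- spec$p_continuous + j
      Z[, col] <- as.numeric(latent[, col] > stats::qnorm(1 - spec$binary_props[j]))
    }
  }
  if (spec$standardize && spec$p_continuous > 0L && n > 1L) {
    idx <- seq_len(spec$p_continuous)
    Z[, idx] <- scale(Z[, idx, drop = FALSE])
  }
  colnames(Z) <- paste0("z", seq_len(p))
  Z
}

## Population variance of the linear predictor Z %*% slopes under the
## generator's nominal second moments: unit variance for continuous columns,
## p(1-p) for binary ones, exchangeable cross-correlation on that scale.
linear_predictor_variance <- function(slopes, spec) {
  v <- c(rep(1, spec$p_continuous),
         spec$binary_props * (1 - spec$binary_props))
  sd_ <- sqrt(v)
  Sigma <- spec$correlation * outer(sd_, sd_)
  diag(Sigma) <- v
  drop(crossprod(slopes, Sigma %*% slopes))
}

#' Generative parameters for the partial-surrogate outcome model
#'
#' Bundles every parameter of the two-subpopulation outcome model: a latent
#' indicator splits the cohort into an informative subpopulation V, in which
#' the surrogate `S` follows the same linear model as the target `T`, and an
#' uninformative subpopulation I, in which `S` carries no (or scrambled)
#' information about `T`.
#'
#' Default slope vectors are the fitted cohort coefficients of the
#' two-component mixture on standardized covariates (informative column
#' `beta_V`, attenuated column `beta_I`); the default mixing proportion is
#' the cohort's modal share of the informative subpopulation, 728/4737.
#' Because the residual scales of the clinical fit are not published,
#' `sigma_V` defaults to the value giving the informative model a signal
#' fraction of `signal_r2` against `Var(Z beta_V)` under the covariate
#' model, with `signal_r2 = 0.9` chosen so that a cohort-scale mixture fit
#' reproduces the reported separation (relative entropy near 0.6);
#' `sigma_I = 2 * sigma_V`.
#'
#' @param spec A [covariate_spec()]; used to size default vectors and to
#'   compute the default residual scales.
#' @param beta_V Coefficient vector of the informative (V) outcome model,
#'   intercept first, length `p + 1`.
#' @param beta_I_intercept Intercept of the uninformative (I) surrogate
#'   model used by scenario `"sim1"`.
#' @param sigma_V,sigma_I Positive residual SDs of the V and I models.
#' @param beta_T_intercept,beta_T_slopes Intercept and slopes of the
#'   target-given-covariates model used by the `"theory"` scenario.
#' @param signal_r2 Signal fraction of the informative model, used only to
#'   derive the default `sigma_V`: residual variance is set to
#'   `Var(Z beta_V) * (1 - signal_r2) / signal_r2`. The default 0.9
#'   calibrates the generator to the separation reported for the clinical
#'   fit (a two-component mixture fitted to a cohort-scale draw attains
#'   relative entropy near 0.6).
#' @param mixing_prop Marginal probability of membership in V, in `[0, 1]`.
#' @param membership_mode `"random"` (i.i.d. Bernoulli) or
#'   `"covariate_dependent"` (inverse-logit in `Z`, intercept solved so the
#'   marginal probability equals `mixing_prop`).
#' @param membership_slopes Logit slopes on `Z`; required when
#'   `membership_mode = "covariate_dependent"`.
#' @param beta_R_sd SD of the random I-model slopes redrawn per replication
#'   in scenario `"sim1"`.
#' @param target_mean,target_sd Sample mean and SD that the realized target
#'   vector is affinely rescaled to (defaults 0 and 50, the scale of 90-day
#'   eGFR change).
#' @return An object of class `"generative_params"`.
#' @export
generative_params <- function(spec = covariate_spec(),
                              beta_V = NULL,
                              beta_I_intercept = 0,
                              sigma_V = NULL,
                              sigma_I = NULL,
                              beta_T_intercept = 0,
                              beta_T_slopes = NULL,
                              signal_r2 = 0.9,
                              mixing_prop = 728 / 4737,
                              membership_mode = c("random", "covariate_dependent"),
                              membership_slopes = NULL,
                              beta_R_sd = 0.176,
                              target_mean = 0,
                              target_sd = 50) {
  if (!inherits(spec, "covariate_spec")) stop("'spec' must be a covariate_spec")
  membership_mode <- match.arg(membership_mode)
  p <- n_covariates(spec)
  if (is.null(beta_V)) {
    if (p == 10L) {
      ## informative-component slopes of the cohort mixture fit, ordered
      ## BMI, urine output, fluids, age, baseline eGFR, haemoglobin,
      ## lactate, surgery length | diabetes, emergency surgery
      beta_V <- c(0, 0.25, -0.147, -0.134, 0.213, 0.388, -0.253, 0.206,
                  0.193, -0.109, 0.05)
    } else {
      beta_V <- c(0, rep_len(c(0.3, -0.2, 0.25, -0.15), p))
    }
  }
  if (length(beta_V) != p + 1L)
    stop("'beta_V' must have length p + 1 (intercept first)")
  if (is.null(beta_T_slopes)) beta_T_slopes <- beta_V[-1L]
  if (length(beta_T_slopes) != p) stop("'beta_T_slopes' must have length p")
  if (is.null(sigma_V)) {
    if (signal_r2 <= 0 || signal_r2 >= 1) stop("'signal_r2' must lie in (0, 1)")
    sigma_V <- sqrt(linear_predictor_variance(beta_V[-1L], spec) *
                      (1 - signal_r2) / signal_r2)
  }
  if (is.null(sigma_I)) sigma_I <- 2 * sigma_V
  if (sigma_V <= 0 || sigma_I <= 0) stop("residual SDs must be positive")
  if (mixing_prop < 0 || mixing_prop > 1) stop("'mixing_prop' must lie in [0, 1]")
  if (target_sd <= 0) stop("'target_sd' must be positive")
  if (membership_mode == "covariate_dependent" && is.null(membership_slopes))
    stop("'membership_slopes' required in covariate_dependent mode")
  if (!is.null(membership_slopes) && length(membership_slopes) != p)
    stop("'membership_slopes' must have length p")
  structure(
    list(beta_V = as.numeric(beta_V),
         beta_I_intercept = beta_I_intercept,
         sigma_V = sigma_V, sigma_I = sigma_I,
         beta_T_intercept = beta_T_intercept,
         beta_T_slopes = as.numeric(beta_T_slopes),
         mixing_prop = mixing_prop,
         membership_mode = membership_mode,
         membership_slopes = membership_slopes,
         beta_R_sd = beta_R_sd,
         target_mean = target_mean, target_sd = target_sd),
    class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Partial-surrogate generative parameters\n")
  cat("  p =", length(x$beta_T_slopes),
      "| mixing P(V) =", signif(x$mixing_prop, 4),
      "(", x$membership_mode, ")\n")
  cat("  sigma_V =", signif(x$sigma_V, 4),
      "| sigma_I =", signif(x$sigma_I, 4),
      "| target scale:", x$target_mean, "+/-", x$target_sd, "\n")
  invisible(x)
}

## Solve the logit intercept a so that mean(plogis(a + offset)) == target.
solve_logit_intercept <- function(offset, target) {
  if (target <= 0 || target >= 1)
    stop("marginal probability must be interior to (0, 1) for root finding")
  f <- function(a) mean(stats::plogis(a + offset)) - target
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-12)$root
}

#' Draw latent subpopulation membership
#'
#' Assigns each subject to the informative subpopulation `"V"` or the
#' uninformative one `"I"`. In `"random"` mode the labels are i.i.d.
#' Bernoulli(`mixing_prop`). In `"covariate_dependent"` mode the per-subject
#' probability is `plogis(a + Z %*% membership_slopes)` with the intercept
#' `a` solved numerically so that the sample-average probability equals
#' `mixing_prop`.
#'
#' @param Z Covariate matrix.
#' @param params A [generative_params()].
#' @param seed Optional integer seed.
#' @return Character vector of `"V"`/`"I"` labels, length `nrow(Z)`.
#' @export
generate_membership <- function(Z, params, seed = NULL) {
  if (!inherits(params, "generative_params"))
    stop("'params' must be a generative_params")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Z)
  pv <- params$mixing_prop
  if (pv == 0) return(rep("I", n))
  if (pv == 1) return(rep("V", n))
  prob <- if (params$membership_mode == "random") {
    rep(pv, n)
  } else {
    if (is.null(params$membership_slopes))
      stop("'membership_slopes' required in covariate_dependent mode")
    offset <- drop(Z %*% params$membership_slopes)
    stats::plogis(solve_logit_intercept(offset, pv) + offset)
  }
  ifelse(stats::rbinom(n, 1L, prob) == 1L, "V", "I")
}

#' Generate surrogate and target outcomes
#'
#' Draws the surrogate `S` and target `T` under the partial-surrogate model,
#' given covariates and latent membership labels.
#'
#' All scenarios share the target model: `T | Z ~ N(Z beta, sigma)` with the
#' informative coefficients for every subject, after which the realized `T`
#' is affinely rescaled to sample mean `target_mean` and SD `target_sd`
#' exactly. The scenarios differ in the surrogate:
#' \describe{
#'   \item{`"sim1"`}{V-subjects: `S | Z, V ~ N(Z beta_V, sigma_V)` (same
#'     model as `T`, fresh noise). I-subjects: `S` follows an alternative
#'     linear model whose slopes are redrawn once per call from
#'     `N(0, beta_R_sd)` (returned as `beta_R`), with intercept
#'     `beta_I_intercept` and residual SD `sigma_I`.}
#'   \item{`"sim2"`}{V-subjects as in `"sim1"`; I-subjects:
#'     `S | Z, I ~ N(0, sigma_I)` — covariate-free noise.}
#'   \item{`"theory"`}{The stylized model in which the target equals the
#'     surrogate plus error in V. `S ~ N(0, sigma_I)` for all subjects
#'     (so its marginal is identical across subpopulations);
#'     `T = S + N(0, sigma_V)` for V-subjects and
#'     `T = beta_T_intercept + Z beta_T_slopes + N(0, sigma_V)` for
#'     I-subjects. The affine rescaling of `T` is applied to `S` as well,
#'     so the mixture identity
#'     `E[T | S] = P(V) S + (1 - P(V)) E[T]` is preserved on the reported
#'     scale.}
#' }
#'
#' @param Z Covariate matrix.
#' @param labels Character membership labels `"V"`/`"I"` (as produced by
#'   [generate_membership()]).
#' @param params A [generative_params()].
#' @param scenario One of `"sim1"`, `"sim2"`, `"theory"`.
#' @param seed Optional integer seed.
#' @return A list with components `S`, `T` (numeric length-n vectors) and
#'   `beta_R` (the redrawn I-model slopes for `"sim1"`, otherwise `NULL`).
#' @export
generate_outcomes <- function(Z, labels, params,
                              scenario = c("sim1", "sim2", "theory"),
                              seed = NULL) {
  scenario <- match.arg(scenario)
  if (!inherits(params, "generative_params"))
    stop("'params' must be a generative_params")
  n <- nrow(Z)
  if (n < 1L) stop("empty cohort")
  if (length(labels) != n) stop("'labels' and 'Z' are not conformable")
  if (!is.null(seed)) set.seed(seed)
  isV <- labels == "V"
  beta_R <- NULL

  if (scenario == "theory") {
    S <- stats::rnorm(n, 0, params$sigma_I)
    T_ <- numeric(n)
    T_[isV] <- S[isV] + stats::rnorm(sum(isV), 0, params$sigma_V)
    if (any(!isV)) {
      lpT <- params$beta_T_intercept +
        drop(Z[!isV, , drop = FALSE] %*% params$beta_T_slopes)
      T_[!isV] <- lpT + stats::rnorm(sum(!isV), 0, params$sigma_V)
    }
    ## one affine map applied to both T and S keeps T = S + error intact
    mu <- mean(T_); s <- stats::sd(T_)
    if (n < 2L || s == 0) stop("cannot rescale a degenerate target vector")
    a <- params$target_sd / s
    T_ <- (T_ - mu) * a + params$target_mean
    S <- (S - mu) * a + params$target_mean
    return(list(S = S, T = T_, beta_R = NULL))
  }

  lpV <- drop(Z %*% params$beta_V[-1L]) + params$beta_V[1L]
  T_ <- lpV + stats::rnorm(n, 0, params$sigma_V)
  S <- numeric(n)
  S[isV] <- lpV[isV] + stats::rnorm(sum(isV), 0, params$sigma_V)
  if (any(!isV)) {
    nI <- sum(!isV)
    if (scenario == "sim1") {
      beta_R <- stats::rnorm(ncol(Z), 0, params$beta_R_sd)
      lpI <- params$beta_I_intercept +
        drop(Z[!isV, , drop = FALSE] %*% beta_R)
      S[!isV] <- lpI + stats::rnorm(nI, 0, params$sigma_I)
    } else {
      S[!isV] <- stats::rnorm(nI, 0, params$sigma_I)
    }
  }
  mu <- mean(T_); s <- stats::sd(T_)
  if (n < 2L || s == 0) stop("cannot rescale a degenerate target vector")
  T_ <- (T_ - mu) / s * params$target_sd + params$target_mean
  list(S = S, T = T_, beta_R = beta_R)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_covariates()],
#' [generate_membership()] and [generate_outcomes()] into a single cohort
#' data frame. Sub-seeds for the three stages are derived deterministically
#' from `seed`.
#'
#' @param n Number of subjects.
#' @param scenario Outcome scenario, see [generate_outcomes()].
#' @param spec A [covariate_spec()].
#' @param params A [generative_params()].
#' @param seed Optional integer seed.
#' @return A data frame of class `"cohort"` with columns `z1..zp`, `S`,
#'   `T`, `observed_T` (all `TRUE` until [apply_missingness()]) and
#'   `label`; attributes `beta_R` (scenario `"sim1"`), `scenario`, `seed`.
#' @examples
#' coh <- simulate_cohort(500, scenario = "sim2", seed = 1)
#' table(coh$label)
#' @export
simulate_cohort <- function(n, scenario = c("sim1", "sim2", "theory"),
                            spec = covariate_spec(),
                            params = generative_params(spec),
                            seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 3L)
  Z <- generate_covariates(n, spec, seed = seeds[1L])
  labels <- generate_membership(Z, params, seed = seeds[2L])
  out <- generate_outcomes(Z, labels, params, scenario, seed = seeds[3L])
  coh <- data.frame(Z, S = out$S, T = out$T,
                    observed_T = rep(TRUE, n), label = labels)
  attr(coh, "beta_R") <- out$beta_R
  attr(coh, "scenario") <- scenario
  attr(coh, "seed") <- seed
  class(coh) <- c("cohort", "data.frame")
  coh
}

#' Mask the target outcome
#'
#' Updates the `observed_T` mask of a cohort to emulate incomplete follow-up
#' of the target outcome. `"mcar"` masks completely at random; `"mar"`
#' masks with logit-linear dependence on the covariates, the intercept
#' solved numerically so the marginal missingness rate equals `rate`.
#' Simulated target values are retained in the `T` column (they are the
#' generator's ground truth); evaluation functions and [write_cohort()]
#' honour the mask.
#'
#' @param cohort A `"cohort"` data frame.
#' @param mechanism `"mcar"` or `"mar"`.
#' @param rate Marginal missingness proportion in `[0, 1]`.
#' @param mar_slopes Logit slopes on `Z` (required for `"mar"`).
#' @param seed Optional integer seed.
#' @return The cohort with its `observed_T` column updated.
#' @export
apply_missingness <- function(cohort, mechanism = c("mcar", "mar"),
                              rate, mar_slopes = NULL, seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate > 1) stop("'rate' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  Z <- cohort_covariates(cohort)
  miss <- if (rate == 0) {
    rep(FALSE, n)
  } else if (rate == 1) {
    rep(TRUE, n)
  } else if (mechanism == "mcar") {
    stats::runif(n) < rate
  } else {
    if (is.null(mar_slopes)) stop("'mar_slopes' required for mechanism 'mar'")
    if (length(mar_slopes) != ncol(Z)) stop("'mar_slopes' must have length p")
    offset <- drop(Z %*% mar_slopes)
    prob <- stats::plogis(solve_logit_intercept(offset, rate) + offset)
    stats::rbinom(n, 1L, prob) == 1L
  }
  cohort$observed_T <- !miss
  cohort
}

#' Extract the covariate matrix from a cohort
#'
#' @param cohort A `"cohort"` data frame (or any data frame with `z*`
#'   covariate columns).
#' @return The `n x p` numeric covariate matrix.
#' @export
cohort_covariates <- function(cohort) {
  zc <- grep("^z[0-9]+$", names(cohort), value = TRUE)
  if (length(zc) == 0L) stop("no covariate columns (z1..zp) found")
  as.matrix(cohort[zc])
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes a CSV with header `z1..zp,S,T,observed_T,label`;
#' target values of unobserved subjects are written as empty fields.
#' `read_cohort()` reads such a file back, reconstructing the mask from the
#' empty fields when an `observed_T` column is absent.
#'
#' @param cohort A `"cohort"` data frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `"cohort"` data frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$T[!out$observed_T] <- NA
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("S", "T") %in% names(coh)))
    stop("cohort file must contain columns 'S' and 'T'")
  if (is.null(coh$observed_T)) coh$observed_T <- !is.na(coh$T)
  coh$observed_T <- as.logical(coh$observed_T)
  class(coh) <- c("cohort", "data.frame")
  coh
}
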
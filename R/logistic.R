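#' Fit a binomial logistic regression for sex estimation
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (Newton–Raphson on the log-likelihood). By default females are coded 1, so
#' the fitted equation returns P(Female) directly,
#' \eqn{P_1 = 1 / (1 + e^{-(b_0 + b_1 x_1 + \dots + b_n x_n)})}, and
#' P(Male) = 1 − P(Female); the coding is recorded in the model and can be
#' flipped.
#'
#' Convergence is declared when the largest coefficient step falls below
#' `1e-8` or the relative log-likelihood change falls below `1e-10`, within
#' 100 iterations. (Quasi-)complete separation — common for strongly
#' dimorphic single measurements — is detected as any fitted |linear
#' predictor| exceeding 30 across the sample; the fit then stops with
#' `converged = FALSE` and a warning rather than drifting to numerically
#' meaningless coefficients, and the sign of the linear predictor remains
#' usable for classification.
#'
#' @param sample a [reference_sample()].
#' @param variables measurement names to use (default: all in the sample).
#' @param coded_one_sex which sex is coded 1 (default `"F"`).
#' @return An object of class `logr_sex_model` with elements `variables`,
#'   `coefficients`, `intercept`, `coded_one_sex`, `log_likelihood`, `aic`
#'   (counting the intercept as a parameter), `n`, `converged`, `iterations`,
#'   `vcov` (observed-information covariance of (intercept, coefficients))
#'   and `metadata`.
#' @examples
#' s <- generate_reference_sample(default_population(), seed = 1)
#' m <- fit_logr(s, "head_diameter")
#' odds_ratios(m)
#' @export
fit_logr <- function(sample, variables = sample$variables,
                     coded_one_sex = c("F", "M")) {
  stopifnot(inherits(sample, "reference_sample"))
  coded_one_sex <- match.arg(coded_one_sex)
  x <- measurement_matrix(sample, variables)
  y <- as.numeric(sample$data$sex == coded_one_sex)
  if (sum(y) < 1L || sum(1 - y) < 1L) stop("need at least 1 record per sex")
  constant <- apply(x, 2L, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    stop("variable(s) constant across the sample: ",
         paste(variables[constant], collapse = ", "))
  }
  fit <- irls_logistic(cbind(`(intercept)` = 1, x), y)
  k <- length(variables) + 1L

  structure(list(
    variables = variables,
    coefficients = stats::setNames(fit$beta[-1L], variables),
    intercept = fit$beta[[1L]],
    coded_one_sex = coded_one_sex,
    log_likelihood = fit$loglik,
    aic = 2 * k - 2 * fit$loglik,
    n = length(y),
    n_F = sample$n_F, n_M = sample$n_M,
    converged = fit$converged,
    iterations = fit$iterations,
    separated = fit$separated,
    vcov = fit$vcov,
    metadata = list(link = "logit", estimator = "ML (IRLS)")),
    class = "logr_sex_model")
}

# Newton-Raphson/IRLS core. X includes the intercept column.
irls_logistic <- function(X, y, max_iter = 100L,
                          tol_step = 1e-8, tol_loglik = 1e-10) {
  beta <- rep(0, ncol(X))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    # log(1 + e^eta) computed stably for large |eta|
    log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    sum(y * eta - log1pe)
  }
  ll_old <- loglik(beta)
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)              # guard against exactly flat weights
    XtWX <- crossprod(X, X * w)
    if (rcond(XtWX) < 1e-14) {
      stop("information matrix is (near-)singular; collinear predictors")
    }
    step <- solve(XtWX, crossprod(X, y - p))
    beta <- beta + drop(step)
    ll_new <- loglik(beta)
    eta_new <- drop(X %*% beta)
    if (any(abs(eta_new) > 30)) {
      separated <- TRUE
      warning("(quasi-)complete separation detected: |linear predictor| > 30; ",
              "coefficients are not maximum-likelihood estimates",
              call. = FALSE)
      break
    }
    if (max(abs(step)) < tol_step ||
        abs(ll_new - ll_old) < tol_loglik * (abs(ll_old) + tol_loglik)) {
      converged <- TRUE
      break
    }
    ll_old <- ll_new
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  vcov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
  if (!is.null(vcov)) dimnames(vcov) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(drop(beta), colnames(X)),
       loglik = loglik(beta), converged = converged && !separated,
       separated = separated, iterations = iter, vcov = vcov)
}

#' Predicted sex probabilities from a logistic model
#'
#' @param model a `logr_sex_model`.
#' @param measurements named numeric vector, or matrix/data.frame with the
#'   model variables as columns.
#' @return A matrix with columns `P_F` and `P_M`; rows sum to 1 exactly
#'   (the complement rule P0 = 1 − P1).
#' @export
predict_prob <- function(model, measurements) {
  stopifnot(inherits(model, "logr_sex_model"))
  x <- coerce_measurements(measurements, model$variables)
  eta <- drop(x %*% model$coefficients) + model$intercept
  p1 <- stats::plogis(eta)
  if (model$coded_one_sex == "F") {
    cbind(P_F = p1, P_M = 1 - p1)
  } else {
    cbind(P_F = 1 - p1, P_M = p1)
  }
}

#' Odds ratios of a logistic model
#'
#' \eqn{OR_i = e^{b_i}}: the multiplicative change in the odds of the
#' coded-1 sex per mm of the predictor. An OR of 1 is no effect.
#'
#' @param model a `logr_sex_model`.
#' @return Named numeric vector of odds ratios.
#' @export
odds_ratios <- function(model) {
  stopifnot(inherits(model, "logr_sex_model"))
  exp(model$coefficients)
}

#' Classify by logistic probability at a decision probability
#'
#' As [classify_lda()], but on the directly predicted probabilities: the sex
#' with the larger probability is assigned when that probability reaches the
#' decision level, otherwise `indeterminate`.
#'
#' @inheritParams classify_lda
#' @param model a `logr_sex_model`.
#' @return A data.frame with columns `P_F`, `P_M`, `label`, `probability`.
#' @export
classify_logr <- function(model, measurements, decision_probability = 0.5) {
  check_decision_probability(decision_probability)
  post <- predict_prob(model, measurements)
  finalize_classification(NULL, post, decision_probability)
}

#' @export
print.logr_sex_model <- function(x, digits = 4, ...) {
  cat("Binomial logistic sex model (", x$coded_one_sex, " coded 1)\n", sep = "")
  coefs <- c(`(intercept)` = x$intercept, x$coefficients)
  print(round(coefs, digits))
  cat("  odds ratios: ",
      paste(sprintf("%s %.4g", x$variables, odds_ratios(x)), collapse = ", "),
      "\n", sep = "")
  cat("  logLik ", format(x$log_likelihood, digits = digits),
      ", AIC ", format(x$aic, digits = digits),
      ", n = ", x$n, ", converged: ", x$converged,
      " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}
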
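#' Fit a two-group linear discriminant function for sex estimation
#'
#' Fisher's two-group linear discriminant on a standardized score axis. The
#' direction is the classical \eqn{\Sigma_w^{-1}(\mu_M - \mu_F)} (pooled
#' within-group covariance, divisor \eqn{n_F + n_M - 2}), rescaled so that the
#' pooled within-group variance of the discriminant score is exactly 1, and
#' shifted so that the midpoint of the two group score means is 0. Males score
#' positive, so with equal priors the classical sign rule applies:
#' female < 0 < male. The standardized axis is what makes score cutoffs
#' (including bootstrap PMarks, see [compute_pmarks()]) comparable across
#' refits.
#'
#' @param sample a [reference_sample()].
#' @param variables measurement names to use (default: all in the sample).
#' @param priors prior probabilities, either `"equal"` (uninformative, the
#'   default) or a named numeric vector `c(F = , M = )` summing to 1.
#' @return An object of class `lda_sex_model` with elements `variables`,
#'   `coefficients`, `intercept`, `score_mean_F`, `score_mean_M`, `priors`,
#'   `n_F`, `n_M` and `metadata`.
#' @examples
#' spec <- default_population()
#' s <- generate_reference_sample(spec, seed = 1)
#' m <- fit_lda(s, c("head_diameter", "epicondylar_breadth"))
#' discriminant_score(m, c(head_diameter = 45, epicondylar_breadth = 60))
#' @export
fit_lda <- function(sample, variables = sample$variables, priors = "equal") {
  stopifnot(inherits(sample, "reference_sample"))
  if (sample$n_F < 2L || sample$n_M < 2L) {
    stop("need at least 2 records per sex to fit (have ",
         sample$n_F, " F, ", sample$n_M, " M)")
  }
  priors <- normalize_priors(priors)
  x <- measurement_matrix(sample, variables)
  sex <- sample$data$sex
  xF <- x[sex == "F", , drop = FALSE]
  xM <- x[sex == "M", , drop = FALSE]
  mu_F <- colMeans(xF)
  mu_M <- colMeans(xM)
  n_F <- nrow(xF); n_M <- nrow(xM)

  # pooled within-group covariance, divisor n - 2
  ssF <- crossprod(sweep(xF, 2L, mu_F))
  ssM <- crossprod(sweep(xM, 2L, mu_M))
  S_w <- (ssF + ssM) / (n_F + n_M - 2L)

  if (rcond(S_w) < 1e-12) {
    stop("pooled within-group covariance is (near-)singular; ",
         "variables are collinear or constant")
  }
  delta <- mu_M - mu_F
  a <- solve(S_w, delta)
  within_var <- drop(crossprod(a, S_w %*% a))  # = t(delta) %*% solve(S_w) %*% delta
  if (within_var <= 0) stop("degenerate fit: zero between-group separation")
  b <- a / sqrt(within_var)                    # unit pooled within-group score variance

  midpoint <- (mu_F + mu_M) / 2
  b0 <- -drop(crossprod(b, midpoint))
  score_mean_M <- drop(crossprod(b, mu_M)) + b0
  score_mean_F <- drop(crossprod(b, mu_F)) + b0

  structure(list(
    variables = variables,
    coefficients = stats::setNames(as.numeric(b), variables),
    intercept = b0,
    score_mean_F = score_mean_F,
    score_mean_M = score_mean_M,
    priors = priors,
    n_F = n_F, n_M = n_M,
    metadata = list(scaling = "unit pooled within-group score variance",
                    intercept_convention = "midpoint of group score means at 0",
                    covariance_divisor = "n_F + n_M - 2")),
    class = "lda_sex_model")
}

normalize_priors <- function(priors) {
  if (identical(priors, "equal")) return(c(F = 0.5, M = 0.5))
  if (!is.numeric(priors) || length(priors) != 2L ||
      !setequal(names(priors), c("F", "M"))) {
    stop("priors must be \"equal\" or a named numeric vector c(F = , M = )")
  }
  priors <- priors[c("F", "M")]
  if (any(priors <= 0) || abs(sum(priors) - 1) > 1e-8) {
    stop("priors must be positive and sum to 1")
  }
  priors
}

#' Compute a discriminant score
#'
#' Evaluates \eqn{D = b_0 + b_1 x_1 + \dots + b_n x_n} for one individual or a
#' matrix of individuals.
#'
#' @param model an `lda_sex_model`.
#' @param measurements named numeric vector, or a numeric matrix/data.frame
#'   with the model variables as columns.
#' @return Numeric score(s).
#' @export
discriminant_score <- function(model, measurements) {
  stopifnot(inherits(model, "lda_sex_model"))
  x <- coerce_measurements(measurements, model$variables)
  drop(x %*% model$coefficients) + model$intercept
}

coerce_measurements <- function(measurements, variables) {
  if (is.data.frame(measurements)) measurements <- as.matrix(measurements)
  if (is.null(dim(measurements))) {
    missing_vars <- setdiff(variables, names(measurements))
    if (length(missing_vars) > 0L) {
      stop("missing variable(s): ", paste(missing_vars, collapse = ", "))
    }
    measurements <- matrix(measurements[variables], nrow = 1L,
                           dimnames = list(NULL, variables))
  } else {
    missing_vars <- setdiff(variables, colnames(measurements))
    if (length(missing_vars) > 0L) {
      stop("missing variable(s): ", paste(missing_vars, collapse = ", "))
    }
    measurements <- measurements[, variables, drop = FALSE]
  }
  storage.mode(measurements) <- "double"
  measurements
}

#' Plug-in posterior probabilities from a discriminant score
#'
#' On the standardized score axis the two sexes have unit-variance normal
#' score distributions centred at the group score means, so Bayes' rule with
#' the model priors gives
#' \eqn{P(M \mid D) \propto \pi_M \phi(D - \bar{D}_M)} and
#' \eqn{P(F \mid D) \propto \pi_F \phi(D - \bar{D}_F)}. With equal priors this
#' reduces to a logistic function of the score with slope equal to the
#' separation of the group score means.
#'
#' @param model an `lda_sex_model` with fitted score means.
#' @param score numeric vector of discriminant scores.
#' @return A matrix with columns `P_F` and `P_M` (rows sum to 1).
#' @export
lda_posterior <- function(model, score) {
  stopifnot(inherits(model, "lda_sex_model"))
  if (is.na(model$score_mean_F) || is.na(model$score_mean_M)) {
    stop("model carries no fitted score means; posterior probabilities ",
         "require the reference data (equation-only models support only ",
         "the sign rule and PMark classification)")
  }
  pr <- model$priors
  if (abs(sum(pr) - 1) > 1e-8) stop("priors must sum to 1")
  # work on the log scale for numerical stability far from the means
  lF <- log(pr[["F"]]) + stats::dnorm(score, model$score_mean_F, 1, log = TRUE)
  lM <- log(pr[["M"]]) + stats::dnorm(score, model$score_mean_M, 1, log = TRUE)
  p_M <- 1 / (1 + exp(lF - lM))
  cbind(P_F = 1 - p_M, P_M = p_M)
}

#' Score cutoff at a given posterior-probability level
#'
#' Analytic inversion of the plug-in posterior: the discriminant score at
#' which `P(sex | D)` equals `p`. Under equal priors and the midpoint-centred
#' intercept the male cutoff is
#' \eqn{\ln(p/(1-p)) / (\bar{D}_M - \bar{D}_F)} and the female cutoff is its
#' negative; with unequal priors the prior log-odds shift is included.
#'
#' @param model an `lda_sex_model`.
#' @param p posterior probability level in (0, 1).
#' @param sex `"M"` or `"F"`: which sex's posterior is set to `p`.
#' @return The score (a single number).
#' @export
score_at_posterior <- function(model, p, sex = c("M", "F")) {
  sex <- match.arg(sex)
  stopifnot(p > 0, p < 1)
  mF <- model$score_mean_F; mM <- model$score_mean_M
  if (is.na(mF) || is.na(mM)) stop("model carries no fitted score means")
  pr <- model$priors
  # log(P_M/P_F) = log(pi_M/pi_F) + (mM - mF) D - (mM^2 - mF^2)/2
  target <- if (sex == "M") log(p / (1 - p)) else -log(p / (1 - p))
  (target - log(pr[["M"]] / pr[["F"]]) + (mM^2 - mF^2) / 2) / (mM - mF)
}

#' Classify by discriminant posterior at a decision probability
#'
#' The label of the sex with the larger posterior is returned when that
#' posterior reaches the decision probability, otherwise `indeterminate`. At
#' decision probability 0.5 (and equal priors) this is exactly the classical
#' sign-of-score rule, female < 0 < male.
#'
#' @param model an `lda_sex_model`.
#' @param measurements as in [discriminant_score()].
#' @param decision_probability minimum posterior required to assign a sex; in
#'   \[0.5, 1).
#' @return A data.frame with columns `score`, `P_F`, `P_M`, `label` (factor
#'   F / M / indeterminate) and `probability` (the winning posterior).
#' @export
classify_lda <- function(model, measurements, decision_probability = 0.5) {
  check_decision_probability(decision_probability)
  score <- discriminant_score(model, measurements)
  post <- lda_posterior(model, score)
  finalize_classification(score, post, decision_probability)
}

check_decision_probability <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 0.5 || p >= 1) {
    stop("decision_probability must be in [0.5, 1)")
  }
}

finalize_classification <- function(score, post, decision_probability) {
  winner <- ifelse(post[, "P_M"] >= post[, "P_F"], "M", "F")
  prob <- pmax(post[, "P_M"], post[, "P_F"])
  label <- ifelse(prob >= decision_probability, winner, "indeterminate")
  out <- data.frame(P_F = post[, "P_F"], P_M = post[, "P_M"],
                    label = factor(label, levels = c("F", "M", "indeterminate")),
                    probability = prob)
  if (!is.null(score)) out <- cbind(data.frame(score = score), out)
  rownames(out) <- NULL
  out
}

#' @export
print.lda_sex_model <- function(x, digits = 4, ...) {
  cat("Linear discriminant sex model (standardized score axis)\n")
  eq <- paste(sprintf("%.*g x %s", digits, x$coefficients, x$variables),
              collapse = " + ")
  cat("  D = ", eq, " ", ifelse(x$intercept < 0, "- ", "+ "),
      format(abs(x$intercept), digits = digits), "\n", sep = "")
  cat("  group score means: F ", format(x$score_mean_F, digits = digits),
      ", M ", format(x$score_mean_M, digits = digits), "\n", sep = "")
  cat("  priors: F ", x$priors[["F"]], ", M ", x$priors[["M"]],
      "; n = ", x$n_F, " F / ", x$n_M, " M\n", sep = "")
  cat("  classical cutoff at score 0 (female < 0 < male)\n")
  invisible(x)
}
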
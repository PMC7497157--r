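#' Variance inflation factors
#'
#' VIF_j = 1 / (1 − R²_j), from regressing measurement j on the other
#' measurements with sexes pooled. Values near 1 indicate no
#' multicollinearity.
#'
#' @param sample a [reference_sample()].
#' @param variables measurement names (at least 2).
#' @return Named numeric vector of VIFs (each ≥ 1).
#' @export
vif <- function(sample, variables = sample$variables) {
  stopifnot(inherits(sample, "reference_sample"))
  if (length(variables) < 2L) stop("VIF needs at least 2 variables")
  x <- as.data.frame(measurement_matrix(sample, variables))
  if (nrow(x) < length(variables) + 2L) stop("too few records")
  if (qr(cbind(1, as.matrix(x)))$rank < length(variables) + 1L) {
    stop("design matrix is rank deficient")
  }
  out <- vapply(variables, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(variables, v), response = v),
                     data = x)
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1L))
  out
}

#' Box's M test for homogeneity of covariance matrices
#'
#' Tests whether the per-sex covariance matrices can be pooled, using the
#' standard chi-square approximation:
#' \eqn{M = (n-k)\ln|S_p| - \sum_g (n_g-1)\ln|S_g|}, scaled by the Box
#' correction factor, referred to \eqn{\chi^2} with
#' df = (k−1)·p·(p+1)/2.
#'
#' @param sample a [reference_sample()].
#' @param variables measurement names.
#' @return A list: `M`, `chi_sq`, `df`, `p`.
#' @export
box_m <- function(sample, variables = sample$variables) {
  stopifnot(inherits(sample, "reference_sample"))
  x <- measurement_matrix(sample, variables)
  sex <- sample$data$sex
  groups <- split.data.frame(x, sex)
  k <- length(groups)
  p <- ncol(x)
  n_g <- vapply(groups, nrow, integer(1L))
  if (any(n_g <= p)) stop("each group needs more records than variables")
  S_g <- lapply(groups, stats::cov)
  if (any(vapply(S_g, function(s) rcond(s) < 1e-12, logical(1L)))) {
    stop("singular group covariance matrix")
  }
  n <- sum(n_g)
  S_p <- Reduce(`+`, Map(function(s, ng) (ng - 1L) * s, S_g, n_g)) / (n - k)
  M <- (n - k) * determinant(S_p, logarithm = TRUE)$modulus -
    sum((n_g - 1L) * vapply(S_g, function(s) {
      as.numeric(determinant(s, logarithm = TRUE)$modulus)
    }, numeric(1L)))
  M <- as.numeric(M)
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1)) *
    (sum(1 / (n_g - 1L)) - 1 / (n - k))
  chi_sq <- M * (1 - c1)
  df <- (k - 1) * p * (p + 1) / 2
  list(M = M, chi_sq = chi_sq, df = df,
       p = stats::pchisq(chi_sq, df, lower.tail = FALSE))
}

#' Mahalanobis-distance outlier screen
#'
#' Squared Mahalanobis distances of every individual to the multivariate
#' mean, compared against the \eqn{\chi^2_p} quantile. Reported both pooled
#' (all individuals against the overall mean and covariance) and within each
#' sex (against that sex's own mean and covariance); the classical
#' (non-robust) estimator is used.
#'
#' @param sample a [reference_sample()].
#' @param variables measurement names.
#' @param quantile chi-square quantile for flagging (default 0.975).
#' @return A list with data.frames `pooled` and `by_sex` (columns id, sex,
#'   distance = squared Mahalanobis distance, flagged), and `cutoff`
#'   (the chi-square quantile value).
#' @export
mahalanobis_outliers <- function(sample, variables = sample$variables,
                                 quantile = 0.975) {
  stopifnot(inherits(sample, "reference_sample"))
  x <- measurement_matrix(sample, variables)
  sex <- as.character(sample$data$sex)
  cutoff <- stats::qchisq(quantile, df = ncol(x))

  dist_for <- function(xs) {
    S <- stats::cov(xs)
    if (rcond(S) < 1e-12) stop("singular covariance matrix")
    stats::mahalanobis(xs, colMeans(xs), S)
  }
  pooled <- data.frame(id = rownames(x), sex = sex,
                       distance = dist_for(x), stringsAsFactors = FALSE)
  pooled$flagged <- pooled$distance > cutoff

  by_sex <- do.call(rbind, lapply(split.data.frame(x, sex), function(xs) {
    data.frame(id = rownames(xs), distance = dist_for(xs),
               stringsAsFactors = FALSE)
  }))
  by_sex$sex <- sex[match(by_sex$id, rownames(x))]
  by_sex$flagged <- by_sex$distance > cutoff
  rownames(pooled) <- rownames(by_sex) <- NULL
  list(pooled = pooled, by_sex = by_sex[, c("id", "sex", "distance", "flagged")],
       cutoff = cutoff, quantile = quantile)
}

#' Logit-linearity check (Box–Tidwell-style)
#'
#' Tests linearity between the logit of sex and each measurement by fitting
#' a logistic regression augmented, for every measurement x, with the
#' interaction term x·ln(x); a significant interaction indicates a
#' non-linear logit. By default all interaction terms enter one joint model;
#' `joint = FALSE` tests one variable at a time.
#'
#' @param sample a [reference_sample()].
#' @param variables measurement names (all values must be positive).
#' @param joint single augmented model (default) or per-variable models.
#' @param coded_one_sex logistic coding, see [fit_logr()].
#' @return A data.frame with one row per variable: `z` (Wald statistic of
#'   the x·ln(x) term) and `p`.
#' @export
logit_linearity <- function(sample, variables = sample$variables,
                            joint = TRUE, coded_one_sex = "F") {
  stopifnot(inherits(sample, "reference_sample"))
  x <- measurement_matrix(sample, variables)
  if (any(x <= 0)) stop("all measurements must be positive for the log term")
  constant <- apply(x, 2L, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    stop("variable(s) constant across the sample (log term collinear ",
         "with the intercept): ",
         paste(variables[constant], collapse = ", "))
  }
  y <- as.numeric(sample$data$sex == coded_one_sex)
  inter <- x * log(x)
  colnames(inter) <- paste0(variables, ":log")

  wald_for <- function(X, terms) {
    fit <- withCallingHandlers(
      irls_logistic(X, y),
      warning = function(w) invokeRestart("muffleWarning"))
    if (fit$separated) {
      warning("separation in the augmented logit-linearity model; ",
              "Wald statistics are unreliable", call. = FALSE)
    }
    if (is.null(fit$vcov)) stop("could not invert the information matrix")
    se <- sqrt(diag(fit$vcov))
    z <- fit$beta / se
    data.frame(variable = sub(":log$", "", terms), z = z[terms],
               p = 2 * stats::pnorm(-abs(z[terms])),
               stringsAsFactors = FALSE)
  }

  out <- if (joint) {
    X <- cbind(`(intercept)` = 1, x, inter)
    wald_for(X, colnames(inter))
  } else {
    do.call(rbind, lapply(seq_along(variables), function(j) {
      X <- cbind(`(intercept)` = 1, x[, j, drop = FALSE],
                 inter[, j, drop = FALSE])
      wald_for(X, colnames(inter)[j])
    }))
  }
  rownames(out) <- NULL
  out
}

#' Run the full assumption screen
#'
#' Bundles [vif()], [box_m()], [mahalanobis_outliers()] and
#' [logit_linearity()] into one report.
#'
#' @inheritParams vif
#' @param quantile outlier cutoff quantile, see [mahalanobis_outliers()].
#' @return An object of class `assumption_report`.
#' @export
check_assumptions <- function(sample, variables = sample$variables,
                              quantile = 0.975) {
  structure(list(
    vif = if (length(variables) >= 2L) vif(sample, variables) else NULL,
    box_m = box_m(sample, variables),
    outliers = mahalanobis_outliers(sample, variables, quantile),
    logit_linearity = logit_linearity(sample, variables),
    variables = variables),
    class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Assumption diagnostics (", paste(x$variables, collapse = ", "), ")\n",
      sep = "")
  if (!is.null(x$vif)) {
    cat("VIF: ", paste(sprintf("%s %.4g", names(x$vif), x$vif),
                       collapse = ", "), "\n", sep = "")
  }
  bm <- x$box_m
  cat(sprintf("Box's M: chi-sq(%d) = %.4f, p = %.4f\n",
              bm$df, bm$chi_sq, bm$p))
  fl <- x$outliers$pooled[x$outliers$pooled$flagged, "id"]
  fl2 <- x$outliers$by_sex[x$outliers$by_sex$flagged, "id"]
  cat("Mahalanobis outliers (pooled): ",
      if (length(fl)) paste(fl, collapse = ", ") else "none",
      "; (within sex): ",
      if (length(fl2)) paste(fl2, collapse = ", ") else "none", "\n", sep = "")
  cat("Logit linearity (x log x Wald tests):\n")
  ll <- x$logit_linearity
  ll$z <- round(ll$z, 3); ll$p <- round(ll$p, 4)
  print(ll, row.names = FALSE)
  invisible(x)
}
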
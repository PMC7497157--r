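#' Leave-one-out cross-validation of a sex-estimation model
#'
#' Each individual is predicted by a model refit on the remaining n − 1, so
#' the reported probabilities and accuracies are out-of-sample. The procedure
#' is deterministic. Accuracy is reported at each requested decision
#' probability: individuals whose winning probability falls below the level
#' are set aside as indeterminate, and accuracy (overall and per sex) is
#' computed among the retained individuals only. The B (Brier-based) and Q
#' (logarithmic) predictive indices are computed from the LOOCV
#' probabilities, so they reward calibration as well as raw accuracy.
#'
#' Logistic folds that hit (quasi-)complete separation are flagged (count in
#' `separated_folds`) but still classified by the sign of the linear
#' predictor.
#'
#' @param sample a [reference_sample()].
#' @param method `"lda"` or `"logr"`.
#' @param variables measurement names to use.
#' @param decision_probabilities vector of decision levels in \[0.5, 1).
#' @param priors LDA priors, see [fit_lda()].
#' @param coded_one_sex logistic coding, see [fit_logr()].
#' @return An object of class `evaluation_report`: list with
#'   `per_individual` (id, true_sex, P_F, P_M, p_true, winning label and
#'   probability, and one label column per decision level), `summary` (one
#'   row per decision level: retained_n, misclassified, accuracy,
#'   accuracy_F, accuracy_M, in percent), `B`, `Q`, `method`, `variables`,
#'   `n`, `separated_folds`.
#' @examples
#' s <- generate_reference_sample(default_population(), seed = 1)
#' loocv(s, "lda", c("head_diameter", "epicondylar_breadth"))
#' @export
loocv <- function(sample, method = c("lda", "logr"),
                  variables = sample$variables,
                  decision_probabilities = c(0.5, 0.8),
                  priors = "equal", coded_one_sex = "F") {
  stopifnot(inherits(sample, "reference_sample"))
  method <- match.arg(method)
  for (p in decision_probabilities) check_decision_probability(p)
  x <- measurement_matrix(sample, variables)
  sex <- as.character(sample$data$sex)
  res <- loocv_probs(x, sex, method, priors = priors,
                     coded_one_sex = coded_one_sex)
  build_report(sample$data$id, sex, res$post, decision_probabilities,
               method, variables, separated_folds = res$separated_folds)
}

# LOOCV probabilities on bare matrices (shared by loocv() and the
# sample-size experiment, where data.frame bookkeeping would dominate).
loocv_probs <- function(x, sex, method, priors = "equal", coded_one_sex = "F") {
  n <- nrow(x)
  post <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("P_F", "P_M")))
  separated_folds <- 0L
  if (method == "lda") {
    priors <- normalize_priors(priors)
    for (i in seq_len(n)) {
      fit <- tryCatch(lda_core(x[-i, , drop = FALSE], sex[-i]),
                      error = function(e) {
                        stop("LOOCV fold ", i, " failed to fit: ",
                             conditionMessage(e), call. = FALSE)
                      })
      d <- drop(x[i, ] %*% fit$b) + fit$b0
      lF <- log(priors[["F"]]) + stats::dnorm(d, fit$mF, 1, log = TRUE)
      lM <- log(priors[["M"]]) + stats::dnorm(d, fit$mM, 1, log = TRUE)
      post[i, 2L] <- 1 / (1 + exp(lF - lM))
      post[i, 1L] <- 1 - post[i, 2L]
    }
  } else {
    y <- as.numeric(sex == coded_one_sex)
    X <- cbind(1, x)
    for (i in seq_len(n)) {
      fit <- withCallingHandlers(
        tryCatch(irls_logistic(X[-i, , drop = FALSE], y[-i]),
                 error = function(e) {
                   stop("LOOCV fold ", i, " failed to fit: ",
                        conditionMessage(e), call. = FALSE)
                 }),
        warning = function(w) invokeRestart("muffleWarning"))
      if (fit$separated) separated_folds <- separated_folds + 1L
      p1 <- stats::plogis(drop(X[i, ] %*% fit$beta))
      if (coded_one_sex == "F") {
        post[i, ] <- c(p1, 1 - p1)
      } else {
        post[i, ] <- c(1 - p1, p1)
      }
    }
  }
  list(post = post, separated_folds = separated_folds)
}

# bare-matrix two-group LDA used by loocv_probs and the bootstrap
lda_core <- function(x, sex) {
  f <- sex == "F"
  xF <- x[f, , drop = FALSE]; xM <- x[!f, , drop = FALSE]
  if (nrow(xF) < 2L || nrow(xM) < 2L) stop("a sex has fewer than 2 records")
  mu_F <- colMeans(xF); mu_M <- colMeans(xM)
  S_w <- (crossprod(sweep(xF, 2L, mu_F)) + crossprod(sweep(xM, 2L, mu_M))) /
    (nrow(x) - 2L)
  if (rcond(S_w) < 1e-12) stop("singular pooled within-group covariance")
  a <- solve(S_w, mu_M - mu_F)
  wv <- drop(crossprod(a, S_w %*% a))
  if (wv <= 0) stop("zero between-group separation")
  b <- a / sqrt(wv)
  b0 <- -drop(crossprod(b, (mu_F + mu_M) / 2))
  list(b = b, b0 = b0,
       mF = drop(crossprod(b, mu_F)) + b0,
       mM = drop(crossprod(b, mu_M)) + b0)
}

build_report <- function(ids, sex, post, decision_probabilities,
                         method, variables, separated_folds = 0L) {
  winner <- ifelse(post[, "P_M"] >= post[, "P_F"], "M", "F")
  prob <- pmax(post[, "P_F"], post[, "P_M"])
  p_true <- ifelse(sex == "F", post[, "P_F"], post[, "P_M"])
  per <- data.frame(id = ids, true_sex = sex,
                    P_F = post[, "P_F"], P_M = post[, "P_M"],
                    p_true = p_true, winner = winner, probability = prob,
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(decision_probabilities, function(dp) {
    retained <- prob >= dp
    lab <- ifelse(retained, winner, "indeterminate")
    per[[paste0("label_", format(dp))]] <<- lab
    acc <- function(mask) {
      m <- mask & retained
      if (sum(m) == 0L) return(NA_real_)
      100 * sum(winner[m] == sex[m]) / sum(m)
    }
    data.frame(decision_probability = dp,
               retained_n = sum(retained),
               misclassified = sum(retained & winner != sex),
               accuracy = acc(rep(TRUE, length(sex))),
               accuracy_F = acc(sex == "F"),
               accuracy_M = acc(sex == "M"))
  }))
  rownames(summ) <- NULL
  # indices use P(F) as the class-1 probability, matching the F = 1 coding;
  # both are invariant to swapping the coding together with P -> 1 - P
  y <- as.numeric(sex == "F")
  structure(list(per_individual = per, summary = summ,
                 B = brier_index(post[, "P_F"], y),
                 Q = q_index(post[, "P_F"], y),
                 method = method, variables = variables,
                 n = length(sex), separated_folds = separated_folds),
            class = "evaluation_report")
}

#' B index (Brier-based predictive index)
#'
#' \eqn{B = 1 - \frac{1}{n}\sum_i (P_i - Y_i)^2}: 1 for perfect confident
#' prediction; uninformative P = 0.5 throughout gives 0.75.
#'
#' @param probabilities predicted probabilities of the class coded 1, in
#'   \[0, 1\].
#' @param outcomes 0/1 outcomes.
#' @return A single number ≤ 1.
#' @export
brier_index <- function(probabilities, outcomes) {
  check_prob_outcomes(probabilities, outcomes)
  1 - mean((probabilities - outcomes)^2)
}

#' Q index (logarithmic predictive index)
#'
#' \eqn{Q = \frac{1}{n}\sum_i (1 + \log_2 P_i^{Y_i}(1-P_i)^{1-Y_i})}: the
#' mean of 1 plus the log2-probability assigned to the true class. 1 for
#' perfect confident prediction, 0 at chance (P = 0.5), negative when worse
#' than chance. Probabilities are clamped to \[1e-15, 1 − 1e-15\] before the
#' logarithm so a single (near-)separated fold cannot drive Q to −Inf.
#'
#' @inheritParams brier_index
#' @return A single number ≤ 1.
#' @export
q_index <- function(probabilities, outcomes) {
  check_prob_outcomes(probabilities, outcomes)
  eps <- 1e-15
  p_true <- ifelse(outcomes == 1, probabilities, 1 - probabilities)
  p_true <- pmin(pmax(p_true, eps), 1 - eps)
  mean(1 + log2(p_true))
}

check_prob_outcomes <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes)) {
    stop("probabilities and outcomes differ in length")
  }
  if (length(outcomes) < 1L) stop("need at least one observation")
  stopifnot(all(probabilities >= 0 & probabilities <= 1),
            all(outcomes %in% c(0, 1)))
}

#' Accuracy among individuals below a probability threshold
#'
#' The complement of threshold-retained accuracy: how well does the plain
#' sign/majority rule do on exactly those individuals whose LOOCV probability
#' never reached the threshold? These are the cases a dichotomous published
#' equation silently classifies anyway.
#'
#' @param report an [loocv()] report.
#' @param threshold probability threshold (default 0.8).
#' @return A list with `n`, `applicable`, `accuracy`, `accuracy_F`,
#'   `accuracy_M` (percent; `NA` and `applicable = FALSE` when no individual
#'   falls below the threshold).
#' @export
subthreshold_accuracy <- function(report, threshold = 0.8) {
  stopifnot(inherits(report, "evaluation_report"))
  per <- report$per_individual
  sub <- per[per$probability < threshold, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(n = 0L, applicable = FALSE, accuracy = NA_real_,
                accuracy_F = NA_real_, accuracy_M = NA_real_))
  }
  acc <- function(mask) {
    if (sum(mask) == 0L) return(NA_real_)
    100 * sum(sub$winner[mask] == sub$true_sex[mask]) / sum(mask)
  }
  list(n = nrow(sub), applicable = TRUE,
       accuracy = acc(rep(TRUE, nrow(sub))),
       accuracy_F = acc(sub$true_sex == "F"),
       accuracy_M = acc(sub$true_sex == "M"))
}

#' Effect of sample size on LOOCV accuracy
#'
#' For each size n in `sizes`, draws subsamples of n individuals with
#' replacement from the reference sample and computes the LOOCV accuracy
#' (decision probability 0.5) within each subsample. Draws in which a sex
#' ends up with fewer than 2 distinct individuals or fewer than 3 records —
#' or whose LOOCV cannot be fit (e.g. a fold with a singular covariance from
#' heavy duplication) — are redrawn; redraws are counted in the result.
#'
#' @param sample a [reference_sample()].
#' @param method `"lda"` or `"logr"`.
#' @param variables measurement names to use.
#' @param sizes subsample sizes (default 10 up to the full sample size).
#' @param replicates_per_size subsamples drawn per size (default 100).
#' @param seed integer seed; the experiment is reproducible given the seed.
#' @return An object of class `sample_size_curve`: list with `per_size`
#'   (data.frame: size, mean_accuracy in percent, sd_accuracy as a
#'   proportion), `accuracies` (size × replicate matrix of proportions),
#'   `mean_accuracy` (percent, over all runs), `sd_accuracy` (proportion
#'   scale), `redraws`.
#' @export
sample_size_experiment <- function(sample, method = c("lda", "logr"),
                                   variables = sample$variables,
                                   sizes = 10:nrow(sample$data),
                                   replicates_per_size = 100L, seed = NULL) {
  stopifnot(inherits(sample, "reference_sample"))
  method <- match.arg(method)
  if (min(sizes) < 6L) stop("sizes below 6 cannot support per-sex LOOCV fitting")
  x <- measurement_matrix(sample, variables)
  sex <- as.character(sample$data$sex)
  n <- nrow(x)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  redraws <- 0L
  acc <- matrix(NA_real_, length(sizes), replicates_per_size)
  for (si in seq_along(sizes)) {
    m <- sizes[si]
    for (r in seq_len(replicates_per_size)) {
      repeat {
        idx <- sample.int(n, m, replace = TRUE)
        s_sex <- sex[idx]
        ok <- ok_subsample(idx, s_sex)
        if (ok) {
          res <- tryCatch(
            loocv_probs(x[idx, , drop = FALSE], s_sex, method),
            error = function(e) NULL)
          if (!is.null(res)) break
        }
        redraws <- redraws + 1L
        if (redraws > 10L * length(sizes) * replicates_per_size) {
          stop("persistent degenerate resampling")
        }
      }
      winner <- ifelse(res$post[, "P_M"] >= res$post[, "P_F"], "M", "F")
      acc[si, r] <- mean(winner == s_sex)
    }
  }
  per_size <- data.frame(size = sizes,
                         mean_accuracy = 100 * rowMeans(acc),
                         sd_accuracy = apply(acc, 1L, stats::sd))
  structure(list(per_size = per_size, accuracies = acc,
                 mean_accuracy = 100 * mean(acc),
                 sd_accuracy = stats::sd(acc),
                 method = method, variables = variables,
                 replicates_per_size = replicates_per_size,
                 seed = seed, redraws = redraws),
            class = "sample_size_curve")
}

ok_subsample <- function(idx, s_sex) {
  f <- s_sex == "F"
  sum(f) >= 3L && sum(!f) >= 3L &&
    length(unique(idx[f])) >= 2L && length(unique(idx[!f])) >= 2L
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Welch two-sample comparison of a measurement between the sexes
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, as implemented in [stats::t.test()]. The difference is reported
#' as M − F, which is positive for the usual direction of skeletal
#' dimorphism.
#'
#' @param sample a [reference_sample()].
#' @param variable one measurement name.
#' @param confidence confidence level for the interval (default 0.90).
#' @return A list: `mean_F`, `mean_M`, `sd_F`, `sd_M`, `difference` (M − F),
#'   `ci` (length-2), `t`, `df`, `p`, `confidence`.
#' @export
welch_mean_difference <- function(sample, variable, confidence = 0.90) {
  stopifnot(inherits(sample, "reference_sample"), length(variable) == 1L)
  x <- measurement_matrix(sample, variable)[, 1L]
  sex <- sample$data$sex
  xF <- x[sex == "F"]; xM <- x[sex == "M"]
  if (length(xF) < 2L || length(xM) < 2L) stop("need at least 2 per sex")
  if (stats::sd(xF) == 0 && stats::sd(xM) == 0) {
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(xM, xF, conf.level = confidence, var.equal = FALSE)
  list(mean_F = mean(xF), mean_M = mean(xM),
       sd_F = stats::sd(xF), sd_M = stats::sd(xM),
       difference = mean(xM) - mean(xF),
       ci = as.numeric(tt$conf.int),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, confidence = confidence)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("LOOCV evaluation (", x$method, " on ",
      paste(x$variables, collapse = " + "), "), n = ", x$n, "\n", sep = "")
  summ <- x$summary
  summ$accuracy <- round(summ$accuracy, 2)
  summ$accuracy_F <- round(summ$accuracy_F, 2)
  summ$accuracy_M <- round(summ$accuracy_M, 2)
  print(summ, row.names = FALSE)
  cat("B index: ", format(round(x$B, 4), nsmall = 4),
      "   Q index: ", format(round(x$Q, 4), nsmall = 4), "\n", sep = "")
  if (x$separated_folds > 0L) {
    cat(x$separated_folds, "logistic fold(s) hit separation;",
        "classified by sign of the linear predictor\n")
  }
  invisible(x)
}

#' @export
print.sample_size_curve <- function(x, ...) {
  cat("Sample-size experiment (", x$method, "), sizes ",
      min(x$per_size$size), "-", max(x$per_size$size), ", ",
      x$replicates_per_size, " replicate(s)/size\n", sep = "")
  cat("overall mean LOOCV accuracy: ",
      round(x$mean_accuracy, 2), "% (SD ",
      round(x$sd_accuracy, 5), " on the proportion scale)\n", sep = "")
  if (x$redraws > 0L) cat(x$redraws, "degenerate draw(s) redrawn\n")
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the per-individual LOOCV table as CSV and the summaries (accuracy
#' strata, B and Q) as JSON.
#'
#' @param report an [loocv()] report.
#' @param csv_path,json_path output paths; `NULL` skips that file.
#' @return Invisibly, the list written to JSON.
#' @export
export_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_individual, csv_path, row.names = FALSE)
  }
  out <- list(method = report$method, variables = report$variables,
              n = report$n, summary = report$summary,
              B = report$B, Q = report$Q,
              separated_folds = report$separated_folds)
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17),
                                dataframe = "rows", pretty = TRUE),
               json_path)
  }
  invisible(out)
}
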
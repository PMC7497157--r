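test_that("1-D fit centres the cutoff at the raw midpoint with males positive", {
  s <- toy_1d()
  m <- fit_lda(s, "x")
  # F at x {1,2,3}, M at {5,6,7}: midpoint 4 must score 0
  expect_equal(discriminant_score(m, c(x = 4)), 0, tolerance = 1e-12)
  expect_gt(m$score_mean_M, 0)
  expect_equal(m$score_mean_F, -m$score_mean_M, tolerance = 1e-12)
  # pooled within-group SS = 2 + 2, divisor n - 2 = 4 -> unit variance,
  # so the coefficient is exactly 1 and D = x - 4
  expect_equal(unname(m$coefficients), 1, tolerance = 1e-12)
  expect_equal(discriminant_score(m, c(x = 6.5)), 2.5, tolerance = 1e-12)
})

test_that("coefficients equal pooled-covariance matrix arithmetic done by hand", {
  s <- toy_2d()
  m <- fit_lda(s, c("a", "b"))
  x <- as.matrix(s$data[, c("a", "b")])
  xF <- x[s$data$sex == "F", ]; xM <- x[s$data$sex == "M", ]
  Sw <- (crossprod(scale(xF, scale = FALSE)) +
           crossprod(scale(xM, scale = FALSE))) / (nrow(x) - 2)
  direction <- solve(Sw) %*% (colMeans(xM) - colMeans(xF))
  # same direction up to the standardizing scale factor
  expect_equal(unname(m$coefficients / drop(direction)),
               rep(unname(m$coefficients[1] / direction[1]), 2),
               tolerance = 1e-10)
  # the scale is fixed by unit pooled within-group score variance
  d <- drop(x %*% m$coefficients) + m$intercept
  dF <- d[s$data$sex == "F"]; dM <- d[s$data$sex == "M"]
  pooled_var <- (sum((dF - mean(dF))^2) + sum((dM - mean(dM))^2)) / (nrow(x) - 2)
  expect_equal(pooled_var, 1, tolerance = 1e-10)
  # and the intercept maps the centroid midpoint to score 0
  expect_equal(drop(((colMeans(xF) + colMeans(xM)) / 2) %*% m$coefficients) +
                 m$intercept, 0, tolerance = 1e-10)
})

test_that("fit agrees with the MASS reference implementation", {
  s <- default_sample(seed = 21)
  vars <- c("head_diameter", "epicondylar_breadth")
  m <- fit_lda(s, vars)
  ref <- MASS::lda(x = s$data[, vars], grouping = s$data$sex,
                   prior = c(0.5, 0.5))
  # MASS uses the same unit within-group-variance scaling (up to sign)
  scl <- drop(ref$scaling)
  if (scl[1] * m$coefficients[1] < 0) scl <- -scl
  expect_equal(unname(m$coefficients), unname(scl), tolerance = 1e-8)
  # plug-in posteriors match individual by individual
  post <- lda_posterior(m, discriminant_score(m, s$data[, vars]))
  ref_post <- stats::predict(ref, s$data[, vars], method = "plug-in")$posterior
  expect_equal(unname(post[, "P_F"]), unname(ref_post[, "F"]), tolerance = 1e-8)
  expect_equal(unname(post[, "P_M"]), unname(ref_post[, "M"]), tolerance = 1e-8)
})

test_that("posteriors are symmetric, monotone, and invert in closed form", {
  s <- default_sample(seed = 3)
  m <- fit_lda(s, c("head_diameter", "epicondylar_breadth"))
  # midpoint score -> 0.5/0.5 under equal priors
  expect_equal(as.numeric(lda_posterior(m, 0)), c(0.5, 0.5), tolerance = 1e-12)
  d <- seq(-3, 3, by = 0.25)
  post <- lda_posterior(m, d)
  expect_prob_matrix(post)
  # mirror symmetry and strict monotonicity
  expect_equal(unname(post[, "P_M"]), rev(unname(post[, "P_F"])),
               tolerance = 1e-12)
  expect_true(all(diff(post[, "P_M"]) > 0))
  expect_true(all(diff(post[, "P_F"]) < 0))
  # closed-form inversion: D(P_M = p) = logit(p) / separation
  sep <- m$score_mean_M - m$score_mean_F
  for (p in c(0.6, 0.8, 0.95)) {
    d_p <- score_at_posterior(m, p, "M")
    expect_equal(d_p, log(p / (1 - p)) / sep, tolerance = 1e-12)
    expect_equal(unname(lda_posterior(m, d_p)[, "P_M"]), p, tolerance = 1e-10)
    expect_equal(score_at_posterior(m, p, "F"), -d_p, tolerance = 1e-12)
  }
  # the worked separation-3.08 example: D = 0.45 gives P_M close to 0.80
  m2 <- m
  m2$score_mean_F <- -1.54; m2$score_mean_M <- 1.54
  expect_equal(unname(lda_posterior(m2, 0.45)[, "P_M"]),
               1 / (1 + exp(-3.08 * 0.45)), tolerance = 1e-12)
})

test_that("unequal priors shift the 0.5-posterior point off score zero", {
  s <- default_sample(seed = 3)
  m <- fit_lda(s, c("head_diameter", "epicondylar_breadth"),
               priors = c(F = 0.7, M = 0.3))
  expect_lt(unname(lda_posterior(m, 0)[, "P_M"]), 0.5)
  d_half <- score_at_posterior(m, 0.5 + 1e-12, "M")
  expect_gt(d_half, 0)
  expect_equal(unname(lda_posterior(m, d_half)[, "P_M"]), 0.5,
               tolerance = 1e-9)
})

test_that("rescaling a variable rescales its coefficient and preserves scores", {
  s <- default_sample(seed = 9)
  vars <- c("head_diameter", "epicondylar_breadth")
  m <- fit_lda(s, vars)
  k <- 10
  df <- s$data
  df$head_diameter <- df$head_diameter * k
  s2 <- make_sample(df, vars)
  m2 <- fit_lda(s2, vars)
  expect_equal(unname(m2$coefficients["head_diameter"]),
               unname(m$coefficients["head_diameter"]) / k, tolerance = 1e-10)
  d1 <- discriminant_score(m, s$data[, vars])
  d2 <- discriminant_score(m2, s2$data[, vars])
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("classification honours the decision probability", {
  s <- default_sample(seed = 3)
  m <- fit_lda(s, c("head_diameter", "epicondylar_breadth"))
  # the 0.5 rule is the sign rule
  x <- s$data[, m$variables]
  cl <- classify_lda(m, x, 0.5)
  expect_identical(as.character(cl$label), ifelse(cl$score < 0, "F", "M"))
  # a posterior just below the level is indeterminate
  d79 <- score_at_posterior(m, 0.79, "M")
  meas <- c(head_diameter = unname((d79 - m$intercept) /
                                     m$coefficients["head_diameter"]),
            epicondylar_breadth = 0)
  cl8 <- classify_lda(m, meas, 0.8)
  expect_identical(as.character(cl8$label), "indeterminate")
  expect_equal(cl8$probability, 0.79, tolerance = 1e-9)
  expect_error(classify_lda(m, x, 0.4), "decision_probability")
  expect_error(classify_lda(m, x, 1), "decision_probability")
})

test_that("degenerate fits fail loudly", {
  df <- data.frame(id = paste0("i", 1:8),
                   sex = rep(c("F", "M"), each = 4),
                   a = c(1, 2, 3, 4, 6, 7, 8, 9))
  df$b <- 2 * df$a  # exactly collinear
  s <- make_sample(df, c("a", "b"))
  expect_error(fit_lda(s, c("a", "b")), "singular")
  s1 <- make_sample(data.frame(id = c("a", "b", "c"),
                               sex = c("F", "M", "M"),
                               x = c(1, 5, 6)), "x")
  expect_error(fit_lda(s1, "x"), "at least 2")
  m <- fit_lda(toy_1d(), "x")
  expect_error(discriminant_score(m, c(y = 1)), "missing variable.*x")
})
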
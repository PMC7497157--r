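test_that("VIF is 1 for orthogonal predictors and 1/(1-r^2) in two dimensions", {
  # exactly orthogonal, mean-centred design (shifted positive)
  s <- make_sample(data.frame(
    id = paste0("i", 1:8),
    sex = rep(c("F", "M"), 4),
    a = 10 + c(1, -1, 1, -1, 1, -1, 1, -1),
    b = 10 + c(1, 1, -1, -1, 1, 1, -1, -1)), c("a", "b"))
  v <- vif(s, c("a", "b"))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12)

  s2 <- default_sample(seed = 101)
  v2 <- vif(s2, c("head_diameter", "epicondylar_breadth"))
  r <- stats::cor(s2$data$head_diameter, s2$data$epicondylar_breadth)
  expect_equal(unname(v2), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  expect_true(all(v2 >= 1))
})

test_that("VIF is invariant to affine rescaling of a variable", {
  s <- default_sample(seed = 103)
  vars <- s$variables
  v1 <- vif(s, vars)
  df <- s$data
  df$head_diameter <- df$head_diameter * 7 + 3
  v2 <- vif(make_sample(df, vars), vars)
  expect_equal(v1, v2, tolerance = 1e-10)
  expect_error(vif(s, "head_diameter"), "at least 2")
})

test_that("Box's M is zero for identical groups and matches a frozen oracle", {
  df <- data.frame(id = paste0("i", 1:8),
                   sex = rep(c("F", "M"), each = 4),
                   a = rep(c(2, 4, 6, 3), 2), b = rep(c(3, 5.5, 5, 4), 2))
  bm0 <- box_m(make_sample(df, c("a", "b")), c("a", "b"))
  expect_equal(bm0$M, 0, tolerance = 1e-10)
  expect_equal(bm0$p, 1, tolerance = 1e-10)
  expect_equal(bm0$df, 3)

  # frozen values from an independent step-by-step computation
  s <- make_sample(data.frame(
    id = paste0("i", 1:13),
    sex = c(rep("F", 6), rep("M", 7)),
    a = c(2, 4, 6, 3, 5, 4.5, 3, 5, 7, 4, 6.5, 5.5, 4),
    b = c(3, 5.5, 5, 4, 6.5, 3.5, 2, 3, 6, 5, 4.5, 6.5, 3)), c("a", "b"))
  bm <- box_m(s, c("a", "b"))
  expect_equal(bm$M, 0.3696914332845669, tolerance = 1e-9)
  expect_equal(bm$chi_sq, 0.2960643347028089, tolerance = 1e-9)
  expect_equal(bm$df, 3)
  expect_equal(bm$p, 0.9607669654147241, tolerance = 1e-9)
})

test_that("Box's M is invariant to a common nonsingular linear transform", {
  s <- default_sample(seed = 107)
  vars <- c("head_diameter", "epicondylar_breadth")
  bm1 <- box_m(s, vars)
  A <- matrix(c(2, 0.5, -1, 3), 2, 2)
  xt <- as.matrix(s$data[, vars]) %*% t(A)
  df <- s$data
  df[, vars] <- xt - min(xt) + 1  # keep measurements positive
  bm2 <- box_m(make_sample(df, vars), vars)
  expect_equal(bm1$chi_sq, bm2$chi_sq, tolerance = 1e-8)
  expect_equal(bm1$p, bm2$p, tolerance = 1e-8)
})

test_that("Mahalanobis distances reduce to squared Euclidean under identity covariance", {
  s <- default_sample(seed = 109)
  vars <- c("head_diameter", "epicondylar_breadth")
  out <- mahalanobis_outliers(s, vars)
  x <- as.matrix(s$data[, vars])
  # direct quadratic-form oracle
  S <- stats::cov(x)
  mu <- colMeans(x)
  d_hand <- apply(x, 1, function(r) drop(t(r - mu) %*% solve(S) %*% (r - mu)))
  expect_equal(out$pooled$distance, unname(d_hand), tolerance = 1e-10)
  expect_equal(out$cutoff, stats::qchisq(0.975, 2))
  # whitened data: distance equals squared Euclidean distance
  E <- eigen(S)
  W <- E$vectors %*% diag(1 / sqrt(E$values)) %*% t(E$vectors)
  xw <- scale(x %*% W, scale = FALSE)
  d_w <- stats::mahalanobis(xw, colMeans(xw), stats::cov(xw))
  expect_equal(unname(d_w), unname(rowSums(xw^2)), tolerance = 1e-6)
  # affine invariance of the flags
  df <- s$data
  df[, vars[1]] <- df[, vars[1]] * 3 + 2
  out2 <- mahalanobis_outliers(make_sample(df, vars), vars)
  expect_equal(out$pooled$distance, out2$pooled$distance, tolerance = 1e-8)
  # a point at the multivariate mean has distance 0 and is never flagged
  df0 <- s$data[1, ]; df0$id <- "at_mean"
  df0[, vars] <- as.list(mu)
  d0 <- stats::mahalanobis(matrix(mu, 1), mu, S)
  expect_equal(unname(d0), 0)
  expect_true(min(out$pooled$distance) < out$cutoff)
})

test_that("per-sex outlier screen reports every individual against its own group", {
  s <- default_sample(seed = 113)
  out <- mahalanobis_outliers(s, s$variables)
  expect_setequal(out$by_sex$id, s$data$id)
  expect_true(all(out$by_sex$distance >= 0))
})

test_that("logit-linearity interactions are well-calibrated under a true linear logit", {
  hits <- 0L; total <- 0L
  for (r in 1:40) {
    g <- generate_known_model_sample(
      "logr", n = 300, seed = 200 + r,
      intercept = 0, coefficients = c(v1 = 0.8, v2 = -0.5),
      mu = c(v1 = 10, v2 = 12), sd = c(2, 2), correlation = 0.3)
    ll <- suppressWarnings(logit_linearity(g$sample))
    hits <- hits + sum(ll$p < 0.05)
    total <- total + nrow(ll)
  }
  # nominal 5% false-positive rate; allow generous sampling slack
  expect_lt(hits / total, 0.15)
})

test_that("logit-linearity rejects degenerate inputs", {
  s <- default_sample(seed = 127)
  df <- s$data
  df$flat <- 5
  s2 <- reference_sample(df, c("head_diameter", "flat"), quiet = TRUE)
  expect_error(logit_linearity(s2, c("head_diameter", "flat")), "constant")
  # one-at-a-time mode returns one row per variable too
  ll <- suppressWarnings(logit_linearity(s, joint = FALSE))
  expect_equal(ll$variable, s$variables)
  expect_true(all(ll$p >= 0 & ll$p <= 1))
})

test_that("the bundled assumption screen returns a coherent report", {
  s <- default_sample(seed = 131)
  rep <- suppressWarnings(check_assumptions(s))
  expect_s3_class(rep, "assumption_report")
  expect_true(all(rep$vif >= 1))
  expect_equal(rep$box_m$df, 6)  # (k-1) p (p+1) / 2 with k = 2, p = 3
  expect_true(rep$box_m$p >= 0 && rep$box_m$p <= 1)
  expect_equal(nrow(rep$logit_linearity), 3L)
})
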
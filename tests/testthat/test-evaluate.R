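test_that("LOOCV reproduces a naive externally-coded refit loop", {
  spec <- population_spec(
    n_F = 10L, n_M = 10L,
    mean_F = c(hd = 41.6, eb = 55.3), mean_M = c(hd = 49.3, eb = 63.8),
    sd_F = c(hd = 2.3, eb = 3.3), sd_M = c(hd = 2.8, eb = 4.8))
  s <- generate_reference_sample(spec, seed = 31)
  vars <- c("hd", "eb")
  for (method in c("lda", "logr")) {
    rep <- suppressWarnings(loocv(s, method, vars))
    naive <- t(vapply(seq_len(nrow(s$data)), function(i) {
      train <- make_sample(s$data[-i, ], vars)
      if (method == "lda") {
        m <- fit_lda(train, vars)
        unname(lda_posterior(m, discriminant_score(m, s$data[i, vars]))[1, ])
      } else {
        m <- suppressWarnings(fit_logr(train, vars))
        unname(predict_prob(m, s$data[i, vars])[1, ])
      }
    }, numeric(2)))
    expect_equal(rep$per_individual$P_F, naive[, 1], tolerance = 1e-10)
    expect_equal(rep$per_individual$P_M, naive[, 2], tolerance = 1e-10)
  }
})

test_that("perfectly separated data give 100% LOOCV accuracy for both methods", {
  s <- separated_sample()
  r_lda <- loocv(s, "lda", "x")
  expect_equal(r_lda$summary$accuracy[1], 100)
  r_logr <- loocv(s, "logr", "x")
  expect_equal(r_logr$summary$accuracy[1], 100)
  expect_gt(r_logr$separated_folds, 0)
})

test_that("LOOCV is invariant to record order", {
  s <- default_sample(seed = 23)
  vars <- c("head_diameter", "epicondylar_breadth")
  r1 <- loocv(s, "lda", vars)
  perm <- sample(seq_len(nrow(s$data)))
  s2 <- make_sample(s$data[perm, ], vars)
  r2 <- loocv(s2, "lda", vars)
  o <- match(r1$per_individual$id, r2$per_individual$id)
  expect_equal(r1$per_individual$P_F, r2$per_individual$P_F[o],
               tolerance = 1e-12)
  expect_equal(r1$summary, r2$summary, tolerance = 1e-12)
})

test_that("raising the decision probability only sheds individuals", {
  s <- default_sample(seed = 23)
  r <- loocv(s, "lda", c("head_diameter", "epicondylar_breadth"),
             decision_probabilities = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95))
  expect_equal(r$summary$retained_n[1], nrow(s$data))
  expect_true(all(diff(r$summary$retained_n) <= 0))
  # accuracy bookkeeping: accuracy = correct / retained in every stratum
  expect_equal(r$summary$accuracy,
               100 * (r$summary$retained_n - r$summary$misclassified) /
                 r$summary$retained_n)
})

test_that("retained and sub-threshold individuals partition the sample", {
  s <- default_sample(seed = 23)
  r <- loocv(s, "lda", c("head_diameter", "epicondylar_breadth"),
             decision_probabilities = c(0.5, 0.8))
  st <- subthreshold_accuracy(r, 0.8)
  expect_equal(r$summary$retained_n[2] + st$n, r$n)
  # sub-threshold accuracy is the 0.5 sign rule restricted to the subset
  sub <- r$per_individual[r$per_individual$probability < 0.8, ]
  expect_equal(st$accuracy,
               100 * mean(sub$winner == sub$true_sex))
})

test_that("sub-threshold accuracy handles empty and tiny subsets", {
  s <- separated_sample()
  r <- loocv(s, "lda", "x")
  st <- subthreshold_accuracy(r, 0.51)
  expect_false(st$applicable)
  expect_true(is.na(st$accuracy))
  # constructed subset of 2 correct + 2 wrong -> 50%
  post <- cbind(P_F = c(0.7, 0.7, 0.3, 0.3, 0.99),
                P_M = c(0.3, 0.3, 0.7, 0.7, 0.01))
  rep2 <- osteosex:::build_report(paste0("i", 1:5),
                                  c("F", "M", "F", "M", "F"),
                                  post, 0.5, "lda", "x")
  st2 <- subthreshold_accuracy(rep2, 0.8)
  expect_equal(st2$n, 4L)
  expect_equal(st2$accuracy, 50)
})

test_that("B and Q indices take their closed-form values", {
  y <- c(1, 0, 1, 1, 0)
  expect_equal(brier_index(y, y), 1)
  expect_equal(q_index(y, y), 1)
  p_half <- rep(0.5, 5)
  expect_equal(brier_index(p_half, y), 0.75)
  expect_equal(q_index(p_half, y), 0)
  # worse than chance goes negative for Q
  expect_lt(q_index(1 - y * 0.9 - 0.05, y), 0)
  expect_error(brier_index(c(0.5, 0.5), c(1, 0, 1)), "length")
  expect_error(q_index(c(0.5, 0.5), c(1, 0, 1)), "length")
  # clamping keeps Q finite on confidently wrong predictions
  expect_true(is.finite(q_index(c(0, 1), c(1, 0))))
})

test_that("B and Q are invariant to swapping the class coding", {
  set.seed(41)
  p <- runif(30)
  y <- rbinom(30, 1, p)
  expect_equal(brier_index(p, y), brier_index(1 - p, 1 - y), tolerance = 1e-12)
  expect_equal(q_index(p, y), q_index(1 - p, 1 - y), tolerance = 1e-12)
})

test_that("Welch comparison matches the textbook formula and t.test", {
  s <- make_sample(data.frame(
    id = paste0("i", 1:11),
    sex = c(rep("F", 5), rep("M", 6)),
    x = c(10, 12, 11.5, 9, 13, 14, 15.5, 13, 16, 14.5, 17)), "x")
  w <- welch_mean_difference(s, "x", confidence = 0.90)
  # frozen values from an independent step-by-step Welch computation
  expect_equal(w$difference, 3.9, tolerance = 1e-12)
  expect_equal(w$t, 4.205478154934098, tolerance = 1e-9)
  expect_equal(w$df, 8.261379502932142, tolerance = 1e-9)
  expect_equal(w$ci, c(2.182572697996223, 5.617427302003778),
               tolerance = 1e-9)
  # identical groups: difference 0 with a CI containing 0
  s0 <- make_sample(data.frame(id = paste0("i", 1:8),
                               sex = rep(c("F", "M"), each = 4),
                               x = rep(c(1, 2, 3, 4), 2)), "x")
  w0 <- welch_mean_difference(s0, "x")
  expect_equal(w0$difference, 0)
  expect_true(w0$ci[1] < 0 && w0$ci[2] > 0)
  s_const <- make_sample(data.frame(id = paste0("i", 1:4),
                                    sex = c("F", "F", "M", "M"),
                                    x = c(2, 2, 2, 2)), "x")
  expect_error(welch_mean_difference(s_const, "x"), "zero variance")
})

test_that("sample-size experiment honours its contract and is seed-stable", {
  s <- default_sample(seed = 29)
  vars <- c("head_diameter", "epicondylar_breadth")
  e1 <- sample_size_experiment(s, "lda", vars, sizes = c(12, 20, 30),
                               replicates_per_size = 5, seed = 101)
  expect_equal(nrow(e1$per_size), 3L)
  expect_true(all(e1$accuracies >= 0 & e1$accuracies <= 1))
  expect_true(e1$mean_accuracy >= 0 && e1$mean_accuracy <= 100)
  e2 <- sample_size_experiment(s, "lda", vars, sizes = c(12, 20, 30),
                               replicates_per_size = 5, seed = 101)
  expect_identical(e1$accuracies, e2$accuracies)
  expect_error(sample_size_experiment(s, "lda", vars, sizes = 4:8), "sizes")
})

test_that("on well-separated data accuracy trends upward with sample size", {
  spec <- population_spec(
    n_F = 30L, n_M = 30L,
    mean_F = c(hd = 40), mean_M = c(hd = 50),
    sd_F = c(hd = 2.5), sd_M = c(hd = 2.5))
  s <- generate_reference_sample(spec, seed = 37)
  e <- sample_size_experiment(s, "lda", "hd", sizes = seq(10, 60, by = 5),
                              replicates_per_size = 10, seed = 53)
  trend <- stats::cor(e$per_size$size, e$per_size$mean_accuracy,
                      method = "spearman")
  expect_gt(trend, 0)
})
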
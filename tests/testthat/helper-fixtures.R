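# fixtures and small independent oracles shared across test files

# tiny labelled data.frame -> reference_sample without CSV plumbing
make_sample <- function(df, variables) {
  reference_sample(df, variables = variables, quiet = TRUE)
}

# strongly dimorphic 1-D toy: F score axis {-2,-1,0}, M {2,3,4} on x
toy_1d <- function() {
  make_sample(data.frame(
    id = paste0("i", 1:6),
    sex = c("F", "F", "F", "M", "M", "M"),
    x = c(1, 2, 3, 5, 6, 7)), "x")
}

# 8-point 2-variable toy with overlap, used for hand-oracle checks
toy_2d <- function() {
  make_sample(data.frame(
    id = paste0("i", 1:8),
    sex = c("F", "F", "F", "F", "M", "M", "M", "M"),
    a = c(40.0, 42.5, 41.0, 43.5, 47.0, 48.5, 46.0, 50.0),
    b = c(54.0, 56.5, 55.0, 53.5, 60.0, 63.5, 61.0, 64.5)), c("a", "b"))
}

# moderate synthetic humeral sample used across files
default_sample <- function(seed = 11, correlation = 0.5) {
  generate_reference_sample(default_population(correlation), seed = seed)
}

# perfectly separated 1-D sample (finite LDA, separated logistic)
separated_sample <- function() {
  make_sample(data.frame(
    id = paste0("s", 1:10),
    sex = rep(c("F", "M"), each = 5),
    x = c(10, 11, 12, 11.5, 10.5, 20, 21, 22, 21.5, 20.5)), "x")
}

# moderate-overlap sample generated from a true logistic law, for checks
# that need a regular (non-separated) maximum-likelihood problem
overlap_sample <- function(seed = 19, n = 150) {
  generate_known_model_sample(
    "logr", n = n, seed = seed,
    intercept = -(0.8 * 45 - 0.4 * 58), coefficients = c(hd = 0.8, eb = -0.4),
    mu = c(hd = 45, eb = 58), sd = c(2.5, 4), correlation = 0.4)$sample
}

# independent logistic log-likelihood used by oracle checks
loglik_logistic <- function(b0, b, X, y) {
  eta <- b0 + drop(X %*% b)
  sum(y * eta - log(1 + exp(eta)))
}

expect_prob_matrix <- function(p) {
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)
}
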
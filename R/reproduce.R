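#' Recompute the full benchmark analysis from a reference CSV
#'
#' Runs the complete published-style analysis on a reference CSV with the
#' three humeral measurements: all five single- and multi-variable
#' discriminant functions (LDF1–LDF5) and logistic models (LogR1–LogR5),
#' their LOOCV accuracies at decision probabilities 0.5 and 0.8,
#' sub-threshold accuracies, B and Q indices, Welch mean differences with
#' 90% CIs, assumption diagnostics, PMarks at 0.80/0.90/0.95 for the
#' head-diameter + epicondylar-breadth function, and (optionally) the
#' sample-size experiment.
#'
#' The original 84-individual reference series this analysis was designed
#' around is not redistributable with the package; pass its CSV export (or
#' any sample with the same column structure) via `path`.
#'
#' @param path CSV with columns id, sex and the three measurements.
#' @param variable_columns the measurement column names, in the order
#'   max length, head diameter, epicondylar breadth.
#' @param id_column,sex_column column names.
#' @param n_boot bootstrap iterations for the PMarks.
#' @param seed seed for the PMark bootstrap and sample-size experiment.
#' @param run_sample_size run the (slower) sample-size experiment.
#' @param replicates_per_size replicates per size for that experiment.
#' @return A list with components `sample`, `models` (per equation: the
#'   fitted model, its LOOCV report and sub-threshold accuracies), `welch`,
#'   `assumptions`, `pmarks`, and `sample_size` (or `NULL`).
#' @export
reproduce_reference_results <- function(path,
                                        variable_columns = c("max_length",
                                                             "head_diameter",
                                                             "epicondylar_breadth"),
                                        id_column = "id", sex_column = "sex",
                                        n_boot = 1000L, seed = 1L,
                                        run_sample_size = FALSE,
                                        replicates_per_size = 100L) {
  stopifnot(length(variable_columns) == 3L)
  s <- read_reference_csv(path, sex_column = sex_column,
                          variable_columns = variable_columns,
                          id_column = id_column, quiet = TRUE)
  ml <- variable_columns[[1L]]; hd <- variable_columns[[2L]]
  eb <- variable_columns[[3L]]
  varsets <- list(`1` = ml, `2` = hd, `3` = eb, `4` = c(hd, eb),
                  `5` = c(ml, hd, eb))

  models <- lapply(varsets, function(v) {
    ld <- fit_lda(s, v)
    lr <- fit_logr(s, v)
    rep_ld <- loocv(s, "lda", v, decision_probabilities = c(0.5, 0.8))
    rep_lr <- suppressWarnings(
      loocv(s, "logr", v, decision_probabilities = c(0.5, 0.8)))
    list(variables = v, lda = ld, logr = lr,
         loocv_lda = rep_ld, loocv_logr = rep_lr,
         subthreshold_lda = subthreshold_accuracy(rep_ld, 0.8),
         subthreshold_logr = subthreshold_accuracy(rep_lr, 0.8))
  })
  names(models) <- paste0("set", names(varsets))

  out <- list(
    sample = s,
    models = models,
    welch = lapply(stats::setNames(nm = variable_columns), function(v) {
      welch_mean_difference(s, v, confidence = 0.90)
    }),
    assumptions = check_assumptions(s, variable_columns),
    pmarks = multilevel_pmarks(s, c(hd, eb), levels = c(0.8, 0.9, 0.95),
                               n_boot = n_boot, seed = seed),
    sample_size = NULL)
  if (run_sample_size) {
    out$sample_size <- sample_size_experiment(
      s, "lda", c(hd, eb), sizes = 10:nrow(s$data),
      replicates_per_size = replicates_per_size, seed = seed)
  }
  out
}
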
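#' Write a fitted model to a JSON model file
#'
#' Model files carry everything a future user needs to apply a published
#' equation without access to the reference data: the ordered variable names,
#' the coefficients and intercept, and metadata (sex coding, priors, per-sex
#' counts, scaling convention). Numbers are written at full double precision
#' so a write/read cycle is exact; rounding to the precision of a printed
#' equation is a user choice, not something the serializer imposes.
#'
#' @param model an `lda_sex_model` (from [fit_lda()]), a `logr_sex_model`
#'   (from [fit_logr()]), or a list with the same fields as produced by
#'   [read_model()].
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @seealso [read_model()], [write_pmarks()]
#' @export
write_model <- function(model, path) {
  obj <- as_model_file(model)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

as_model_file <- function(model) {
  if (inherits(model, "lda_sex_model")) {
    list(model_kind = "lda",
         variables = as.list(model$variables),
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         score_mean_F = model$score_mean_F,
         score_mean_M = model$score_mean_M,
         priors = list(F = model$priors[["F"]], M = model$priors[["M"]]),
         n_F = model$n_F, n_M = model$n_M,
         metadata = model$metadata)
  } else if (inherits(model, "logr_sex_model")) {
    list(model_kind = "logr",
         variables = as.list(model$variables),
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         coded_one_sex = model$coded_one_sex,
         log_likelihood = model$log_likelihood,
         aic = model$aic,
         n = model$n, n_F = model$n_F, n_M = model$n_M,
         converged = model$converged, iterations = model$iterations,
         metadata = model$metadata)
  } else if (is.list(model) && !is.null(model$model_kind)) {
    model
  } else {
    stop("unknown model class: ", paste(class(model), collapse = "/"))
  }
}

#' Read a model file written by [write_model()]
#'
#' Validates the schema: the coefficient names must match the declared
#' variables exactly (same set, no extras), and `model_kind` must be one of
#' `lda` or `logr`. Published equations with either sex coding can be loaded;
#' the coding is part of the file.
#'
#' @param path path to a JSON model file.
#' @return An `lda_sex_model` or `logr_sex_model` usable with
#'   [discriminant_score()], [predict_prob()], [classify_lda()] and
#'   [classify_logr()]. Models loaded from a file that omits fitted score
#'   means (an equation-only publication) can still be scored and classified
#'   by the sign rule, but posterior probabilities require the score means.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  kind <- obj$model_kind
  if (is.null(kind) || !kind %in% c("lda", "logr")) {
    stop("unknown model_kind: ", if (is.null(kind)) "<missing>" else kind)
  }
  vars <- as.character(unlist(obj$variables))
  coefs <- unlist(obj$coefficients)
  if (!setequal(names(coefs), vars) || length(coefs) != length(vars)) {
    stop("schema error: coefficient names do not match declared variables")
  }
  coefs <- coefs[vars]  # restore declared order

  if (kind == "lda") {
    structure(list(
      variables = vars, coefficients = coefs,
      intercept = as.numeric(obj$intercept),
      score_mean_F = null_na(obj$score_mean_F),
      score_mean_M = null_na(obj$score_mean_M),
      priors = c(F = null_na(obj$priors$F, 0.5), M = null_na(obj$priors$M, 0.5)),
      n_F = null_na(obj$n_F), n_M = null_na(obj$n_M),
      metadata = obj$metadata), class = "lda_sex_model")
  } else {
    structure(list(
      variables = vars, coefficients = coefs,
      intercept = as.numeric(obj$intercept),
      coded_one_sex = if (is.null(obj$coded_one_sex)) "F" else obj$coded_one_sex,
      log_likelihood = null_na(obj$log_likelihood),
      aic = null_na(obj$aic),
      n = null_na(obj$n), n_F = null_na(obj$n_F), n_M = null_na(obj$n_M),
      converged = if (is.null(obj$converged)) NA else obj$converged,
      iterations = null_na(obj$iterations),
      vcov = NULL,
      metadata = obj$metadata), class = "logr_sex_model")
  }
}

null_na <- function(x, default = NA_real_) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) default else as.numeric(x)
}

#' Write a PMark set to JSON
#' @param pmarks a `pmark_set` or `pmark_levels` object (see
#'   [compute_pmarks()], [multilevel_pmarks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmarks <- function(pmarks, path) {
  if (inherits(pmarks, "pmark_set")) pmarks <- list(pmarks)
  obj <- lapply(pmarks, function(pm) {
    list(probability_level = pm$probability_level,
         pmark_F = pm$pmark_F, pmark_M = pm$pmark_M,
         n_boot = pm$n_boot, seed = pm$seed,
         sd_F = pm$sd_F, sd_M = pm$sd_M,
         method = pm$method, redraws = pm$redraws,
         model_ref = pm$model_ref)
  })
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a PMark set written by [write_pmarks()]
#' @param path path to the JSON file.
#' @return A list of `pmark_set` objects (class `pmark_levels`), ordered by
#'   probability level.
#' @export
read_pmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(obj, function(pm) {
    structure(list(probability_level = pm$probability_level,
                   pmark_F = pm$pmark_F, pmark_M = pm$pmark_M,
                   n_boot = null_na(pm$n_boot), seed = null_na(pm$seed),
                   sd_F = null_na(pm$sd_F), sd_M = null_na(pm$sd_M),
                   method = pm$method, redraws = null_na(pm$redraws),
                   model_ref = pm$model_ref),
              class = "pmark_set")
  })
  out <- out[order(vapply(out, `[[`, numeric(1L), "probability_level"))]
  structure(out, class = "pmark_levels")
}
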
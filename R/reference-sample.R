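#' Construct a reference sample of sexed skeletal measurements
#'
#' A reference sample is the labelled data a sex-estimation model is built
#' from: one row per individual of known sex, one column per continuous
#' skeletal measurement (in mm). Rows with any missing value in the selected
#' variables are dropped (listwise deletion over the selected variables only;
#' no imputation), mirroring the usual inclusion rule that an individual
#' enters the reference sample only with all measurements present.
#'
#' @param data data.frame containing at least an id column, a sex column and
#'   the measurement columns.
#' @param variables character vector of measurement column names, in the
#'   order they should be kept.
#' @param id_column,sex_column,age_column names of the id, sex and (optional)
#'   age columns. `age_column = NULL` omits age.
#' @param quiet suppress the message reporting dropped rows.
#'
#' @return An object of class `reference_sample`: a list with elements
#'   `data` (data.frame with columns id, sex, age and the measurements, sex a
#'   factor with levels F/M), `variables`, `n_F`, `n_M` and `dropped` (ids of
#'   rows removed for missing measurements).
#' @seealso [read_reference_csv()], [fit_lda()], [fit_logr()]
#' @examples
#' d <- data.frame(id = c("a", "b", "c", "d"),
#'                 sex = c("female", "male", "f", "M"),
#'                 hd = c(41, 49, 42, 50))
#' reference_sample(d, variables = "hd")
#' @export
reference_sample <- function(data, variables,
                             id_column = "id", sex_column = "sex",
                             age_column = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(data), length(variables) >= 1L)
  missing_cols <- setdiff(c(id_column, sex_column, variables), names(data))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(data[[id_column]])
  sex <- parse_sex(data[[sex_column]])
  age <- if (!is.null(age_column) && age_column %in% names(data)) {
    as.numeric(data[[age_column]])
  } else {
    rep(NA_real_, nrow(data))
  }

  meas <- data[, variables, drop = FALSE]
  for (v in variables) meas[[v]] <- as.numeric(meas[[v]])

  keep <- stats::complete.cases(meas)
  dropped <- ids[!keep]
  if (length(dropped) > 0L && !quiet) {
    message("dropped ", length(dropped),
            " record(s) with missing measurements: ",
            paste(dropped, collapse = ", "))
  }
  ids <- ids[keep]; sex <- sex[keep]; age <- age[keep]
  meas <- meas[keep, , drop = FALSE]

  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- vapply(meas, function(x) any(x <= 0), logical(1L))
  if (any(bad)) {
    stop("non-positive measurement values in: ",
         paste(variables[bad], collapse = ", "))
  }
  n_F <- sum(sex == "F"); n_M <- sum(sex == "M")
  if (n_F == 0L || n_M == 0L) {
    stop("a sex has zero records after filtering (have ",
         n_F, " F, ", n_M, " M)")
  }

  out <- data.frame(id = ids, sex = sex, age = age,
                    stringsAsFactors = FALSE)
  out <- cbind(out, meas)
  rownames(out) <- NULL
  structure(list(data = out, variables = variables,
                 n_F = n_F, n_M = n_M, dropped = dropped),
            class = "reference_sample")
}

# F/M parser with the conventional synonyms; errors name the offending rows
parse_sex <- function(x, allow_unknown = FALSE) {
  raw <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("f", "female", "0", "w")] <- "F"
  out[raw %in% c("m", "male", "1")] <- "M"
  if (allow_unknown) {
    out[raw %in% c("", "na", "unknown", "u", "?") | is.na(raw)] <- "unknown"
  }
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("unparseable sex value(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": ", paste(unique(raw[utils::head(bad, 5L)]), collapse = ", "))
  }
  factor(out, levels = if (allow_unknown) c("F", "M", "unknown") else c("F", "M"))
}

#' Read a reference sample from a CSV file
#'
#' Reads a header-bearing CSV (delimiter auto-detected among comma, semicolon
#' and tab), parses the sex column (accepting `female`/`f`/`0` and
#' `male`/`m`/`1`, case-insensitively) and drops rows missing any selected
#' measurement.
#'
#' @inheritParams reference_sample
#' @param path path to the CSV file.
#' @param variable_columns measurement column names to retain, in order.
#' @return A [reference_sample()].
#' @export
read_reference_csv <- function(path, sex_column = "sex",
                               variable_columns, id_column = "id",
                               age_column = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path)
  reference_sample(df, variables = variable_columns, id_column = id_column,
                   sex_column = sex_column, age_column = age_column,
                   quiet = quiet)
}

detect_delimiter <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  counts <- c("," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))),
              "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))))
  if (all(counts == 0L)) stop("could not detect delimiter in ", path)
  names(counts)[which.max(counts)]
}

#' Write a reference sample back to CSV
#'
#' Values are written at full precision so that a read/write cycle preserves
#' all retained rows and values exactly.
#'
#' @param sample a [reference_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(sample, path) {
  stopifnot(inherits(sample, "reference_sample"))
  df <- sample$data
  df$age <- ifelse(is.na(df$age), "", format(df$age, digits = 17, trim = TRUE))
  for (v in sample$variables) {
    df[[v]] <- format(df[[v]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the measurement matrix of a reference sample
#' @param sample a [reference_sample()].
#' @param variables subset of variables (default: all).
#' @return numeric matrix, rows named by record id.
#' @keywords internal
measurement_matrix <- function(sample, variables = sample$variables) {
  stopifnot(inherits(sample, "reference_sample"))
  miss <- setdiff(variables, sample$variables)
  if (length(miss) > 0L) {
    stop("variable(s) not in sample: ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(sample$data[, variables, drop = FALSE])
  rownames(m) <- sample$data$id
  m
}

#' @export
print.reference_sample <- function(x, ...) {
  cat("Reference sample: ", nrow(x$data), " individuals (",
      x$n_F, " F / ", x$n_M, " M)\n", sep = "")
  cat("Variables (mm): ", paste(x$variables, collapse = ", "), "\n", sep = "")
  if (length(x$dropped) > 0L) {
    cat("Dropped for missing measurements: ",
        paste(x$dropped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Subset a reference sample by record index
#' @param sample a [reference_sample()].
#' @param idx integer indices into the records (duplicates allowed, e.g. for
#'   bootstrap resamples; ids are made unique).
#' @return a [reference_sample()].
#' @keywords internal
subset_sample <- function(sample, idx) {
  df <- sample$data[idx, , drop = FALSE]
  df$id <- make.unique(df$id)
  rownames(df) <- NULL
  structure(list(data = df, variables = sample$variables,
                 n_F = sum(df$sex == "F"), n_M = sum(df$sex == "M"),
                 dropped = character(0)),
            class = "reference_sample")
}
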
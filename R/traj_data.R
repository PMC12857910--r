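#' Build a longitudinal trajectory dataset from a data frame
#'
#' Validates and indexes an observation-level table (one row per visit) for
#' trajectory modelling.  The table must contain a subject-identifier column,
#' numeric predictor columns (typically transformations of age or time, plus
#' an intercept), and one or more target columns.  Continuous and binary
#' targets may contain missing values; predictors may not.
#'
#' @param df A data frame or tibble with one row per observation.
#' @param subject Name of the subject-identifier column.
#' @param predictors Character vector of predictor column names.
#' @param targets Character vector of continuous target column names.
#' @param targets_binary Character vector of binary (0/1) target column names.
#' @param intercept If `TRUE`, prepend a constant predictor column named
#'   `"(Intercept)"` to the design matrix (unless a predictor of that name is
#'   already listed).
#'
#' @return An object of class `traj_data`: a list with the original tibble
#'   (`df`), the design matrix `X`, continuous target matrix `Y` and binary
#'   target matrix `B` (both with `NA` marking missing cells), the subject
#'   identifiers and a subject index that partitions the rows.
#' @seealso [read_traj_csv()] to load directly from a CSV file.
#' @export
#' @examples
#' df <- tibble::tibble(id = rep(1:2, each = 3), age = rep(0:2, 2),
#'                      y = rnorm(6))
#' td <- traj_data(df, subject = "id", predictors = "age",
#'                 targets = "y", intercept = TRUE)
#' td
traj_data <- function(df, subject, predictors, targets = character(),
                      targets_binary = character(), intercept = FALSE) {
  df <- tibble::as_tibble(df)
  wanted <- c(subject, predictors, targets, targets_binary)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(targets) + length(targets_binary) == 0) {
    stop("at least one continuous or binary target is required", call. = FALSE)
  }

  subject_id <- df[[subject]]
  if (anyNA(subject_id)) {
    stop("missing subject identifier in row(s) ",
         paste(utils::head(which(is.na(subject_id)), 5), collapse = ", "),
         call. = FALSE)
  }
  subject_id <- as.character(subject_id)

  X <- .numeric_matrix(df, predictors, "predictor")
  bad <- which(!stats::complete.cases(X) | rowSums(!is.finite(X)) > 0)
  if (length(bad) > 0) {
    stop("missing or non-finite predictor value(s) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (intercept && !("(Intercept)" %in% predictors)) {
    X <- cbind(`(Intercept)` = 1, X)
    predictors <- colnames(X)
  }

  Y <- .numeric_matrix(df, targets, "continuous target")
  Y[is.nan(Y)] <- NA_real_
  B <- .numeric_matrix(df, targets_binary, "binary target")
  B[is.nan(B)] <- NA_real_
  if (length(targets_binary) > 0) {
    ok <- is.na(B) | B == 0 | B == 1
    if (!all(ok)) {
      bad <- which(rowSums(!ok) > 0)
      stop("binary target value not in {0, 1} in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }

  subjects <- unique(subject_id)
  structure(list(
    df = df,
    subject_col = subject,
    predictors = predictors,
    targets = targets,
    targets_binary = targets_binary,
    subject_id = subject_id,
    subjects = subjects,
    subj_index = match(subject_id, subjects),
    X = X, Y = Y, B = B
  ), class = "traj_data")
}

.numeric_matrix <- function(df, cols, what) {
  if (length(cols) == 0) {
    return(matrix(numeric(0), nrow = nrow(df), ncol = 0))
  }
  m <- matrix(NA_real_, nrow(df), length(cols), dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    v <- df[[cols[j]]]
    if (!is.numeric(v) && !is.logical(v)) {
      stop(what, " column '", cols[j], "' is not numeric", call. = FALSE)
    }
    m[, j] <- as.numeric(v)
  }
  m
}

#' Read a longitudinal CSV file
#'
#' Reads a comma-separated file with a header row (one observation per line)
#' and validates it with [traj_data()].  Empty cells and the literal string
#' `"NaN"` both denote missing target values; rows with missing predictors are
#' rejected.
#'
#' @inheritParams traj_data
#' @param path Path to the CSV file.
#' @return A `traj_data` object.
#' @export
read_traj_csv <- function(path, subject, predictors, targets = character(),
                          targets_binary = character(), intercept = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA", "NaN"))
  traj_data(df, subject = subject, predictors = predictors, targets = targets,
            targets_binary = targets_binary, intercept = intercept)
}

#' @export
print.traj_data <- function(x, ...) {
  cat("<traj_data> ", nrow(x$X), " observations, ",
      length(x$subjects), " subjects\n", sep = "")
  cat("  subject column: ", x$subject_col, "\n", sep = "")
  cat("  predictors:     ", paste(x$predictors, collapse = ", "), "\n", sep = "")
  if (length(x$targets) > 0) {
    cat("  continuous:     ", paste(x$targets, collapse = ", "), "\n", sep = "")
  }
  if (length(x$targets_binary) > 0) {
    cat("  binary:         ", paste(x$targets_binary, collapse = ", "), "\n",
        sep = "")
  }
  n_miss <- sum(is.na(x$Y)) + sum(is.na(x$B))
  if (n_miss > 0) cat("  missing target cells: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a trajectory dataset
#' @param data A `traj_data` object.
#' @return Integer count of distinct subjects.
#' @export
n_subjects <- function(data) {
  stopifnot(inherits(data, "traj_data"))
  length(data$subjects)
}
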
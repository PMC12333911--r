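#' Competing-risks dataset
#'
#' Construct and validate a subject-level competing-risks dataset: an
#' observation time `T* = min(T, C)`, an event status in `{0, 1, ..., K}`
#' (0 = censored), a binary treatment, and baseline covariates. Factor or
#' character covariates are expanded to reference-coded indicator columns
#' with lexicographically ordered levels, so repeated construction from the
#' same input yields the same column order.
#'
#' @param time numeric vector of non-negative observation times.
#' @param status integer vector with values in `0:K`; 0 marks censoring.
#' @param treatment integer (or logical) vector with values 0/1.
#' @param covariates data frame or matrix of baseline covariates; factors
#'   and character columns are expanded to indicators.
#' @param id optional subject identifiers (defaults to row numbers).
#' @param K number of competing event types; inferred as `max(status)` when
#'   `NULL`.
#'
#' @return A data frame of class `"cr_data"` with columns `id`, `time`,
#'   `status`, `treatment` and one numeric column per (expanded) covariate,
#'   plus attributes `K` and `covariates` (the covariate column names).
#'
#' @details Missing values are rejected (complete-case analysis). Ties
#'   between an event and a censoring at the same time follow the
#'   product-limit convention that events precede censoring: the censored
#'   subject still counts as at risk at that time.
#'
#' @examples
#' d <- cr_data(time = c(1, 2, 3, 4), status = c(1, 0, 2, 1),
#'              treatment = c(0, 0, 1, 1),
#'              covariates = data.frame(x = c(0.5, -1, 2, 0)))
#' attr(d, "K")
#' @export
cr_data <- function(time, status, treatment, covariates = NULL, id = NULL,
                    K = NULL) {
  n <- length(time)
  if (n < 1L) stop("empty dataset")
  if (length(status) != n || length(treatment) != n)
    stop("time, status and treatment must have equal length")
  treatment <- as.integer(treatment)
  status <- as.integer(status)

  X <- expand_covariates(covariates, n)

  bad <- which(is.na(time) | is.na(status) | is.na(treatment))
  if (!is.null(X)) bad <- union(bad, which(rowSums(is.na(X)) > 0))
  if (length(bad))
    stop("missing values in row(s) ", paste(sort(bad)[seq_len(min(5, length(bad)))],
                                            collapse = ", "),
         " (complete cases required)")
  bad <- which(time < 0)
  if (length(bad)) stop("negative time in row ", bad[1])
  if (is.null(K)) K <- max(status, 1L)
  bad <- which(status < 0L | status > K)
  if (length(bad))
    stop("status outside {0..", K, "} in row ", bad[1])
  bad <- which(!treatment %in% c(0L, 1L))
  if (length(bad)) stop("treatment not in {0,1} in row ", bad[1])
  if (length(unique(treatment)) < 2L)
    stop("both treatment arms must be present")

  out <- data.frame(id = if (is.null(id)) seq_len(n) else id,
                    time = as.numeric(time), status = status,
                    treatment = treatment)
  if (!is.null(X)) out <- cbind(out, as.data.frame(X))
  structure(out, K = as.integer(K),
            covariates = if (is.null(X)) character(0) else colnames(X),
            class = c("cr_data", "data.frame"))
}

# Expand a covariate frame to a numeric matrix, reference-coding factors
# with lexicographic level order. Returns NULL when there are no covariates.
expand_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  if (!is.data.frame(covariates)) covariates <- data.frame(x = covariates)
  if (nrow(covariates) != n) stop("covariates must have one row per subject")
  if (ncol(covariates) == 0L) return(NULL)
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]], levels = sort(unique(covariates[[j]])))
    else if (is.factor(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]],
                                levels = sort(levels(covariates[[j]])))
  }
  X <- model.matrix(~ ., data = covariates)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  rownames(X) <- NULL
  X
}

#' Read a competing-risks dataset from delimited text
#'
#' Reads a header-ed delimited file and builds a validated [cr_data()]
#' object. Column roles are given by name; all remaining columns are used
#' as covariates unless `covariate_cols` is supplied.
#'
#' @param path file path.
#' @param time_col,status_col,treat_col column names for the observation
#'   time, event status and treatment indicator.
#' @param covariate_cols character vector of covariate column names;
#'   defaults to every other column.
#' @param sep field separator (default comma).
#' @param K number of event types; inferred from the data when `NULL`.
#' @return A `"cr_data"` object.
#' @export
read_cr_data <- function(path, time_col = "time", status_col = "status",
                         treat_col = "treatment", covariate_cols = NULL,
                         sep = ",", K = NULL) {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c(time_col, status_col, treat_col, covariate_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("column(s) not found in ", path, ": ", paste(miss, collapse = ", "))
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(df), c(time_col, status_col, treat_col, "id"))
  cr_data(time = df[[time_col]], status = df[[status_col]],
          treatment = df[[treat_col]],
          covariates = if (length(covariate_cols))
            df[covariate_cols] else NULL,
          id = if ("id" %in% names(df)) df[["id"]] else NULL,
          K = K)
}

#' Write and read estimate tables
#'
#' `write_estimates()` writes the long-format estimate table of an
#' [adjcif()] fit (or the data frame produced by `as.data.frame()` on one)
#' to delimited text with full double precision, so that
#' `read_estimates()` reproduces the numeric values bit-identically.
#'
#' @param estimate an `adjcif` object or a long-format estimate data frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `write_estimates()` returns `path` invisibly;
#'   `read_estimates()` returns a data frame.
#' @export
write_estimates <- function(estimate, path, sep = ",") {
  df <- if (inherits(estimate, "adjcif")) as.data.frame(estimate) else estimate
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  for (col in intersect(c("time", "estimate", "lower", "upper"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}

# coerce helpers used across the package
as_cr_data <- function(x) {
  if (inherits(x, "cr_data")) return(x)
  stop("expected a 'cr_data' object; see cr_data() or read_cr_data()")
}

cov_matrix <- function(data) {
  cn <- attr(data, "covariates")
  if (!length(cn)) return(matrix(numeric(0), nrow(data), 0))
  as.matrix(data[cn])
}
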
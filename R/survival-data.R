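#' Construct a right-censored survival dataset
#'
#' Bundles observed times, event indicators and a covariate matrix into the
#' container used by every fitting function in the package. Covariates listed
#' in `unpenalized` are estimated freely: they enter the Cox model but are
#' excluded from the fusion penalty and from cluster extraction (the typical
#' use is an adjustment covariate such as gender alongside the features being
#' clustered).
#'
#' @param time numeric vector of strictly positive observed times (event or
#'   censoring time).
#' @param status integer/numeric vector of event indicators: 1 = event,
#'   0 = right-censored.
#' @param x numeric matrix (or data frame) of covariates, one row per subject.
#'   Column names are kept and define the coefficient order; unnamed columns
#'   are named `x1, x2, ...`.
#' @param unpenalized columns excluded from the fusion penalty, given as
#'   column names or integer indices. May be empty.
#' @return An object of class `"survival_data"`: a list with elements `time`,
#'   `status`, `x`, and `unpenalized` (integer column indices).
#' @examples
#' d <- survival_data(time = c(2, 5, 3), status = c(1, 0, 1),
#'                    x = matrix(rnorm(6), 3, 2))
#' d
#' @export
survival_data <- function(time, status, x, unpenalized = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = length(time))
  storage.mode(x) <- "double"
  n <- length(time)
  if (length(status) != n || nrow(x) != n)
    stop("time, status and x must describe the same number of subjects", call. = FALSE)
  if (anyNA(time) || anyNA(status) || anyNA(x))
    stop("missing values are not allowed", call. = FALSE)
  if (any(time <= 0))
    stop("times must be strictly positive", call. = FALSE)
  if (!all(status %in% c(0, 1)))
    stop("status must be 0 (censored) or 1 (event)", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  p <- ncol(x)
  if (is.character(unpenalized)) {
    miss <- setdiff(unpenalized, colnames(x))
    if (length(miss))
      stop("unknown unpenalized column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    unpenalized <- match(unpenalized, colnames(x))
  }
  unpenalized <- sort(unique(as.integer(unpenalized)))
  if (length(unpenalized) && (min(unpenalized) < 1L || max(unpenalized) > p))
    stop("unpenalized indices out of range", call. = FALSE)
  structure(list(time = time, status = status, x = x,
                 unpenalized = unpenalized),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat("Right-censored survival dataset\n")
  cat(sprintf("  n = %d subjects (%d events, %d censored)\n",
              length(x$time), sum(x$status == 1), sum(x$status == 0)))
  cat(sprintf("  p = %d covariates (%d unpenalized)\n",
              ncol(x$x), length(x$unpenalized)))
  invisible(x)
}

# Indices of covariate columns subject to the fusion penalty.
penalized_cols <- function(data) {
  setdiff(seq_len(ncol(data$x)), data$unpenalized)
}

#' Read a survival table from delimited text
#'
#' Expects a header row with columns `time` and `status`; every remaining
#' column is treated as a covariate, in file order.
#'
#' @param path path to a CSV (or other delimited) file.
#' @param unpenalized covariate columns excluded from the fusion penalty
#'   (names or indices into the covariate block).
#' @param sep field separator, default comma.
#' @return A [survival_data] object.
#' @export
read_survival_table <- function(path, unpenalized = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  for (col in c("time", "status"))
    if (!col %in% names(df))
      stop(sprintf("input table is missing required column '%s'", col), call. = FALSE)
  covar <- df[, setdiff(names(df), c("time", "status")), drop = FALSE]
  if (ncol(covar) == 0L)
    stop("input table has no covariate columns", call. = FALSE)
  survival_data(df$time, df$status, as.matrix(covar), unpenalized = unpenalized)
}

#' Write a survival dataset as CSV
#'
#' Inverse of [read_survival_table()]: columns `time`, `status`, then the
#' covariates.
#'
#' @param data a [survival_data] object.
#' @param path output file path.
#' @export
write_survival_table <- function(data, path) {
  stopifnot(inherits(data, "survival_data"))
  df <- data.frame(time = data$time, status = data$status, check.names = FALSE)
  df <- cbind(df, as.data.frame(data$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
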
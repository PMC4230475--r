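#' Construct a subject-level survival sample
#'
#' The container used throughout the package: observed follow-up times,
#' event indicators (1 = failure observed, 0 = censored), an exposure
#' (binary 0/1 or continuous) and optional measured covariates.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event is required.
#' @param exposure numeric exposure, one value per subject.
#' @param covariates optional data frame or matrix of measured covariates
#'   with named columns, one row per subject.
#' @return An object of class `survival_sample`.
#' @export
survival_sample <- function(time, event, exposure, covariates = NULL) {
  n <- length(time)
  if (length(event) != n || length(exposure) != n)
    stop("time, event and exposure must have equal length")
  if (anyNA(time) || anyNA(event) || anyNA(exposure))
    stop("missing values are not allowed in time, event or exposure")
  bad <- which(!(time > 0))
  if (length(bad))
    stop("non-positive follow-up time in row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be coded 0 (censored) / 1 (event)")
  if (sum(event) == 0)
    stop("no events present: at least one event is required")
  cov_names <- character()
  df <- data.frame(time = as.numeric(time), event = as.numeric(event),
                   exposure = as.numeric(exposure))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject")
    if (anyNA(covariates)) stop("missing values are not allowed in covariates")
    cov_names <- names(covariates)
    if (anyDuplicated(c(names(df), cov_names)))
      stop("covariate names must be unique and distinct from time/event/exposure")
    df <- cbind(df, covariates)
  }
  structure(list(data = df, covariate_names = cov_names),
            class = "survival_sample")
}

#' @export
print.survival_sample <- function(x, ...) {
  cat(sprintf("survival_sample: %d subjects, %d events (%.1f%% censored)\n",
              nrow(x$data), sum(x$data$event),
              100 * (1 - mean(x$data$event))))
  if (length(x$covariate_names))
    cat("covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a sample
#' @param sample a [survival_sample()].
#' @export
n_subjects <- function(sample) nrow(sample$data)

#' Read a survival sample from delimited text
#'
#' Reads a CSV/TSV file with a header and maps its columns onto the internal
#' convention (`time`, `event` with 1 = event, `exposure`). Rows with missing
#' values in any mapped column are rejected; the retained/rejected counts are
#' attached as attributes and reported via a message, so no row is dropped
#' silently.
#'
#' @param path file path to a delimited text file with header.
#' @param columns named list/vector mapping internal names (`time`, `event`,
#'   `exposure`) to column names in the file.
#' @param covariates optional character vector of covariate column names.
#' @param sep field separator; `NULL` picks `,` or tab from the first line.
#' @return A [survival_sample()] with attributes `retained` and `rejected`.
#' @export
read_sample <- function(path,
                        columns = c(time = "time", event = "event",
                                    exposure = "exposure"),
                        covariates = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  columns <- as.list(columns)
  for (nm in c("time", "event", "exposure"))
    if (is.null(columns[[nm]]))
      stop("column map must name a '", nm, "' column")
  needed <- c(unlist(columns), covariates)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("column(s) not present in file: ", paste(missing_cols, collapse = ", "))
  sub <- raw[, needed, drop = FALSE]
  ok <- stats::complete.cases(sub)
  rejected <- sum(!ok)
  if (rejected > 0)
    message(rejected, " row(s) with missing mapped fields rejected; ",
            sum(ok), " retained")
  sub <- sub[ok, , drop = FALSE]
  covs <- if (length(covariates)) sub[, covariates, drop = FALSE] else NULL
  out <- survival_sample(sub[[columns$time]], sub[[columns$event]],
                         sub[[columns$exposure]], covariates = covs)
  attr(out, "retained") <- sum(ok)
  attr(out, "rejected") <- rejected
  out
}

#' Write a results table to CSV
#'
#' Writes a rectangular results table with numeric columns rendered at 10
#' significant digits, so that [read_table()] round-trips values to within
#' 1e-9 relative accuracy.
#'
#' @param table a non-empty data frame.
#' @param path output file path.
#' @export
write_table <- function(table, path) {
  table <- as.data.frame(table)
  if (nrow(table) == 0L || ncol(table) == 0L)
    stop("refusing to write an empty table")
  if (anyDuplicated(names(table))) stop("column names must be unique")
  out <- table
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.10g", out[[j]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write table to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a results table written by [write_table()]
#' @param path file path.
#' @return data frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
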
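#' Read and write two-stage SMART trial tables
#'
#' A trial table is stored as comma-separated text with header
#' `O1,A1,O2,A2,Y` and empty cells for missing values.  Binary variables
#' use the -1/+1 coding throughout the package; files using 0/1 coding can
#' be converted on read with `recode01 = TRUE` (never silently).
#'
#' @param path File path.
#' @param recode01 If `TRUE`, map 0/1-coded binary columns to -1/+1 on read
#'   (and back to 0/1 on write).  Default `FALSE`.
#' @return `read_trial` returns a `data.frame` with columns
#'   `O1, A1, O2, A2, Y`; `write_trial` returns `path` invisibly.
#' @export
#' @examples
#' tab <- simulate_trial(treatment_effect_preset(1)$params, 5, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trial(tab, f)
#' identical(dim(read_trial(f)), dim(tab))
read_trial <- function(path, recode01 = FALSE) {
  tab <- utils::read.csv(path, header = TRUE, na.strings = "",
                         colClasses = "numeric")
  expected <- c("O1", "A1", "O2", "A2", "Y")
  if (!identical(names(tab), expected)) {
    stop("trial file must have header exactly O1,A1,O2,A2,Y; got: ",
         paste(names(tab), collapse = ","))
  }
  if (recode01) {
    for (v in c("O1", "A1", "O2", "A2")) tab[[v]] <- 2 * tab[[v]] - 1
  }
  validate_trial(tab)
  tab
}

#' @rdname read_trial
#' @param data A trial `data.frame` (columns `O1, A1, O2, A2, Y`).
#' @export
write_trial <- function(data, path, recode01 = FALSE) {
  validate_trial(data)
  out <- data
  if (recode01) {
    for (v in c("O1", "A1", "O2", "A2")) out[[v]] <- (out[[v]] + 1) / 2
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# Structural checks shared by I/O and estimators: column set, -1/+1 coding
# of non-missing binary cells, O1/A1 complete, at least one record.
validate_trial <- function(data) {
  expected <- c("O1", "A1", "O2", "A2", "Y")
  if (!is.data.frame(data) || !identical(names(data), expected)) {
    stop("trial table must be a data.frame with columns O1, A1, O2, A2, Y")
  }
  if (nrow(data) < 1) stop("trial table must contain at least one record")
  for (v in c("O1", "A1", "O2", "A2")) {
    x <- data[[v]]
    if (!all(x[!is.na(x)] %in% c(-1, 1))) {
      stop("non-missing values of ", v, " must all be -1 or +1")
    }
  }
  if (anyNA(data$O1) || anyNA(data$A1)) {
    stop("O1 and A1 must be fully observed")
  }
  invisible(data)
}
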
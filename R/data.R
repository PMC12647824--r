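#' Validate clustered two-sample (possibly censored) data
#'
#' Checks the invariants of the clustered two-sample layout used throughout
#' the package: one row per subject with a cluster identifier, an outcome
#' \code{y} (for survival data the observed time \code{min(T, C)}), an
#' optional \code{event} indicator (1 = event observed; if absent all rows
#' are treated as events) and a binary treatment \code{arm}.
#'
#' @param data data.frame with columns \code{cluster}, \code{y}, \code{arm}
#'   and optionally \code{event}.  Extra columns are ignored.
#' @return the validated data.frame with \code{event} filled in.
#' @export
as_clustered_data <- function(data) {
  data <- as.data.frame(data)
  need <- c("cluster", "y", "arm")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 1L) stop("empty dataset")
  if (!all(is.finite(data$y)))
    stop("non-finite outcome y at row(s) ",
         paste(utils::head(which(!is.finite(data$y)), 5L), collapse = ", "))
  if (!all(data$arm %in% c(0, 1)))
    stop("arm must be binary 0/1")
  if (is.null(data$event)) {
    data$event <- 1L
  } else if (!all(data$event %in% c(0, 1))) {
    stop("event must be binary 0/1")
  }
  data
}

#' Validate clustered paired-difference data
#'
#' One row per subunit with a cluster identifier, a subunit identifier and
#' either a paired difference \code{d} or the pair \code{(y1, y2)} from
#' which \code{d = y2 - y1} is computed.
#'
#' @param data data.frame with columns \code{cluster}, \code{subunit} and
#'   \code{d} (or \code{y1} and \code{y2}).
#' @return the validated data.frame with column \code{d} present.
#' @export
as_paired_data <- function(data) {
  data <- as.data.frame(data)
  if (is.null(data$cluster)) stop("missing required column(s): cluster")
  if (is.null(data$d)) {
    if (is.null(data$y1) || is.null(data$y2))
      stop("paired data needs either column d or columns y1 and y2")
    data$d <- data$y2 - data$y1
  }
  if (is.null(data$subunit)) data$subunit <- stats::ave(
    rep(1, nrow(data)), data$cluster, FUN = seq_along)
  if (!all(is.finite(data$d)))
    stop("non-finite paired difference at row(s) ",
         paste(utils::head(which(!is.finite(data$d)), 5L), collapse = ", "))
  data
}

#' Read clustered data from a delimited text file
#'
#' The separator is auto-detected from the file extension (\code{.csv} =
#' comma, anything else = tab).  A header line is required; extra columns
#' are ignored.  Survival/two-sample files use columns
#' \code{cluster,y,event,arm} (\code{event} optional); paired files use
#' \code{cluster,subunit,d} or \code{cluster,subunit,y1,y2}.
#'
#' @param path file path.
#' @param type "survival" (two-sample, possibly censored) or "paired".
#' @return validated data.frame.
#' @export
read_clustered_data <- function(path, type = c("survival", "paired")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (type == "survival") as_clustered_data(df) else as_paired_data(df)
}
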
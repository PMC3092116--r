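#' @useDynLib omicsurv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad sd quantile rnorm runif rexp rbinom p.adjust
#'   pchisq pt loess loess.control predict setNames complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

# Internal: stop with a message naming the offending argument/field.
fail_field <- function(field, why) {
  stop(sprintf("invalid '%s': %s", field, why), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    fail_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_real <- function(x, field, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper)
    fail_field(field, sprintf("must be a number in [%s, %s]", lower, upper))
  as.numeric(x)
}

#' Read a tab-separated table
#'
#' Thin wrapper over [utils::read.delim()] with the conventions used by all
#' pipeline inputs: header row, no row names, strings kept as character.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: read a features x samples matrix from TSV (first column = feature id).
read_matrix_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_table(df, path)
}

# Internal: midpoint median (stats::median already does this for even n).
# Kept as a named helper so the convention is explicit at call sites.
midpoint_median <- function(x) median(x, na.rm = TRUE)
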
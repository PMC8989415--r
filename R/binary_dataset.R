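#' Binary dataset container
#'
#' Wraps an M x N matrix with entries in \{0, 1\}: M samples (rows) of N binary
#' units (columns). Entries other than exactly 0 or 1 (including missing
#' values) are rejected rather than coerced, since silent coercion corrupts
#' the exact counts all downstream statistics rest on.
#'
#' @param values numeric or integer matrix with entries in \{0, 1\}.
#' @param labels optional character vector of unit names (length N).
#' @param flip_mask optional logical vector of length N recording columns that
#'   were relabelled by \code{sigma -> 1 - sigma} (see
#'   [flip_majority_columns()]).
#' @return an object of class \code{"binary_dataset"}: an integer matrix with
#'   \code{labels} and \code{flip_mask} attributes.
#' @seealso [read_binary_dataset()], [column_frequencies()], [word_count()]
#' @export
binary_dataset <- function(values, labels = NULL, flip_mask = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a binary dataset needs at least one row and one column")
  bad <- which(is.na(values) | !(values == 0 | values == 1))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("non-binary entry at row %d, column %d", i, j))
  }
  storage.mode(values) <- "integer"
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("u", seq_len(ncol(values)))
  }
  if (length(labels) != ncol(values))
    stop("labels must have one entry per column")
  if (is.null(flip_mask)) flip_mask <- rep(FALSE, ncol(values))
  if (length(flip_mask) != ncol(values))
    stop("flip_mask must have one entry per column")
  colnames(values) <- labels
  structure(values,
            labels = labels, flip_mask = as.logical(flip_mask),
            class = c("binary_dataset", "matrix", "array"))
}

#' @export
print.binary_dataset <- function(x, ...) {
  f <- column_frequencies(x) / nrow(x)
  cat(sprintf("binary dataset: %d samples x %d units\n", nrow(x), ncol(x)))
  cat(sprintf("  mean activation %.3f (range %.3f-%.3f)\n",
              mean(f), min(f), max(f)))
  if (any(attr(x, "flip_mask")))
    cat("  flipped columns:",
        paste(which(attr(x, "flip_mask")), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.binary_dataset <- function(x, ...) {
  y <- unclass(x)
  attr(y, "labels") <- NULL
  attr(y, "flip_mask") <- NULL
  y
}

as_binary_dataset <- function(x) {
  if (inherits(x, "binary_dataset")) x else binary_dataset(x)
}

#' Read a binary dataset from delimited text
#'
#' One sample per row, comma- or tab-separated, with an optional header row of
#' unit labels. The delimiter is sniffed from the first line unless given.
#'
#' @param file path to the file.
#' @param header logical; does the first row carry unit labels?
#' @param sep field separator; \code{NULL} (default) picks tab if present in
#'   the first line, otherwise comma.
#' @return a [binary_dataset()].
#' @export
read_binary_dataset <- function(file, header = FALSE, sep = NULL) {
  if (!file.exists(file)) stop("input file not found: ", file)
  if (is.null(sep)) {
    l1 <- readLines(file, n = 1L)
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  d <- read.table(file, header = header, sep = sep, check.names = FALSE)
  binary_dataset(as.matrix(d),
                 labels = if (header) colnames(d) else NULL)
}

#' Write a binary dataset as delimited text
#'
#' @param data a [binary_dataset()] (or plain binary matrix).
#' @param file output path.
#' @param sep field separator (default tab).
#' @param header write the unit labels as a first row?
#' @return \code{file}, invisibly.
#' @export
write_binary_dataset <- function(data, file, sep = "\t", header = TRUE) {
  data <- as_binary_dataset(data)
  write.table(as.matrix(data), file, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = header)
  invisible(file)
}

#' Per-unit activation counts
#'
#' @param data a [binary_dataset()] or binary matrix.
#' @return integer vector \code{n_i}: the number of samples in which unit i
#'   equals 1.
#' @export
column_frequencies <- function(data) {
  data <- as_binary_dataset(data)
  as.integer(colSums(data))
}

check_support <- function(support, n_units) {
  support <- as.integer(support)
  if (length(support) == 0L) stop("word support must be nonempty")
  if (anyDuplicated(support)) stop("word support indices must be unique")
  if (any(support < 1L) || any(support > n_units))
    stop("word support indices out of range")
  sort(support)
}

#' Empirical count of a word
#'
#' The number of samples in which every unit of \code{support} equals 1.
#'
#' @param data a [binary_dataset()] or binary matrix.
#' @param support integer vector of unit (column) indices, nonempty.
#' @return integer count \code{n_mu}.
#' @export
word_count <- function(data, support) {
  data <- as_binary_dataset(data)
  support <- check_support(support, ncol(data))
  sub <- data[, support, drop = FALSE]
  sum(rowSums(sub) == length(support))
}

#' Null-model expectation of a word's frequency
#'
#' Under the independent null model matching each unit's marginal frequency,
#' the expected frequency of a word is the product of its units' marginals:
#' \code{prod(n_i / M)} over \code{i} in the support.
#'
#' @param n integer vector of per-unit counts (see [column_frequencies()]).
#' @param M number of samples.
#' @param support integer vector of unit indices.
#' @return the null expectation, in \[0, 1\].
#' @export
null_expectation <- function(n, M, support) {
  if (M < 1) stop("M must be positive")
  if (any(n > M) || any(n < 0)) stop("counts must lie in [0, M]")
  support <- check_support(support, length(n))
  prod(n[support] / M)
}

#' Null-model variance of a word indicator
#'
#' A word indicator is Bernoulli under the null, so its variance is
#' \code{p * (1 - p)} with \code{p} the null expectation.
#'
#' @param null_mean null expectation in \[0, 1\].
#' @return the null variance.
#' @export
null_variance <- function(null_mean) {
  if (any(null_mean < 0 | null_mean > 1)) stop("null_mean must lie in [0, 1]")
  null_mean * (1 - null_mean)
}

#' Null-model covariance between two word indicators
#'
#' \code{prod over the union of n_k/M} minus the product of the two null
#' means. Exactly zero when the supports are disjoint.
#'
#' @param n integer vector of per-unit counts.
#' @param M number of samples.
#' @param support_a,support_b integer vectors of unit indices.
#' @return the null covariance.
#' @export
null_covariance <- function(n, M, support_a, support_b) {
  support_a <- check_support(support_a, length(n))
  support_b <- check_support(support_b, length(n))
  if (length(intersect(support_a, support_b)) == 0L) return(0)
  pu <- prod(n[union(support_a, support_b)] / M)
  pu - null_expectation(n, M, support_a) * null_expectation(n, M, support_b)
}

#' Complement columns that are active in more than half the samples
#'
#' The null-model analysis of absent words requires the mean activation to be
#' below 1/2; columns with frequency strictly above 1/2 are relabelled
#' \code{sigma -> 1 - sigma}, and the returned \code{flip_mask} attribute
#' records which. Columns at exactly 1/2 are left unchanged.
#'
#' @param data a [binary_dataset()] or binary matrix.
#' @return a [binary_dataset()] with the flipped columns and an updated
#'   \code{flip_mask} attribute.
#' @export
flip_majority_columns <- function(data) {
  data <- as_binary_dataset(data)
  f <- column_frequencies(data) / nrow(data)
  flip <- f > 0.5
  values <- as.matrix(data)
  values[, flip] <- 1L - values[, flip, drop = FALSE]
  binary_dataset(values, labels = attr(data, "labels"),
                 flip_mask = xor(attr(data, "flip_mask"), flip))
}
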
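#' Configuration of the candidate-word stage
#'
#' @param k_max maximum word order (number of units in a support). Orders
#'   beyond 4-5 carry no signal at typical activation levels (the expected
#'   count of an order-k word scales as \code{M * q^k}), so the default is 5.
#' @param absent_threshold minimum null-expected count \code{M * <sigma_mu>}
#'   for an absent word to stay a candidate (default 0.02). Absent words below
#'   it have vanishing fields and are dropped.
#' @param n_max number of candidates retained for the Ising stage, keeping the
#'   largest absolute fields (default 500).
#' @return a list of class \code{"candidate_config"}.
#' @export
candidate_config <- function(k_max = 5L, absent_threshold = 0.02, n_max = 500L) {
  k_max <- as.integer(k_max)
  n_max <- as.integer(n_max)
  stopifnot(k_max >= 1L, absent_threshold > 0, n_max >= 1L)
  structure(list(k_max = k_max, absent_threshold = absent_threshold,
                 n_max = n_max), class = "candidate_config")
}

#' Enumerate candidate words with their moment statistics
#'
#' Scans every support of order up to \code{k_max} over the non-constant
#' columns and keeps those that either occur at least once in the data, or are
#' absent but have null-expected count \code{M * <sigma_mu>} at or above
#' \code{absent_threshold} (absent-but-expected words can be significantly
#' under-represented). Constant columns (all 0 or all 1) have zero null
#' variance and vanishing fields, so they are excluded from supports.
#'
#' @param data a [binary_dataset()] or binary matrix.
#' @param config a [candidate_config()].
#' @return a data frame of class \code{"candidate_set"} with one row per
#'   candidate: \code{mask} (bit encoding over usable columns), \code{order},
#'   \code{n_mu}, \code{sigma_bar}, \code{null_mean}, \code{null_var},
#'   \code{h} (the magnetic field, see [compute_field()]), and a
#'   deterministic lexicographic tie-break key. Attributes: \code{M},
#'   \code{columns} (original column index of each mask bit), \code{labels}.
#' @export
enumerate_candidates <- function(data, config = candidate_config()) {
  data <- as_binary_dataset(data)
  M <- nrow(data)
  n <- column_frequencies(data)
  usable <- which(n > 0L & n < M)
  k_max <- config$k_max
  if (k_max > length(usable)) {
    warning("k_max exceeds the number of usable columns; clipped to ",
            length(usable))
    k_max <- length(usable)
  }
  if (length(usable) == 0L) {
    res <- data.frame(mask = numeric(0), order = integer(0), n_mu = integer(0),
                      sigma_bar = numeric(0), null_mean = numeric(0),
                      null_var = numeric(0), h = numeric(0), lexkey = numeric(0))
  } else {
    raw <- .enum_candidates_cpp(as.matrix(data), usable, k_max,
                                config$absent_threshold)
    res <- data.frame(mask = raw$mask, order = raw$order, n_mu = raw$n_mu,
                      sigma_bar = raw$n_mu / M, null_mean = raw$null_mean,
                      null_var = raw$null_mean * (1 - raw$null_mean),
                      lexkey = raw$lexkey)
    res$h <- compute_field(res$sigma_bar, res$null_mean, M, res$null_var)
  }
  structure(res, M = M, columns = usable, labels = attr(data, "labels"),
            config = config, class = c("candidate_set", "data.frame"))
}

#' Decode candidate supports
#'
#' @param cands a \code{"candidate_set"} (see [enumerate_candidates()]) or an
#'   Ising system.
#' @param rows optional row indices to decode.
#' @return list of integer vectors of original column indices.
#' @export
candidate_supports <- function(cands, rows = NULL) {
  cols <- attr(cands, "columns")
  masks <- cands$mask
  if (!is.null(rows)) masks <- masks[rows]
  decode_masks(masks, cols)
}

decode_masks <- function(masks, cols) {
  bits <- mask_bits(masks, length(cols))
  apply(bits, 1L, function(b) cols[which(b > 0)], simplify = FALSE)
}

# rows = masks, columns = bit indicators (exact for masks below 2^52)
mask_bits <- function(masks, nbits) {
  out <- matrix(0, length(masks), nbits)
  for (j in seq_len(nbits)) out[, j] <- (masks %/% 2^(j - 1)) %% 2
  out
}

encode_support <- function(support, cols) {
  j <- match(support, cols)
  if (anyNA(j)) return(NA_real_)
  sum(2^(j - 1))
}

#' Magnetic field of a candidate word
#'
#' \code{h = (M^2 / 2) * ((sigma_bar - null_mean)^2 - null_var / M)}: positive
#' when the squared deviation of the empirical frequency from the null
#' expectation exceeds the null variance of the frequency estimate (i.e. the
#' word is anomalously represented, in either direction), negative when the
#' frequency is as expected.
#'
#' @param sigma_bar empirical frequency \code{n_mu / M}.
#' @param null_mean null expectation (see [null_expectation()]).
#' @param M number of samples.
#' @param null_var null variance; defaults to \code{null_mean * (1 - null_mean)}.
#' @return the field (vectorised).
#' @export
compute_field <- function(sigma_bar, null_mean, M,
                          null_var = null_mean * (1 - null_mean)) {
  (M^2 / 2) * ((sigma_bar - null_mean)^2 - null_var / M)
}

#' Exchange coupling between two candidate words
#'
#' \code{J = (M^2 / 4) * cov * (cov - 2 * M * dev_a * dev_b)} where \code{cov}
#' is the null covariance of the two word indicators and \code{dev} the
#' deviations \code{sigma_bar - null_mean}. Exactly zero for disjoint
#' supports. Predominantly negative when two overlapping words are expected
#' to be correlated and co-occur roughly as expected, which makes related
#' candidates compete for inclusion in the dictionary.
#'
#' @param dev_a,dev_b deviations of the two words.
#' @param cov_ab their null covariance (see [null_covariance()]).
#' @param M number of samples.
#' @return the coupling (vectorised).
#' @export
compute_coupling <- function(dev_a, dev_b, cov_ab, M) {
  (M^2 / 4) * cov_ab * (cov_ab - 2 * M * dev_a * dev_b)
}

#' Select the top candidates and build the indicator Ising system
#'
#' Retains the \code{n_max} candidates with the largest absolute fields (ties
#' broken by lower order, then lexicographic support) and computes the full
#' exchange-coupling matrix among them; couplings are nonzero only for pairs
#' with intersecting supports.
#'
#' @param cands a \code{"candidate_set"} from [enumerate_candidates()].
#' @param config a [candidate_config()] (for \code{n_max}).
#' @return an object of class \code{"ising_system"}: list with
#'   \code{candidates} (retained rows of \code{cands}), \code{supports}
#'   (decoded, original column indices), \code{h}, \code{J} (dense symmetric
#'   matrix, zero diagonal), \code{M}, \code{columns}, \code{labels}.
#' @export
select_top_candidates <- function(cands, config = attr(cands, "config")) {
  if (is.null(config)) config <- candidate_config()
  M <- attr(cands, "M")
  cols <- attr(cands, "columns")
  ord <- order(-abs(cands$h), cands$order, cands$lexkey)
  keep <- ord[seq_len(min(config$n_max, nrow(cands)))]
  top <- cands[keep, , drop = FALSE]
  S <- mask_bits(top$mask, length(cols))
  J <- coupling_matrix(S, column_frequencies_from(cands), M,
                       top$null_mean, top$sigma_bar - top$null_mean)
  structure(list(candidates = top, supports = decode_masks(top$mask, cols),
                 h = top$h, J = J, M = M, columns = cols,
                 labels = attr(cands, "labels"), config = config),
            class = "ising_system")
}

# per-usable-column marginal frequencies recovered from the order-1 candidates
column_frequencies_from <- function(cands) {
  cols <- attr(cands, "columns")
  o1 <- cands[cands$order == 1L, , drop = FALSE]
  f <- numeric(length(cols))
  j <- round(log2(o1$mask)) + 1L
  f[j] <- o1$sigma_bar
  if (any(f <= 0))
    stop("marginal frequencies missing for some usable columns")
  f
}

# S: n_ret x nc 0/1 support matrix over usable columns with frequencies f.
# Null covariance via cov = exp(sum_union log f) - exp(sum_a + sum_b log f)
#                        = exp(sum_a + sum_b) * expm1(-sum_intersection),
# which is exactly zero for disjoint pairs.
coupling_matrix <- function(S, f, M, null_mean, dev) {
  logf <- log(f)
  A <- sweep(S, 2L, logf, `*`)
  I <- tcrossprod(A, S)              # sum of log f over the intersection
  sumlog <- as.vector(S %*% logf)
  cov <- exp(outer(sumlog, sumlog, `+`)) * expm1(-I)
  J <- compute_coupling(outer(dev, rep(1, length(dev))),
                        outer(rep(1, length(dev)), dev), cov, M)
  diag(J) <- 0
  J
}

#' @export
print.ising_system <- function(x, ...) {
  cat(sprintf("indicator Ising system: %d candidates over %d units (M = %d)\n",
              length(x$h), length(x$columns), x$M))
  cat(sprintf("  |h| range %.3g - %.3g; %d nonzero couplings\n",
              min(abs(x$h)), max(abs(x$h)), sum(x$J != 0) / 2))
  invisible(x)
}

#' Write fields and couplings as delimited text
#'
#' Two files: \code{<stem>_fields.tsv} (candidate, support, h) and
#' \code{<stem>_couplings.tsv} (candidate_a, candidate_b, J; nonzero entries
#' with a < b). Support indices are serialised 0-based, semicolon-joined.
#'
#' @param system an \code{"ising_system"}.
#' @param stem output path stem.
#' @return the two file paths, invisibly.
#' @export
write_ising_system <- function(system, stem) {
  supp <- vapply(system$supports,
                 function(s) paste(s - 1L, collapse = ";"), character(1))
  ff <- paste0(stem, "_fields.tsv")
  write.table(data.frame(candidate = seq_along(system$h), support = supp,
                         h = system$h),
              ff, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(system$J) & system$J != 0, arr.ind = TRUE)
  fc <- paste0(stem, "_couplings.tsv")
  write.table(data.frame(candidate_a = idx[, 1], candidate_b = idx[, 2],
                         J = system$J[idx]),
              fc, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ff, fc))
}

#' Write candidate statistics as delimited text
#'
#' Columns: support (0-based, semicolon-joined), n_mu, sigma_bar, null_mean,
#' null_var.
#'
#' @param cands a \code{"candidate_set"}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_candidates <- function(cands, file) {
  supp <- vapply(candidate_supports(cands),
                 function(s) paste(s - 1L, collapse = ";"), character(1))
  write.table(data.frame(support = supp, n_mu = cands$n_mu,
                         sigma_bar = cands$sigma_bar,
                         null_mean = cands$null_mean,
                         null_var = cands$null_var),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
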
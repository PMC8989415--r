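#' Read spike-time trial data from delimited text
#'
#' One row per trial: a trial id, one column per scalar behavioural feature
#' (e.g. pitch, amplitude, spectral entropy), and a final column of
#' semicolon-separated spike times in ms (negative = before the
#' feature-measurement time).
#'
#' @param file path to a tab- or comma-separated file with a header row; the
#'   first column is the trial id and the last the spike times.
#' @return an object of class \code{"trial_set"}: list with \code{spikes}
#'   (list of numeric vectors, ms) and \code{features} (data frame, one
#'   column per feature).
#' @export
read_trials <- function(file) {
  if (!file.exists(file)) stop("input file not found: ", file)
  l1 <- readLines(file, n = 1L)
  sep <- if (grepl("\t", l1)) "\t" else ","
  d <- read.table(file, header = TRUE, sep = sep, check.names = FALSE,
                  colClasses = "character")
  if (ncol(d) < 3L) stop("expected trial id, feature columns and spike times")
  spikes <- lapply(strsplit(d[[ncol(d)]], ";", fixed = TRUE), function(s) {
    s <- s[nzchar(trimws(s))]
    as.numeric(s)
  })
  features <- as.data.frame(lapply(d[-c(1L, ncol(d))], as.numeric))
  trial_set(spikes, features)
}

#' Construct a trial set
#'
#' @param spikes list of numeric spike-time vectors (ms, one per trial).
#' @param features data frame with one scalar behavioural feature per column
#'   and one row per trial.
#' @return an object of class \code{"trial_set"}.
#' @export
trial_set <- function(spikes, features) {
  features <- as.data.frame(features)
  if (length(spikes) != nrow(features))
    stop("one feature row per trial is required")
  structure(list(spikes = spikes, features = features), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("trial set: %d trials, features: %s\n", length(x$spikes),
              paste(names(x$features), collapse = ", ")))
  invisible(x)
}

#' Binarize spike times into a trials x bins matrix
#'
#' The premotor window \code{[-window, 0)} ms is cut into
#' \code{window / bin_width} half-open bins \code{[(t-1) dt, t dt)} (so a
#' spike exactly on a boundary lands in the later bin); a bin is 1 iff at
#' least one spike falls in it. Spikes outside the window are ignored and
#' counted in a message.
#'
#' @param trials a \code{"trial_set"} or a list of spike-time vectors (ms).
#' @param bin_width bin width in ms (default 2).
#' @param window window length in ms before time 0 (default 40).
#' @return an M x (window/bin_width) binary matrix; column t covers
#'   \code{[-window + (t-1) * bin_width, -window + t * bin_width)} ms.
#' @export
binarize_spikes <- function(trials, bin_width = 2, window = 40) {
  if (inherits(trials, "trial_set")) trials <- trials$spikes
  nb <- window / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("window must be a multiple of bin_width")
  nb <- as.integer(round(nb))
  out <- matrix(0L, length(trials), nb)
  dropped <- 0L
  for (m in seq_along(trials)) {
    s <- trials[[m]]
    inw <- s >= -window & s < 0
    dropped <- dropped + sum(!inw)
    t <- floor((s[inw] + window) / bin_width) + 1L
    out[m, unique(t)] <- 1L
  }
  if (dropped > 0L)
    message(dropped, " spike(s) outside the [-", window, ", 0) ms window ignored")
  colnames(out) <- sprintf("bin%02d", seq_len(nb))
  out
}

#' Binarize a scalar behavioural feature
#'
#' \describe{
#'   \item{median}{1 iff the value is strictly above the median (ties at the
#'     median go to 0); \code{polarity = "below"} swaps the labels.}
#'   \item{percentile}{1 iff the value's percentile rank (computed with
#'     average ranks, \code{100 * rank / n}) lies in \code{[lo, hi]}.}
#'   \item{tercile}{1 iff the value falls in the \code{index}-th third of the
#'     ranked values (1 = low, 2 = medium, 3 = high).}
#' }
#'
#' @param values finite numeric vector, at least two distinct values.
#' @param scheme \code{"median"}, \code{"percentile"} or \code{"tercile"}.
#' @param lo,hi percentile window bounds in \[0, 100\] (percentile scheme).
#' @param index which tercile maps to 1 (tercile scheme).
#' @param polarity \code{"above"} (default) or \code{"below"}: which side of
#'   the median maps to 1.
#' @return integer vector of 0/1 bits, one per trial.
#' @export
binarize_behavior <- function(values, scheme = c("median", "percentile", "tercile"),
                              lo = 0, hi = 20, index = 1L,
                              polarity = c("above", "below")) {
  scheme <- match.arg(scheme)
  polarity <- match.arg(polarity)
  if (!all(is.finite(values))) stop("behaviour values must be finite")
  if (length(unique(values)) < 2L)
    stop("behaviour values are all identical; no split possible")
  bits <- switch(scheme,
    median = {
      b <- as.integer(values > median(values))
      if (polarity == "below") 1L - b else b
    },
    percentile = {
      stopifnot(lo >= 0, hi <= 100, lo <= hi)
      pr <- 100 * rank(values, ties.method = "average") / length(values)
      as.integer(pr >= lo & pr <= hi)
    },
    tercile = {
      stopifnot(index %in% 1:3)
      third <- ceiling(3 * rank(values, ties.method = "first") / length(values))
      as.integer(third == index)
    })
  bits
}

#' Assemble the neuro-behavioural binary dataset
#'
#' Column 1 is the behaviour bit; the remaining columns are the spike time
#' bins, so a 20-bin window yields N = 21 units. Dictionary words whose
#' support includes column 1 are codewords. (In serialised output the
#' behaviour unit is index 0.)
#'
#' @param behavior_bits 0/1 vector, one per trial (see [binarize_behavior()]).
#' @param spike_matrix binary trials x bins matrix (see [binarize_spikes()]).
#' @param feature optional feature name used in the unit labels.
#' @return a [binary_dataset()] with \code{behavior_col = 1} semantics.
#' @export
assemble_neurobehavioral <- function(behavior_bits, spike_matrix,
                                     feature = "behavior") {
  if (length(behavior_bits) != nrow(spike_matrix))
    stop("behaviour bits and spike matrix disagree on the number of trials")
  values <- cbind(as.integer(behavior_bits), spike_matrix)
  labels <- c(feature, colnames(spike_matrix))
  if (is.null(colnames(spike_matrix)))
    labels <- c(feature, sprintf("bin%02d", seq_len(ncol(spike_matrix))))
  binary_dataset(values, labels = labels)
}

#' Deterministic synthetic trial generator
#'
#' Builds synthetic spike-time trials with known structure so the full neural
#' pipeline is testable without recorded data: background spikes appear in
#' each bin with probability \code{rate}, and each planted codeword (a set of
#' bin indices) is injected with probability \code{p_high} on trials whose
#' feature is drawn from the upper half and \code{p_low} otherwise. Spikes
#' are placed at the centre of their bins, so binarization round-trips
#' exactly. All output is synthetic.
#'
#' @param n_trials number of trials.
#' @param codewords list of integer bin-index vectors to plant (may be empty).
#' @param p_high,p_low injection probabilities for high/low-feature trials
#'   (defaults 0.5 and 0.05).
#' @param rate background per-bin spike probability (default 0.15).
#' @param bin_width,window binning geometry in ms (defaults 2 and 40).
#' @param feature_name name of the scalar feature (default "pitch").
#' @return a \code{"trial_set"}; the feature is continuous with its upper
#'   half on the trials labelled high.
#' @export
synthetic_trials <- function(n_trials, codewords = list(), p_high = 0.5,
                             p_low = 0.05, rate = 0.15, bin_width = 2,
                             window = 40, feature_name = "pitch") {
  nb <- as.integer(window / bin_width)
  high <- rep(c(TRUE, FALSE), length.out = n_trials)
  feature <- ifelse(high, runif(n_trials, 0.5, 1), runif(n_trials, 0, 0.5))
  centre <- function(bin) -window + (bin - 0.5) * bin_width
  spikes <- vector("list", n_trials)
  for (m in seq_len(n_trials)) {
    bins <- which(runif(nb) < rate)
    for (cw in codewords) {
      p <- if (high[m]) p_high else p_low
      if (runif(1) < p) bins <- union(bins, cw)
    }
    spikes[[m]] <- centre(sort(bins))
  }
  ts <- trial_set(spikes, setNames(data.frame(feature), feature_name))
  ts
}

#' Write a trial set as delimited text
#'
#' @param trials a \code{"trial_set"}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_trials <- function(trials, file) {
  d <- data.frame(trial = seq_along(trials$spikes), trials$features,
                  spikes = vapply(trials$spikes, paste, character(1),
                                  collapse = ";"))
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Summary statistics over a collection of dictionaries
#'
#' Aggregates fitted dictionaries (e.g. one per neuron x feature) sharing an
#' encoding: proportions of m-spike codewords by spike count, mean inter-
#' spike interval (ISI) of codewords versus significant non-coding words,
#' cross-feature overlap counts, and mean dictionary/codeword sizes. The ISI
#' of a word is the mean gap in ms between consecutive active bins;
#' single-bin words are excluded.
#'
#' @param fits a named list of [isingdict()] fits (names = feature labels),
#'   or a list of such lists (one per dataset).
#' @param bin_width bin width in ms (default 2).
#' @return a list of class \code{"dictionary_stats"} with
#'   \code{order_proportions} (by spike count), \code{mean_isi_codewords},
#'   \code{mean_isi_noncoding}, \code{overlap} (counts of spike supports
#'   shared by each feature combination), \code{mean_words},
#'   \code{mean_codewords}.
#' @export
dictionary_statistics <- function(fits, bin_width = 2) {
  if (inherits(fits[[1]], "isingdict")) fits <- list(fits)
  spike_orders <- integer(0)
  isi_cw <- numeric(0)
  isi_nc <- numeric(0)
  n_words <- integer(0)
  n_codewords <- integer(0)
  overlap_keys <- list()
  word_isi <- function(support, behavior_col = 1L) {
    bins <- setdiff(support, behavior_col) - 1L   # spike columns start at 2
    if (length(bins) < 2L) return(NA_real_)
    mean(diff(sort(bins))) * bin_width
  }
  for (dataset in fits) {
    per_feature <- lapply(names(dataset), function(f) {
      d <- dataset[[f]]$dictionary
      cw <- d[d$codeword, , drop = FALSE]
      vapply(cw$support, function(s) paste(setdiff(s, 1L), collapse = ";"),
             character(1))
    })
    names(per_feature) <- names(dataset)
    overlap_keys[[length(overlap_keys) + 1L]] <- per_feature
    for (fit in dataset) {
      d <- fit$dictionary
      n_words <- c(n_words, nrow(d))
      n_codewords <- c(n_codewords, sum(d$codeword))
      for (i in seq_len(nrow(d))) {
        s <- d$support[[i]]
        isi <- word_isi(s)
        if (d$codeword[i]) {
          spike_orders <- c(spike_orders, length(setdiff(s, 1L)))
          if (!is.na(isi)) isi_cw <- c(isi_cw, isi)
        } else if (!(1L %in% s)) {
          if (!is.na(isi)) isi_nc <- c(isi_nc, isi)
        }
      }
    }
  }
  features <- unique(unlist(lapply(overlap_keys, names)))
  combos <- list()
  if (length(features) > 1L) {
    for (k in 2:length(features)) {
      for (cmb in combn(features, k, simplify = FALSE)) {
        cnt <- sum(vapply(overlap_keys, function(pf) {
          if (!all(cmb %in% names(pf))) return(0L)
          length(Reduce(intersect, pf[cmb]))
        }, integer(1)))
        combos[[paste(cmb, collapse = "&")]] <- cnt
      }
    }
  }
  structure(list(
    order_proportions = if (length(spike_orders))
      prop.table(table(spike_orders)) else table(integer(0)),
    mean_isi_codewords = if (length(isi_cw)) mean(isi_cw) else NA_real_,
    mean_isi_noncoding = if (length(isi_nc)) mean(isi_nc) else NA_real_,
    overlap = combos,
    mean_words = mean(n_words),
    mean_codewords = mean(n_codewords)),
    class = "dictionary_stats")
}

#' @export
print.dictionary_stats <- function(x, ...) {
  cat("dictionary statistics\n")
  cat(sprintf("  mean words per dictionary: %.2f (codewords %.2f)\n",
              x$mean_words, x$mean_codewords))
  if (length(x$order_proportions)) {
    cat("  codeword spike-count proportions:\n")
    print(round(x$order_proportions, 3))
  }
  cat(sprintf("  mean ISI: codewords %.2f ms, non-coding %.2f ms\n",
              x$mean_isi_codewords, x$mean_isi_noncoding))
  if (length(x$overlap))
    cat("  feature overlaps:",
        paste(names(x$overlap), unlist(x$overlap), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}
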
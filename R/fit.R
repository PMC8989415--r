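#' Extract an irreducible dictionary of anomalous binary patterns
#'
#' The main fitting function. Runs the full pipeline on an M x N binary
#' dataset: (optional) majority-column flip, exhaustive candidate enumeration
#' up to order \code{k_max} with the absent-word filter, magnetic fields and
#' top-\code{n_max} selection, exchange couplings among overlapping
#' candidates, naive mean-field solution of the indicator Ising model along
#' the regularisation schedule, shuffle-null calibration of the magnetization
#' threshold, and extraction of the dictionary entries above threshold.
#'
#' Words are admitted to the dictionary when their marginal magnetization
#' exceeds the threshold at which column-shuffled data (which preserves every
#' unit's marginal frequency but destroys dependence) yields on average at
#' most \code{n_false} detections.
#'
#' @param x a [binary_dataset()] or binary 0/1 matrix, samples in rows.
#' @param k_max,absent_threshold,n_max candidate-stage settings, see
#'   [candidate_config()].
#' @param n_false target mean number of false detections on shuffled data
#'   (default 0.5).
#' @param shuffles number of column-shuffled replicates used to calibrate the
#'   threshold (default 100).
#' @param flip complement columns active in more than half the samples before
#'   the analysis (default \code{FALSE}); see [flip_majority_columns()].
#' @param behavior_col optional column index of a designated output/behaviour
#'   unit; dictionary words containing it are flagged as codewords.
#' @param seed optional integer seed; with a fixed seed the fit is fully
#'   deterministic.
#' @param calibrate set \code{FALSE} to skip shuffle calibration (no
#'   dictionary is extracted then, only fields and magnetizations).
#' @return an object of class \code{"isingdict"}: a list with
#'   \describe{
#'     \item{dictionary}{data frame of admitted words: support (list column,
#'       1-based unit indices), order, n_mu, null_mean, magnetization, h,
#'       direction ("over"/"under"), codeword flag.}
#'     \item{threshold}{the calibrated magnetization threshold \code{m*}.}
#'     \item{curve}{the false-discovery calibration curve ([false_discovery_curve()]).}
#'     \item{system}{the indicator Ising system ([select_top_candidates()]).}
#'     \item{trajectory}{the mean-field trajectory ([solve_trajectory()]).}
#'     \item{candidates}{the full candidate table ([enumerate_candidates()]).}
#'     \item{config, M, N, flip_mask, behavior_col, seed}{run metadata.}
#'   }
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(200 * 8, 1, 0.25), 200, 8)
#' x[, 2] <- x[, 1]                     # a planted perfect pair
#' fit <- isingdict(x, k_max = 3, shuffles = 20, seed = 7)
#' fit
#' @export
isingdict <- function(x, k_max = 5L, absent_threshold = 0.02, n_max = 500L,
                      n_false = 0.5, shuffles = 100L, flip = FALSE,
                      behavior_col = NULL, seed = NULL, calibrate = TRUE) {
  data <- as_binary_dataset(x)
  if (!is.null(seed)) set.seed(seed)
  if (flip) data <- flip_majority_columns(data)
  config <- candidate_config(k_max, absent_threshold, n_max)

  cands <- enumerate_candidates(data, config)
  system <- select_top_candidates(cands, config)
  traj <- solve_trajectory(system)

  curve <- NULL
  m_star <- NA_real_
  if (calibrate && length(traj$m_final)) {
    curve <- false_discovery_curve(data, config, R = shuffles)
    m_star <- threshold_for(curve, n_false)
  }

  dict <- extract_entries(system, traj$m_final, m_star, behavior_col)
  structure(list(dictionary = dict, threshold = m_star, curve = curve,
                 system = system, trajectory = traj, candidates = cands,
                 config = config, n_false = n_false, shuffles = shuffles,
                 M = nrow(data), N = ncol(data),
                 flip_mask = attr(data, "flip_mask"),
                 behavior_col = behavior_col, seed = seed,
                 labels = attr(data, "labels")),
            class = "isingdict")
}

extract_entries <- function(system, m_final, m_star, behavior_col) {
  dev <- system$candidates$sigma_bar - system$candidates$null_mean
  keep <- if (is.na(m_star)) integer(0) else which(m_final > m_star)
  data.frame(
    support = I(system$supports[keep]),
    order = system$candidates$order[keep],
    n_mu = system$candidates$n_mu[keep],
    null_mean = system$candidates$null_mean[keep],
    magnetization = m_final[keep],
    h = system$h[keep],
    direction = ifelse(dev[keep] >= 0, "over", "under"),
    codeword = if (is.null(behavior_col)) rep(FALSE, length(keep)) else
      vapply(system$supports[keep], function(s) behavior_col %in% s, logical(1))
  )
}

#' Column-shuffled surrogate of a binary dataset
#'
#' Permutes each column independently across samples: every unit's marginal
#' count is preserved exactly while all dependence between units is
#' destroyed. Uses the current RNG state.
#'
#' @param data a [binary_dataset()] or binary matrix.
#' @return a [binary_dataset()] of the same size.
#' @export
shuffle_dataset <- function(data) {
  data <- as_binary_dataset(data)
  values <- as.matrix(data)
  for (j in seq_len(ncol(values)))
    values[, j] <- values[sample.int(nrow(values)), j]
  binary_dataset(values, labels = attr(data, "labels"),
                 flip_mask = attr(data, "flip_mask"))
}

#' False-discovery calibration curve from column-shuffled data
#'
#' Runs the full candidate/field/mean-field pipeline on \code{R} independently
#' column-shuffled copies of the data and records every resulting
#' magnetization. \code{n_false(m)} is the mean number of words per shuffle
#' with magnetization strictly above \code{m}; the threshold grid is the
#' sorted set of observed shuffle magnetizations (exact inversion).
#'
#' @param data a [binary_dataset()] or binary matrix.
#' @param config a [candidate_config()].
#' @param R number of shuffles (>= 1).
#' @return an object of class \code{"fdr_curve"}: data frame with columns
#'   \code{m} (increasing) and \code{n_false} (non-increasing), plus
#'   attributes \code{R} and \code{mags} (all shuffle magnetizations).
#' @export
false_discovery_curve <- function(data, config = candidate_config(), R = 100L) {
  stopifnot(R >= 1L)
  data <- as_binary_dataset(data)
  mags <- vector("list", R)
  for (r in seq_len(R)) {
    sh <- shuffle_dataset(data)
    cands <- enumerate_candidates(sh, config)
    system <- select_top_candidates(cands, config)
    mags[[r]] <- solve_trajectory(system)$m_final
  }
  v <- sort(unlist(mags))
  grid <- unique(v)
  # count of shuffle magnetizations strictly greater than each grid point
  greater <- length(v) - findInterval(grid, v)
  curve <- data.frame(m = grid, n_false = greater / R)
  structure(curve, R = R, mags = v, class = c("fdr_curve", "data.frame"))
}

#' Magnetization threshold for a target false-discovery count
#'
#' The smallest threshold on the calibration grid whose mean shuffled-data
#' detection count is at or below \code{target}.
#'
#' @param curve an \code{"fdr_curve"} from [false_discovery_curve()].
#' @param target the acceptable mean number of false detections (> 0),
#'   default 0.5.
#' @return the threshold \code{m*}.
#' @export
threshold_for <- function(curve, target = 0.5) {
  stopifnot(target > 0)
  if (nrow(curve) == 0L) return(-1)    # no shuffle magnetizations: all pass
  ok <- which(curve$n_false <= target)
  if (length(ok) == 0L) {
    warning("false-discovery target unreachable; using the largest threshold")
    return(max(curve$m))
  }
  curve$m[ok[1L]]
}

#' Count of words detected above a threshold
#'
#' @param m_final magnetizations of a run.
#' @param m_star threshold.
#' @return integer count with magnetization strictly above the threshold.
#' @export
count_detected <- function(m_final, m_star) sum(m_final > m_star)

#' Contradictory codewords between complementary-output dictionaries
#'
#' When the same data are analysed with the output bit labelled both ways
#' (e.g. above- versus below-median behaviour), a spike pattern must not be
#' anomalous in the same direction in both dictionaries; such contradictions
#' estimate the false-positive load.
#'
#' @param dict_a,dict_b two [isingdict()] fits of the same neural data with
#'   complementary output labelling.
#' @return the number of codeword supports present with the same
#'   over/under direction in both dictionaries.
#' @export
consistency_check <- function(dict_a, dict_b) {
  if (!identical(dict_a$config, dict_b$config) ||
      !identical(dict_a$behavior_col, dict_b$behavior_col))
    stop("dictionaries were built with different configurations")
  a <- dict_a$dictionary[dict_a$dictionary$codeword, , drop = FALSE]
  b <- dict_b$dictionary[dict_b$dictionary$codeword, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  key <- function(d) paste(vapply(d$support, paste, character(1),
                                  collapse = ";"), d$direction)
  sum(key(a) %in% key(b))
}

#' Fraction of large-field candidates pruned by word-word interactions
#'
#' Among candidates in the Ising system whose field magnitude exceeds the
#' smallest field magnitude of any retained dictionary word, the fraction
#' that did not make it into the dictionary. Without couplings the
#' magnetization is monotone in the field, so no positive-field word above
#' the cut can be lost; nonzero values quantify how strongly the exchange
#' interactions enforce irreducibility.
#'
#' @param fit an [isingdict()] fit.
#' @return the fraction in \[0, 1\], or \code{NA} (with attribute
#'   \code{reason}) when the dictionary is empty.
#' @export
interaction_pruning_fraction <- function(fit) {
  dict <- fit$dictionary
  if (nrow(dict) == 0L)
    return(structure(NA_real_, reason = "empty dictionary"))
  h_min <- min(abs(dict$h))
  m_final <- fit$trajectory$m_final
  big <- abs(fit$system$h) > h_min
  if (!any(big)) return(0)
  retained <- m_final > fit$threshold
  mean(!retained[big])
}

#' @export
print.isingdict <- function(x, ...) {
  cat(sprintf("irreducible dictionary fit: M = %d samples, N = %d units\n",
              x$M, x$N))
  cat(sprintf("  candidates: %d enumerated (k <= %d), %d in the Ising system\n",
              nrow(x$candidates), x$config$k_max, length(x$system$h)))
  tr <- x$trajectory
  cat(sprintf("  eps1 = %.3g, eps2 = %s, eps_max = %.3g\n", tr$eps1,
              if (is.na(tr$eps2)) "(not reached)" else sprintf("%.3g", tr$eps2),
              tr$eps_max))
  if (is.na(x$threshold)) {
    cat("  uncalibrated (no threshold; dictionary not extracted)\n")
  } else {
    cat(sprintf("  threshold m* = %.4f at n_false = %.3g (%d shuffles)\n",
                x$threshold, x$n_false, x$shuffles))
    cat(sprintf("  dictionary: %d words (%d codewords)\n",
                nrow(x$dictionary), sum(x$dictionary$codeword)))
  }
  invisible(x)
}

#' @export
summary.isingdict <- function(object, ...) {
  d <- object$dictionary
  structure(list(
    M = object$M, N = object$N,
    n_candidates = nrow(object$candidates),
    n_system = length(object$system$h),
    eps = c(eps1 = object$trajectory$eps1, eps2 = object$trajectory$eps2,
            eps_max = object$trajectory$eps_max),
    threshold = object$threshold,
    n_words = nrow(d), n_codewords = sum(d$codeword),
    order_table = if (nrow(d)) table(d$order) else table(integer(0)),
    n_over = sum(d$direction == "over"),
    n_under = sum(d$direction == "under"),
    pruning_fraction = interaction_pruning_fraction(object)),
    class = "summary.isingdict")
}

#' @export
print.summary.isingdict <- function(x, ...) {
  cat(sprintf("dictionary of %d words (%d codewords) from %d x %d data\n",
              x$n_words, x$n_codewords, x$M, x$N))
  cat(sprintf("  %d over-, %d under-represented; orders: %s\n", x$n_over,
              x$n_under, paste(names(x$order_table), x$order_table,
                               sep = ":", collapse = " ")))
  cat(sprintf("  threshold m* = %.4f; eps_max = %.3g\n", x$threshold,
              x$eps["eps_max"]))
  if (!is.na(x$pruning_fraction))
    cat(sprintf("  large-field pruning fraction: %.2f\n", x$pruning_fraction))
  invisible(x)
}

#' @describeIn isingdict magnetizations of the retained candidates, named by
#'   their supports (semicolon-joined 1-based indices).
#' @param object,... method arguments.
#' @export
coef.isingdict <- function(object, ...) {
  setNames(object$trajectory$m_final,
           vapply(object$system$supports, paste, character(1), collapse = ";"))
}

#' Plot a dictionary fit
#'
#' Left: the false-discovery calibration curve with the chosen operating
#' point. Right: magnetizations of the retained candidates against their
#' fields, dictionary words highlighted.
#'
#' @param x an [isingdict()] fit.
#' @param ... passed to [plot()].
#' @export
plot.isingdict <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (!is.null(x$curve)) {
    plot(x$curve$m, pmax(x$curve$n_false, 0.005), type = "s", log = "y",
         xlab = "magnetization threshold m", ylab = "n_false (mean per shuffle)",
         main = "shuffle calibration", ...)
    graphics::abline(v = x$threshold, h = x$n_false, lty = 2, col = "grey40")
  }
  m <- x$trajectory$m_final
  ind <- m > x$threshold & !is.na(x$threshold)
  plot(x$system$h, m, pch = 16, cex = 0.5,
       col = ifelse(ind, "firebrick", "grey60"),
       xlab = "field h", ylab = "magnetization m", main = "candidates", ...)
  if (!is.na(x$threshold))
    graphics::abline(h = x$threshold, lty = 2, col = "grey40")
  invisible(x)
}
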
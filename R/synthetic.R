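#' Random log-linear generative model with planted higher-order interactions
#'
#' Draws a generative model for N binary units: per-unit biases
#' \code{theta_i ~ N(bias_mean, bias_sd^2)} and \code{K = round(alpha * N / 3)}
#' planted interactions split as evenly as possible across orders 2, 3 and 4,
#' with distinct, uniformly drawn supports. Interaction strengths come from
#' either an equal-weight mixture of two Gaussians at \code{+/- 0.5} (sd 0.1)
#' or a single zero-mean Gaussian (sd 0.5). The log-probability of a state is
#' \code{2 * sum(theta_i * sigma_i) + sum(theta_mu * prod(sigma_i))} up to
#' normalisation, so that without interactions the per-unit marginal is
#' \code{p_i = 1 / (1 + exp(-2 * theta_i))} (about 0.2 at the default bias of
#' -0.7, matching sparse spiking data).
#'
#' Uses the current RNG state (set a seed for reproducibility).
#'
#' @param n_units number of binary units N (default 20).
#' @param alpha interaction density: planted interactions per unit, counting
#'   each interaction once per member unit at the mean order 3 (default 2;
#'   2-4 spans tree-like to lattice-like densities).
#' @param strength \code{"mixture"} (two Gaussians at +/-0.5, sd 0.1) or
#'   \code{"gaussian"} (one zero-mean Gaussian, sd 0.5).
#' @param bias_mean,bias_sd bias distribution parameters (defaults -0.7, 0.1).
#' @param orders interaction orders to plant (default 2:4).
#' @return an object of class \code{"pattern_model"}: list with
#'   \code{n_units}, \code{bias}, \code{interactions} (data frame: list-column
#'   \code{support}, \code{order}, \code{theta}), \code{alpha},
#'   \code{strength}.
#' @export
pattern_model <- function(n_units = 20L, alpha = 2, strength = c("mixture", "gaussian"),
                          bias_mean = -0.7, bias_sd = 0.1, orders = 2:4) {
  strength <- match.arg(strength)
  n_units <- as.integer(n_units)
  stopifnot(n_units >= max(orders), alpha > 0)
  # each interaction touches mean(orders) units, so K = round(alpha * N / 3)
  # for the default orders 2:4 gives ~alpha interactions per unit
  K <- round(alpha * n_units / mean(orders))
  # equal split across orders, remainder spread deterministically
  n_per <- diff(round(K * (0:length(orders)) / length(orders)))
  ks <- rep(orders, times = n_per)
  if (any(n_per > choose(n_units, orders)))
    stop("more interactions requested than distinct supports available")
  seen <- character(0)
  supports <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    repeat {
      s <- sort(sample.int(n_units, ks[i]))
      key <- paste(s, collapse = ";")
      if (!key %in% seen) { seen <- c(seen, key); supports[[i]] <- s; break }
    }
  }
  theta <- switch(strength,
    mixture = sample(c(-1, 1), length(ks), replace = TRUE) * 0.5 +
      rnorm(length(ks), 0, 0.1),
    gaussian = rnorm(length(ks), 0, 0.5))
  structure(list(n_units = n_units,
                 bias = rnorm(n_units, bias_mean, bias_sd),
                 interactions = data.frame(support = I(supports),
                                           order = ks, theta = theta),
                 alpha = alpha, strength = strength),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("log-linear pattern model: %d units, %d planted interactions (alpha = %g, %s strengths)\n",
              x$n_units, nrow(x$interactions), x$alpha, x$strength))
  cat("  per order:", paste(names(table(x$interactions$order)),
                            table(x$interactions$order),
                            sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Exact state distribution of a pattern model
#'
#' Enumerates all \code{2^N} states and returns their probabilities
#' (normalised to 1). Feasible for N up to 22; use the Gibbs sampler in
#' [simulate.pattern_model()] beyond that.
#'
#' @param model a [pattern_model()].
#' @return numeric vector of length \code{2^N}; element \code{k+1} is the
#'   probability of the state whose active-unit bitmask is \code{k} (bit
#'   \code{i-1} set iff unit i is active).
#' @export
exact_distribution <- function(model) {
  N <- model$n_units
  if (N > 22L) stop("exact enumeration is limited to 22 units; use Gibbs sampling")
  states <- 0:(2^N - 1)
  logp <- numeric(length(states))
  for (i in seq_len(N))
    logp <- logp + 2 * model$bias[i] * (bitwAnd(states, 2^(i - 1)) > 0)
  for (r in seq_len(nrow(model$interactions))) {
    mask <- sum(2^(model$interactions$support[[r]] - 1))
    hit <- bitwAnd(states, mask) == mask
    logp[hit] <- logp[hit] + model$interactions$theta[r]
  }
  w <- exp(logp - max(logp))
  w / sum(w)
}

#' Sample binary datasets from a pattern model
#'
#' Draws \code{M} i.i.d. samples, by exact enumeration of the state
#' distribution for N <= 22 or by Gibbs sampling (5000 burn-in sweeps,
#' thinning 10) for larger systems.
#'
#' @param object a [pattern_model()].
#' @param nsim number of datasets (default 1).
#' @param seed optional seed, as in [stats::simulate()].
#' @param M samples per dataset (default 200; must be >= 1).
#' @param method \code{"exact"} or \code{"gibbs"}; default picks exact when
#'   feasible.
#' @param burn_in,thin Gibbs contract (defaults 5000 sweeps, 10).
#' @param ... unused.
#' @return a [binary_dataset()] when \code{nsim = 1}, else a list of them.
#' @export
simulate.pattern_model <- function(object, nsim = 1, seed = NULL, M = 200L,
                                   method = c("auto", "exact", "gibbs"),
                                   burn_in = 5000L, thin = 10L, ...) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (method == "auto")
    method <- if (object$n_units <= 22L) "exact" else "gibbs"
  out <- vector("list", nsim)
  p <- if (method == "exact") exact_distribution(object) else NULL
  for (s in seq_len(nsim)) {
    values <- if (method == "exact") {
      idx <- sample.int(length(p), M, replace = TRUE, prob = p) - 1L
      states_to_matrix(idx, object$n_units)
    } else {
      gibbs_sample(object, M, burn_in = burn_in, thin = thin)
    }
    out[[s]] <- binary_dataset(values)
  }
  if (nsim == 1L) out[[1L]] else out
}

states_to_matrix <- function(states, N) {
  m <- matrix(0L, length(states), N)
  for (i in seq_len(N)) m[, i] <- as.integer(bitwAnd(states, 2^(i - 1)) > 0)
  m
}

# single-site Gibbs sampler over the log-linear model
gibbs_sample <- function(model, M, burn_in = 5000L, thin = 10L) {
  N <- model$n_units
  touching <- lapply(seq_len(N), function(i)
    which(vapply(model$interactions$support, function(s) i %in% s, logical(1))))
  sigma <- as.integer(runif(N) < 0.2)
  out <- matrix(0L, M, N)
  taken <- 0L
  sweep_no <- 0L
  while (taken < M) {
    sweep_no <- sweep_no + 1L
    for (i in seq_len(N)) {
      lo <- 2 * model$bias[i]
      for (r in touching[[i]]) {
        others <- setdiff(model$interactions$support[[r]], i)
        if (all(sigma[others] == 1L))
          lo <- lo + model$interactions$theta[r]
      }
      sigma[i] <- as.integer(runif(1) < 1 / (1 + exp(-lo)))
    }
    if (sweep_no > burn_in && (sweep_no - burn_in) %% thin == 0L) {
      taken <- taken + 1L
      out[taken, ] <- sigma
    }
  }
  out
}

#' Precision and recall of a dictionary against the planted model
#'
#' A detected word counts as true only when its support exactly equals a
#' planted interaction support (sub- and super-words are false positives).
#' Precision is the fraction of detected words that are planted; recall the
#' fraction of planted interactions detected.
#'
#' @param fit an [isingdict()] fit of data generated from \code{model}.
#' @param model the generating [pattern_model()].
#' @param thresholds optional magnetization thresholds at which to evaluate
#'   the curve; defaults to the fit's calibrated threshold only.
#' @return a data frame with columns \code{m}, \code{n_detected},
#'   \code{precision} (NA when nothing is detected) and \code{recall}.
#' @export
score_dictionary <- function(fit, model, thresholds = fit$threshold) {
  truth <- vapply(model$interactions$support, paste, character(1),
                  collapse = ";")
  keys <- vapply(fit$system$supports, paste, character(1), collapse = ";")
  m <- fit$trajectory$m_final
  out <- lapply(thresholds, function(th) {
    det <- keys[m > th]
    hits <- sum(det %in% truth)
    data.frame(m = th, n_detected = length(det),
               precision = if (length(det)) hits / length(det) else NA_real_,
               recall = sum(truth %in% det) / length(truth))
  })
  do.call(rbind, out)
}

#' Synthetic benchmark sweep
#'
#' For each combination of interaction density \code{alpha} and sample size
#' \code{M}, draws replicate pattern models, samples a dataset from each,
#' runs the full calibrated pipeline and scores precision, recall (at the
#' \code{n_false} operating point) and the large-field pruning fraction.
#'
#' @param alphas interaction densities to sweep (default \code{c(2, 4)}).
#' @param M_values sample sizes (default 1600).
#' @param replicates replicate models per combination (default 10).
#' @param strength strength family, see [pattern_model()].
#' @param n_units units per model (default 20).
#' @param shuffles calibration shuffles per dataset (default 20; benchmark
#'   scale).
#' @param n_false calibration target (default 0.5).
#' @param k_max,absent_threshold,n_max candidate-stage settings.
#' @param seed optional seed for the whole sweep.
#' @return an object of class \code{"ising_benchmark"}: list with
#'   \code{runs} (one row per replicate: alpha, M, replicate, precision,
#'   recall, pruning, n_detected, n_planted, threshold) and \code{summary}
#'   (means and standard errors per alpha x M cell).
#' @export
run_benchmark <- function(alphas = c(2, 4), M_values = 1600L, replicates = 10L,
                          strength = "mixture", n_units = 20L, shuffles = 20L,
                          n_false = 0.5, k_max = 5L, absent_threshold = 0.02,
                          n_max = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (alpha in alphas) for (M in M_values) for (r in seq_len(replicates)) {
    model <- pattern_model(n_units = n_units, alpha = alpha,
                           strength = strength)
    data <- simulate(model, M = M)
    fit <- isingdict(data, k_max = k_max, absent_threshold = absent_threshold,
                     n_max = n_max, n_false = n_false, shuffles = shuffles)
    sc <- score_dictionary(fit, model)
    rows[[length(rows) + 1L]] <- data.frame(
      alpha = alpha, M = M, replicate = r,
      precision = sc$precision, recall = sc$recall,
      pruning = as.numeric(interaction_pruning_fraction(fit)),
      n_detected = sc$n_detected, n_planted = nrow(model$interactions),
      threshold = fit$threshold)
  }
  runs <- do.call(rbind, rows)
  cell <- interaction(runs$alpha, runs$M, drop = TRUE)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       se = sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  summ <- do.call(rbind, lapply(split(runs, cell), function(d) {
    data.frame(alpha = d$alpha[1], M = d$M[1], replicates = nrow(d),
               precision = agg(d$precision)[1], precision_se = agg(d$precision)[2],
               recall = agg(d$recall)[1], recall_se = agg(d$recall)[2],
               pruning = agg(d$pruning)[1], pruning_se = agg(d$pruning)[2])
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, strength = strength,
                 n_false = n_false),
            class = "ising_benchmark")
}

#' @export
print.ising_benchmark <- function(x, ...) {
  cat(sprintf("synthetic benchmark (%s strengths, n_false = %g):\n",
              x$strength, x$n_false))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
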
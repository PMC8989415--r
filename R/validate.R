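#' Codeword activation features
#'
#' One binary column per codeword: a trial activates the feature iff every
#' spike bin of the codeword's support is active on that trial (the behaviour
#' unit itself is excluded from the feature).
#'
#' @param spike_matrix binary trials x bins matrix.
#' @param fit an [isingdict()] fit with codewords, or a list of supports
#'   given as unit indices of the assembled dataset (behaviour unit = 1).
#' @param behavior_col index of the behaviour unit in the supports (default 1).
#' @return binary matrix, one column per codeword.
#' @export
codeword_features <- function(spike_matrix, fit, behavior_col = 1L) {
  supports <- if (inherits(fit, "isingdict")) {
    d <- fit$dictionary
    d$support[d$codeword]
  } else fit
  if (length(supports) == 0L) stop("no codewords to build features from")
  out <- matrix(0L, nrow(spike_matrix), length(supports))
  for (k in seq_along(supports)) {
    bins <- setdiff(supports[[k]], behavior_col) - behavior_col
    sub <- spike_matrix[, bins, drop = FALSE]
    out[, k] <- as.integer(rowSums(sub) == length(bins))
  }
  colnames(out) <- vapply(supports, function(s)
    paste(setdiff(s, behavior_col) - behavior_col, collapse = ";"), character(1))
  out
}

#' Ridge-penalised logistic regression
#'
#' Maximises \code{sum(log p(y | z, beta)) - (lambda / 2) * sum(beta_i^2)}
#' (the intercept unpenalised) by Newton-Raphson on the exact objective; the
#' problem is strictly concave for \code{lambda > 0}, so the fit is
#' deterministic and the gradient vanishes at the optimum to near machine
#' precision.
#'
#' @param z numeric feature matrix (trials x features).
#' @param y binary response vector.
#' @param lambda L2 penalty (default 0.1; > 0 guards against separation).
#' @param tol gradient max-norm at convergence (default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return list with \code{coefficients} (intercept first),
#'   \code{fitted}, \code{loglik} (unpenalised), \code{gradient} (at the
#'   optimum), \code{lambda}; class \code{"ridge_logit"}.
#' @export
fit_logistic <- function(z, y, lambda = 0.1, tol = 1e-10, max_iter = 100L) {
  z <- as.matrix(z)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(z) == length(y))
  if (length(y) < 10L) stop("at least 10 samples are required")
  X <- cbind(1, z)
  k <- ncol(X)
  pen <- c(0, rep(lambda, k - 1L))      # intercept unpenalised
  beta <- numeric(k)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- as.vector(crossprod(X, y - p)) - pen * beta
    if (max(abs(g)) < tol) break
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X) + diag(pen, k)
    beta <- beta + solve(H, g)
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  structure(list(coefficients = setNames(beta, c("(Intercept)", colnames(z))),
                 fitted = p,
                 loglik = sum(y * log(p) + (1 - y) * log(1 - p)),
                 gradient = as.vector(crossprod(X, y - p)) - pen * beta,
                 lambda = lambda),
            class = "ridge_logit")
}

#' @export
predict.ridge_logit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata))
  as.vector(1 / (1 + exp(-X %*% object$coefficients)))
}

cross_entropy <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# stratified twofold split; resplits (with a warning) if a fold is single-class
stratified_folds <- function(y, seed, max_tries = 20L) {
  for (try in seq_len(max_tries)) {
    set.seed(seed + try - 1L)
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(1:2, length.out = length(idx))
    }
    ok <- all(vapply(1:2, function(f) length(unique(y[fold == f])) == 2L,
                     logical(1)))
    if (ok) return(fold)
    warning("degenerate fold; resplitting with the next seed")
  }
  stop("could not produce non-degenerate folds")
}

#' Compare behaviour prediction from time bins versus codewords
#'
#' Fits two ridge-penalised logistic models of the binary behaviour: one on
#' the raw spike time-bin columns, one on the codeword activation features,
#' and evaluates both by stratified twofold cross-validation with a held-out
#' accuracy (0.5 threshold) and mean cross-entropy (normalised negative
#' log-likelihood). Requires at least 4 codewords; smaller dictionaries are
#' skipped with a reason.
#'
#' @param spike_matrix binary trials x bins matrix.
#' @param behavior binary behaviour vector (one per trial).
#' @param fit an [isingdict()] fit providing the codewords (or a list of
#'   supports, see [codeword_features()]).
#' @param lambda L2 penalty (default 0.1).
#' @param cv_seed seed for the fold split (default 1).
#' @param min_codewords minimum codeword count (default 4).
#' @return a data frame with one row per model (\code{bins},
#'   \code{codewords}) and columns \code{accuracy}, \code{cross_entropy},
#'   \code{n_features}; or \code{NULL} (with a message) when skipped.
#' @export
compare_predictors <- function(spike_matrix, behavior, fit, lambda = 0.1,
                               cv_seed = 1L, min_codewords = 4L) {
  supports <- if (inherits(fit, "isingdict")) {
    d <- fit$dictionary
    d$support[d$codeword]
  } else fit
  if (length(supports) < min_codewords) {
    message("skipped: only ", length(supports), " codewords (need ",
            min_codewords, ")")
    return(NULL)
  }
  y <- as.numeric(behavior)
  zc <- codeword_features(spike_matrix, supports)
  fold <- stratified_folds(y, cv_seed)
  eval_model <- function(z) {
    acc <- ce <- numeric(2)
    for (f in 1:2) {
      train <- fold != f
      m <- fit_logistic(z[train, , drop = FALSE], y[train], lambda = lambda)
      p <- predict(m, z[!train, , drop = FALSE])
      acc[f] <- mean((p > 0.5) == (y[!train] == 1))
      ce[f] <- cross_entropy(p, y[!train])
    }
    c(accuracy = mean(acc), cross_entropy = mean(ce))
  }
  bins <- eval_model(spike_matrix)
  cw <- eval_model(zc)
  data.frame(model = c("bins", "codewords"),
             accuracy = c(bins["accuracy"], cw["accuracy"]),
             cross_entropy = c(bins["cross_entropy"], cw["cross_entropy"]),
             n_features = c(ncol(spike_matrix), ncol(zc)),
             row.names = NULL)
}
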
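#' One naive mean-field update of the indicator magnetizations
#'
#' \code{m' = tanh((eps/2) * (h + eps * rowSums(J) + eps^2 * J \%*\% m))},
#' with the diagonal of \code{J} excluded (it is zero in systems built by
#' [select_top_candidates()]).
#'
#' @param system an \code{"ising_system"}, or a list with \code{h} and
#'   \code{J}.
#' @param m current magnetizations (in (-1, 1)).
#' @param eps inverse regularisation strength, >= 0.
#' @return updated magnetizations.
#' @export
mean_field_update <- function(system, m, eps) {
  if (!all(is.finite(m))) stop("non-finite magnetizations")
  if (eps < 0) stop("eps must be >= 0")
  h <- system$h
  if (length(h) == 0L) return(numeric(0))
  J <- system$J
  tanh((eps / 2) * (h + eps * rowSums(J) + eps^2 * as.vector(J %*% m)))
}

#' Perturbative validity of the mean-field expansion
#'
#' The quadratic (coupling) corrections must stay below the linear (field)
#' terms: true iff \code{mean(|h|) >= mean(|eps * h_eff|)} over candidates,
#' with the effective field \code{h_eff = rowSums(J) + eps * J \%*\% m}.
#'
#' @inheritParams mean_field_update
#' @return logical.
#' @export
perturbative_bound <- function(system, m, eps) {
  heff <- effective_field(system, m, eps)
  mean(abs(system$h)) >= mean(abs(eps * heff))
}

effective_field <- function(system, m, eps) {
  rowSums(system$J) + eps * as.vector(system$J %*% m)
}

# damped fixed-point iteration at a single eps
mf_fixed_point <- function(system, m, eps, tol = 1e-10, max_sweeps = 1000L,
                           damping = 0.5) {
  res_prev <- Inf
  damp <- FALSE
  for (it in seq_len(max_sweeps)) {
    m_new <- mean_field_update(system, m, eps)
    if (damp) m_new <- damping * m_new + (1 - damping) * m
    res <- max(abs(m_new - m))
    m <- m_new
    if (res < tol) return(list(m = m, converged = TRUE, sweeps = it))
    if (res > res_prev) damp <- TRUE   # oscillation: switch to damped updates
    res_prev <- res
  }
  list(m = m, converged = FALSE, sweeps = max_sweeps)
}

#' Solve the indicator Ising model along the regularisation schedule
#'
#' Sweeps \code{eps} from 0 upward in steps of \code{1/(20 M)}, iterating the
#' naive mean-field equations to a fixed point at each step (warm-started from
#' the previous one). The sweep stops at \code{eps_max = min(eps1, eps2)}:
#' \code{eps1 = 1/M} is the saddle-point validity limit, and \code{eps2} is
#' the last grid point at which the perturbative bound
#' ([perturbative_bound()]) still holds. If the bound already fails at the
#' first grid step, that step is kept with a warning.
#'
#' @param system an \code{"ising_system"}.
#' @param M number of samples (defaults to \code{system$M}).
#' @param tol fixed-point convergence tolerance (max-norm), default 1e-10.
#' @param max_sweeps iteration cap per eps, default 1000; non-convergence is
#'   flagged and warned about, never silent.
#' @return an object of class \code{"mf_trajectory"}: list with
#'   \code{eps_grid}, \code{m} (candidates x grid matrix), \code{converged},
#'   \code{eps1}, \code{eps2}, \code{eps_max}, and \code{m_final} (the
#'   magnetizations at \code{eps_max}).
#' @export
solve_trajectory <- function(system, M = system$M, tol = 1e-10,
                             max_sweeps = 1000L) {
  S <- length(system$h)
  delta <- 1 / (20 * M)
  eps1 <- 1 / M
  grid <- seq(delta, eps1, by = delta)
  if (S == 0L) {
    return(structure(list(eps_grid = numeric(0),
                          m = matrix(0, 0, 0), converged = logical(0),
                          eps1 = eps1, eps2 = NA_real_, eps_max = eps1,
                          m_final = numeric(0)),
                     class = "mf_trajectory"))
  }
  m <- numeric(S)           # total ignorance at eps = 0
  m_path <- matrix(NA_real_, S, length(grid))
  conv <- logical(length(grid))
  used <- 0L
  eps2 <- NA_real_
  for (g in seq_along(grid)) {
    eps <- grid[g]
    fp <- mf_fixed_point(system, m, eps, tol = tol, max_sweeps = max_sweeps)
    if (!fp$converged)
      warning(sprintf("mean field not converged at eps = %.3g", eps))
    ok <- perturbative_bound(system, fp$m, eps)
    if (!ok) {
      eps2 <- if (g == 1L) eps else grid[g - 1L]
      if (g == 1L) {
        warning("perturbative bound fails at the first grid step; using it")
        m <- fp$m
        m_path[, g] <- fp$m
        conv[g] <- fp$converged
        used <- 1L
      }
      break
    }
    m <- fp$m
    m_path[, g] <- fp$m
    conv[g] <- fp$converged
    used <- g
  }
  eps_max <- grid[used]
  structure(list(eps_grid = grid[seq_len(used)],
                 m = m_path[, seq_len(used), drop = FALSE],
                 converged = conv[seq_len(used)],
                 eps1 = eps1, eps2 = eps2, eps_max = eps_max,
                 m_final = m),
            class = "mf_trajectory")
}

#' @export
print.mf_trajectory <- function(x, ...) {
  cat(sprintf("mean-field trajectory: %d candidates, %d eps steps\n",
              nrow(x$m), length(x$eps_grid)))
  cat(sprintf("  eps1 = %.3g, eps2 = %s, eps_max = %.3g\n", x$eps1,
              if (is.na(x$eps2)) "(not reached)" else sprintf("%.3g", x$eps2),
              x$eps_max))
  if (length(x$m_final))
    cat(sprintf("  final |m| range %.3g - %.3g\n",
                min(abs(x$m_final)), max(abs(x$m_final))))
  invisible(x)
}

#' Exact indicator marginals by state enumeration
#'
#' Computes \code{m_mu = 2 <s_mu> - 1} under the Boltzmann distribution
#' \code{P(s) propto exp(eps * sum h s + eps^2 * sum_{mu != nu} J s s)} by
#' summing all \code{2^S} indicator states. Serves as the independent oracle
#' for the mean-field solver on small systems.
#'
#' @param system an \code{"ising_system"} (or list with \code{h}, \code{J})
#'   with at most 20 candidates.
#' @param eps inverse regularisation strength.
#' @return exact magnetizations.
#' @export
exact_indicator_marginals <- function(system, eps) {
  h <- system$h
  J <- system$J
  S <- length(h)
  if (S > 20L) stop("exact enumeration is limited to 20 candidates")
  if (S == 0L) return(numeric(0))
  states <- 0:(2^S - 1)
  bits <- lapply(seq_len(S), function(mu)
    as.numeric(bitwAnd(states, 2^(mu - 1)) > 0))
  logw <- numeric(length(states))
  for (mu in seq_len(S)) logw <- logw + eps * h[mu] * bits[[mu]]
  if (S > 1L) {
    for (mu in seq_len(S - 1L)) for (nu in (mu + 1L):S) {
      if (J[mu, nu] != 0)
        logw <- logw + 2 * eps^2 * J[mu, nu] * bits[[mu]] * bits[[nu]]
    }
  }
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  vapply(seq_len(S), function(mu) 2 * sum(p * bits[[mu]]) - 1, numeric(1))
}
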
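test_that("column shuffling preserves marginals and destroys dependence", {
  set.seed(51)
  x <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6)
  sh <- shuffle_dataset(x)
  expect_equal(column_frequencies(sh), column_frequencies(x))
  one <- binary_dataset(matrix(c(1, 0, 1), 1, 3))
  expect_equal(as.matrix(shuffle_dataset(one)), as.matrix(one))
  # perfectly correlated columns decorrelate to O(1/sqrt(M))
  M <- 1000
  y <- rbinom(M, 1, 0.5)
  z <- shuffle_dataset(cbind(y, y))
  expect_lt(abs(cor(z[, 1], z[, 2])), 3 / sqrt(M))
})

test_that("the false-discovery curve is monotone and inverts conservatively", {
  set.seed(52)
  x <- matrix(rbinom(150 * 8, 1, 0.25), 150, 8)
  curve <- false_discovery_curve(x, candidate_config(k_max = 3, n_max = 100),
                                 R = 15)
  expect_true(all(diff(curve$n_false) <= 0))
  # nothing exceeds the largest observed magnetization
  expect_equal(curve$n_false[nrow(curve)], 0)
  mags <- attr(curve, "mags")
  expect_equal(sum(mags > max(curve$m)), 0)
  # at threshold -1 every shuffle magnetization is counted
  expect_equal(sum(mags > -1) / 15, length(mags) / 15)
  # threshold selection: smallest grid point meeting the target
  m_star <- threshold_for(curve, 0.5)
  expect_lte(curve$n_false[match(m_star, curve$m)], 0.5)
  idx <- match(m_star, curve$m)
  if (idx > 1) expect_gt(curve$n_false[idx - 1], 0.5)
  # an unreachable target warns and returns the top of the grid
  fake <- structure(data.frame(m = c(0.1, 0.2), n_false = c(5, 2)),
                    class = c("fdr_curve", "data.frame"))
  expect_warning(top <- threshold_for(fake, 1), "unreachable")
  expect_equal(top, 0.2)
  # a huge target admits everything
  expect_equal(threshold_for(curve, 1e9), min(curve$m))
})

test_that("a fit is deterministic given data and seed", {
  set.seed(53)
  x <- matrix(rbinom(120 * 7, 1, 0.3), 120, 7)
  f1 <- isingdict(x, k_max = 3, n_max = 100, shuffles = 10, seed = 99)
  f2 <- isingdict(x, k_max = 3, n_max = 100, shuffles = 10, seed = 99)
  expect_identical(f1$threshold, f2$threshold)
  expect_identical(f1$dictionary, f2$dictionary)
  expect_identical(coef(f1), coef(f2))
})

test_that("running the pipeline on shuffled data detects about the
           false-discovery target or fewer", {
  set.seed(54)
  model <- pattern_model(n_units = 12, alpha = 2)
  data <- simulate(model, M = 400)
  sh <- shuffle_dataset(data)
  fit <- isingdict(sh, k_max = 4, n_max = 200, shuffles = 20, seed = 1)
  # a single run can fluctuate; it must stay within a few words of the target
  expect_lte(nrow(fit$dictionary), 4)
})

test_that("contradictory codewords across complementary labelings are counted", {
  mk <- function(supports, directions, codeword) {
    entries <- data.frame(order = lengths(supports),
                          n_mu = 1L, null_mean = 0.1, magnetization = 0.5,
                          h = 10, direction = directions, codeword = codeword)
    entries$support <- I(supports)
    list(dictionary = entries, config = candidate_config(),
         behavior_col = 1L)
  }
  a <- mk(list(c(1, 3), c(1, 5), c(4, 6)), c("over", "under", "over"),
          c(TRUE, TRUE, FALSE))
  # same support + direction as a's first codeword: one contradiction
  b <- mk(list(c(1, 3), c(1, 5)), c("over", "over"), c(TRUE, TRUE))
  expect_equal(consistency_check(a, b), 1L)
  # disjoint codeword sets
  c2 <- mk(list(c(1, 7)), "over", TRUE)
  expect_equal(consistency_check(a, c2), 0L)
  # matching supports that are not codewords do not count
  d <- mk(list(c(4, 6)), "over", FALSE)
  expect_equal(consistency_check(a, d), 0L)
  d$config <- candidate_config(k_max = 3)
  expect_error(consistency_check(a, d), "different configurations")
})

test_that("without couplings no positive-field word above the dictionary
           cut is lost, and empty dictionaries are flagged", {
  set.seed(55)
  x <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6)
  fit <- isingdict(x, k_max = 3, n_max = 100, shuffles = 15, seed = 2)
  if (nrow(fit$dictionary) == 0) {
    expect_true(is.na(interaction_pruning_fraction(fit)))
    expect_equal(attr(interaction_pruning_fraction(fit), "reason"),
                 "empty dictionary")
  }
  # decoupled counterfactual: kill the couplings, refit the trajectory
  sys0 <- fit$system
  sys0$J[] <- 0
  tr0 <- solve_trajectory(sys0)
  fit0 <- fit
  fit0$system <- sys0
  fit0$trajectory <- tr0
  fit0$dictionary <- fit$dictionary[0, ]
  if (!is.na(fit$threshold)) {
    keep <- which(tr0$m_final > fit$threshold)
    if (length(keep)) {
      fit0$dictionary <- data.frame(
        support = I(sys0$supports[keep]), order = 1L, n_mu = 1L,
        null_mean = 0.1, magnetization = tr0$m_final[keep],
        h = sys0$h[keep], direction = "over", codeword = FALSE)
      # monotonicity: every positive-field word above the cut is retained
      h_min <- min(abs(fit0$dictionary$h))
      lost <- sys0$h > h_min & tr0$m_final <= fit$threshold
      expect_equal(sum(lost), 0)
    }
  }
})
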
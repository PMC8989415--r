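test_that("enumeration is exhaustive: matches a brute-force subset scan", {
  set.seed(3)
  x <- matrix(rbinom(60 * 7, 1, 0.3), 60, 7)
  d <- binary_dataset(x)
  cfg <- candidate_config(k_max = 4, absent_threshold = 0.02)
  cands <- enumerate_candidates(d, cfg)
  n <- column_frequencies(d)
  usable <- which(n > 0 & n < 60)
  brute <- list()
  for (k in 1:4) for (s in combn(usable, k, simplify = FALSE)) {
    cnt <- word_count(d, s)
    nm <- null_expectation(n, 60, s)
    if (cnt > 0 || 60 * nm >= 0.02)
      brute[[paste(s, collapse = ";")]] <- c(cnt, nm)
  }
  keys <- vapply(candidate_supports(cands), paste, character(1), collapse = ";")
  expect_setequal(keys, names(brute))
  ord <- match(names(brute), keys)
  expect_equal(cands$n_mu[ord], unname(vapply(brute, `[`, numeric(1), 1)))
  expect_equal(cands$null_mean[ord], unname(vapply(brute, `[`, numeric(1), 2)))
})

test_that("the absent-word filter keeps expected-but-absent supports only", {
  # single sample 111: every nonempty subset occurs -> 7 candidates
  d <- binary_dataset(matrix(1, 1, 3))
  # all columns constant (all ones) -> no usable columns
  expect_warning(cands <- enumerate_candidates(d, candidate_config(k_max = 3)),
                 "clipped")
  expect_equal(nrow(cands), 0)
  # uniform q = 0.2, M = 100: absent order-3 word has <n> = 0.8 >= 0.02 kept,
  # while at threshold 1.0 it would be dropped
  set.seed(8)
  x <- matrix(0L, 100, 6)
  for (j in 1:6) x[sample.int(100, 20), j] <- 1L
  cands <- enumerate_candidates(x, candidate_config(k_max = 3,
                                                    absent_threshold = 0.02))
  absent3 <- cands$order == 3 & cands$n_mu == 0
  expect_true(any(absent3))
  expect_true(all(100 * cands$null_mean[absent3] >= 0.02))
  strict <- enumerate_candidates(x, candidate_config(k_max = 3,
                                                     absent_threshold = 1.0))
  expect_true(all(strict$n_mu > 0 | 100 * strict$null_mean >= 1.0))
  expect_lt(nrow(strict), nrow(cands))
})

test_that("all-zero data yields no candidates", {
  d <- binary_dataset(matrix(0, 5, 4))
  expect_warning(cands <- enumerate_candidates(d), "clipped")
  expect_equal(nrow(cands), 0)
})

test_that("the field formula matches its closed form and sign structure", {
  # frequency exactly as expected -> h = -M var / 2 < 0
  expect_equal(compute_field(0.1, 0.1, 100), -100 * 0.09 / 2)
  expect_equal(compute_field(0.2, 0.1, 100, 0.09), 45.5)
  # over- and under-representation with equal deviation give identical h
  expect_equal(compute_field(0.3, 0.2, 50), compute_field(0.1, 0.2, 50))
  # h grows with M once the deviation dominates the standard error
  hs <- compute_field(0.25, 0.2, c(200, 400, 800, 1600))
  expect_true(all(diff(hs) > 0))
})

test_that("couplings vanish for disjoint supports and match the closed form", {
  expect_equal(compute_coupling(0, 0, 0.0625, 100), 2500 * 0.0625^2)
  expect_identical(compute_coupling(0.3, 0.2, 0, 100), 0)
  # expected-and-observed co-occurrence makes the coupling negative
  expect_lt(compute_coupling(0.02, 0.02, 0.008, 1600), 0)
})

test_that("top-candidate selection keeps the largest |h| with deterministic
           tie-breaks and a symmetric sparse coupling table", {
  set.seed(4)
  x <- matrix(rbinom(80 * 8, 1, 0.3), 80, 8)
  cands <- enumerate_candidates(x, candidate_config(k_max = 3))
  sys <- select_top_candidates(cands, candidate_config(k_max = 3, n_max = 30))
  expect_length(sys$h, 30)
  expect_gte(min(abs(sys$h)), max(abs(cands$h[-match(sys$candidates$mask,
                                                     cands$mask)])) - 1e-12)
  expect_equal(sys$J, t(sys$J))
  expect_equal(diag(sys$J), rep(0, 30))
  # couplings exist only for intersecting supports
  n <- column_frequencies(x)
  for (a in 1:10) for (b in (a + 1):11) {
    inter <- length(intersect(sys$supports[[a]], sys$supports[[b]]))
    if (inter == 0) expect_identical(sys$J[a, b], 0)
    cov_ab <- null_covariance(n, 80, sys$supports[[a]], sys$supports[[b]])
    dev <- sys$candidates$sigma_bar - sys$candidates$null_mean
    expect_equal(sys$J[a, b], compute_coupling(dev[a], dev[b], cov_ab, 80),
                 tolerance = 1e-9)
  }
  # fewer candidates than n_max -> all retained; reruns identical
  sys_all <- select_top_candidates(cands, candidate_config(k_max = 3,
                                                           n_max = 10000))
  expect_length(sys_all$h, nrow(cands))
  sys2 <- select_top_candidates(cands, candidate_config(k_max = 3, n_max = 30))
  expect_identical(sys$candidates$mask, sys2$candidates$mask)
})

test_that("fields and couplings serialise to delimited text", {
  set.seed(5)
  x <- matrix(rbinom(40 * 5, 1, 0.4), 40, 5)
  cands <- enumerate_candidates(x, candidate_config(k_max = 2))
  sys <- select_top_candidates(cands)
  stem <- file.path(withr::local_tempdir(), "sys")
  write_ising_system(sys, stem)
  fields <- read.table(paste0(stem, "_fields.tsv"), header = TRUE, sep = "\t")
  expect_equal(fields$h, sys$h)
  coup <- read.table(paste0(stem, "_couplings.tsv"), header = TRUE, sep = "\t")
  expect_true(all(coup$J != 0))
  tf <- withr::local_tempfile()
  write_candidates(cands, tf)
  tab <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(cands))
  expect_equal(tab$n_mu, cands$n_mu)
})
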
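test_that("spike binarization follows the half-open 2 ms grid", {
  expect_equal(binarize_spikes(list(numeric(0)))[1, ], rep(0L, 20),
               ignore_attr = TRUE)
  # two spikes in one bin saturate to 1
  m <- binarize_spikes(list(c(-39.5, -39.1)))
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, 1]), 1L)
  # a spike exactly on a boundary lands in the later bin: -38.0 -> bin 2
  m2 <- binarize_spikes(list(-38.0))
  expect_equal(unname(which(m2[1, ] == 1L)), 2L)
  # spikes outside the window are ignored (with a log message)
  expect_message(m3 <- binarize_spikes(list(c(-50, -1, 3))), "outside")
  expect_equal(sum(m3), 1)
  expect_equal(unname(which(m3[1, ] == 1L)), 20L)
  # a deterministic pattern round-trips through bin centres
  centre <- function(bin) -40 + (bin - 0.5) * 2
  bins <- c(3, 7, 18)
  m4 <- binarize_spikes(list(centre(bins)))
  expect_equal(unname(which(m4[1, ] == 1L)), bins)
})

test_that("behaviour binarization implements median, percentile and tercile
           schemes", {
  v <- 1:100
  bits <- binarize_behavior(v, "median")
  expect_equal(bits, rep(c(0L, 1L), each = 50))
  expect_equal(binarize_behavior(v, "median", polarity = "below"),
               rep(c(1L, 0L), each = 50))
  expect_equal(sum(binarize_behavior(v, "percentile", lo = 0, hi = 20)), 20)
  expect_equal(which(binarize_behavior(v, "percentile", lo = 10, hi = 30) == 1L),
               10:30)
  t1 <- binarize_behavior(1:99, "tercile", index = 1)
  t2 <- binarize_behavior(1:99, "tercile", index = 2)
  t3 <- binarize_behavior(1:99, "tercile", index = 3)
  expect_equal(c(sum(t1), sum(t2), sum(t3)), c(33, 33, 33))
  expect_equal(t1 + t2 + t3, rep(1L, 99))
  expect_error(binarize_behavior(rep(1, 10), "median"), "identical")
  # median splits are balanced to within one trial for distinct values
  set.seed(71)
  for (r in 1:10) {
    u <- runif(sample(20:60, 1))
    b <- binarize_behavior(u, "median")
    expect_lte(abs(sum(b) - sum(1 - b)), 1)
  }
})

test_that("the assembled neuro-behavioural dataset puts behaviour first", {
  set.seed(72)
  spikes <- matrix(rbinom(200 * 20, 1, 0.2), 200, 20)
  bits <- rbinom(200, 1, 0.5)
  d <- assemble_neurobehavioral(bits, spikes, feature = "pitch")
  expect_equal(dim(d), c(200L, 21L))
  expect_equal(as.integer(d[, 1]), bits)
  expect_equal(attr(d, "labels")[1], "pitch")
  expect_equal(column_frequencies(d)[1] / 200, mean(bits))
  # swapped polarity complements only the behaviour column
  d2 <- assemble_neurobehavioral(1L - bits, spikes)
  expect_equal(as.matrix(d2[, -1]), as.matrix(d[, -1]), ignore_attr = TRUE)
  expect_equal(as.integer(d2[, 1]), 1L - bits)
  expect_error(assemble_neurobehavioral(bits[-1], spikes), "trials")
})

test_that("trial files round-trip and binarization preserves trial order", {
  set.seed(73)
  ts <- synthetic_trials(40, codewords = list(c(4, 9)), rate = 0.2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_trials(ts, tf)
  back <- read_trials(tf)
  expect_equal(length(back$spikes), 40)
  expect_equal(back$features$pitch, ts$features$pitch, tolerance = 1e-12)
  expect_equal(back$spikes, ts$spikes, tolerance = 1e-12)
  # permuting trials permutes rows identically across behaviour and spikes
  perm <- sample.int(40)
  m1 <- binarize_spikes(ts)[perm, ]
  m2 <- binarize_spikes(trial_set(ts$spikes[perm], ts$features[perm, , drop = FALSE]))
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("a planted behaviour-coupled pattern is recovered as a codeword", {
  set.seed(74)
  ts <- synthetic_trials(600, codewords = list(c(5, 11)), p_high = 0.65,
                         p_low = 0.03, rate = 0.10)
  spikes <- binarize_spikes(ts)
  bits <- binarize_behavior(ts$features$pitch, "median")
  d <- assemble_neurobehavioral(bits, spikes)
  fit <- isingdict(d, k_max = 4, shuffles = 15, seed = 4, behavior_col = 1L)
  keys <- vapply(fit$dictionary$support[fit$dictionary$codeword],
                 paste, character(1), collapse = ";")
  # the planted word occupies units {behaviour, bin5, bin11} = {1, 6, 12}
  expect_true(any(vapply(keys, function(k)
    grepl("^1;", k) && all(c(6, 12) %in% as.integer(strsplit(k, ";")[[1]])),
    logical(1))) || "1;6;12" %in% keys)
})

test_that("dictionary statistics aggregate orders, ISIs and feature overlaps", {
  mk_fit <- function(supports, codeword) {
    entries <- data.frame(order = lengths(supports), n_mu = 1L,
                          null_mean = 0.1, magnetization = 0.5, h = 10,
                          direction = "over", codeword = codeword)
    entries$support <- I(supports)
    structure(list(dictionary = entries, behavior_col = 1L),
              class = "isingdict")
  }
  # supports use assembled indexing: 1 = behaviour, bin b = column b + 1
  pitch <- mk_fit(list(c(1L, 4L, 8L), c(1L, 5L), c(3L, 9L)),
                  c(TRUE, TRUE, FALSE))
  amp <- mk_fit(list(c(1L, 4L, 8L), c(2L, 6L)), c(TRUE, FALSE))
  stats <- dictionary_statistics(list(list(pitch = pitch, amplitude = amp)),
                                 bin_width = 2)
  # codeword bins {4,8}-1 = {3,7}: ISI (7-3)*2 = 8 ms
  expect_equal(stats$mean_isi_codewords, 8)
  # non-coding words {3,9}-1 = {2,8} (12 ms) and {2,6}-1 = {1,5} (8 ms)
  expect_equal(stats$mean_isi_noncoding, 10)
  expect_equal(as.vector(stats$order_proportions),
               c(1 / 3, 2 / 3))                    # one 1-spike, two 2-spike
  expect_equal(stats$overlap[["pitch&amplitude"]], 1L)
  expect_equal(stats$mean_words, 2.5)
  expect_equal(stats$mean_codewords, 1.5)
})
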
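# the full synthetic benchmark is expensive, and several checks look at
# different statistics of the same sweep; compute it once per test run
.benchmark_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.benchmark_cache$result)) {
    .benchmark_cache$result <- run_benchmark(
      alphas = c(2, 4), M_values = 1600L, replicates = 25L,
      strength = "mixture", n_units = 20L, shuffles = 40L,
      n_false = 0.5, seed = 20260921L)
  }
  .benchmark_cache$result
}
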
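# Shared fixtures, generated in code and memoised for the test session.

# Internal helpers exercised directly by the tests.
welch_psd <- neograde:::welch_psd
loglog_slope <- neograde:::loglog_slope
logical_runs <- neograde:::logical_runs
fir_apply <- neograde:::fir_apply

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small balanced corpus: `n_per_grade` subjects per grade, `duration` s.
tiny_corpus <- function(n_per_grade = 2, duration = 120, seed = 11) {
  cached(sprintf("corpus_%d_%d_%d", n_per_grade, duration, seed),
         simulate_corpus(n_per_grade, duration = duration, fs = 64,
                         seed = seed))
}

# Burst-suppression envelope spec used across AM/IBI tests (grade-3
# conditions: mean IBI 30 s within the 10-60 s band).
bs_spec <- function(mean_ibi = 30) {
  envelope_spec("burst_suppression", baseline_amplitude = 3,
                burst_amplitude = 25, mean_ibi = mean_ibi, ibi_jitter = 8,
                ibi_range = c(10.5, 59), burst_duration = 6)
}

expect_deterministic <- function(f) {
  expect_identical(f(), f())
}
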
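# Shared fixtures built once per test run.

# 120-pair signal table with planted tumor/non-tumor entropy structure;
# used by the discrimination and wrapper-recovery tests.
.fixture_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      set.seed(42)
      pairs <- c(
        lapply(1:60, function(i)
          generate_signal_pair("tumor", 256, source_image_id = paste0("t", i))),
        lapply(1:60, function(i)
          generate_signal_pair("non_tumor", 256,
                               source_image_id = paste0("n", i))))
      tab <<- feature_table(pairs)
    }
    tab
  }
})

# short deterministic test signals for oracle comparisons
.osc_signals <- function() {
  set.seed(99)
  list(
    runif(20) * 10,
    rnorm(25),
    sin(seq_len(30)) + rnorm(30, 0, 0.2),
    rep(c(1, 2, 3, 5), 7),
    cumsum(rnorm(24))
  )
}
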
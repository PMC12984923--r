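test_that("shannon entropy matches analytic histogram values", {
  # 8 equally occupied bins of the 256-bin [0,255] histogram
  sig <- rep(seq(0, 224, by = 32) + 0.5, each = 4)
  expect_equal(shannon_entropy(sig, 8), 3.0)
  expect_equal(shannon_entropy(rep(100, 50), 256), 0)
  # two bins with counts 3 and 1
  sig2 <- c(10, 10, 10, 200)
  expect_equal(shannon_entropy(sig2, 2),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_true(shannon_entropy(runif(100, 0, 255), 16) <= log2(16))
})

test_that("approximate and sample entropy agree with brute-force oracles", {
  for (x in .osc_signals()) {
    r <- 0.3 * sd(x)
    for (m in 0:2) {
      expect_equal(approximate_entropy(x, m, r), o_apen(x, m, r),
                   tolerance = 1e-9)
      expect_equal(as.numeric(sample_entropy(x, m, r)), o_sampen(x, m, r),
                   tolerance = 1e-9)
    }
  }
  # degenerate regularity
  const <- rep(4, 40)
  expect_equal(approximate_entropy(const, 1), 0, tolerance = 1e-9)
  expect_equal(as.numeric(sample_entropy(const, 2)), 0, tolerance = 1e-9)
  # hand-checked 10-point fixtures
  x1 <- c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)
  expect_equal(approximate_entropy(x1, 1, 0.5), o_apen(x1, 1, 0.5),
               tolerance = 1e-12)
  x2 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  expect_equal(as.numeric(sample_entropy(x2, 1, 1.0)), o_sampen(x2, 1, 1.0),
               tolerance = 1e-12)
  # ApEn(m=0) = -Phi^1 >= 0
  for (x in .osc_signals())
    expect_gte(approximate_entropy(x, 0, 0.2 * sd(x)), 0)
})

test_that("fuzzy, permutation, dispersion, distribution, range match oracles", {
  for (x in .osc_signals()) {
    r <- 0.25 * sd(x)
    expect_equal(fuzzy_entropy(x, 1, r, 2), o_fuzzy(x, 1, r, 2),
                 tolerance = 1e-9)
    expect_equal(fuzzy_entropy(x, 2, r, 2), o_fuzzy(x, 2, r, 2),
                 tolerance = 1e-9)
    expect_equal(permutation_entropy(x, 3, 1), o_permen(x, 3, 1),
                 tolerance = 1e-9)
    expect_equal(dispersion_entropy(x, 2, 6, 1), o_dispen(x, 2, 6, 1),
                 tolerance = 1e-9)
    expect_equal(distribution_entropy(x, 2, 64), o_disten(x, 2, 64),
                 tolerance = 1e-9)
    expect_equal(as.numeric(range_entropy(x, 2, 0.4)), o_rangeen(x, 2, 0.4),
                 tolerance = 1e-9)
  }
})

test_that("fuzzy entropy is exactly translation-invariant and zero on constants", {
  set.seed(3)
  x <- rnorm(30)
  r <- 0.2 * sd(x)
  expect_equal(fuzzy_entropy(x, 1, r), fuzzy_entropy(x + 10, 1, r),
               tolerance = 1e-12)
  expect_equal(fuzzy_entropy(rep(2, 30), 1, 0.1), 0, tolerance = 1e-12)
})

test_that("permutation entropy hits its analytic anchors", {
  expect_equal(permutation_entropy(1:30, 3), 0)
  # all m! = 2 patterns equally often
  expect_equal(permutation_entropy(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 2), 1,
               tolerance = 1e-12)
  # hand-enumerated six ordinal pairs: 4 up, 2 down
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutation_entropy(x, 2, 1),
               -(4 / 6 * log2(4 / 6) + 2 / 6 * log2(2 / 6)) / log2(2),
               tolerance = 1e-12)
})

test_that("spectral entropy spans its normalized range", {
  n <- 64
  t <- seq_len(n) - 1
  pure <- sin(2 * pi * 4 * t / n)
  expect_equal(spectral_entropy(pure), 0, tolerance = 1e-9)
  imp <- c(1, rep(0, n - 1))
  expect_equal(spectral_entropy(imp), 1, tolerance = 1e-9)
  two <- sin(2 * pi * 4 * t / n) + cos(2 * pi * 9 * t / n)
  expect_equal(spectral_entropy(two), log(2) / log(n / 2), tolerance = 1e-9)
  expect_error(spectral_entropy(rep(0, 64)), "invalid")
})

test_that("dispersion entropy is 0 for constants and at most 1", {
  expect_equal(dispersion_entropy(rep(5, 40), 2, 6), 0)
  set.seed(8)
  for (i in 1:5)
    expect_lte(dispersion_entropy(runif(50, 0, 255), 2, 6), 1)
})

test_that("composite multiscale entropy follows the coarse-graining contract", {
  set.seed(11)
  x <- rnorm(120)
  r <- 0.2 * sd(x)
  expect_equal(composite_multiscale_entropy(x, 1, 2, r),
               as.numeric(sample_entropy(x, 2, r)), tolerance = 1e-12)
  # coarse series at scale 3, offset 0 has floor(N/3) points: reproduce one
  cg <- colMeans(matrix(x[1:(40 * 3)], nrow = 3))
  expect_length(cg, 40)
  # periodic signals are more regular than their shuffles
  per <- rep(sin(2 * pi * (1:12) / 12), 5)
  rp <- 0.2 * sd(per)
  worse <- 0
  set.seed(21)
  for (i in 1:100) {
    sh <- sample(per)
    if (as.numeric(sample_entropy(per, 2, rp)) <=
        as.numeric(sample_entropy(sh, 2, rp))) worse <- worse + 1
  }
  expect_gte(worse, 95)
})

test_that("coarse-grained white noise loses sample entropy with scale", {
  set.seed(13)
  deltas <- replicate(50, {
    x <- rnorm(200)
    r <- 0.2 * sd(x)
    composite_multiscale_entropy(x, 1, 2, r) -
      composite_multiscale_entropy(x, 3, 2, r)
  })
  expect_gt(mean(deltas), 0)
})

test_that("cross measures agree with brute-force cross-template oracles", {
  set.seed(17)
  for (i in 1:3) {
    x <- rnorm(22); y <- x + rnorm(22, 0, 0.5)
    r <- 0.5 * sd(x)
    for (m in 0:2)
      expect_equal(as.numeric(cross_sample_entropy(x, y, m, r)),
                   o_cross_sampen(x, y, m, r), tolerance = 1e-9)
    for (m in 1:2) {
      expect_equal(cross_approximate_entropy(x, y, m, r),
                   o_cross_apen(x, y, m, r), tolerance = 1e-9)
      expect_equal(cross_fuzzy_entropy(x, y, m, r, 2),
                   o_cross_fuzzy(x, y, m, r, 2), tolerance = 1e-9)
      expect_equal(cross_kolmogorov_entropy(x, y, m, r),
                   o_cross_k2(x, y, m, r), tolerance = 1e-9)
    }
  }
})

test_that("cross-sample entropy on identical signals equals self-counting across copies", {
  set.seed(23)
  x <- rnorm(10)
  r <- 0.6 * sd(x)
  v <- cross_sample_entropy(x, x, 0, r)
  expect_equal(as.numeric(v), o_cross_sampen(x, x, 0, r), tolerance = 1e-12)
  # cross counting includes the diagonal i = j, so it can only be more
  # regular than the self variant that excludes it
  expect_lte(as.numeric(v), o_sampen(x, 0, r) + 1e-12)
})

test_that("normalized measures stay in [0,1] and ratio measures non-negative", {
  set.seed(31)
  for (i in 1:10) {
    x <- scale_intensity(rnorm(80))
    for (v in c(permutation_entropy(x), dispersion_entropy(x),
                spectral_entropy(x), diversity_entropy(x),
                distribution_entropy(x), cosine_similarity_entropy(x))) {
      expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    }
    r <- 0.2 * sd(x)
    for (v in c(approximate_entropy(x, 1, r),
                as.numeric(sample_entropy(x, 1, r)),
                fuzzy_entropy(x, 1, r),
                as.numeric(range_entropy(x, 2, 0.2))))
      expect_gte(v, -1e-9)
  }
})

test_that("remaining single-signal measures behave on anchors", {
  set.seed(37)
  x <- scale_intensity(rnorm(100))
  expect_gte(attention_entropy(x), 0)
  expect_gte(bubble_entropy(x, 10), 0)
  expect_gte(corrected_conditional_entropy(x, 2, 6), 0)
  expect_gte(entropy_of_entropy(x, 5, 5), 0)
  expect_lte(gridded_distribution_entropy(x, 3), 2 * log2(3) + 1e-12)
  expect_gte(phase_entropy(x, 4), 0)
  expect_lte(phase_entropy(x, 4), log(4) + 1e-12)
  expect_gte(slope_entropy(x, 2), 0)
  # constants collapse to zero for the pattern-based measures
  cz <- rep(9, 60)
  expect_equal(corrected_conditional_entropy(cz), 0)
  expect_equal(gridded_distribution_entropy(cz), 0)
  expect_equal(phase_entropy(cz), 0)
  expect_equal(slope_entropy(cz), 0)
  expect_equal(entropy_of_entropy(cz), 0)
})
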
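test_that("maturity and flight coefficient follow their closed forms", {
  expect_equal(maturity(0, 100), 0)
  expect_equal(maturity(100, 100), 1)
  expect_equal(maturity(50, 100), 0.5)
  expect_error(maturity(1, 0), "invalid")

  expect_equal(flight_coefficient(0, 100), 0.2)
  expect_equal(flight_coefficient(100, 100), 0, tolerance = 1e-15)
  expect_equal(flight_coefficient(50, 100), 0.2 * sin(pi / 4),
               tolerance = 1e-12)
  ks <- sapply(0:50, flight_coefficient, max_fes = 50)
  expect_true(all(diff(ks) <= 1e-15))
  ps <- sapply(0:50, maturity, max_fes = 50)
  expect_true(all(diff(ps) >= 0))
})

test_that("stage updates satisfy their fixed-point identities", {
  x <- c(0.3, 0.6, 0.9)
  # growth: zero difference vector or zero rand leaves the position alone
  expect_equal(growth_update(x, x), x)
  expect_equal(growth_update(x, c(0.1, 0.2, 0.3), rand = 0), x)
  expect_equal(growth_update(0.6, 0.4, rand = 0.5), 0.7)
  # breeding: coincident or fully-immature cases collapse onto the best
  b <- c(0.5, 0.5, 0.5)
  expect_equal(breeding_update(b, b, p = 0.7), b)
  expect_equal(breeding_update(x, b, p = 0), b)
  expect_equal(breeding_update(0.9, 0.5, p = 0.5, C = 0.8), 0.66)
  # the printed control-coefficient displacement
  expect_equal(breeding_update(1, 0, p = 1, C = 0.8), 0.8)
  # enemy avoidance: zero difference or exhausted budget freezes movement
  expect_equal(enemies_update(x, x, 10, 100), x)
  expect_equal(enemies_update(x, c(0.9, 0.8, 0.7), 100, 100), x)
  k <- flight_coefficient(0, 100)
  expect_equal(enemies_update(0.2, 0.8, 0, 100, l = 1), 0.2 + 1 * k * 0.6)
  # updates clip into bounds
  expect_true(all(growth_update(c(0.9, 0.1), c(0.1, 0.9), rand = 1) >= 0 &
                  growth_update(c(0.9, 0.1), c(0.1, 0.9), rand = 1) <= 1))
})

test_that("levy steps are seeded, heavy-tailed draws", {
  set.seed(1); a <- levy_step(1.5, 100)
  set.seed(1); b <- levy_step(1.5, 100)
  expect_identical(a, b)
  set.seed(2)
  steps <- abs(levy_step(1.5, 10000))
  expect_gt(max(steps), 10 * median(steps))
  expect_gt(median(steps), 0)
  expect_true(is.finite(median(steps)))
})

test_that("mask binarization thresholds with an argmax fallback", {
  m1 <- binarize_mask(rep(0.9, 39), 0.8)
  expect_equal(m1$selected_count, 39)
  m2 <- binarize_mask(rep(0.1, 39), 0.8)
  expect_equal(m2$selected_count, 1)
  expect_true(m2$fallback)
  expect_equal(which(m2$bits == 1L), 1L)   # lowest index wins ties
  m3 <- binarize_mask(c(0.85, 0.5, 0.81), 0.8)
  expect_equal(m3$bits, c(1L, 0L, 1L))
  expect_equal(m3$selected_count, 2)
})

test_that("the wrapper fitness trades accuracy against subset size", {
  expect_equal(fitness(1, 1, 39, alpha = 0.99), 0.01 * 1 / 39)
  expect_equal(fitness(0, 39, 39), 1)
  expect_equal(fitness(0.95, 5, 39, 0.99), 0.99 * 0.05 + 0.01 * 5 / 39,
               tolerance = 1e-12)
  expect_error(fitness(0.5, 40, 39), "invalid")
  # monotonicity
  expect_lt(fitness(0.9, 5, 39), fitness(0.8, 5, 39))
  expect_lt(fitness(0.9, 5, 39), fitness(0.9, 6, 39))
})

test_that("evaluate_mask matches exhaustive enumeration on a toy problem", {
  set.seed(10)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(
    ifelse(y == "a", 0, 10) + rnorm(n, 0, 0.1),  # perfectly separating
    rnorm(n), rnorm(n), rnorm(n))
  colnames(x) <- paste0("V", 1:4)
  ctx <- fitness_context(x, y, alpha = 0.99, seed = 7)
  # perfectly separating single feature: accuracy term vanishes
  f1 <- evaluate_mask(c(1, 0, 0, 0), ctx)
  expect_equal(as.numeric(f1), (1 - 0.99) * 1 / 4, tolerance = 1e-12)
  expect_equal(attr(f1, "accuracy"), 1)
  # oracle: recompute every mask fitness from its parts
  for (bits in 1:15) {
    mask <- as.integer(intToBits(bits))[1:4]
    got <- evaluate_mask(mask, ctx)
    tr <- setdiff(seq_len(n), ctx$val_idx)
    std <- standardize(x[tr, mask == 1, drop = FALSE],
                       x[ctx$val_idx, mask == 1, drop = FALSE])
    acc <- mean(o_knn(std$train, y[tr], std$apply, 1) == y[ctx$val_idx])
    expect_equal(as.numeric(got), 0.99 * (1 - acc) + 0.01 * sum(mask) / 4,
                 tolerance = 1e-12)
  }
})

test_that("population initialization is bounded, seeded and centered", {
  cfg <- optimizer_config(pop_size = 50, dim = 39, seed = 1)
  set.seed(1); p1 <- initialize_population(cfg)
  set.seed(1); p2 <- initialize_population(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$current >= 0 & p1$current <= 1))
  expect_identical(p1$current, p1$previous)
  expect_true(mean(p1$current) > 0.45 && mean(p1$current) < 0.55)
})

test_that("all four optimizers honor the trace contracts", {
  set.seed(20)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(ifelse(y == "a", 0, 3) + rnorm(n), matrix(rnorm(n * 7), n, 7))
  colnames(x) <- paste0("V", 1:8)
  ctx <- fitness_context(x, y, seed = 3)
  for (alg in c("sfoa", "pso", "hho", "po")) {
    cfg <- optimizer_config(algorithm = alg, pop_size = 8, max_iter = 10,
                            dim = 8, seed = 5)
    tr <- run_optimizer(ctx, cfg)
    expect_true(all(diff(tr$trace) <= 1e-15))          # non-increasing
    expect_lte(tr$fes, 8 * 10 + 8)                     # budget accounting
    expect_true(all(tr$best_position >= 0 & tr$best_position <= 1))
    expect_gte(tr$best_mask$selected_count, 1)
    # bit-reproducible for a fixed seed
    tr2 <- run_optimizer(ctx, cfg)
    expect_identical(tr$best_position, tr2$best_position)
    expect_identical(tr$trace, tr2$trace)
  }
})

test_that("SFOA approaches the exhaustive optimum on an 8-feature problem", {
  set.seed(30)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  # two clearly informative features among noise, mirroring the
  # near-perfect separability regime the entropy features exhibit
  x <- cbind(ifelse(y == "a", 0, 4) + rnorm(n),
             ifelse(y == "a", -2, 2) + rnorm(n),
             matrix(rnorm(n * 6), n, 6))
  colnames(x) <- paste0("V", 1:8)
  ctx <- fitness_context(x, y, seed = 11)
  exhaustive <- min(sapply(1:255, function(b)
    evaluate_mask(as.integer(intToBits(b))[1:8], ctx)))
  hits <- 0
  for (s in 1:10) {
    cfg <- optimizer_config("sfoa", pop_size = 20, max_iter = 30, dim = 8,
                            seed = s)
    tr <- run_optimizer(ctx, cfg)
    if (tr$best_fitness <= exhaustive + 0.01) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
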
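#' Optimizer configuration for wrapper feature selection
#'
#' Shared settings for the superb fairy-wren optimizer (SFOA) and the
#' PSO/HHO/PO baselines over the `[0, 1]^D` search space with
#' threshold-binarized feature masks.
#'
#' @param algorithm One of `"sfoa"`, `"pso"`, `"hho"`, `"po"`.
#' @param pop_size Population size `N` (default 50).
#' @param max_iter Maximum iterations (default 100).
#' @param dim Search-space dimension `D` (default 39 features).
#' @param threshold Binarization cut-off in `(0, 1)` (default 0.8).
#' @param C Breeding-stage control coefficient (default 0.8, held constant).
#' @param levy_beta Levy-flight exponent in `(0, 2]` (default 1.5).
#' @param stage_probs Probabilities of the growth / breeding / enemy-
#'   avoidance stages drawn independently per individual each iteration.
#' @param rand_mode `"scalar"` (one U(0,1) draw per growth update, applied
#'   to all coordinates) or `"vector"` (per-coordinate draws).
#' @param pso,hho Named lists of baseline parameters (PSO: inertia
#'   `w_start` 0.9 linearly to `w_end` 0.4, `c1 = c2 = 2`; HHO: escape
#'   energy linearly decreasing).
#' @param seed Integer seed controlling the full run.
#' @return List of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("sfoa", "pso", "hho", "po"),
                             pop_size = 50, max_iter = 100, dim = 39,
                             threshold = 0.8, C = 0.8, levy_beta = 1.5,
                             stage_probs = c(1, 1, 1) / 3,
                             rand_mode = c("scalar", "vector"),
                             pso = list(w_start = 0.9, w_end = 0.4,
                                        c1 = 2, c2 = 2),
                             hho = list(),
                             seed = 1L) {
  algorithm <- match.arg(algorithm)
  rand_mode <- match.arg(rand_mode)
  if (pop_size < 2) stop("invalid argument: pop_size must be >= 2")
  if (threshold <= 0 || threshold >= 1)
    stop("invalid argument: threshold must be in (0, 1)")
  if (levy_beta <= 0 || levy_beta > 2)
    stop("invalid argument: levy_beta must be in (0, 2]")
  structure(list(
    algorithm = algorithm, pop_size = as.integer(pop_size),
    max_iter = as.integer(max_iter), dim = as.integer(dim),
    threshold = threshold, C = C, levy_beta = levy_beta,
    stage_probs = stage_probs / sum(stage_probs), rand_mode = rand_mode,
    pso = pso, hho = hho, seed = as.integer(seed)
  ), class = "optimizer_config")
}

#' Fitness context: data and validation scheme behind the wrapper
#'
#' Bundles the feature table, labels, the kNN classifier settings and the
#' validation scheme used to score candidate feature masks with the fitness
#' `alpha * (1 - accuracy) + (1 - alpha) * Ns / Nt` (lower is better).
#'
#' @param features Numeric matrix or data frame of feature columns.
#' @param labels Binary class labels (factor or character).
#' @param alpha Accuracy/sparsity trade-off in `(0, 1]` (default 0.99).
#' @param k kNN neighbor count (default 1).
#' @param validation `"holdout"` (stratified split, matching a fixed
#'   validation set) or `"cv"` (stratified k-fold).
#' @param val_fraction Held-out fraction for `"holdout"` (default 1/3).
#' @param folds Folds for `"cv"` (default 5).
#' @param seed Seed fixing the split, so every mask is scored on identical
#'   partitions.
#' @return List of class `fitness_context`.
#' @export
fitness_context <- function(features, labels, alpha = 0.99, k = 1,
                            validation = c("holdout", "cv"),
                            val_fraction = 1 / 3, folds = 5, seed = 1L) {
  validation <- match.arg(validation)
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("invalid input: features must be numeric")
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L)
    stop("invalid input: labels must have exactly two classes")
  if (nrow(features) != length(labels))
    stop("invalid input: features/labels length mismatch")
  if (alpha <= 0 || alpha > 1) stop("invalid argument: alpha must be in (0,1]")
  ctx <- list(features = features, labels = labels, alpha = alpha, k = k,
              validation = validation, folds = as.integer(folds),
              nt = ncol(features), seed = as.integer(seed),
              cache = new.env(parent = emptyenv()))
  if (validation == "holdout") {
    # stratified split fixed once per context
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    val_idx <- unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1L, round(length(idx) * val_fraction)))
    }))
    ctx$val_idx <- sort(val_idx)
  }
  structure(ctx, class = "fitness_context")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Maturity factor of the search
#'
#' Fraction of the evaluation budget consumed, `p = FEs / MaxFES`, scaling
#' the intensity of the exploitation (breeding) stage.
#'
#' @param fes Evaluations used so far.
#' @param max_fes Total evaluation budget, `> 0`.
#' @return Scalar in `[0, 1]`.
#' @export
maturity <- function(fes, max_fes) {
  if (max_fes <= 0) stop("invalid argument: max_fes must be > 0")
  if (fes < 0 || fes > max_fes) stop("invalid argument: fes out of range")
  fes / max_fes
}

#' Adaptive flight coefficient of the enemy-avoidance stage
#'
#' `k = 0.2 * sin(pi/2 - omega)` with `omega = (pi/2) * FEs / MaxFES`;
#' starts at 0.2, decays monotonically to 0 as the budget is spent.
#'
#' @inheritParams maturity
#' @return Scalar in `[0, 0.2]`.
#' @export
flight_coefficient <- function(fes, max_fes) {
  p <- maturity(fes, max_fes)
  0.2 * sin(pi / 2 - pi / 2 * p)
}

#' Levy-flight step (Mantegna algorithm)
#'
#' Heavy-tailed random step `u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and the standard Mantegna scale for `sigma_u`.
#'
#' @param beta Stability exponent in `(0, 2]` (default 1.5).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
levy_step <- function(beta = 1.5, n = 1) {
  if (beta <= 0 || beta > 2) stop("invalid argument: beta must be in (0, 2]")
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(n, 0, sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Growth-stage position update
#'
#' `X_new = X + rand * (X - X_prev)`, one `U(0,1)` draw (scalar mode)
#' applied to all coordinates, clipped into `[0, 1]`. The difference vector
#' mimics the juvenile learning jumps that drive exploration.
#'
#' @param current,previous Position vectors in `[0, 1]^D`.
#' @param rand Optional fixed coefficient; drawn from `U(0,1)` if `NULL`.
#' @param rand_mode `"scalar"` or `"vector"` (per-coordinate draws).
#' @return Updated position.
#' @export
growth_update <- function(current, previous, rand = NULL,
                          rand_mode = "scalar") {
  if (is.null(rand))
    rand <- if (rand_mode == "vector") stats::runif(length(current))
            else stats::runif(1)
  .clip01(current + rand * (current - previous))
}

#' Breeding-stage position update
#'
#' `X_new = X_b + C * p * (X - X_b)`: the population best acts as the
#' guiding position; the constant `C = 0.8` and the maturity factor `p`
#' control the pull, so early iterations stay exploratory and late ones
#' contract onto the best solution.
#'
#' @param current Position vector.
#' @param best Best position found so far.
#' @param p Maturity factor in `[0, 1]`.
#' @param C Control coefficient (default 0.8).
#' @return Updated position, clipped into `[0, 1]`.
#' @export
breeding_update <- function(current, best, p, C = 0.8) {
  if (p < 0 || p > 1) stop("invalid argument: p must be in [0, 1]")
  .clip01(best + C * p * (current - best))
}

#' Enemy-avoidance position update
#'
#' `X_new = X + l * k * (X_b - X)` with `l` a Levy-flight step and `k` the
#' adaptive flight coefficient; occasional long jumps re-explore the space
#' while the shrinking coefficient stabilizes late iterations.
#'
#' @param current,best Position vectors.
#' @param fes,max_fes Evaluation budget counters.
#' @param beta Levy exponent.
#' @param l Optional fixed Levy step (drawn if `NULL`).
#' @return Updated position, clipped into `[0, 1]`.
#' @export
enemies_update <- function(current, best, fes, max_fes, beta = 1.5,
                           l = NULL) {
  k <- flight_coefficient(fes, max_fes)
  if (is.null(l)) l <- levy_step(beta)
  .clip01(current + l * k * (best - current))
}

#' Binarize a continuous position into a feature-selection mask
#'
#' Coordinate `j` selects feature `j` iff it exceeds `threshold`. If no
#' coordinate exceeds it, the single largest coordinate is selected
#' (lowest index on ties) and the mask is flagged as a fallback, so every
#' mask selects at least one feature.
#'
#' @param position Numeric vector in `[0, 1]^D`.
#' @param threshold Cut-off in `(0, 1)` (default 0.8).
#' @return List of class `selection_mask`: `bits` (0/1 integer vector),
#'   `selected_count`, `fallback`.
#' @export
binarize_mask <- function(position, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1)
    stop("invalid argument: threshold must be in (0, 1)")
  bits <- as.integer(position > threshold)
  fallback <- FALSE
  if (sum(bits) == 0L) {
    bits[which.max(position)] <- 1L
    fallback <- TRUE
  }
  structure(list(bits = bits, selected_count = sum(bits),
                 fallback = fallback), class = "selection_mask")
}

#' Wrapper-selection fitness
#'
#' `alpha * (1 - accuracy) + (1 - alpha) * ns / nt`; lower is better, and
#' the value lies in `[0, 1]`. Monotone decreasing in accuracy, increasing
#' in the selected-feature count.
#'
#' @param accuracy Validation accuracy in `[0, 1]`.
#' @param ns Number of selected features, `1 <= ns <= nt`.
#' @param nt Total number of features.
#' @param alpha Trade-off weight in `(0, 1]`.
#' @return Scalar fitness.
#' @export
fitness <- function(accuracy, ns, nt, alpha = 0.99) {
  if (ns > nt) stop("invalid argument: ns cannot exceed nt")
  if (accuracy < 0 || accuracy > 1)
    stop("invalid argument: accuracy must be in [0, 1]")
  alpha * (1 - accuracy) + (1 - alpha) * ns / nt
}

#' Score a feature mask against the fitness context
#'
#' Restricts the feature table to the selected columns, runs the kNN
#' classifier under the context's validation scheme (standardization fitted
#' on the training part only), and plugs the accuracy into [fitness()].
#' Results are memoized per mask, and deterministic for a fixed context.
#'
#' @param mask A [binarize_mask()] result or a 0/1 vector.
#' @param ctx A [fitness_context()].
#' @return Fitness value with attribute `accuracy`.
#' @export
evaluate_mask <- function(mask, ctx) {
  bits <- if (inherits(mask, "selection_mask")) mask$bits else as.integer(mask)
  if (sum(bits) < 1L) stop("invalid argument: mask selects no features")
  key <- paste(bits, collapse = "")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  cols <- which(bits == 1L)
  feats <- ctx$features[, cols, drop = FALSE]
  acc <- if (ctx$validation == "holdout") {
    tr <- setdiff(seq_len(nrow(feats)), ctx$val_idx)
    std <- standardize(feats[tr, , drop = FALSE],
                       feats[ctx$val_idx, , drop = FALSE])
    pred <- knn_predict(std$train, ctx$labels[tr], std$apply, k = ctx$k)
    mean(pred$labels == ctx$labels[ctx$val_idx])
  } else {
    rep <- cross_validate(feats, ctx$labels,
                          spec = classifier_spec("knn", k = ctx$k),
                          folds = ctx$folds, seed = ctx$seed)
    rep$accuracy
  }
  out <- fitness(acc, sum(bits), ctx$nt, ctx$alpha)
  attr(out, "accuracy") <- acc
  ctx$cache[[key]] <- out
  out
}

#' Run a metaheuristic wrapper feature selection
#'
#' Iterates the configured population update rules (SFOA's three stages, or
#' the PSO/HHO/PO baseline rules) over `[0, 1]^D`, scoring threshold-
#' binarized masks with [evaluate_mask()]. SFOA uses greedy acceptance (a
#' candidate replaces an individual only if its fitness improves) and the
#' budget `MaxFES = pop_size * (max_iter + 1)` counting initialization.
#' Runs are bit-reproducible for a fixed config seed.
#'
#' @param ctx A [fitness_context()].
#' @param config An [optimizer_config()].
#' @return Object of class `optim_trace`: `best_fitness`, `best_position`,
#'   `best_mask`, `best_accuracy`, per-iteration `trace`, `fes`, `max_fes`,
#'   `algorithm`, `config`.
#' @export
run_optimizer <- function(ctx, config = optimizer_config()) {
  stopifnot(inherits(ctx, "fitness_context"))
  if (config$dim != ctx$nt)
    stop("invalid argument: config dim must match feature count")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  switch(config$algorithm,
    sfoa = .run_sfoa(ctx, config),
    pso = .run_pso(ctx, config),
    hho = .run_hho(ctx, config),
    po = .run_po(ctx, config))
}

.eval_pos <- function(pos, ctx, config) {
  as.numeric(evaluate_mask(binarize_mask(pos, config$threshold), ctx))
}

.mk_trace <- function(config, ctx, best_fit, best_pos, trace, fes, max_fes) {
  mask <- binarize_mask(best_pos, config$threshold)
  fit <- evaluate_mask(mask, ctx)
  structure(list(
    algorithm = config$algorithm, config = config,
    best_fitness = best_fit, best_position = best_pos,
    best_mask = mask, best_accuracy = attr(fit, "accuracy"),
    trace = trace, fes = fes, max_fes = max_fes
  ), class = "optim_trace")
}

#' Initialize a uniform random population
#'
#' `N` positions uniform on `[0, 1]^D`; the previous-iteration positions
#' start equal to the current ones, so the first growth update is a no-op.
#'
#' @param config An [optimizer_config()]; the caller controls the RNG state.
#' @return List with matrices `current` and `previous` (`N x D`).
#' @export
initialize_population <- function(config) {
  pos <- matrix(stats::runif(config$pop_size * config$dim),
                config$pop_size, config$dim)
  list(current = pos, previous = pos)
}

.run_sfoa <- function(ctx, config) {
  N <- config$pop_size; D <- config$dim
  max_fes <- N * (config$max_iter + 1L)
  pop <- initialize_population(config)
  X <- pop$current; Xprev <- pop$previous
  fit <- apply(X, 1, .eval_pos, ctx = ctx, config = config)
  fes <- N
  bi <- which.min(fit)
  best_fit <- fit[bi]; best_pos <- X[bi, ]
  trace <- numeric(0)
  for (t in seq_len(config$max_iter)) {
    for (i in seq_len(N)) {
      if (fes >= max_fes) break
      u <- stats::runif(1)
      cum <- cumsum(config$stage_probs)
      cand <- if (u < cum[1]) {
        growth_update(X[i, ], Xprev[i, ], rand_mode = config$rand_mode)
      } else if (u < cum[2]) {
        breeding_update(X[i, ], best_pos, maturity(fes, max_fes), config$C)
      } else {
        enemies_update(X[i, ], best_pos, fes, max_fes, config$levy_beta)
      }
      f_new <- .eval_pos(cand, ctx, config)
      fes <- fes + 1L
      if (f_new < fit[i]) {          # greedy acceptance
        Xprev[i, ] <- X[i, ]
        X[i, ] <- cand
        fit[i] <- f_new
        if (f_new < best_fit) { best_fit <- f_new; best_pos <- cand }
      }
    }
    trace <- c(trace, best_fit)
    if (fes >= max_fes) break
  }
  .mk_trace(config, ctx, best_fit, best_pos, trace, fes, max_fes)
}

.run_pso <- function(ctx, config) {
  N <- config$pop_size; D <- config$dim
  max_fes <- N * (config$max_iter + 1L)
  w0 <- config$pso$w_start; w1 <- config$pso$w_end
  c1 <- config$pso$c1; c2 <- config$pso$c2
  X <- matrix(stats::runif(N * D), N, D)
  V <- matrix(0, N, D)
  fit <- apply(X, 1, .eval_pos, ctx = ctx, config = config)
  fes <- N
  P <- X; pfit <- fit
  bi <- which.min(fit); best_fit <- fit[bi]; best_pos <- X[bi, ]
  trace <- numeric(0)
  for (t in seq_len(config$max_iter)) {
    w <- w0 + (w1 - w0) * (t - 1) / max(1, config$max_iter - 1)
    for (i in seq_len(N)) {
      if (fes >= max_fes) break
      r1 <- stats::runif(D); r2 <- stats::runif(D)
      V[i, ] <- w * V[i, ] + c1 * r1 * (P[i, ] - X[i, ]) +
        c2 * r2 * (best_pos - X[i, ])
      X[i, ] <- .clip01(X[i, ] + V[i, ])
      f <- .eval_pos(X[i, ], ctx, config)
      fes <- fes + 1L
      fit[i] <- f
      if (f < pfit[i]) { pfit[i] <- f; P[i, ] <- X[i, ] }
      if (f < best_fit) { best_fit <- f; best_pos <- X[i, ] }
    }
    trace <- c(trace, best_fit)
    if (fes >= max_fes) break
  }
  .mk_trace(config, ctx, best_fit, best_pos, trace, fes, max_fes)
}

.run_hho <- function(ctx, config) {
  N <- config$pop_size; D <- config$dim
  max_fes <- N * (config$max_iter + 1L)
  X <- matrix(stats::runif(N * D), N, D)
  fit <- apply(X, 1, .eval_pos, ctx = ctx, config = config)
  fes <- N
  bi <- which.min(fit); best_fit <- fit[bi]; best_pos <- X[bi, ]
  trace <- numeric(0)
  for (t in seq_len(config$max_iter)) {
    for (i in seq_len(N)) {
      if (fes >= max_fes) break
      E0 <- stats::runif(1, -1, 1)
      E <- 2 * E0 * (1 - t / config$max_iter)   # linearly decreasing energy
      J <- 2 * (1 - stats::runif(1))
      Xi <- X[i, ]
      if (abs(E) >= 1) {                         # exploration
        if (stats::runif(1) >= 0.5) {
          Xr <- X[sample.int(N, 1), ]
          cand <- Xr - stats::runif(1) * abs(Xr - 2 * stats::runif(1) * Xi)
        } else {
          Xm <- colMeans(X)
          cand <- (best_pos - Xm) - stats::runif(1) *
            stats::runif(D)                       # bounds are [0, 1]
        }
        cand <- .clip01(cand)
        f <- .eval_pos(cand, ctx, config); fes <- fes + 1L
        X[i, ] <- cand; fit[i] <- f
      } else {                                   # exploitation
        r <- stats::runif(1)
        if (r >= 0.5 && abs(E) >= 0.5) {         # soft besiege
          cand <- .clip01((best_pos - Xi) - E * abs(J * best_pos - Xi))
          f <- .eval_pos(cand, ctx, config); fes <- fes + 1L
          X[i, ] <- cand; fit[i] <- f
        } else if (r >= 0.5) {                   # hard besiege
          cand <- .clip01(best_pos - E * abs(best_pos - Xi))
          f <- .eval_pos(cand, ctx, config); fes <- fes + 1L
          X[i, ] <- cand; fit[i] <- f
        } else {                                 # progressive rapid dives
          base <- if (abs(E) >= 0.5) Xi else colMeans(X)
          Y <- .clip01(best_pos - E * abs(J * best_pos - base))
          fY <- .eval_pos(Y, ctx, config); fes <- fes + 1L
          if (fY < fit[i]) {
            X[i, ] <- Y; fit[i] <- fY
          } else if (fes < max_fes) {
            Z <- .clip01(Y + stats::runif(D) * levy_step(config$levy_beta, D))
            fZ <- .eval_pos(Z, ctx, config); fes <- fes + 1L
            if (fZ < fit[i]) { X[i, ] <- Z; fit[i] <- fZ }
          }
        }
      }
      if (fit[i] < best_fit) { best_fit <- fit[i]; best_pos <- X[i, ] }
    }
    trace <- c(trace, best_fit)
    if (fes >= max_fes) break
  }
  .mk_trace(config, ctx, best_fit, best_pos, trace, fes, max_fes)
}

# Simplified puma-style baseline: exploration (dimension-wise recombination
# of random individuals) and exploitation (best-guided contraction with
# occasional Levy kicks), with the phase chosen by a running score of which
# phase recently improved the global best. Greedy per-individual acceptance.
.run_po <- function(ctx, config) {
  N <- config$pop_size; D <- config$dim
  max_fes <- N * (config$max_iter + 1L)
  X <- matrix(stats::runif(N * D), N, D)
  fit <- apply(X, 1, .eval_pos, ctx = ctx, config = config)
  fes <- N
  bi <- which.min(fit); best_fit <- fit[bi]; best_pos <- X[bi, ]
  score <- c(explore = 1, exploit = 1)
  trace <- numeric(0)
  for (t in seq_len(config$max_iter)) {
    p_explore <- max(0.2, min(0.8, score["explore"] / sum(score)))
    phase <- if (stats::runif(1) < p_explore) "explore" else "exploit"
    improved <- FALSE
    for (i in seq_len(N)) {
      if (fes >= max_fes) break
      Xi <- X[i, ]
      cand <- if (phase == "explore") {
        abc <- sample.int(N, 3)
        G <- 2 * stats::runif(1) - 1
        v <- X[abc[1], ] + G * (X[abc[2], ] - X[abc[3], ])
        flip <- stats::runif(D) < 0.2        # partial random re-seeding
        v[flip] <- stats::runif(sum(flip))
        v
      } else {
        if (stats::runif(1) < 0.5)
          best_pos + 2 * stats::runif(1) * (best_pos - Xi)
        else
          best_pos + 0.1 * levy_step(config$levy_beta, D) * (Xi - best_pos)
      }
      cand <- .clip01(cand)
      f <- .eval_pos(cand, ctx, config); fes <- fes + 1L
      if (f < fit[i]) {
        X[i, ] <- cand; fit[i] <- f
        if (f < best_fit) { best_fit <- f; best_pos <- cand; improved <- TRUE }
      }
    }
    score[phase] <- 0.9 * score[phase] + (if (improved) 1 else 0)
    score[setdiff(names(score), phase)] <-
      0.9 * score[setdiff(names(score), phase)]
    trace <- c(trace, best_fit)
    if (fes >= max_fes) break
  }
  .mk_trace(config, ctx, best_fit, best_pos, trace, fes, max_fes)
}

#' @export
print.optim_trace <- function(x, ...) {
  cat("Wrapper feature selection (", toupper(x$algorithm), ")\n", sep = "")
  cat("  evaluations:", x$fes, "of", x$max_fes, "\n")
  cat("  best fitness:", format(x$best_fitness, digits = 6), "\n")
  cat("  selected features (", x$best_mask$selected_count, "): ",
      paste(which(x$best_mask$bits == 1L), collapse = ", "), "\n", sep = "")
  if (!is.null(x$best_accuracy))
    cat("  validation accuracy:", format(x$best_accuracy, digits = 6), "\n")
  invisible(x)
}
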
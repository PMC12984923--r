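#' @useDynLib entrosel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft pnorm sd median runif rnorm quantile wilcox.test
#' @importFrom utils read.csv write.csv head
NULL

.check_signal <- function(x, min_len = 2L, what = "signal") {
  if (!is.numeric(x) || length(x) == 0L)
    stop("invalid input: empty ", what)
  if (!all(is.finite(x)))
    stop("invalid input: non-finite values in ", what)
  if (length(x) < min_len)
    stop("insufficient length: ", what, " needs >= ", min_len, " samples")
  invisible(x)
}

# Tolerance guard: SD = 0 signals would make r = 0; use a machine-eps floor
# so degenerate (constant) signals yield zero-entropy values, not NaN.
.r_default <- function(x, factor = 0.2) {
  r <- factor * stats::sd(x)
  if (!is.finite(r) || r <= 0) r <- .Machine$double.eps
  r
}

# Shannon entropy of a count vector; base 2 ("bits") or e ("nats").
.shannon <- function(counts, base = 2) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

#' Shannon entropy of a histogram over the fixed intensity range
#'
#' Bins span `[0, 255]` (the standardized intensity scale used by the
#' preprocessing stage); values outside the range are clamped into the end
#' bins. Result is in bits, bounded by `log2(n_bins)`.
#'
#' @param signal Numeric vector.
#' @param n_bins Number of equal-width bins, `>= 2` (registry default 256).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(signal, n_bins = 256) {
  .check_signal(signal, 1L)
  if (n_bins < 2) stop("invalid argument: n_bins must be >= 2")
  b <- pmin(pmax(floor(signal / 256 * n_bins), 0), n_bins - 1)
  .shannon(tabulate(b + 1L, nbins = n_bins), base = 2)
}

#' Approximate entropy
#'
#' `ApEn(m, r) = Phi^m(r) - Phi^(m+1)(r)` with
#' `Phi^m = mean_i ln C_i^m(r)`, Chebyshev distance, self-matches included.
#' `m = 0` is handled by the generalized convention `Phi^0 = 0` (zero-length
#' templates match universally), so `ApEn(0) = -Phi^1`.
#'
#' @param signal Numeric vector, length `> m + 1`.
#' @param m Embedding dimension, `>= 0`.
#' @param r Match tolerance, `> 0`; defaults to `0.2 * sd(signal)`.
#' @return Non-negative scalar (up to numerical tolerance).
#' @export
approximate_entropy <- function(signal, m = 2, r = .r_default(signal)) {
  .check_signal(signal, m + 2L)
  if (m < 0) stop("invalid argument: m must be >= 0")
  if (r <= 0) stop("invalid argument: r must be > 0")
  phi_m <- if (m == 0) 0 else .apen_phi_cpp(signal, as.integer(m), r)
  phi_m1 <- .apen_phi_cpp(signal, as.integer(m) + 1L, r)
  phi_m - phi_m1
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` with `B` the number of m-template pairs and
#' `A` the number of (m+1)-template pairs within tolerance `r` (Chebyshev
#' distance, self-matches excluded, template indices `1..N-m`). `m = 0`
#' counts all ordered pairs as `B`. When `A = 0` (or `B = 0`) the value is
#' capped at `ln(B) + ln(N - m)` (resp. `2 ln(N - m)`) and flagged via the
#' `"capped"` attribute so downstream feature vectors stay finite.
#'
#' @inheritParams approximate_entropy
#' @return Non-negative scalar, possibly carrying attribute `capped = TRUE`.
#' @export
sample_entropy <- function(signal, m = 2, r = .r_default(signal)) {
  .check_signal(signal, m + 2L)
  if (m < 0) stop("invalid argument: m must be >= 0")
  if (r <= 0) stop("invalid argument: r must be > 0")
  ab <- .sampen_counts_cpp(signal, as.integer(m), r)
  A <- ab[1]; B <- ab[2]
  n <- length(signal)
  if (B == 0) return(structure(2 * log(n - m), capped = TRUE))
  if (A == 0) return(structure(log(B) + log(n - m), capped = TRUE))
  -log(A / B)
}

#' Permutation entropy (normalized)
#'
#' Shannon entropy of ordinal-pattern frequencies divided by `log2(m!)`;
#' ties are broken by order of occurrence (stable ranking). Result in
#' `[0, 1]`.
#'
#' @param signal Numeric vector, length `>= (m - 1) * tau + 1`.
#' @param m Pattern length, `>= 2` (registry default 3).
#' @param tau Embedding delay, `>= 1`.
#' @return Normalized entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(signal, m = 3, tau = 1) {
  if (m < 2) stop("invalid argument: m must be >= 2")
  if (tau < 1) stop("invalid argument: tau must be >= 1")
  .check_signal(signal, (m - 1) * tau + 1L)
  n <- length(signal)
  nt <- n - (m - 1) * tau
  pats <- character(nt)
  for (i in seq_len(nt)) {
    w <- signal[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(w), collapse = ".")  # stable: ties by occurrence
  }
  .shannon(table(pats), base = 2) / log2(factorial(m))
}

#' Spectral entropy (normalized)
#'
#' Shannon entropy of the one-sided periodogram power distribution with the
#' DC component excluded, divided by the log of the number of frequency
#' bins. A flat spectrum gives 1, a single-line spectrum 0.
#'
#' @param signal Numeric vector, length `>= 8`.
#' @return Normalized entropy in `[0, 1]`.
#' @export
spectral_entropy <- function(signal) {
  .check_signal(signal, 8L)
  n <- length(signal)
  pw <- Mod(stats::fft(signal - mean(signal)))^2
  bins <- pw[2:(floor(n / 2) + 1)]
  if (sum(bins) <= 0) stop("invalid input: signal has no spectral power")
  p <- bins / sum(bins)
  .shannon(p, base = exp(1)) / log(length(bins))
}

#' Dispersion entropy (normalized)
#'
#' Signal values are mapped through the normal CDF (using the signal's own
#' mean and SD) to `c` classes; Shannon entropy of the dispersion-pattern
#' frequencies is normalized by `log(c^m)`.
#'
#' @param signal Numeric vector.
#' @param m Pattern length, `>= 2`.
#' @param c Number of classes, `>= 2` (registry default 6).
#' @param tau Embedding delay.
#' @return Normalized entropy in `[0, 1]`.
#' @export
dispersion_entropy <- function(signal, m = 2, c = 6, tau = 1) {
  if (c < 2) stop("invalid argument: c must be >= 2")
  if (m < 2) stop("invalid argument: m must be >= 2")
  .check_signal(signal, (m - 1) * tau + 1L)
  s <- stats::sd(signal)
  y <- if (s > 0) stats::pnorm(signal, mean = mean(signal), sd = s)
       else rep(0.5, length(signal))
  z <- pmin(pmax(round(c * y + 0.5), 1), c)
  n <- length(signal)
  nt <- n - (m - 1) * tau
  idx <- sapply(0:(m - 1), function(k) z[seq_len(nt) + k * tau])
  pats <- apply(matrix(idx, nrow = nt), 1, paste, collapse = ".")
  .shannon(table(pats), base = exp(1)) / log(c^m)
}

#' Fuzzy entropy
#'
#' SampEn-style conditional ratio with exponential membership
#' `exp(-(d / r)^n_exp)` computed on baseline-removed (per-template mean
#' subtracted) templates, making the measure translation-invariant.
#'
#' @inheritParams approximate_entropy
#' @param n_exp Membership exponent, `> 0` (registry default 2).
#' @return Non-negative scalar.
#' @export
fuzzy_entropy <- function(signal, m = 2, r = .r_default(signal), n_exp = 2) {
  .check_signal(signal, m + 2L)
  if (m < 1) stop("invalid argument: m must be >= 1")
  if (r <= 0 || n_exp <= 0) stop("invalid argument: r and n_exp must be > 0")
  ph <- .fuzzy_phis_cpp(signal, as.integer(m), r, n_exp)
  log(ph[1]) - log(ph[2])
}

#' Composite multiscale entropy
#'
#' Mean of [sample_entropy()] over the `scale` offset coarse-grained series
#' (non-overlapping window means starting at offsets `0..scale-1`), with the
#' tolerance `r` fixed from the original signal's SD.
#'
#' @inheritParams approximate_entropy
#' @param scale Time scale, `>= 1`.
#' @return Non-negative scalar.
#' @export
composite_multiscale_entropy <- function(signal, scale = 1, m = 2,
                                         r = .r_default(signal)) {
  if (scale < 1) stop("invalid argument: scale must be >= 1")
  .check_signal(signal, (m + 2L) * as.integer(scale))
  vals <- vapply(seq_len(scale) - 1L, function(offset) {
    xs <- signal[(offset + 1):length(signal)]
    ng <- floor(length(xs) / scale)
    if (ng <= m + 1) stop("insufficient length: coarse series too short")
    cg <- colMeans(matrix(xs[seq_len(ng * scale)], nrow = scale))
    as.numeric(sample_entropy(cg, m = m, r = r))
  }, numeric(1))
  mean(vals)
}

#' Attention entropy
#'
#' Mean Shannon entropy (bits) of the four inter-key-point interval
#' distributions of the signal: intervals between consecutive local maxima,
#' between local minima, and between alternating max-to-min / min-to-max
#' pairs. Fewer than two key points of a kind contribute zero.
#'
#' @param signal Numeric vector.
#' @return Non-negative scalar.
#' @export
attention_entropy <- function(signal) {
  .check_signal(signal, 3L)
  n <- length(signal)
  mid <- 2:(n - 1)
  is_max <- signal[mid] > signal[mid - 1] & signal[mid] > signal[mid + 1]
  is_min <- signal[mid] < signal[mid - 1] & signal[mid] < signal[mid + 1]
  pk_max <- mid[is_max]; pk_min <- mid[is_min]
  h_of <- function(intervals) {
    if (length(intervals) < 1L) return(0)
    .shannon(table(intervals), base = 2)
  }
  keyed <- sort(c(pk_max, pk_min))
  kind <- ifelse(keyed %in% pk_max, "M", "m")
  trans <- function(from, to) {
    if (length(keyed) < 2L) return(numeric(0))
    sel <- kind[-length(kind)] == from & kind[-1] == to
    diff(keyed)[sel]
  }
  mean(c(h_of(diff(pk_max)), h_of(diff(pk_min)),
         h_of(trans("M", "m")), h_of(trans("m", "M"))))
}

#' Bubble entropy
#'
#' Renyi-2 entropy of the bubble-sort swap-count distribution at embedding
#' dimensions `m` and `m + 1`, differenced and normalized by
#' `log((m + 1) / (m - 1))`.
#'
#' @param signal Numeric vector.
#' @param m Embedding dimension, `>= 2` (registry default 10).
#' @return Scalar (typically in `[0, 1]` for irregular signals).
#' @export
bubble_entropy <- function(signal, m = 10) {
  if (m < 2) stop("invalid argument: m must be >= 2")
  .check_signal(signal, m + 2L)
  renyi2 <- function(mm) {
    counts <- table(.bubble_swaps_cpp(signal, as.integer(mm)))
    p <- as.numeric(counts) / sum(counts)
    -log(sum(p^2))
  }
  (renyi2(m + 1) - renyi2(m)) / log((m + 1) / (m - 1))
}

#' Corrected conditional entropy
#'
#' Signal quantized into `q` uniform bins over its range; the conditional
#' entropy of m-length patterns, `E(m) - E(m-1)`, is corrected by the
#' fraction of singleton patterns times `E(1)` (natural log).
#'
#' @param signal Numeric vector.
#' @param m Pattern length, `>= 2`.
#' @param q Number of quantization bins (registry default 6).
#' @return Non-negative scalar.
#' @export
corrected_conditional_entropy <- function(signal, m = 2, q = 6) {
  if (m < 2) stop("invalid argument: m must be >= 2")
  .check_signal(signal, m + 1L)
  z <- .quantize_uniform(signal, q)
  e_of <- function(mm) {
    nt <- length(z) - mm + 1L
    pats <- apply(matrix(sapply(0:(mm - 1), function(k) z[seq_len(nt) + k]),
                         nrow = nt), 1, paste, collapse = ".")
    tab <- table(pats)
    list(H = .shannon(tab, base = exp(1)), perc = sum(tab == 1) / sum(tab))
  }
  e1 <- e_of(1); em <- e_of(m); em1 <- e_of(m - 1)
  (em$H - em1$H) + em$perc * e1$H
}

.quantize_uniform <- function(x, q) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(1L, length(x)))
  pmin(pmax(floor((x - rng[1]) / (rng[2] - rng[1]) * q) + 1L, 1L), q)
}

#' Cosine similarity entropy
#'
#' Fraction `P` of embedded template pairs whose angular distance
#' `acos(cos_sim) / pi` is within `tol`, turned into the binary Shannon
#' entropy `-[P log2 P + (1 - P) log2(1 - P)]`.
#'
#' @param signal Numeric vector.
#' @param m Embedding dimension, `>= 2`.
#' @param tol Angular tolerance in `[0, 1]` (registry default 0.1).
#' @return Scalar in `[0, 1]`.
#' @export
cosine_similarity_entropy <- function(signal, m = 2, tol = 0.1) {
  if (m < 2) stop("invalid argument: m must be >= 2")
  .check_signal(signal, m + 1L)
  p <- .cosine_pair_frac_cpp(signal, as.integer(m), tol)
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

#' Distribution entropy (normalized)
#'
#' Shannon entropy (bits) of the histogram of all pairwise Chebyshev
#' template distances, `n_bins` equal-width bins over `[0, max distance]`,
#' normalized by `log2(n_bins)`.
#'
#' @param signal Numeric vector.
#' @param m Embedding dimension (registry default 2).
#' @param n_bins Histogram bins (registry default 512).
#' @return Scalar in `[0, 1]`.
#' @export
distribution_entropy <- function(signal, m = 2, n_bins = 512) {
  if (m < 1) stop("invalid argument: m must be >= 1")
  .check_signal(signal, m + 2L)
  counts <- .dist_hist_cpp(signal, as.integer(m), as.integer(n_bins))
  .shannon(counts, base = 2) / log2(n_bins)
}

#' Diversity entropy (normalized)
#'
#' Cosine similarities between consecutive embedded templates (the orbit of
#' the trajectory) are histogrammed into `n_bins` bins over `[-1, 1]`;
#' Shannon entropy of the bin distribution is normalized by `log(n_bins)`.
#'
#' @param signal Numeric vector.
#' @param m Embedding dimension.
#' @param n_bins Similarity bins (registry default 5).
#' @return Scalar in `[0, 1]`.
#' @export
diversity_entropy <- function(signal, m = 2, n_bins = 5) {
  if (m < 2) stop("invalid argument: m must be >= 2")
  .check_signal(signal, m + 2L)
  n <- length(signal)
  nt <- n - m + 1L
  emb <- sapply(0:(m - 1), function(k) signal[seq_len(nt) + k])
  emb <- matrix(emb, nrow = nt)
  a <- emb[-nt, , drop = FALSE]; b <- emb[-1, , drop = FALSE]
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  sim <- rowSums(a * b) / (na * nb)
  sim[!is.finite(sim)] <- 1  # zero-norm templates treated as parallel
  sim <- pmin(pmax(sim, -1), 1)
  bins <- pmin(floor((sim + 1) / 2 * n_bins) + 1L, n_bins)
  .shannon(tabulate(bins, nbins = n_bins), base = exp(1)) / log(n_bins)
}

#' Entropy of entropy
#'
#' The signal is cut into consecutive windows of `w` samples; each window's
#' Shannon entropy over `levels` amplitude slices of the global range forms
#' a derived series whose own Shannon entropy (over its distinct values) is
#' returned (natural log).
#'
#' @param signal Numeric vector.
#' @param w Window length in samples (registry default 5).
#' @param levels Amplitude slices (registry default 5).
#' @return Non-negative scalar.
#' @export
entropy_of_entropy <- function(signal, w = 5, levels = 5) {
  if (w < 2) stop("invalid argument: w must be >= 2")
  .check_signal(signal, 2L * w)
  z <- .quantize_uniform(signal, levels)
  nwin <- floor(length(z) / w)
  h1 <- vapply(seq_len(nwin), function(i) {
    win <- z[((i - 1) * w + 1):(i * w)]
    .shannon(tabulate(win, nbins = levels), base = exp(1))
  }, numeric(1))
  .shannon(table(round(h1, 12)), base = exp(1))
}

#' Gridded distribution entropy
#'
#' Shannon entropy (bits) of the occupancy distribution of the Poincare
#' plot (`x_i`, `x_{i+1}`) over an `n_grid x n_grid` uniform grid.
#'
#' @param signal Numeric vector.
#' @param n_grid Grid side (registry default 3).
#' @return Non-negative scalar, at most `2 log2(n_grid)`.
#' @export
gridded_distribution_entropy <- function(signal, n_grid = 3) {
  .check_signal(signal, 3L)
  gx <- .quantize_uniform(signal[-length(signal)], n_grid)
  gy <- .quantize_uniform(signal[-1], n_grid)
  .shannon(table(paste(gx, gy)), base = 2)
}

#' Phase entropy
#'
#' Shannon entropy (natural log) of the angular sector occupancy of the
#' second-order difference plot (successive differences plotted against
#' their successors), with `sectors` equal angular sectors.
#'
#' @param signal Numeric vector.
#' @param sectors Number of angular sectors (registry default 4).
#' @return Non-negative scalar.
#' @export
phase_entropy <- function(signal, sectors = 4) {
  .check_signal(signal, 4L)
  d <- diff(signal)
  a <- d[-length(d)]; b <- d[-1]
  keep <- !(a == 0 & b == 0)
  if (!any(keep)) return(0)
  ang <- atan2(b[keep], a[keep])  # [-pi, pi)
  sec <- pmin(floor((ang + pi) / (2 * pi) * sectors) + 1L, sectors)
  .shannon(tabulate(sec, nbins = sectors), base = exp(1))
}

#' Range entropy
#'
#' SampEn-style conditional ratio using the normalized range distance
#' `(max - min) / (max + min)` of componentwise absolute template
#' differences. Because this distance lives in `[0, 1]`, the tolerance `r`
#' is dimensionless (default 0.2) rather than SD-scaled.
#'
#' @param signal Numeric vector.
#' @param m Embedding dimension (registry default 2).
#' @param r Tolerance on the normalized distance scale, in `(0, 1)`.
#' @return Non-negative scalar, capped as in [sample_entropy()].
#' @export
range_entropy <- function(signal, m = 2, r = 0.2) {
  if (m < 1) stop("invalid argument: m must be >= 1")
  if (r <= 0 || r >= 1) stop("invalid argument: r must be in (0, 1)")
  .check_signal(signal, m + 2L)
  ab <- .rangeen_counts_cpp(signal, as.integer(m), r)
  n <- length(signal)
  if (ab[2] == 0) return(structure(2 * log(n - m), capped = TRUE))
  if (ab[1] == 0) return(structure(log(ab[2]) + log(n - m), capped = TRUE))
  -log(ab[1] / ab[2])
}

#' Slope entropy
#'
#' Consecutive within-template differences are classified into five symbols
#' by thresholds `gamma` (steep) and `delta` (flat); Shannon entropy
#' (natural log) of the symbol-pattern distribution.
#'
#' @param signal Numeric vector.
#' @param m Embedding dimension, `>= 2`.
#' @param gamma Steep-slope threshold in intensity units (default 5).
#' @param delta Flat-slope threshold (default 0.001).
#' @return Non-negative scalar.
#' @export
slope_entropy <- function(signal, m = 2, gamma = 5, delta = 0.001) {
  if (m < 2) stop("invalid argument: m must be >= 2")
  if (delta < 0 || gamma <= delta) stop("invalid argument: need gamma > delta >= 0")
  .check_signal(signal, m + 1L)
  d <- diff(signal)
  sym <- ifelse(d > gamma, 2L,
         ifelse(d > delta, 1L,
         ifelse(d >= -delta, 0L,
         ifelse(d >= -gamma, -1L, -2L))))
  nt <- length(signal) - m + 1L
  k <- m - 1L
  pats <- apply(matrix(sapply(0:(k - 1), function(j) sym[seq_len(nt) + j]),
                       nrow = nt), 1, paste, collapse = ".")
  .shannon(table(pats), base = exp(1))
}

# ---- cross-signal measures ---------------------------------------------

.check_pair_args <- function(x, y, min_len) {
  .check_signal(x, min_len, "primary signal")
  .check_signal(y, min_len, "reference signal")
  if (length(x) != length(y))
    stop("invalid input: cross measures need equal-length signals")
  invisible(NULL)
}

#' Cross-approximate entropy
#'
#' Asynchrony of a primary signal relative to a reference:
#' `Phi^m - Phi^(m+1)` where `Phi^m` averages `ln` of the fraction of
#' reference templates within `r` of each primary template. `m = 0` uses
#' `Phi^0 = 0`. The tolerance defaults to `0.2 * sd(primary)`.
#'
#' @param x Primary signal.
#' @param y Reference signal (same length).
#' @param m Embedding dimension, `>= 0`.
#' @param r Match tolerance, `> 0`.
#' @return Scalar; may be non-finite if no templates match (imputed at the
#'   feature-vector level).
#' @export
cross_approximate_entropy <- function(x, y, m = 2, r = .r_default(x)) {
  if (m < 0) stop("invalid argument: m must be >= 0")
  if (r <= 0) stop("invalid argument: r must be > 0")
  .check_pair_args(x, y, m + 2L)
  phi_m <- if (m == 0) 0 else .cross_apen_phi_cpp(x, y, as.integer(m), r)
  phi_m1 <- .cross_apen_phi_cpp(x, y, as.integer(m) + 1L, r)
  phi_m - phi_m1
}

#' Cross-sample entropy
#'
#' `-ln(A / B)` over all ordered (primary-template, reference-template)
#' pairs; `i = j` pairs are included since the templates come from different
#' signals. `m = 0` counts all pairs as `B`. Capping as in
#' [sample_entropy()].
#'
#' @inheritParams cross_approximate_entropy
#' @return Non-negative scalar, possibly `capped`.
#' @export
cross_sample_entropy <- function(x, y, m = 2, r = .r_default(x)) {
  if (m < 0) stop("invalid argument: m must be >= 0")
  if (r <= 0) stop("invalid argument: r must be > 0")
  .check_pair_args(x, y, m + 2L)
  ab <- .cross_sampen_counts_cpp(x, y, as.integer(m), r)
  n <- length(x)
  if (ab[2] == 0) return(structure(2 * log(n - m), capped = TRUE))
  if (ab[1] == 0) return(structure(log(ab[2]) + log(n - m), capped = TRUE))
  -log(ab[1] / ab[2])
}

#' Cross-fuzzy entropy
#'
#' Fuzzy-membership conditional ratio across two signals, with
#' baseline-removed templates and exponential membership.
#'
#' @inheritParams cross_approximate_entropy
#' @param n_exp Membership exponent.
#' @return Scalar.
#' @export
cross_fuzzy_entropy <- function(x, y, m = 2, r = .r_default(x), n_exp = 2) {
  if (m < 1) stop("invalid argument: m must be >= 1")
  if (r <= 0 || n_exp <= 0) stop("invalid argument: r and n_exp must be > 0")
  .check_pair_args(x, y, m + 2L)
  ph <- .cross_fuzzy_phis_cpp(x, y, as.integer(m), r, n_exp)
  log(ph[1]) - log(ph[2])
}

#' Cross-Kolmogorov (K2-style) entropy
#'
#' `ln(C_m(r) / C_{m+1}(r))` on cross correlation sums (fractions of
#' ordered primary/reference template pairs within `r`). The least
#' standardized measure of the bank; results may be non-finite when no
#' pairs match at the larger dimension and are then imputed downstream.
#'
#' @inheritParams cross_approximate_entropy
#' @return Scalar.
#' @export
cross_kolmogorov_entropy <- function(x, y, m = 2, r = .r_default(x)) {
  if (m < 1) stop("invalid argument: m must be >= 1")
  if (r <= 0) stop("invalid argument: r must be > 0")
  .check_pair_args(x, y, m + 2L)
  cs <- .cross_corr_sums_cpp(x, y, as.integer(m), r)
  log(cs[1] / cs[2])
}

#' Corrected cross-conditional entropy
#'
#' Both signals quantized into `q` uniform bins; the uncertainty of the
#' next reference sample given the preceding primary pattern,
#' `E_cross(m) - E_x(m - 1)`, is corrected by the singleton fraction times
#' the reference's first-order entropy.
#'
#' @inheritParams cross_approximate_entropy
#' @param q Quantization bins (registry default 6).
#' @return Non-negative scalar.
#' @export
cross_conditional_entropy <- function(x, y, m = 2, q = 6) {
  if (m < 2) stop("invalid argument: m must be >= 2")
  .check_pair_args(x, y, m + 1L)
  zx <- .quantize_uniform(x, q); zy <- .quantize_uniform(y, q)
  nt <- length(x) - m + 1L
  past <- apply(matrix(sapply(0:(m - 2), function(k) zx[seq_len(nt) + k]),
                       nrow = nt), 1, paste, collapse = ".")
  joint <- paste(past, zy[seq_len(nt) + (m - 1L)])
  tabj <- table(joint)
  e_joint <- .shannon(tabj, base = exp(1))
  e_past <- .shannon(table(past), base = exp(1))
  perc <- sum(tabj == 1) / sum(tabj)
  e1y <- .shannon(tabulate(zy, nbins = q), base = exp(1))
  (e_joint - e_past) + perc * e1y
}

#' Cross-distribution entropy (normalized)
#'
#' Distribution entropy on the histogram of Chebyshev distances between all
#' primary/reference template pairs.
#'
#' @inheritParams cross_approximate_entropy
#' @param n_bins Histogram bins (registry default 512).
#' @return Scalar in `[0, 1]`.
#' @export
cross_distribution_entropy <- function(x, y, m = 2, n_bins = 512) {
  if (m < 1) stop("invalid argument: m must be >= 1")
  .check_pair_args(x, y, m + 2L)
  counts <- .cross_dist_hist_cpp(x, y, as.integer(m), as.integer(n_bins))
  .shannon(counts, base = 2) / log2(n_bins)
}

#' Cross-spectral entropy (normalized)
#'
#' Shannon entropy of the normalized cross-spectral magnitude distribution
#' (DC excluded) of the two signals, divided by the log of the number of
#' frequency bins.
#'
#' @inheritParams cross_approximate_entropy
#' @return Scalar in `[0, 1]`.
#' @export
cross_spectral_entropy <- function(x, y) {
  .check_pair_args(x, y, 8L)
  n <- length(x)
  fx <- stats::fft(x - mean(x)); fy <- stats::fft(y - mean(y))
  cs <- Mod(fx * Conj(fy))[2:(floor(n / 2) + 1)]
  if (sum(cs) <= 0) return(NaN)
  p <- cs / sum(cs)
  .shannon(p, base = exp(1)) / log(length(p))
}
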
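#' Construct a primary/reference signal pair
#'
#' Cross-signal measures (F27-F39) consume a primary signal together with a
#' reference signal; by default the reference is the complementary-region
#' signal from the same source image. Unequal lengths are truncated to the
#' shorter signal and recorded.
#'
#' @param primary Numeric vector (the signal the features describe).
#' @param reference Numeric vector for the ten cross measures.
#' @param class_label `"tumor"` or `"non_tumor"`.
#' @param source_image_id Identifier of the originating image.
#' @return Object of class `sample_pair`.
#' @export
sample_pair <- function(primary, reference, class_label = "tumor",
                        source_image_id = "img") {
  primary <- as.numeric(primary); reference <- as.numeric(reference)
  if (!all(is.finite(primary)) || !all(is.finite(reference)))
    stop("invalid input: non-finite signal values")
  truncated <- length(primary) != length(reference)
  n <- min(length(primary), length(reference))
  if (n < 32L)
    stop("insufficient length: signals need >= 32 samples")
  if (!class_label %in% c("tumor", "non_tumor"))
    stop("invalid argument: class_label must be 'tumor' or 'non_tumor'")
  structure(list(
    primary = primary[seq_len(n)],
    reference = reference[seq_len(n)],
    class_label = class_label,
    source_image_id = source_image_id,
    truncated = truncated
  ), class = "sample_pair")
}

#' The 39-entry entropy feature registry
#'
#' Fixed-order registry of the descriptor bank: feature ids `F1..F39`, the
#' measure family each dispatches to, its parameters, and whether it
#' consumes the reference signal (true for `F27`-`F39`). Parameter defaults
#' follow the standard literature conventions of each measure (see the
#' individual measure help pages) and can be overridden through `params`.
#'
#' @param params Optional named list overriding registry parameters, keyed
#'   by feature id, e.g. `list(F19 = list(m = 4))`.
#' @return Data frame with columns `feature_id`, `name`, `family`,
#'   `requires_reference` and a list-column `params`.
#' @export
feature_registry <- function(params = NULL) {
  # flag argument placed after the dots so measure parameters like `r` or
  # `n_bins` can never partially match it
  e <- function(id, name, family, flag, ...) {
    list(feature_id = id, name = name, family = family,
         requires_reference = flag, params = list(...))
  }
  entries <- list(
    e("F1", "Approximate Entropy (m=0)", "approximate", FALSE, m = 0),
    e("F2", "Approximate Entropy (m=1)", "approximate", FALSE, m = 1),
    e("F3", "Approximate Entropy (m=2)", "approximate", FALSE, m = 2),
    e("F4", "Attention Entropy", "attention", FALSE),
    e("F5", "Bubble Entropy", "bubble", FALSE, m = 10),
    e("F6", "Composite Multiscale Entropy (time scale 1)", "cmse", FALSE,
      scale = 1, m = 2),
    e("F7", "Composite Multiscale Entropy (time scale 2)", "cmse", FALSE,
      scale = 2, m = 2),
    e("F8", "Composite Multiscale Entropy (time scale 3)", "cmse", FALSE,
      scale = 3, m = 2),
    e("F9", "Shannon Entropy", "shannon", FALSE, n_bins = 256),
    e("F10", "Corrected Conditional Entropy", "cce", FALSE, m = 2, q = 6),
    e("F11", "Cosine Similarity Entropy", "cosine", FALSE, m = 2, tol = 0.1),
    e("F12", "Dispersion Entropy", "dispersion", FALSE, m = 2, c = 6,
      tau = 1),
    e("F13", "Distribution Entropy", "distribution", FALSE, m = 2,
      n_bins = 512),
    e("F14", "Diversity Entropy", "diversity", FALSE, m = 2, n_bins = 5),
    e("F15", "Entropy of Entropy", "eoe", FALSE, w = 5, levels = 5),
    e("F16", "Fuzzy Entropy (m=1)", "fuzzy", FALSE, m = 1, n_exp = 2),
    e("F17", "Fuzzy Entropy (m=2)", "fuzzy", FALSE, m = 2, n_exp = 2),
    e("F18", "Gridded Distribution Entropy", "gde", FALSE, n_grid = 3),
    e("F19", "Permutation Entropy", "permutation", FALSE, m = 3, tau = 1),
    e("F20", "Phase Entropy", "phase", FALSE, sectors = 4),
    e("F21", "Range Entropy", "range", FALSE, m = 2, r = 0.2),
    e("F22", "Sample Entropy (m=0)", "sample", FALSE, m = 0),
    e("F23", "Sample Entropy (m=1)", "sample", FALSE, m = 1),
    e("F24", "Sample Entropy (m=2)", "sample", FALSE, m = 2),
    e("F25", "Slope Entropy", "slope", FALSE, m = 2, gamma = 5,
      delta = 0.001),
    e("F26", "Spectral Entropy", "spectral", FALSE),
    e("F27", "Cross-approximate Entropy (m=0)", "cross_approximate", TRUE,
      m = 0),
    e("F28", "Cross-approximate Entropy (m=1)", "cross_approximate", TRUE,
      m = 1),
    e("F29", "Cross-approximate Entropy (m=2)", "cross_approximate", TRUE,
      m = 2),
    e("F30", "Corrected Cross-conditional Entropy", "cross_cce", TRUE,
      m = 2, q = 6),
    e("F31", "Cross-distribution Entropy", "cross_distribution", TRUE,
      m = 2, n_bins = 512),
    e("F32", "Cross-fuzzy Entropy (m=1)", "cross_fuzzy", TRUE, m = 1,
      n_exp = 2),
    e("F33", "Cross-fuzzy Entropy (m=2)", "cross_fuzzy", TRUE, m = 2,
      n_exp = 2),
    e("F34", "Cross-Kolmogorov Entropy (m=1)", "cross_kolmogorov", TRUE,
      m = 1),
    e("F35", "Cross-Kolmogorov Entropy (m=2)", "cross_kolmogorov", TRUE,
      m = 2),
    e("F36", "Cross-sample entropy (m=0)", "cross_sample", TRUE, m = 0),
    e("F37", "Cross-sample entropy (m=1)", "cross_sample", TRUE, m = 1),
    e("F38", "Cross-sample entropy (m=2)", "cross_sample", TRUE, m = 2),
    e("F39", "Cross-spectral Entropy", "cross_spectral", TRUE)
  )
  reg <- data.frame(
    feature_id = vapply(entries, `[[`, character(1), "feature_id"),
    name = vapply(entries, `[[`, character(1), "name"),
    family = vapply(entries, `[[`, character(1), "family"),
    requires_reference = vapply(entries, `[[`, logical(1),
                                "requires_reference"),
    stringsAsFactors = FALSE
  )
  reg$params <- lapply(entries, `[[`, "params")
  if (!is.null(params)) {
    for (id in names(params)) {
      i <- match(id, reg$feature_id)
      if (is.na(i)) stop("registry error: unknown feature id '", id, "'")
      reg$params[[i]] <- utils::modifyList(reg$params[[i]], params[[id]])
    }
  }
  reg
}

#' Compute one registry feature on a sample pair
#'
#' Dispatches `feature_id` to its measure family with the registry
#' parameters. Features `F27`-`F39` consume `(primary, reference)`; all
#' others consume the primary signal only. SD-scaled tolerances use
#' `0.2 * sd(primary)`.
#'
#' @param feature_id One of `"F1".."F39"`.
#' @param pair A [sample_pair()].
#' @param registry Registry data frame; defaults to [feature_registry()].
#' @return Scalar feature value (may be non-finite for degenerate inputs;
#'   see [feature_table()] for the imputation rule).
#' @export
compute_feature <- function(feature_id, pair, registry = feature_registry()) {
  i <- match(feature_id, registry$feature_id)
  if (is.na(i)) stop("registry error: unknown feature id '", feature_id, "'")
  p <- registry$params[[i]]
  x <- pair$primary; y <- pair$reference
  r <- .r_default(x)
  val <- tryCatch(switch(registry$family[i],
    approximate = approximate_entropy(x, m = p$m, r = r),
    attention = attention_entropy(x),
    bubble = bubble_entropy(x, m = p$m),
    cmse = composite_multiscale_entropy(x, scale = p$scale, m = p$m, r = r),
    shannon = shannon_entropy(x, n_bins = p$n_bins),
    cce = corrected_conditional_entropy(x, m = p$m, q = p$q),
    cosine = cosine_similarity_entropy(x, m = p$m, tol = p$tol),
    dispersion = dispersion_entropy(x, m = p$m, c = p$c, tau = p$tau),
    distribution = distribution_entropy(x, m = p$m, n_bins = p$n_bins),
    diversity = diversity_entropy(x, m = p$m, n_bins = p$n_bins),
    eoe = entropy_of_entropy(x, w = p$w, levels = p$levels),
    fuzzy = fuzzy_entropy(x, m = p$m, r = r, n_exp = p$n_exp),
    gde = gridded_distribution_entropy(x, n_grid = p$n_grid),
    permutation = permutation_entropy(x, m = p$m, tau = p$tau),
    phase = phase_entropy(x, sectors = p$sectors),
    range = range_entropy(x, m = p$m, r = p$r),
    sample = sample_entropy(x, m = p$m, r = r),
    slope = slope_entropy(x, m = p$m, gamma = p$gamma, delta = p$delta),
    spectral = spectral_entropy(x),
    cross_approximate = cross_approximate_entropy(x, y, m = p$m, r = r),
    cross_cce = cross_conditional_entropy(x, y, m = p$m, q = p$q),
    cross_distribution = cross_distribution_entropy(x, y, m = p$m,
                                                    n_bins = p$n_bins),
    cross_fuzzy = cross_fuzzy_entropy(x, y, m = p$m, r = r, n_exp = p$n_exp),
    cross_kolmogorov = cross_kolmogorov_entropy(x, y, m = p$m, r = r),
    cross_sample = cross_sample_entropy(x, y, m = p$m, r = r),
    cross_spectral = cross_spectral_entropy(x, y),
    stop("registry error: unknown family")
  ), error = function(e) {
    stop("feature ", feature_id, ": ", conditionMessage(e), call. = FALSE)
  })
  as.numeric(val)
}

#' Extract the ordered 39-value feature vector from a sample pair
#'
#' Computes every registry feature in fixed order `F1..F39`. Non-finite raw
#' values (possible for degenerate signals in a few conditional-ratio
#' measures) are returned as `NA` and flagged via the `imputed` attribute;
#' [feature_table()] replaces them with the per-feature median across the
#' table.
#'
#' @param pair A [sample_pair()].
#' @param registry Registry data frame.
#' @return Named numeric vector of length 39 with attributes `class_label`,
#'   `source_image_id`, `imputed` (logical 39-vector).
#' @export
extract_features <- function(pair, registry = feature_registry()) {
  if (!inherits(pair, "sample_pair")) stop("invalid input: need a sample_pair")
  vals <- vapply(registry$feature_id, compute_feature, numeric(1),
                 pair = pair, registry = registry)
  bad <- !is.finite(vals)
  vals[bad] <- NA_real_
  names(vals) <- registry$feature_id
  attr(vals, "class_label") <- pair$class_label
  attr(vals, "source_image_id") <- pair$source_image_id
  attr(vals, "imputed") <- bad
  vals
}

#' Build a feature table from a list of sample pairs
#'
#' One row per pair with columns `sample_id`, `class`, `F1..F39`.
#' Non-finite raw feature values are imputed with the per-feature median of
#' the finite values in the table; the imputation positions are recorded in
#' the `imputed` attribute.
#'
#' @param pairs List of [sample_pair()] objects.
#' @param registry Registry data frame.
#' @return Data frame (39 feature columns), attribute `imputed` a logical
#'   matrix.
#' @export
feature_table <- function(pairs, registry = feature_registry()) {
  vecs <- lapply(pairs, extract_features, registry = registry)
  mat <- do.call(rbind, vecs)
  imputed <- is.na(mat)
  for (j in seq_len(ncol(mat))) {
    if (any(imputed[, j])) {
      med <- stats::median(mat[, j], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      mat[imputed[, j], j] <- med
    }
  }
  out <- data.frame(
    sample_id = vapply(pairs, function(p)
      paste0(p$source_image_id, "_", p$class_label), character(1)),
    class = vapply(pairs, `[[`, character(1), "class_label"),
    mat,
    stringsAsFactors = FALSE
  )
  names(out)[-(1:2)] <- registry$feature_id
  attr(out, "imputed") <- imputed
  out
}

#' Write / read a feature table as CSV
#'
#' Header `sample_id,class,F1..F39`; numeric values round-trip exactly to
#' 12 significant digits.
#'
#' @param table Feature table from [feature_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_csv <- function(table, path) {
  tab <- table
  for (j in seq_along(tab))
    if (is.numeric(tab[[j]])) tab[[j]] <- signif(tab[[j]], 12)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
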
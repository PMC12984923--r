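# Independent brute-force oracles: explicit loops over all template pairs /
# patterns, written against the measure definitions only. They share no code
# with the package internals and are only run on short signals.

o_cheb <- function(a, b) max(abs(a - b))

o_apen_phi <- function(x, m, r) {
  n <- length(x)
  if (m == 0) return(0)
  nt <- n - m + 1
  logs <- numeric(nt)
  for (i in seq_len(nt)) {
    cnt <- 0
    for (j in seq_len(nt)) {
      if (o_cheb(x[i:(i + m - 1)], x[j:(j + m - 1)]) <= r) cnt <- cnt + 1
    }
    logs[i] <- log(cnt / nt)
  }
  mean(logs)
}

o_apen <- function(x, m, r)
  o_apen_phi(x, m, r) - o_apen_phi(x, m + 1, r)

o_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- if (m > 0) o_cheb(x[i:(i + m - 1)], x[j:(j + m - 1)]) else 0
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(2 * log(n - m))
  if (A == 0) return(log(B) + log(n - m))
  -log(A / B)
}

o_fuzzy <- function(x, m, r, nexp = 2) {
  n <- length(x)
  nt <- n - m
  phi <- function(mm) {
    tot <- 0; np <- 0
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        wi <- x[i:(i + mm - 1)]; wj <- x[j:(j + mm - 1)]
        d <- o_cheb(wi - mean(wi), wj - mean(wj))
        tot <- tot + exp(-(d / r)^nexp)
        np <- np + 1
      }
    }
    tot / np
  }
  log(phi(m)) - log(phi(m + 1))
}

o_permen <- function(x, m, tau = 1) {
  n <- length(x)
  nt <- n - (m - 1) * tau
  pats <- character(nt)
  for (i in seq_len(nt))
    pats[i] <- paste(order(x[i + (0:(m - 1)) * tau]), collapse = ".")
  p <- as.numeric(table(pats)); p <- p / sum(p)
  -sum(p * log2(p)) / log2(factorial(m))
}

o_dispen <- function(x, m, cc, tau = 1) {
  s <- sd(x)
  y <- if (s > 0) pnorm(x, mean(x), s) else rep(0.5, length(x))
  z <- pmin(pmax(round(cc * y + 0.5), 1), cc)
  nt <- length(x) - (m - 1) * tau
  pats <- character(nt)
  for (i in seq_len(nt))
    pats[i] <- paste(z[i + (0:(m - 1)) * tau], collapse = ".")
  p <- as.numeric(table(pats)); p <- p / sum(p)
  -sum(p * log(p)) / log(cc^m)
}

o_disten <- function(x, m, nb) {
  n <- length(x); nt <- n - m + 1
  d <- c()
  for (i in seq_len(nt - 1))
    for (j in (i + 1):nt)
      d <- c(d, o_cheb(x[i:(i + m - 1)], x[j:(j + m - 1)]))
  dmax <- max(d)
  b <- if (dmax > 0) pmin(floor(d / dmax * nb), nb - 1) else rep(0, length(d))
  p <- as.numeric(table(b)); p <- p / sum(p)
  -sum(p * log2(p)) / log2(nb)
}

o_rangeen <- function(x, m, r) {
  n <- length(x); nt <- n - m
  rdist <- function(wi, wj) {
    a <- abs(wi - wj)
    if (max(a) + min(a) > 0) (max(a) - min(a)) / (max(a) + min(a)) else 0
  }
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (rdist(x[i:(i + m - 1)], x[j:(j + m - 1)]) <= r) {
        B <- B + 1
        if (rdist(x[i:(i + m)], x[j:(j + m)]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(2 * log(n - m))
  if (A == 0) return(log(B) + log(n - m))
  -log(A / B)
}

o_cross_apen <- function(x, y, m, r) {
  phi <- function(mm) {
    if (mm == 0) return(0)
    n <- length(x); nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt))
        if (o_cheb(x[i:(i + mm - 1)], y[j:(j + mm - 1)]) <= r) cnt <- cnt + 1
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

o_cross_sampen <- function(x, y, m, r) {
  n <- length(x); nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      dm <- if (m > 0) o_cheb(x[i:(i + m - 1)], y[j:(j + m - 1)]) else 0
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - y[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(2 * log(n - m))
  if (A == 0) return(log(B) + log(n - m))
  -log(A / B)
}

o_cross_fuzzy <- function(x, y, m, r, nexp = 2) {
  n <- length(x); nt <- n - m
  phi <- function(mm) {
    tot <- 0
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        wi <- x[i:(i + mm - 1)]; wj <- y[j:(j + mm - 1)]
        d <- o_cheb(wi - mean(wi), wj - mean(wj))
        tot <- tot + exp(-(d / r)^nexp)
      }
    }
    tot / nt^2
  }
  log(phi(m)) - log(phi(m + 1))
}

o_cross_k2 <- function(x, y, m, r) {
  cs <- function(mm) {
    n <- length(x); nt <- n - mm + 1
    cnt <- 0
    for (i in seq_len(nt))
      for (j in seq_len(nt))
        if (o_cheb(x[i:(i + mm - 1)], y[j:(j + mm - 1)]) <= r) cnt <- cnt + 1
    cnt / nt^2
  }
  log(cs(m) / cs(m + 1))
}

# AUC as the pairwise rank statistic: P(score_pos > score_neg) + 0.5 ties
o_auc_rank <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force kNN with nearest-index tie-breaking
o_knn <- function(train, labels, query, k) {
  apply(query, 1, function(q) {
    d <- sqrt(rowSums(sweep(train, 2, q)^2))
    nb <- order(d)[seq_len(k)]
    v <- table(labels[nb])
    top <- names(v)[v == max(v)]
    if (length(top) == 1) top else labels[nb[1]]
  })
}
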
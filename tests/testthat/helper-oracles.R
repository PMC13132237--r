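# Independent brute-force reference implementations used to validate the
# package's entropy battery, LMFP chain and AUC metrics. Deliberately
# written from the mathematical definitions (explicit embeddings, pairwise
# distance matrices, naive parsers), not by calling package internals.

oracle_embed <- function(x, m, tau) {
  nm <- length(x) - (m - 1) * tau
  E <- matrix(0, nm, m)
  for (j in seq_len(m)) E[, j] <- x[seq_len(nm) + (j - 1) * tau]
  E
}

oracle_cheb_mat <- function(E) {
  D <- matrix(0, nrow(E), nrow(E))
  for (j in seq_len(ncol(E)))
    D <- pmax(D, abs(outer(E[, j], E[, j], "-")))
  D
}

oracle_sampen <- function(x, m = 2, tau = 1, r_frac = 0.2) {
  r <- r_frac * sd(x)
  nt <- length(x) - m * tau
  Em <- oracle_embed(x, m, tau)[seq_len(nt), , drop = FALSE]
  Em1 <- oracle_embed(x, m + 1, tau)
  up <- upper.tri(matrix(0, nt, nt))
  B <- sum(oracle_cheb_mat(Em)[up] <= r)
  A <- sum(oracle_cheb_mat(Em1)[up] <= r)
  -log(A / B)
}

oracle_apen <- function(x, m = 2, tau = 1, r_frac = 0.2) {
  r <- r_frac * sd(x)
  phi <- function(mm) {
    E <- oracle_embed(x, mm, tau)
    D <- oracle_cheb_mat(E)
    mean(log(rowSums(D <= r) / nrow(E)))
  }
  phi(m) - phi(m + 1)
}

oracle_perm <- function(x, m = 3, tau = 1) {
  E <- oracle_embed(x, m, tau)
  pat <- apply(E, 1, function(v) paste(order(v), collapse = "."))
  p <- table(pat) / length(pat)
  -sum(p * log(p))
}

oracle_disten <- function(x, m = 2, tau = 1, bins = 64) {
  E <- oracle_embed(x, m, tau)
  D <- oracle_cheb_mat(E)
  d <- D[upper.tri(D)]
  dmax <- max(d)
  b <- if (dmax > 0) pmin(floor(d / dmax * bins), bins - 1) else
    rep(0, length(d))
  p <- table(b) / length(b)
  -sum(p * log2(p)) / log2(bins)
}

oracle_incr <- function(x, m = 2, q = 4) {
  d <- diff(x)
  sig <- sd(d)
  mag <- if (is.na(sig) || sig == 0) rep(0, length(d)) else
    pmin(q, floor(abs(d) * q / sig))
  sym <- paste(sign(d), mag, sep = ":")
  nw <- length(sym) - m + 1
  words <- vapply(seq_len(nw), function(i)
    paste(sym[i:(i + m - 1)], collapse = "|"), character(1))
  p <- table(words) / length(words)
  -sum(p * log2(p))
}

# LZ76 phrase count by direct production parsing: each phrase is the
# longest prefix reproducible from the extended history, plus one symbol.
oracle_lz_count <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  i <- 1; cnt <- 0
  while (i <= n) {
    l <- 1
    while (i + l - 1 <= n &&
           grepl(substr(s, i, i + l - 1), substr(s, 1, i + l - 2),
                 fixed = TRUE)) l <- l + 1
    cnt <- cnt + 1
    i <- i + l
  }
  cnt
}

oracle_lz <- function(x) {
  bits <- as.integer(x > median(x))
  oracle_lz_count(bits) * log2(length(x)) / length(x)
}

oracle_single <- function(x, spec) {
  switch(spec$measure,
         sample = oracle_sampen(x, spec$m, spec$tau, spec$r),
         approximate = oracle_apen(x, spec$m, spec$tau, spec$r),
         permutation = oracle_perm(x, spec$m, spec$tau),
         distribution = oracle_disten(x, spec$m, spec$tau, spec$bins),
         incremental = oracle_incr(x, spec$m, spec$q),
         lempel_ziv = oracle_lz(x))
}

oracle_multiscale <- function(x, proc, base_spec, scale) {
  cg <- function(v, s, off = 0) {
    k <- (length(v) - off) %/% s
    vapply(seq_len(k), function(i)
      mean(v[(off + (i - 1) * s + 1):(off + i * s)]), numeric(1))
  }
  if (scale == 1) return(oracle_single(x, base_spec))
  switch(proc,
    coarse_graining = oracle_single(cg(x, scale), base_spec),
    time_shifted = mean(vapply(0:(scale - 1), function(o)
      oracle_single(x[seq(o + 1, length(x), by = scale)], base_spec),
      numeric(1))),
    composite = mean(vapply(0:(scale - 1), function(o)
      oracle_single(cg(x, scale, o), base_spec), numeric(1))))
}

# ROC-AUC as the concordant-pair fraction (ties count one half).
oracle_roc_auc <- function(y, score) {
  pos <- score[y == "positive"]
  neg <- score[y == "negative"]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Direct evaluation of the field-power dispersion formula.
oracle_lmfp <- function(trial, roi, t) {
  v <- trial[roi, , drop = FALSE]
  k <- nrow(v)
  out <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    vb <- mean(v[, j])
    out[j] <- sqrt(sum((v[, j] - vb)^2) / k)
  }
  out
}

expect_entropy_equal <- function(got, want, tol = 1e-10) {
  if (!is.finite(want) || !is.finite(got)) {
    testthat::expect_identical(is.finite(got), is.finite(want))
  } else {
    testthat::expect_lt(abs(got - want), tol)
  }
}
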
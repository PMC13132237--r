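#' Specify a single-scale entropy measure
#'
#' Describes one member of the entropy battery computed from baseline
#' resting-state EEG. Template-matching measures (approximate, sample,
#' distribution entropy) embed the series with dimension `m` and delay
#' `tau`; the matching tolerance for approximate/sample entropy is
#' `r * sd(series)`, so those measures are invariant to positive affine
#' rescaling of the input.
#'
#' Measures and conventions:
#' * `approximate`: Pincus ApEn, natural log.
#' * `sample`: Richman-Moorman SampEn, natural log; a constant series
#'   returns 0 (with a note) since every template trivially matches.
#' * `permutation`: Shannon entropy (nats) of ordinal patterns of length
#'   `m`; ties are broken by temporal index (stable), so the measure is
#'   deterministic on quantised data.
#' * `distribution`: Shannon entropy (bits, normalised by `log2(bins)`) of
#'   the histogram of pairwise Chebyshev inter-template distances.
#' * `incremental`: sign/magnitude coding of successive increments at
#'   resolution `q`, Shannon entropy (bits) of overlapping words of length
#'   `m`. The coding is a documented in-package formulation with exposed
#'   parameters.
#' * `lempel_ziv`: LZ76 phrase count of the median-binarised series,
#'   normalised by `n / log2(n)`.
#'
#' @param measure One of `"approximate"`, `"sample"`, `"permutation"`,
#'   `"distribution"`, `"incremental"`, `"lempel_ziv"`.
#' @param m Embedding dimension (pattern/word length), `>= 2` where used.
#' @param tau Embedding delay in samples, `>= 1`.
#' @param r Tolerance as a fraction of the series SD (approximate/sample).
#' @param bins Histogram bin count for distribution entropy.
#' @param q Magnitude resolution for incremental entropy.
#' @return An object of class `entropy_spec`.
#' @export
entropy_spec <- function(measure = c("approximate", "sample", "permutation",
                                     "distribution", "incremental",
                                     "lempel_ziv"),
                         m = 2L, tau = 1L, r = 0.2, bins = 64L, q = 4L) {
  measure <- match.arg(measure)
  m <- as.integer(m); tau <- as.integer(tau)
  if (measure %in% c("approximate", "sample", "permutation", "distribution",
                     "incremental") && m < 2L)
    stop("embedding dimension m must be >= 2 for measure '", measure, "'")
  if (tau < 1L) stop("embedding delay tau must be >= 1")
  if (r <= 0) stop("tolerance fraction r must be > 0")
  if (bins < 2L) stop("distribution entropy needs bins >= 2")
  if (q < 1L) stop("incremental entropy needs q >= 1")
  structure(list(measure = measure, m = m, tau = tau, r = r,
                 bins = as.integer(bins), q = as.integer(q)),
            class = "entropy_spec")
}

#' @export
format.entropy_spec <- function(x, ...) {
  code <- switch(x$measure,
                 approximate = paste0("apen_m", x$m),
                 sample = paste0("sampen_m", x$m),
                 permutation = paste0("perm_m", x$m),
                 distribution = paste0("disten_m", x$m),
                 incremental = paste0("incr_m", x$m),
                 lempel_ziv = "lz")
  if (x$tau != 1L) code <- paste0(code, "_tau", x$tau)
  code
}

#' @export
print.entropy_spec <- function(x, ...) {
  cat("<entropy_spec>", format(x), "\n"); invisible(x)
}

check_series <- function(series, spec) {
  if (!is.numeric(series)) stop("series must be numeric")
  if (anyNA(series) || any(!is.finite(series)))
    stop("series contains non-finite values")
  need <- 10L * spec$m
  if (length(series) < need)
    stop("series too short: length ", length(series), " < ", need,
         " (10 * m) required for measure '", spec$measure, "'")
}

# Ordinal pattern codes with stable (temporal-index) tie-breaking: the rank
# of element j within a pattern is the count of elements strictly smaller,
# plus earlier-index elements that are equal.
ordinal_pattern_codes <- function(series, m, tau) {
  n <- length(series)
  nm <- n - (m - 1L) * tau
  cols <- lapply(seq_len(m) - 1L, function(k) series[seq_len(nm) + k * tau])
  codes <- integer(nm)
  for (j in seq_len(m)) {
    rj <- integer(nm)
    for (k in seq_len(m)) {
      if (k == j) next
      if (k < j) rj <- rj + (cols[[k]] <= cols[[j]])
      else       rj <- rj + (cols[[k]] <  cols[[j]])
    }
    codes <- codes + rj * m^(j - 1L)
  }
  codes
}

shannon <- function(counts, base = exp(1)) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(base)
}

# Incremental-entropy symbol coding: increments are coded as a (sign,
# magnitude) pair, magnitude quantised against the SD of the increments at
# resolution q.
incremental_codes <- function(series, q) {
  d <- diff(series)
  s <- sign(d)
  sig <- stats::sd(d)
  qi <- if (is.na(sig) || sig == 0) integer(length(d))
        else pmin(q, floor(abs(d) * q / sig))
  as.integer((s + 1) * (q + 1) + qi)
}

#' Single-scale entropy of a series
#'
#' Evaluates one entropy measure on a numeric series. See [entropy_spec()]
#' for the measure definitions and conventions.
#'
#' @param series Numeric vector, finite, length at least `10 * m`.
#' @param spec An [entropy_spec()].
#' @return A scalar entropy value.
#' @export
single_scale_entropy <- function(series, spec) {
  stopifnot(inherits(spec, "entropy_spec"))
  check_series(series, spec)
  n <- length(series)
  switch(spec$measure,
    sample = {
      sdev <- stats::sd(series)
      if (sdev == 0) {
        message("sample entropy: constant series, returning 0")
        return(0)
      }
      cnt <- sampen_counts_cpp(series, spec$m, spec$tau, spec$r * sdev)
      -log(cnt[2] / cnt[1])  # Inf when no (m+1)-matches, NaN when none at m
    },
    approximate = {
      sdev <- stats::sd(series)
      r <- spec$r * max(sdev, .Machine$double.xmin)
      apen_phi_cpp(series, spec$m, spec$tau, r) -
        apen_phi_cpp(series, spec$m + 1L, spec$tau, r)
    },
    permutation = {
      codes <- ordinal_pattern_codes(series, spec$m, spec$tau)
      shannon(tabulate(codes + 1L))
    },
    distribution = {
      h <- disten_hist_cpp(series, spec$m, spec$tau, spec$bins)
      shannon(h, base = 2) / log2(spec$bins)
    },
    incremental = {
      codes <- incremental_codes(series, spec$q)
      m <- spec$m
      nw <- length(codes) - m + 1L
      base <- 3L * (spec$q + 1L)
      word <- integer(nw)
      for (k in seq_len(m))
        word <- word + codes[seq_len(nw) + k - 1L] * base^(k - 1L)
      shannon(table(word), base = 2)
    },
    lempel_ziv = {
      bits <- as.integer(series > stats::median(series))
      lz76_cpp(bits) * log2(n) / n
    })
}

#' Specify a multiscale entropy procedure
#'
#' Combines a base entropy measure with one of three scale-composition
#' schemes over temporal scales `1..scales`:
#' * `coarse_graining`: non-overlapping window means at scale `s`, entropy
#'   of the reduced series.
#' * `time_shifted`: entropy of each of the `s` lag-subsampled series
#'   (offsets `0..s-1`), averaged.
#' * `composite`: entropy of each of the `s` shifted coarse-grainings at
#'   scale `s`, averaged.
#'
#' All three reduce to the single-scale measure at scale 1.
#'
#' @param procedure One of `"coarse_graining"`, `"time_shifted"`,
#'   `"composite"`.
#' @param base An [entropy_spec()]; the multiscale battery is restricted to
#'   permutation (m = 2 or 3), sample and distribution entropy.
#' @param scales Number of temporal scales (contiguous from 1).
#' @return An object of class `multiscale_spec`.
#' @export
multiscale_spec <- function(procedure = c("coarse_graining", "time_shifted",
                                          "composite"),
                            base = entropy_spec("sample"), scales = 20L) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(base, "entropy_spec"))
  if (!base$measure %in% c("permutation", "sample", "distribution"))
    stop("multiscale base measure must be permutation, sample or ",
         "distribution entropy")
  scales <- as.integer(scales)
  if (scales < 1L) stop("scales must be >= 1")
  structure(list(procedure = procedure, base = base, scales = scales),
            class = "multiscale_spec")
}

#' @export
format.multiscale_spec <- function(x, ...) {
  code <- switch(x$procedure, coarse_graining = "cgmse",
                 time_shifted = "tsmse", composite = "cmse")
  paste0(code, "_", format(x$base))
}

#' @export
print.multiscale_spec <- function(x, ...) {
  cat("<multiscale_spec>", format(x), "over", x$scales, "scales\n")
  invisible(x)
}

coarse_grain <- function(series, s, offset = 0L) {
  n <- length(series) - offset
  k <- n %/% s
  if (k < 1L) return(numeric(0))
  colMeans(matrix(series[offset + seq_len(k * s)], nrow = s))
}

#' Multiscale entropy curve
#'
#' Entropy of a series at each temporal scale under the spec's composition
#' scheme. The series must be long enough that the scale-`scales` reduced
#' series still meets the base measure's length precondition.
#'
#' @param series Numeric vector.
#' @param spec A [multiscale_spec()].
#' @return An object of class `multiscale_curve` with fields `values`
#'   (entropy per scale) and `spec`.
#' @export
multiscale_curve <- function(series, spec) {
  stopifnot(inherits(spec, "multiscale_spec"))
  need <- 10L * spec$base$m
  n <- length(series)
  for (s in seq_len(spec$scales)) {
    # worst case over the shift offsets used by the procedure
    len_s <- switch(spec$procedure,
                    coarse_graining = n %/% s,
                    time_shifted = (n - s) %/% s + 1L,
                    composite = (n - s + 1L) %/% s)
    if (len_s < need)
      stop("series too short for scale ", s, ": reduced length ", len_s,
           " < ", need)
  }
  values <- vapply(seq_len(spec$scales), function(s) {
    if (s == 1L) return(single_scale_entropy(series, spec$base))
    switch(spec$procedure,
      coarse_graining =
        single_scale_entropy(coarse_grain(series, s), spec$base),
      time_shifted = mean(vapply(seq_len(s) - 1L, function(o)
        single_scale_entropy(series[seq(o + 1L, length(series), by = s)],
                             spec$base), numeric(1))),
      composite = mean(vapply(seq_len(s) - 1L, function(o)
        single_scale_entropy(coarse_grain(series, s, o), spec$base),
        numeric(1))))
  }, numeric(1))
  structure(list(values = values, spec = spec), class = "multiscale_curve")
}

#' Complexity index of a multiscale curve
#'
#' Area under the entropy-versus-scale curve by the trapezoid rule on the
#' unit-spaced scale axis. Linear in the curve values; a constant curve
#' `c` over 20 scales gives `19 c`.
#'
#' @param curve A [multiscale_curve()] (or a bare numeric vector of
#'   per-scale entropies).
#' @return Scalar area under the curve.
#' @export
complexity_index <- function(curve) {
  v <- if (inherits(curve, "multiscale_curve")) curve$values else curve
  if (length(v) < 2L) stop("need at least 2 scales for an AUC")
  sum((v[-1] + v[-length(v)]) / 2)
}

#' Default entropy battery
#'
#' The six single-scale measures (approximate, sample, permutation m = 3,
#' distribution, incremental, Lempel-Ziv) and the twelve multiscale
#' combinations (permutation m = 2 and 3, sample, distribution, each under
#' coarse-graining, time-shifted and composite procedures). The battery is
#' configurable; this is the default set.
#'
#' @param scales Scales for the multiscale members.
#' @return A list with elements `single` and `multiscale`.
#' @export
default_entropy_battery <- function(scales = 20L) {
  single <- list(entropy_spec("approximate", m = 2),
                 entropy_spec("sample", m = 2),
                 entropy_spec("permutation", m = 3),
                 entropy_spec("distribution", m = 2),
                 entropy_spec("incremental", m = 2),
                 entropy_spec("lempel_ziv"))
  bases <- list(entropy_spec("permutation", m = 2),
                entropy_spec("permutation", m = 3),
                entropy_spec("sample", m = 2),
                entropy_spec("distribution", m = 2))
  multiscale <- list()
  for (proc in c("coarse_graining", "time_shifted", "composite"))
    for (b in bases)
      multiscale[[length(multiscale) + 1L]] <-
        multiscale_spec(proc, base = b, scales = scales)
  list(single = single, multiscale = multiscale)
}

#' Complexity features of one session
#'
#' Per channel, concatenates the first six 10-s epochs of resting-state EEG
#' into one 60-s series and evaluates every single-scale entropy and every
#' multiscale complexity index on it.
#'
#' @param session A `session_record`.
#' @param battery As returned by [default_entropy_battery()].
#' @param n_epochs_used Number of leading epochs concatenated (default 6,
#'   one minute at 10-s epochs).
#' @return Long data frame `session_id, channel, feature, value`.
#' @export
session_complexity_features <- function(session,
                                        battery = default_entropy_battery(),
                                        n_epochs_used = 6L) {
  stopifnot(inherits(session, "session_record"))
  eeg <- session$rs_eeg
  if (dim(eeg)[1] < n_epochs_used)
    stop("session has ", dim(eeg)[1], " epochs; ", n_epochs_used,
         " required for the 1-minute complexity series")
  channels <- dimnames(eeg)[[2]]
  out <- list()
  for (ch in channels) {
    series <- as.vector(t(eeg[seq_len(n_epochs_used), ch, ]))
    vals <- c(
      vapply(battery$single, function(sp)
        single_scale_entropy(series, sp), numeric(1)),
      vapply(battery$multiscale, function(sp)
        complexity_index(multiscale_curve(series, sp)), numeric(1)))
    names(vals) <- c(
      vapply(battery$single, function(sp) paste0("en_", format(sp)),
             character(1)),
      vapply(battery$multiscale, function(sp) paste0(format(sp), "_ci"),
             character(1)))
    out[[ch]] <- data.frame(session_id = session$session_id, channel = ch,
                            feature = names(vals), value = unname(vals),
                            row.names = NULL)
  }
  do.call(rbind, out)
}
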
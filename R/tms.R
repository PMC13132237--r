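#' Left motor region of interest
#'
#' EEG channels over the left motor cortex used for the local mean field
#' power: C1, C3, C5, FC1, FC3, FC5.
#'
#' @return Character vector of channel names.
#' @export
left_motor_channels <- function() c("C1", "C3", "C5", "FC1", "FC3", "FC5")

#' Time window (ms)
#'
#' @param start_ms,end_ms Window edges in ms, `start < end`.
#' @return A `window` object.
#' @export
tep_window <- function(start_ms, end_ms) {
  if (!(start_ms < end_ms)) stop("window start must be before end")
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "window")
}

#' @export
format.window <- function(x, ...) paste0(x$start_ms, "-", x$end_ms, "ms")

#' Local mean field power of one TEP trial
#'
#' At each time point, the root-mean-square dispersion of the ROI channel
#' voltages around their instantaneous ROI mean:
#' `sqrt(sum_i (V_i(t) - Vbar(t))^2 / K)` with `K` the ROI channel count.
#' The denominator is `K`, not `K - 1` (field-power convention).
#' Invariant to adding a common offset to all ROI channels.
#'
#' @param trial Channels x time matrix with channel rownames.
#' @param roi Channel names to use.
#' @param t Time axis in ms (0 = TMS pulse), one value per column.
#' @return An `lmfp_curve`: fields `t`, `value` (uV), `K`, `roi`.
#' @export
lmfp_curve <- function(trial, roi = left_motor_channels(),
                       t = as.numeric(colnames(trial))) {
  missing_ch <- setdiff(roi, rownames(trial))
  if (length(missing_ch))
    stop("ROI channel(s) missing from trial: ",
         paste(missing_ch, collapse = ", "))
  v <- trial[roi, , drop = FALSE]
  k <- length(roi)
  dev <- sweep(v, 2, colMeans(v))
  structure(list(t = t, value = sqrt(colSums(dev^2) / k), K = k, roi = roi),
            class = "lmfp_curve")
}

# Composite Simpson integral of uniformly sampled values y over their full
# span; even sample counts get a trapezoid correction on the last interval.
simpson_uniform <- function(y, h) {
  n <- length(y)
  if (n < 3) stop("composite Simpson needs at least 3 samples")
  if (n %% 2 == 1) {
    idx <- seq_len(n)
    w <- rep(c(2, 4), length.out = n)
    w[1] <- w[n] <- 1
    sum(w * y) * h / 3
  } else {
    simpson_uniform(y[-n], h) + h * (y[n - 1] + y[n]) / 2
  }
}

#' Window AUC of an LMFP curve
#'
#' Composite-Simpson integral of the curve over a time window. Samples with
#' `start <= t <= end` are used; an even in-window count uses the trapezoid
#' correction on the final interval.
#'
#' @param curve An [lmfp_curve()].
#' @param w A [tep_window()].
#' @return Scalar AUC (uV * ms).
#' @export
window_auc <- function(curve, w) {
  stopifnot(inherits(curve, "lmfp_curve"), inherits(w, "window"))
  sel <- curve$t >= w$start_ms & curve$t <= w$end_ms
  if (sum(sel) < 3)
    stop("window ", format(w), " covers fewer than 3 samples")
  tt <- curve$t[sel]
  h <- diff(tt)
  if (max(h) - min(h) > 1e-9 * max(h))
    stop("window AUC requires a uniform time axis inside the window")
  simpson_uniform(curve$value[sel], h[1])
}

#' Trial-averaged window AUC of a TEP block
#'
#' Per-trial LMFP curve, per-trial window AUC, arithmetic mean across
#' trials.
#'
#' @param block Trials x channels x time array (channel dimnames).
#' @param roi Channel names.
#' @param w A [tep_window()].
#' @param t Time axis in ms.
#' @return Scalar mean AUC.
#' @export
block_lmfp_auc <- function(block, roi = left_motor_channels(), w,
                           t = as.numeric(dimnames(block)[[3]])) {
  n_tr <- dim(block)[1]
  if (n_tr < 1) stop("block has no trials")
  mean(vapply(seq_len(n_tr), function(i)
    window_auc(lmfp_curve(block[i, , ], roi, t), w), numeric(1)))
}

#' Regression quality score of TEP trial consistency
#'
#' For each trial, the ROI-averaged waveform inside the fit window is
#' regressed onto the leave-one-out average of the remaining trials; the
#' score is the median across trials of the squared correlation of that
#' fit, in `[0, 1]`. Identical non-constant trials score 1; independent
#' noise scores near 0.
#'
#' This concrete formula is an in-package composite approximating the
#' published regression-based consistency score, whose exact formulation
#' is not restated here; treat absolute values as pipeline-internal.
#'
#' @param block Trials x channels x time array.
#' @param roi Channel names.
#' @param fit_window A [tep_window()] (default 15-300 ms).
#' @param t Time axis in ms.
#' @return Scalar score in `[0, 1]`.
#' @export
rqs <- function(block, roi = left_motor_channels(),
                fit_window = tep_window(15, 300),
                t = as.numeric(dimnames(block)[[3]])) {
  n_tr <- dim(block)[1]
  if (n_tr < 2) stop("regression quality score needs at least 2 trials")
  sel <- t >= fit_window$start_ms & t <= fit_window$end_ms
  if (sum(sel) < 3) stop("fit window covers fewer than 3 samples")
  waves <- t(vapply(seq_len(n_tr), function(i) {
    m <- block[i, roi, sel, drop = FALSE]
    dim(m) <- dim(m)[2:3]
    colMeans(m)
  }, numeric(sum(sel))))
  tot <- colSums(waves)
  r2 <- vapply(seq_len(n_tr), function(i) {
    ref <- (tot - waves[i, ]) / (n_tr - 1)
    if (stats::sd(waves[i, ]) == 0 || stats::sd(ref) == 0) {
      message("rqs: zero-variance trial ", i, ", scoring 0")
      return(0)
    }
    stats::cor(waves[i, ], ref)^2
  }, numeric(1))
  stats::median(r2)
}

#' Baseline (pre-TBS) TMS features of one session
#'
#' MEP experiments use all four features (MEP mean and SD, left-motor LMFP
#' AUC over 15-80 ms, regression quality score); LMFP-ratio experiments use
#' only the two TEP-derived features, capturing the local response.
#'
#' @param session A `session_record`.
#' @param mode `"mep_experiment"` (4 features) or `"lmfp_experiment"`
#'   (2 features).
#' @param roi Channels for the LMFP.
#' @return Named numeric vector of features (`pre_` prefix).
#' @export
baseline_features <- function(session,
                              mode = c("mep_experiment", "lmfp_experiment"),
                              roi = left_motor_channels()) {
  mode <- match.arg(mode)
  stopifnot(inherits(session, "session_record"))
  tep <- session$tep_blocks[["pre"]]
  if (is.null(tep)) stop("session is missing the pre-TBS TEP block")
  t <- session$tep_time
  lmfp <- block_lmfp_auc(tep, roi, tep_window(15, 80), t)
  score <- rqs(tep, roi, t = t)
  out <- c(pre_lmfp_auc_15_80 = lmfp, pre_rqs = score)
  if (mode == "mep_experiment") {
    mep <- session$mep_blocks[["pre"]]
    if (is.null(mep)) stop("session is missing the pre-TBS MEP block")
    out <- c(pre_mep_mean = mean(mep), pre_mep_sd = stats::sd(mep), out)
  }
  out
}
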
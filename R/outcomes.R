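#' Categorization method for iTBS outcomes
#'
#' Either an MEP t-test outcome (`mep_t5`, `mep_t25`) or an LMFP-ratio
#' outcome for one time window (`lmfp_window`).
#'
#' @param kind `"mep_t5"`, `"mep_t25"` or `"lmfp_window"`.
#' @param window A [tep_window()]; required iff `kind = "lmfp_window"`.
#' @return A `categorization_method`.
#' @export
categorization_method <- function(kind = c("mep_t5", "mep_t25",
                                           "lmfp_window"),
                                  window = NULL) {
  kind <- match.arg(kind)
  if (kind == "lmfp_window") {
    if (is.null(window) || !inherits(window, "window"))
      stop("lmfp_window methods require a window")
  } else if (!is.null(window)) {
    stop("window is only meaningful for lmfp_window methods")
  }
  structure(list(kind = kind, window = window),
            class = "categorization_method")
}

#' @export
format.categorization_method <- function(x, ...) {
  if (x$kind == "lmfp_window") paste0("lmfp_", x$window$start_ms, "_",
                                      x$window$end_ms)
  else x$kind
}

#' MEP responder label from pre/post amplitude distributions
#'
#' Two-tailed two-sample t-test comparing peak-to-peak MEP amplitudes
#' before versus after stimulation. A session is a responder when
#' `p <= alpha` in either direction (facilitation or suppression); the
#' boundary is inclusive. Welch's test by default (switchable to pooled
#' variance). Degenerate zero-variance blocks with equal means give
#' `p = 1` (non-responder).
#'
#' @param pre,post Amplitude vectors (uV), length >= 2 each.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pool variances instead of Welch.
#' @return List `p` (p-value) and `label` (`"positive"` for responder,
#'   `"negative"` otherwise).
#' @export
mep_label <- function(pre, post, alpha = 0.05, var_equal = FALSE) {
  if (length(pre) < 2 || length(post) < 2)
    stop("need at least 2 amplitudes per block")
  if (stats::sd(pre) == 0 && stats::sd(post) == 0) {
    p <- if (mean(pre) == mean(post)) 1 else 0
  } else {
    p <- stats::t.test(pre, post, var.equal = var_equal)$p.value
  }
  list(p = p, label = if (p <= alpha) "positive" else "negative")
}

#' LMFP ratio between post- and pre-TBS blocks
#'
#' Ratio of the trial-averaged window AUC of the local mean field power,
#' post over pre. A ratio `>= 1` is labelled facilitation (positive class),
#' `< 1` suppression.
#'
#' @param pre_block,post_block Trials x channels x time arrays.
#' @param roi Channel names.
#' @param w A [tep_window()].
#' @param t Time axis in ms.
#' @return List `ratio` and `label`.
#' @export
lmfp_ratio <- function(pre_block, post_block, roi = left_motor_channels(),
                       w, t = as.numeric(dimnames(pre_block)[[3]])) {
  pre_auc <- block_lmfp_auc(pre_block, roi, w, t)
  if (pre_auc == 0) stop("pre-TBS LMFP AUC is 0; ratio undefined")
  post_auc <- block_lmfp_auc(post_block, roi, w, t)
  ratio <- post_auc / pre_auc
  list(ratio = ratio, label = if (ratio >= 1) "positive" else "negative")
}

default_apriori_windows <- function() {
  starts <- list(
    # component-anchored windows
    c(15, 45), c(15, 80), c(20, 40), c(30, 60), c(45, 75), c(60, 90),
    c(80, 140), c(90, 120), c(100, 131),
    # half-offset 30 ms windows
    c(40, 70), c(70, 100), c(100, 130), c(130, 160), c(160, 190),
    c(190, 220), c(220, 250), c(250, 280), c(280, 310), c(310, 340),
    # 20 ms windows around canonical deflections
    c(35, 55), c(45, 65), c(55, 75), c(95, 115), c(105, 125), c(115, 135),
    c(170, 190), c(180, 200), c(190, 210), c(200, 220), c(240, 260),
    c(270, 290), c(300, 320))
  lapply(starts, function(s) tep_window(s[1], s[2]))
}

#' Build the LMFP categorization windows
#'
#' Union of a configured a-priori window list and a sweep of fixed-length
#' windows over a span (the final sweep window is flushed to the span end
#' so the whole span is covered), deduplicated and order-stable (a-priori
#' first, then the sweep). The default configuration yields 43 windows:
#' 32 a-priori plus the 11-window 30 ms sweep over 25-345 ms. The a-priori
#' list is editable (see `inst/extdata/lmfp_windows.json`); the set used
#' here is a configurable stand-in for the study's unpublished window
#' table, and includes the 100-131 ms and 85-115 ms windows named in the
#' main analyses.
#'
#' @param apriori List of [tep_window()]s (possibly empty).
#' @param sweep_span Numeric `c(lo, hi)` ms, or `NULL` for no sweep.
#' @param sweep_width Sweep window length (ms).
#' @param sweep_step Sweep step (ms).
#' @param coverage Numeric `c(lo, hi)` ms of available TEP support;
#'   windows outside it are an error.
#' @return List of [tep_window()]s.
#' @export
make_windows <- function(apriori = default_apriori_windows(),
                         sweep_span = c(25, 345), sweep_width = 30,
                         sweep_step = 30, coverage = NULL) {
  if ((is.null(apriori) || length(apriori) == 0) && is.null(sweep_span))
    stop("window configuration is empty")
  wins <- as.list(apriori %||% list())
  if (!is.null(sweep_span)) {
    starts <- seq(sweep_span[1], sweep_span[2] - sweep_width,
                  by = sweep_step)
    if (max(starts) + sweep_width < sweep_span[2])
      starts <- c(starts, sweep_span[2] - sweep_width)
    wins <- c(wins, lapply(starts, function(s)
      tep_window(s, s + sweep_width)))
  }
  keys <- vapply(wins, format, character(1))
  wins <- wins[!duplicated(keys)]
  if (!is.null(coverage)) {
    bad <- vapply(wins, function(w)
      w$start_ms < coverage[1] || w$end_ms > coverage[2], logical(1))
    if (any(bad))
      stop("window(s) outside TEP coverage: ",
           paste(vapply(wins[bad], format, character(1)), collapse = ", "))
  }
  wins
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label every session under one categorization method
#'
#' Applies [mep_label()] or [lmfp_ratio()] to each session; sessions
#' missing a required block are skipped with a warning. Deterministic and
#' invariant to session order.
#'
#' @param sessions List of `session_record`s.
#' @param method A [categorization_method()].
#' @param post_block Post-TBS block used by LMFP methods (`"T5"` or
#'   `"T25"`); MEP methods imply their block.
#' @param roi Channels for LMFP methods.
#' @param alpha MEP significance level.
#' @return A `label_set`: data frame `session_id, method, diagnostic,
#'   label` with the method stored as an attribute.
#' @export
label_all <- function(sessions, method, post_block = c("T5", "T25"),
                      roi = left_motor_channels(), alpha = 0.05) {
  stopifnot(inherits(method, "categorization_method"))
  post_block <- match.arg(post_block)
  post_name <- switch(method$kind, mep_t5 = "T5", mep_t25 = "T25",
                      post_block)
  rows <- lapply(sessions, function(s) {
    if (method$kind %in% c("mep_t5", "mep_t25")) {
      pre <- s$mep_blocks[["pre"]]
      post <- s$mep_blocks[[post_name]]
      if (is.null(pre) || is.null(post)) {
        warning("session ", s$session_id, " missing MEP block; skipped")
        return(NULL)
      }
      r <- mep_label(pre, post, alpha = alpha)
      data.frame(session_id = s$session_id, method = format(method),
                 diagnostic = r$p, label = r$label)
    } else {
      pre <- s$tep_blocks[["pre"]]
      post <- s$tep_blocks[[post_name]]
      if (is.null(pre) || is.null(post)) {
        warning("session ", s$session_id, " missing TEP block; skipped")
        return(NULL)
      }
      r <- lmfp_ratio(pre, post, roi, method$window, s$tep_time)
      data.frame(session_id = s$session_id, method = format(method),
                 diagnostic = r$ratio, label = r$label)
    }
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  structure(out, method = method, class = c("label_set", "data.frame"))
}
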
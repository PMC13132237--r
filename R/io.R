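#' Write a session bundle to disk
#'
#' One directory per session, all plain text: `manifest.json` (identity,
#' sampling rate, channel list, TEP time axis, block inventory),
#' `rs_eeg.csv` (one row per epoch x channel, samples as columns),
#' `mep_<block>.csv` (one amplitude per row) and `tep_<block>.csv` (one
#' row per trial x channel, time points as columns).
#'
#' @param session A [session_record()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    session_id = session$session_id, subject_id = session$subject_id,
    cohort_id = session$cohort_id, visit = session$visit, fs = session$fs,
    channels = session$channels %||% dimnames(session$rs_eeg)[[2]] %||%
      dimnames(session$tep_blocks[[1]])[[2]],
    tep_time_ms = session$tep_time,
    mep_blocks = names(session$mep_blocks),
    tep_blocks = names(session$tep_blocks),
    has_rs_eeg = !is.null(session$rs_eeg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # %.17g round-trips doubles exactly through text
  num17 <- function(m) {
    out <- matrix(sprintf("%.17g", m), nrow = nrow(m))
    colnames(out) <- colnames(m)
    out
  }
  if (!is.null(session$rs_eeg)) {
    d <- dim(session$rs_eeg)
    flat <- matrix(aperm(session$rs_eeg, c(3, 2, 1)), nrow = d[1] * d[2],
                   byrow = TRUE)
    df <- data.frame(epoch = rep(seq_len(d[1]), each = d[2]),
                     channel = rep(dimnames(session$rs_eeg)[[2]], d[1]),
                     num17(flat), check.names = FALSE)
    colnames(df)[-(1:2)] <- paste0("s", seq_len(d[3]))
    utils::write.csv(df, file.path(dir, "rs_eeg.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  for (b in names(session$mep_blocks))
    utils::write.csv(
      data.frame(amplitude_uv = sprintf("%.17g", session$mep_blocks[[b]])),
      file.path(dir, paste0("mep_", b, ".csv")), row.names = FALSE,
      quote = FALSE)
  for (b in names(session$tep_blocks)) {
    arr <- session$tep_blocks[[b]]
    d <- dim(arr)
    flat <- matrix(aperm(arr, c(3, 2, 1)), nrow = d[1] * d[2],
                   byrow = TRUE)
    df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                     channel = rep(dimnames(arr)[[2]], d[1]),
                     num17(flat), check.names = FALSE)
    colnames(df)[-(1:2)] <- paste0("t", seq_len(d[3]))
    utils::write.csv(df, file.path(dir, paste0("tep_", b, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a session bundle
#'
#' Inverse of [write_session()]; validates payload dimensions against the
#' manifest and names the offending file on mismatch.
#'
#' @param dir Bundle directory containing `manifest.json`.
#' @return A [session_record()].
#' @export
read_session <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  channels <- manifest$channels
  rs_eeg <- NULL
  if (isTRUE(manifest$has_rs_eeg)) {
    f <- file.path(dir, "rs_eeg.csv")
    df <- utils::read.csv(f, check.names = FALSE)
    n_ep <- max(df$epoch)
    if (nrow(df) != n_ep * length(channels))
      stop("rs_eeg.csv: ", nrow(df), " rows inconsistent with ",
           length(channels), " manifest channels")
    n_samp <- ncol(df) - 2L
    rs_eeg <- array(0, dim = c(n_ep, length(channels), n_samp),
                    dimnames = list(NULL, channels, NULL))
    m <- as.matrix(df[, -(1:2)])
    for (i in seq_len(nrow(df)))
      rs_eeg[df$epoch[i], df$channel[i], ] <- m[i, ]
  }
  mep_blocks <- list()
  for (b in manifest$mep_blocks)
    mep_blocks[[b]] <-
      utils::read.csv(file.path(dir, paste0("mep_", b, ".csv")))$amplitude_uv
  tep_blocks <- list()
  for (b in manifest$tep_blocks) {
    f <- file.path(dir, paste0("tep_", b, ".csv"))
    df <- utils::read.csv(f, check.names = FALSE)
    n_tr <- max(df$trial)
    if (nrow(df) != n_tr * length(channels))
      stop(basename(f), ": ", nrow(df), " rows inconsistent with ",
           length(channels), " manifest channels")
    n_t <- ncol(df) - 2L
    if (n_t != length(manifest$tep_time_ms))
      stop(basename(f), ": ", n_t, " time columns but manifest declares ",
           length(manifest$tep_time_ms))
    arr <- array(0, dim = c(n_tr, length(channels), n_t),
                 dimnames = list(NULL, channels, manifest$tep_time_ms))
    m <- as.matrix(df[, -(1:2)])
    for (i in seq_len(nrow(df)))
      arr[df$trial[i], df$channel[i], ] <- m[i, ]
    tep_blocks[[b]] <- arr
  }
  session_record(
    session_id = manifest$session_id, subject_id = manifest$subject_id,
    cohort_id = manifest$cohort_id, visit = manifest$visit,
    fs = manifest$fs, rs_eeg = rs_eeg, mep_blocks = mep_blocks,
    tep_blocks = tep_blocks, tep_time = manifest$tep_time_ms)
}

#' Assemble the wide baseline feature table
#'
#' Runs the requested feature extractors over every session and pivots to
#' one row per session. Channel-wise features get `<feature>_<channel>`
#' column names; pre-TBS features keep their `pre_` names; the planted
#' generator trait (when present) appears as `planted_trait`.
#'
#' @param records List of [session_record()]s.
#' @param include Subset of `"spectral"`, `"complexity"`, `"tms"`,
#'   `"planted"`.
#' @param tms_mode Passed to [baseline_features()].
#' @param battery Passed to [session_complexity_features()].
#' @param bands Passed to [session_band_powers()].
#' @return Wide data frame with meta columns `session_id, subject_id,
#'   cohort, visit` (attribute `channels` = montage).
#' @export
feature_table <- function(records,
                          include = c("spectral", "complexity", "tms",
                                      "planted"),
                          tms_mode = "lmfp_experiment",
                          battery = default_entropy_battery(),
                          bands = default_bands()) {
  rows <- lapply(records, function(s) {
    vals <- numeric(0)
    if ("spectral" %in% include) {
      long <- session_band_powers(s, bands)
      v <- stats::setNames(long$value, paste0(long$feature, "_",
                                              long$channel))
      vals <- c(vals, v)
    }
    if ("complexity" %in% include) {
      long <- session_complexity_features(s, battery)
      v <- stats::setNames(long$value, paste0(long$feature, "_",
                                              long$channel))
      vals <- c(vals, v)
    }
    if ("tms" %in% include)
      vals <- c(vals, baseline_features(s, tms_mode))
    if ("planted" %in% include && !is.null(s$planted))
      vals <- c(vals, planted_trait = s$planted$trait)
    out <- data.frame(session_id = s$session_id,
                      subject_id = s$subject_id, cohort = s$cohort_id,
                      visit = s$visit)
    for (nm in names(vals)) out[[nm]] <- vals[[nm]]
    out
  })
  out <- do.call(rbind, rows)
  chans <- unique(unlist(lapply(records, function(s)
    dimnames(s$rs_eeg)[[2]] %||% dimnames(s$tep_blocks[[1]])[[2]])))
  attr(out, "channels") <- chans %||% character(0)
  out
}

#' Attach subject metadata to a label set
#'
#' @param labels A `label_set` (from [label_all()]).
#' @param records The session records the labels came from.
#' @return Data frame with added `subject_id`, `visit`, `cohort`.
#' @export
label_meta <- function(labels, records) {
  meta <- do.call(rbind, lapply(records, function(s)
    data.frame(session_id = s$session_id, subject_id = s$subject_id,
               visit = s$visit, cohort = s$cohort_id)))
  merge(meta, as.data.frame(labels), by = "session_id", sort = FALSE)
}

#' Run the full pipeline on one configuration
#'
#' Synthesis, feature extraction, outcome labelling, drift diagnostics
#' and one model-selection experiment, with per-stage file caching: when
#' `out_dir` is given and a stage's output file already exists (and
#' `overwrite` is `FALSE`), the cached file is read back instead of
#' recomputed, so a re-run is bit-identical and does no new work.
#'
#' @param config A [synth_config()].
#' @param methods Named list of [categorization_method()]s.
#' @param experiment Config list for [run_experiment()] (or `NULL` to
#'   skip).
#' @param design Experiment design.
#' @param include Feature extractors to run (see [feature_table()]).
#' @param battery,bands,tms_mode Passed to [feature_table()].
#' @param out_dir Optional output directory for CSV/JSON artefacts.
#' @param overwrite Recompute even if cached files exist.
#' @return List `records`, `accounting`, `features`, `label_sets`,
#'   `drift`, `report`.
#' @export
run_all <- function(config, methods, experiment = NULL,
                    design = "cross_session",
                    include = c("spectral", "complexity", "tms",
                                "planted"),
                    battery = default_entropy_battery(),
                    bands = default_bands(),
                    tms_mode = "lmfp_experiment",
                    out_dir = NULL, overwrite = FALSE) {
  cache <- function(name, fn, reader, writer) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      if (file.exists(path) && !overwrite) {
        message("run_all: using cached ", name)
        return(reader(path))
      }
      val <- fn()
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writer(val, path)
      return(val)
    }
    fn()
  }
  records <- generate_cohorts(config)
  accounting <- count_sessions(records)
  features <- cache("features.csv",
    function() feature_table(records, include = include,
                             battery = battery, bands = bands,
                             tms_mode = tms_mode),
    function(p) {
      df <- utils::read.csv(p)
      attr(df, "channels") <- config$channels
      df
    },
    function(v, p) utils::write.csv(v, p, row.names = FALSE))
  label_sets <- lapply(methods, function(m)
    label_meta(label_all(records, m), records))
  drift <- drift_report(features, label_sets)
  report <- NULL
  if (!is.null(experiment)) {
    labs <- lapply(label_sets, function(l)
      l[, c("session_id", "label")])
    report <- run_experiment(design, features, labs, experiment)
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(accounting = accounting,
           drift = list(verdict = drift$verdict,
                        frac_ks_significant = drift$frac_ks_significant,
                        frac_fisher_significant =
                          drift$frac_fisher_significant,
                        mean_feature_icc = drift$mean_feature_icc,
                        mean_kappa = drift$mean_kappa)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(records = records, accounting = accounting, features = features,
       label_sets = label_sets, drift = drift, report = report)
}

#' Read a window configuration file
#'
#' JSON (or YAML, if the yaml package is installed) list of
#' `[start, end]` pairs in ms.
#'
#' @param path File path.
#' @return List of [tep_window()]s.
#' @export
read_window_config <- function(path) {
  raw <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML window configs need the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.matrix(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(w) tep_window(w[[1]], w[[2]]))
}
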